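AA_20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Brute-force reference implementations (nested loops, no vectorized tricks)
# used as independent oracles for the scoring operations.

brute_entropy <- function(column) {
  chars <- column[!column %in% c("-", ".")]
  if (length(chars) == 0) return(NA_real_)
  h <- 0
  for (sym in unique(chars)) {
    p <- sum(chars == sym) / length(chars)
    h <- h - p * log2(p)
  }
  h
}

brute_min_score <- function(e, s, r, d) {
  n <- length(e)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- c(e[i], s[i], r[i], d[i])
    if (!any(is.na(v))) out[i] <- min(v)
  }
  out
}

brute_sum_score <- function(e, s, r, d, w = c(1.5, 1, 1, 1)) {
  n <- length(e)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- c(e[i], s[i], r[i], d[i])
    if (!any(is.na(v))) out[i] <- w[1] * v[1] + w[2] * v[2] + w[3] * v[3] + w[4] * v[4]
  }
  out
}

brute_smooth <- function(values, window = 7) {
  n <- length(values)
  half <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    acc <- 0
    k <- 0
    for (j in seq_len(n)) {
      if (j >= i - half && j <= i + half && !is.na(values[j])) {
        acc <- acc + values[j]
        k <- k + 1
      }
    }
    if (k > 0) out[i] <- acc / k
  }
  out
}

brute_rank <- function(smoothed, top_k = 5, min_separation = 8) {
  chosen <- integer(0)
  banned <- rep(FALSE, length(smoothed))
  banned[is.na(smoothed)] <- TRUE
  while (length(chosen) < top_k) {
    best <- NA_integer_
    for (p in seq_along(smoothed)) {
      if (banned[p]) next
      if (is.na(best) || smoothed[p] > smoothed[best]) best <- p
    }
    if (is.na(best)) break
    chosen <- c(chosen, best)
    for (p in seq_along(smoothed)) {
      if (abs(p - best) <= min_separation) banned[p] <- TRUE
    }
  }
  chosen
}

# a random fully-populated normalized profile of the given length
random_profile_tracks <- function(n = 50) {
  list(
    e = runif(n), s = sample(c(0, 0.5, 1), n, replace = TRUE),
    r = runif(n), d = runif(n)
  )
}

# assemble a score_profile directly from numeric tracks
profile_from_tracks <- function(tr, weights = tag_weights(), window = 7) {
  q <- validate_sequence(paste(rep("A", length(tr$e)), collapse = ""), id = "SYN")
  build_profile(
    q,
    feature_track("entropy", tr$e, normalized = TRUE),
    feature_track("secondary_structure", tr$s),
    feature_track("rsa", tr$r),
    feature_track("dbr_complement", tr$d),
    weights = weights, window = window
  )
}

fixture_pipeline <- function(fx, ...) {
  q <- read_query_fasta(fx$paths[["query_fasta"]])
  msa <- read_alignment(fx$paths[["msa"]], query_id = fx$query_id, query = q)
  d <- parse_dssp(fx$paths[["dssp"]])
  a <- parse_iupred2a(fx$paths[["anchor"]], query = q)
  predict_tag_sites(q, msa, dssp = d, anchor = a, ...)
}
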