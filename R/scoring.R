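# The core scoring mathematics: feature normalization, the weighted sum
# score, the unweighted minimum tagging score, sliding-window smoothing and
# peak selection.

#' Maximum per-column entropy over the 20-residue alphabet
#'
#' `log2(20)`, approximately 4.32 bits: the entropy of a uniform column over
#' the 20 standard amino acids, used to normalize entropy to `[0, 1]`.
#'
#' @return A numeric scalar.
#' @export
max_entropy_bits <- function() log2(20)

#' Scoring weights
#'
#' Non-negative weights for the four features in the sum score. The default
#' up-weights conservation entropy to 1.5 and leaves the other three at 1.
#'
#' @param entropy,secondary_structure,rsa,dbr_complement Non-negative reals.
#' @return A named numeric vector of class `tag_weights`.
#' @export
tag_weights <- function(entropy = 1.5, secondary_structure = 1, rsa = 1,
                        dbr_complement = 1) {
  w <- c(entropy = entropy, secondary_structure = secondary_structure,
         rsa = rsa, dbr_complement = dbr_complement)
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("All weights must be finite and non-negative.", class = "tagsite_input_error")
  }
  structure(w, class = "tag_weights")
}

#' Normalize an entropy track to \[0, 1\]
#'
#' Divides per-position Shannon entropy (bits) by `log2(20)`, the maximum
#' possible entropy over the 20 amino acids.
#'
#' @param track A `tag_track` of entropies in bits, or a numeric vector.
#' @return A normalized `tag_track` (`entropy`).
#' @export
normalize_entropy <- function(track) {
  h <- track_values(track, what = "entropy track")
  if (any(h < -1e-9 | h > max_entropy_bits() + 1e-9, na.rm = TRUE)) {
    abort("Entropy values must lie in [0, log2(20)] bits.", class = "tagsite_input_error")
  }
  feature_track("entropy", h / max_entropy_bits(), normalized = TRUE)
}

#' Weighted sum score across the four normalized features
#'
#' `S_i = w1 * H_i/log2(20) + w2 * SS_i + w3 * RSA_i + w4 * (1 - BR_i)`.
#' A position with any missing feature gets a missing sum.
#'
#' @param entropy,ss,rsa,dbr Normalized tracks (or numeric vectors) of equal
#'   length: entropy/log2(20), binned secondary structure, relative solvent
#'   accessibility and the BR complement.
#' @param weights A [tag_weights()] vector.
#' @return Numeric vector `S`.
#' @export
sum_score <- function(entropy, ss, rsa, dbr, weights = tag_weights()) {
  v <- score_matrix(entropy, ss, rsa, dbr)
  as.numeric(v %*% unclass(weights))
}

#' Minimum tagging score across the four normalized features
#'
#' `E_i = min(H_i/log2(20), SS_i, RSA_i, 1 - BR_i)`: a position scores well
#' only when every feature simultaneously favours tagging. The minimum is
#' unweighted; weights enter the sum score only.
#'
#' @inheritParams sum_score
#' @return Numeric vector `E`.
#' @export
min_score <- function(entropy, ss, rsa, dbr) {
  v <- score_matrix(entropy, ss, rsa, dbr)
  out <- unname(pmin(v[, 1], v[, 2], v[, 3], v[, 4]))
  out[rowSums(is.na(v)) > 0] <- NA_real_
  out
}

score_matrix <- function(entropy, ss, rsa, dbr) {
  e <- track_values(entropy, what = "entropy")
  n <- length(e)
  m <- cbind(
    entropy = e,
    secondary_structure = track_values(ss, n, "secondary_structure"),
    rsa = track_values(rsa, n, "rsa"),
    dbr_complement = track_values(dbr, n, "dbr_complement")
  )
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    abort("All features must be normalized to [0, 1] before scoring.",
          class = "tagsite_input_error")
  }
  m
}

#' Centered sliding-window average
#'
#' Averages a per-residue vector over an odd-width centered window (default
#' 7). At the sequence edges the window shrinks to the available positions;
#' nothing is padded. Missing values are excluded from each local mean, and
#' a window containing only missing values yields a missing result.
#'
#' @param values Numeric vector.
#' @param window Odd positive integer window width.
#' @return Numeric vector of the same length.
#' @export
smooth_track <- function(values, window = 7) {
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 1 || window %% 2 != 1) {
    abort("`window` must be an odd positive integer.", class = "tagsite_input_error")
  }
  values <- as.numeric(values)
  n <- length(values)
  half <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- values[max(1L, i - half):min(n, i + half)]
    v <- v[!is.na(v)]
    if (length(v)) out[i] <- mean(v)
  }
  out
}

#' Assemble a score profile from the four feature tracks
#'
#' Normalizes the entropy track, computes the weighted sum score and the
#' minimum tagging score per position, and smooths the minimum score with a
#' centered sliding window. Optionally the individual features can be
#' smoothed before taking the minimum instead (`smooth_features = TRUE`);
#' the default smooths the per-position minimum, reproducing a single
#' smoothed suitability curve.
#'
#' @param query A `query_protein`.
#' @param entropy Entropy track in bits (from [entropy_track()]) or an
#'   already-normalized track.
#' @param ss,rsa,dbr Normalized tracks from [ss_track()], [rsa_track()],
#'   [dbr_complement_track()].
#' @param weights A [tag_weights()] vector.
#' @param window Odd smoothing window width (default 7 residues).
#' @param smooth_features Smooth each feature before the minimum instead of
#'   smoothing the minimum itself.
#' @return A `score_profile`: list with `query`, `scores` (tibble of
#'   per-position features and scores), `weights`, `window`.
#' @export
build_profile <- function(query, entropy, ss, rsa, dbr,
                          weights = tag_weights(), window = 7,
                          smooth_features = FALSE) {
  stopifnot(inherits(query, "query_protein"))
  if (!inherits(weights, "tag_weights")) weights <- do.call(tag_weights, as.list(weights))
  e_norm <- if (inherits(entropy, "tag_track") && track_normalized(entropy)) {
    track_values(entropy, query$length, "entropy")
  } else {
    track_values(normalize_entropy(entropy), query$length, "entropy")
  }
  s_vals <- track_values(ss, query$length, "secondary_structure")
  r_vals <- track_values(rsa, query$length, "rsa")
  d_vals <- track_values(dbr, query$length, "dbr_complement")
  if (isTRUE(smooth_features)) {
    e_used <- smooth_track(e_norm, window)
    s_used <- smooth_track(s_vals, window)
    r_used <- smooth_track(r_vals, window)
    d_used <- smooth_track(d_vals, window)
  } else {
    e_used <- e_norm; s_used <- s_vals; r_used <- r_vals; d_used <- d_vals
  }
  s_sum <- sum_score(e_used, s_used, r_used, d_used, weights)
  e_min <- min_score(e_used, s_used, r_used, d_used)
  scores <- tibble(
    position = seq_len(query$length),
    residue = query$residues,
    entropy_norm = e_norm,
    ss_score = s_vals,
    rsa = r_vals,
    dbr_complement = d_vals,
    sum_score = s_sum,
    min_score = e_min,
    min_score_smoothed = if (isTRUE(smooth_features)) e_min else smooth_track(e_min, window)
  )
  structure(
    list(query = query, scores = scores, weights = weights, window = window,
         smooth_features = isTRUE(smooth_features)),
    class = "score_profile"
  )
}

#' @export
print.score_profile <- function(x, ...) {
  cat(sprintf("<score_profile> %s: %d residues, window %d\n",
              x$query$id, x$query$length, x$window))
  best <- x$scores[which.max(x$scores$min_score_smoothed), ]
  if (nrow(best)) {
    cat(sprintf("  best smoothed min score %.3f at position %d (%s)\n",
                best$min_score_smoothed, best$position, best$residue))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.score_profile <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.score_profile <- function(x, ...) {
  sc <- x$scores
  best <- which.max(sc$min_score_smoothed)
  tibble(
    n_residues = nrow(sc),
    n_missing = sum(is.na(sc$min_score)),
    window = x$window,
    w_entropy = unname(x$weights["entropy"]),
    w_secondary_structure = unname(x$weights["secondary_structure"]),
    w_rsa = unname(x$weights["rsa"]),
    w_dbr_complement = unname(x$weights["dbr_complement"]),
    best_position = if (length(best)) sc$position[best] else NA_integer_,
    best_score = if (length(best)) sc$min_score_smoothed[best] else NA_real_
  )
}

#' Rank candidate insertion sites
#'
#' Sorts positions by the smoothed minimum tagging score (descending, ties
#' broken toward the N-terminus) and reports distinct peaks: once a site is
#' selected, every position within `min_separation` residues of it is
#' suppressed. Positions with a missing score are never selected.
#'
#' @param profile A `score_profile`.
#' @param top_k Maximum number of sites to report (default 5).
#' @param min_separation Minimum residue distance between reported sites
#'   (default 8, about one smoothing window).
#' @return A tibble of class `site_ranking` with columns `rank`, `position`,
#'   `residue`, `score` and the four per-position normalized feature values.
#' @export
rank_sites <- function(profile, top_k = 5, min_separation = 8) {
  stopifnot(inherits(profile, "score_profile"))
  if (!is.numeric(top_k) || top_k < 1) {
    abort("`top_k` must be at least 1.", class = "tagsite_input_error")
  }
  sc <- profile$scores
  cand <- sc[!is.na(sc$min_score_smoothed), ]
  cand <- cand[order(-cand$min_score_smoothed, cand$position), ]
  chosen <- integer(0)
  for (i in seq_len(nrow(cand))) {
    p <- cand$position[i]
    if (length(chosen) && any(abs(chosen - p) <= min_separation)) next
    chosen <- c(chosen, p)
    if (length(chosen) >= top_k) break
  }
  out <- sc[match(chosen, sc$position), c("position", "residue", "entropy_norm",
                                          "ss_score", "rsa", "dbr_complement",
                                          "min_score_smoothed")]
  out <- tibble(
    rank = seq_along(chosen),
    position = out$position,
    residue = out$residue,
    score = out$min_score_smoothed,
    entropy_norm = out$entropy_norm,
    ss_score = out$ss_score,
    rsa = out$rsa,
    dbr_complement = out$dbr_complement
  )
  class(out) <- c("site_ranking", class(out))
  attr(out, "query_id") <- profile$query$id
  out
}

#' Plot a score profile
#'
#' Draws the four normalized feature tracks and the smoothed minimum tagging
#' score along the sequence; optionally marks ranked sites with vertical
#' lines.
#'
#' @param object A `score_profile`.
#' @param sites Optional `site_ranking` to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.score_profile <- function(object, sites = NULL, ...) {
  long <- tidyr::pivot_longer(
    object$scores,
    cols = c("entropy_norm", "ss_score", "rsa", "dbr_complement", "min_score_smoothed"),
    names_to = "track", values_to = "value"
  )
  long$track <- factor(long$track,
                       levels = c("entropy_norm", "ss_score", "rsa",
                                  "dbr_complement", "min_score_smoothed"),
                       labels = c("entropy / log2(20)", "secondary structure",
                                  "RSA", "1 - BR", "smoothed min score"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track)) +
    ggplot2::labs(x = "residue position", y = "normalized score",
                  title = object$query$id) +
    ggplot2::theme_minimal()
  if (!is.null(sites) && nrow(sites)) {
    p <- p + ggplot2::geom_vline(data = tibble(position = sites$position),
                                 ggplot2::aes(xintercept = .data$position),
                                 colour = "red", linetype = 2, linewidth = 0.3)
  }
  p
}
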