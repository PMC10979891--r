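test_that("entropy normalization divides by log2(20)", {
  tr <- normalize_entropy(c(0, log2(20), log2(20) / 2))
  expect_equal(tr$value, c(0, 1, 0.5))
  expect_equal(normalize_entropy(4.32)$value, 4.32 / log2(20))
  expect_error(normalize_entropy(5), class = "tagsite_input_error")
})

test_that("weights validate and default to 1.5/1/1/1", {
  w <- tag_weights()
  expect_equal(unclass(w),
               c(entropy = 1.5, secondary_structure = 1, rsa = 1,
                 dbr_complement = 1))
  expect_error(tag_weights(entropy = -1), class = "tagsite_input_error")
})

test_that("sum score is the weighted feature sum with NA propagation", {
  expect_equal(sum_score(0, 0, 0, 0), 0)
  expect_equal(sum_score(1, 1, 1, 1), 4.5)
  expect_equal(sum_score(0.5, 1, 0.5, 0.8), 3.05)
  expect_equal(sum_score(1, 1, 1, 1, tag_weights(2, 0.5, 1, 0)), 3.5)
  expect_true(is.na(sum_score(c(0.5, NA), c(1, 1), c(1, 1), c(1, 1))[2]))
  expect_error(sum_score(c(1, 1), 1, 1, 1), class = "tagsite_length_error")
  expect_error(sum_score(2, 1, 1, 1), class = "tagsite_input_error")
})

test_that("minimum score is the unweighted feature minimum", {
  expect_equal(min_score(0.8, 1.0, 0.9, 0.7), 0.7)
  expect_equal(min_score(0, 1, 1, 1), 0)
  expect_equal(min_score(0.4, 0.4, 0.4, 0.4), 0.4)
  expect_true(is.na(min_score(NA, 1, 1, 1)))
})

test_that("minimum score ignores weights and is monotone in each feature", {
  set.seed(3)
  for (rep in 1:20) {
    tr <- random_profile_tracks(30)
    base <- min_score(tr$e, tr$s, tr$r, tr$d)
    # weights enter the sum only
    s1 <- sum_score(tr$e, tr$s, tr$r, tr$d, tag_weights(5, 0.1, 2, 0))
    expect_equal(min_score(tr$e, tr$s, tr$r, tr$d), base)
    # bumping one feature never decreases the minimum
    e2 <- pmin(tr$e + runif(30, 0, 0.3), 1)
    expect_true(all(min_score(e2, tr$s, tr$r, tr$d) >= base))
    # E_i <= min feature <= mean feature; default-weight sum <= 4.5
    m <- pmin(tr$e, tr$s, tr$r, tr$d)
    expect_true(all(base <= m + 1e-12))
    expect_true(all(base <= (tr$e + tr$s + tr$r + tr$d) / 4 + 1e-12))
    expect_true(all(sum_score(tr$e, tr$s, tr$r, tr$d) <= 4.5 + 1e-12))
  }
})

test_that("sliding-window smoothing shrinks at edges and skips missing values", {
  expect_equal(smooth_track(rep(0.3, 10), 7), rep(0.3, 10))
  x <- runif(9)
  expect_equal(smooth_track(x, 1), x)
  expect_equal(smooth_track(c(0, 0, 0, 7, 0, 0, 0), 7)[4], 1.0)
  # edges shrink: first value of window-3 smoothing averages positions 1:2
  expect_equal(smooth_track(c(1, 2, 4), 3), c(1.5, 7 / 3, 3))
  # missing values are excluded from the local mean
  expect_equal(smooth_track(c(1, NA, 3), 3)[2], 2)
  expect_true(is.na(smooth_track(c(NA, NA, NA), 3)[1]))
  expect_error(smooth_track(1:5, 4), class = "tagsite_input_error")
  expect_error(smooth_track(1:5, -1), class = "tagsite_input_error")
})

test_that("smoothing preserves bounds and the interior mean", {
  set.seed(5)
  for (rep in 1:20) {
    x <- runif(40)
    sm <- smooth_track(x, 7)
    expect_true(all(sm >= 0 & sm <= 1))
    # interior windows are full, so the interior smoothed mean equals the
    # mean of the averaged windows
    interior <- 4:37
    want <- vapply(interior, function(i) mean(x[(i - 3):(i + 3)]), numeric(1))
    expect_equal(sm[interior], want, tolerance = 1e-12)
  }
})

test_that("profiles assemble the score table and enforce invariants", {
  n <- 12
  q <- validate_sequence(paste(rep("A", n), collapse = ""))
  ones <- rep(1, n)
  pr <- build_profile(q, feature_track("entropy", ones),
                      feature_track("secondary_structure", ones),
                      feature_track("rsa", ones),
                      feature_track("dbr_complement", ones))
  expect_equal(pr$scores$min_score, ones)
  expect_equal(pr$scores$sum_score, rep(4.5, n))
  expect_equal(pr$scores$min_score_smoothed, ones)
  expect_equal(nrow(pr$scores), q$length)

  g <- glance(pr)
  expect_equal(g$n_residues, n)
  expect_equal(g$w_entropy, 1.5)
  td <- tidy(pr)
  expect_true(all(c("position", "min_score", "sum_score") %in% names(td)))

  # entropy supplied in bits is normalized internally
  pr2 <- build_profile(q, rep(log2(20) / 2, n), ones, ones, ones)
  expect_equal(pr2$scores$entropy_norm, rep(0.5, n))
  expect_equal(pr2$scores$min_score, rep(0.5, n))
  expect_error(build_profile(q, rep(0.5, n + 1), ones, ones, ones),
               class = "tagsite_length_error")
})

test_that("site ranking selects separated peaks with N-terminal tie-breaks", {
  n <- 50
  mk <- function(sm) {
    q <- validate_sequence(paste(rep("A", n), collapse = ""))
    pr <- build_profile(q, feature_track("entropy", sm),
                        feature_track("secondary_structure", rep(1, n)),
                        feature_track("rsa", rep(1, n)),
                        feature_track("dbr_complement", rep(1, n)),
                        window = 1)
    pr
  }
  sm <- rep(0.1, n)
  sm[20] <- 0.9
  expect_equal(rank_sites(mk(sm), top_k = 1)$position, 20L)

  sm2 <- rep(0.1, n)
  sm2[c(10, 40)] <- 0.8
  sites <- rank_sites(mk(sm2), top_k = 2, min_separation = 8)
  expect_equal(sites$position, c(10L, 40L))
  expect_equal(sites$rank, 1:2)

  # nearby secondary maxima are suppressed
  sm3 <- rep(0.1, n)
  sm3[20] <- 0.9
  sm3[24] <- 0.85
  sm3[35] <- 0.5
  expect_equal(rank_sites(mk(sm3), top_k = 2, min_separation = 8)$position,
               c(20L, 35L))

  # missing scores are never selected
  sm4 <- c(rep(NA_real_, 10), rep(0.2, n - 10))
  sm4[5] <- NA_real_
  pr4 <- mk(ifelse(is.na(sm4), 0, sm4))
  pr4$scores$min_score_smoothed <- sm4
  expect_false(any(rank_sites(pr4, top_k = 5)$position <= 10))

  expect_error(rank_sites(mk(sm), top_k = 0), class = "tagsite_input_error")
  expect_true(all(diff(rank_sites(mk(sm2), top_k = 5)$score) <= 1e-12))
})
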