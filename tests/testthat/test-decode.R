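# Decoding: subaveraging, LOO SVM, RDM machinery and its variants.

test_that("subaverage partitions without replacement and preserves the mean", {
  x <- matrix(rnorm(60), 30, 2)
  ps <- subaverage(x, 10, seed = 1)
  expect_equal(dim(ps), c(3, 2))
  expect_equal(colMeans(ps), colMeans(x), tolerance = 1e-12)
  # k = 1: the trials themselves, permuted
  p1 <- subaverage(x, 1, seed = 2)
  expect_equal(dim(p1), dim(x))
  expect_equal(p1[order(p1[, 1]), ], x[order(x[, 1]), ], tolerance = 1e-12)
  # leftover trials are dropped
  p2 <- subaverage(x[1:29, ], 10, seed = 3)
  expect_equal(nrow(p2), 2)
  expect_error(subaverage(x, 31), "exceeds")
})

test_that("pairwise accuracy is perfect for separated clouds, chance for identical ones", {
  set.seed(4)
  Xa <- matrix(rnorm(20), 5, 4) + 6
  Xb <- matrix(rnorm(20), 5, 4) - 6
  expect_equal(pairwise_accuracy(Xa, Xb), 100)
  X0 <- matrix(1, 4, 3)
  expect_warning(a0 <- pairwise_accuracy(X0, X0), "degenerate")
  expect_equal(a0, 50)
  # random labels: near 50 in expectation
  accs <- replicate(40, {
    Z <- matrix(rnorm(48), 12, 4)
    pairwise_accuracy(Z[1:6, ], Z[7:12, ])
  })
  expect_lt(abs(mean(accs) - 50), 6)
})

test_that("accuracy is invariant to swapping the two classes", {
  set.seed(5)
  for (i in 1:10) {
    Xa <- matrix(rnorm(24), 6, 4) + 0.8
    Xb <- matrix(rnorm(24), 6, 4)
    expect_equal(pairwise_accuracy(Xa, Xb), pairwise_accuracy(Xb, Xa))
  }
})

test_that("repetition averaging equals the mean of single-repetition courses", {
  set.seed(6)
  d <- 4; M <- 20; Tn <- 7
  A <- array(rnorm(d * Tn * M), c(d, Tn, M))
  B <- array(rnorm(d * Tn * M), c(d, Tn, M))
  A[1, , ] <- A[1, , ] + 1
  pa <- cbind(sample.int(M), sample.int(M))
  pb <- cbind(sample.int(M), sample.int(M))
  both <- reverbdecode:::cpp_pair_course(A, B, pa, pb, 5L, 1, FALSE)
  one1 <- reverbdecode:::cpp_pair_course(A, B, pa[, 1, drop = FALSE],
                                         pb[, 1, drop = FALSE], 5L, 1, FALSE)
  one2 <- reverbdecode:::cpp_pair_course(A, B, pa[, 2, drop = FALSE],
                                         pb[, 2, drop = FALSE], 5L, 1, FALSE)
  expect_equal(rowMeans(both), as.vector(one1 + one2) / 2, tolerance = 1e-12)
})

test_that("RDM series has 36 defined symmetric pairs per time point", {
  es <- simulate_preprocessed_subject(tiny_config(seed = 2), 1)
  r <- rdm_timecourse(es, decoding_params(k = 10, K = 2, seed = 1))
  expect_equal(dim(r$acc), c(9, 9, length(es$time_ms)))
  m <- r$acc[, , 5]
  expect_true(all(is.na(diag(m))))
  expect_equal(sum(!is.na(m)), 72) # 36 pairs, mirrored
  expect_equal(m, t(m))
  expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 100))
  gm <- grand_mean_timecourse(r)
  expect_length(gm, length(es$time_ms))
  expect_equal(gm[5], mean(m[lower.tri(m)]))
})

test_that("grand mean of a constant toy RDM series is that constant", {
  acc <- array(50, c(9, 9, 3))
  for (i in 1:3) diag(acc[, , i]) <- NA
  r <- structure(list(acc = acc, time_ms = 1:3), class = "rdm_series")
  expect_equal(grand_mean_timecourse(r), rep(50, 3))
  acc[, , 2][lower.tri(acc[, , 2])] <- rep(c(60, 70, 80), length.out = 36)
  acc[, , 2] <- t(acc[, , 2]); acc[, , 2][lower.tri(acc[, , 2])] <-
    rep(c(60, 70, 80), length.out = 36)
  r2 <- structure(list(acc = acc, time_ms = 1:3), class = "rdm_series")
  expect_equal(grand_mean_timecourse(r2)[2], mean(rep(c(60, 70, 80), 12)))
})

test_that("pooled decoding uses 3M trials per class and finds the kernels", {
  cfg <- tiny_config(seed = 3)
  es <- simulate_preprocessed_subject(cfg, 1)
  ps <- pooled_decode(es, "source", decoding_params(k = 30, K = 3, seed = 1))
  expect_equal(dim(ps$pairs), c(3, length(es$time_ms)))
  expect_equal(ps$mean, colMeans(ps$pairs))
  # 3M = 90 trials, k = 30 -> 3 pseudo-trials per class (counts via subaverage)
  expect_equal(nrow(subaverage(matrix(0, 90, 1), 30, seed = 1)), 3)
  tm <- es$time_ms
  expect_gt(mean(ps$mean[tm >= 100 & tm <= 200]),
            mean(ps$mean[tm < 0]) + 5)
})

test_that("cross-classification averages nine combinations and generalizes", {
  cfg <- tiny_config(seed = 8)
  es <- simulate_preprocessed_subject(cfg, 1)
  cs <- cross_decode(es, "source", decoding_params(k = 10, K = 3, seed = 2))
  expect_equal(nrow(cs$combinations), 9)
  expect_equal(cs$mean, colMeans(cs$combinations))
  # the source pattern is identical across space levels by construction, so
  # cross accuracy tracks the pooled (within) accuracy
  ps <- pooled_decode(es, "source", decoding_params(k = 10, K = 3, seed = 3))
  tm <- es$time_ms
  sig <- tm >= 100 & tm <= 200
  expect_equal(mean(cs$mean[sig]), mean(ps$mean[sig]), tolerance = 0.1)
  # missing factorial cell is rejected
  bad <- es
  keep <- !(bad$source == 1 & bad$space == 1)
  bad$data <- bad$data[, , keep]
  attr(bad$data, "layout") <- "dtn"
  bad$source <- bad$source[keep]; bad$space <- bad$space[keep]
  expect_error(cross_decode(bad, "source"), "cell")
})

test_that("sensorwise decoding localizes an injected signal", {
  tmm <- seq(-100, 300, 20)
  bump <- function(t) exp(-(tmm[t] - 150)^2 / (2 * 40^2))
  es <- manual_epochs(n_per_cond = 10, d = 9, time_ms = tmm,
                      noise_sd = 1, seed = 9)
  # inject a source-level signal into triplet 1 (channels 1-3) only
  for (ch in 1:3)
    for (i in seq_along(es$source))
      es$data[i, ch, ] <- es$data[i, ch, ] +
        2 * es$source[i] * vapply(seq_along(tmm), bump, numeric(1))
  sw <- sensorwise_decode(es, decoding_params(k = 5, K = 2, seed = 1))
  expect_equal(nrow(sw), 3)
  sig <- tmm >= 100 & tmm <= 200
  expect_gt(mean(sw[1, sig]), 75)
  expect_lt(max(abs(colMeans(sw[2:3, ]) - 50)), 20)
  expect_lt(abs(mean(sw[2:3, ]) - 50), 6)
  noTrip <- es; noTrip$triplet_index <- NULL
  expect_error(sensorwise_decode(noTrip), "triplet")
})

test_that("temporal generalization matches the diagonal and spreads for stationary codes", {
  tmm <- seq(-100, 300, 20)
  plateau <- function(t) as.numeric(tmm[t] >= 60 & tmm[t] <= 260)
  es <- manual_epochs(n_per_cond = 10, d = 6, time_ms = tmm,
                      noise_sd = 1, seed = 10)
  for (i in seq_along(es$source))
    es$data[i, 1, ] <- es$data[i, 1, ] +
      1.5 * es$source[i] * vapply(seq_along(tmm), plateau, numeric(1))
  tg <- temporal_generalization(es, "source",
                                decoding_params(k = 5, K = 3, seed = 4))
  expect_equal(dim(tg), c(length(tmm), length(tmm)))
  ps <- pooled_decode(es, "source", decoding_params(k = 5, K = 3, seed = 4))
  expect_equal(mean(abs(diag(tg) - ps$mean)), 0, tolerance = 6)
  # stationary topography: training at 100 ms generalizes to 220 ms
  i100 <- which(tmm == 100); i220 <- which(tmm == 220); ipre <- which(tmm == -60)
  expect_gt(tg[i100, i220], 80)
  expect_lt(tg[i100, ipre], 70)
})

test_that("decoding is reproducible under a fixed seed", {
  es <- simulate_preprocessed_subject(tiny_config(seed = 12), 1)
  p <- decoding_params(k = 10, K = 2, seed = 42)
  r1 <- rdm_timecourse(es, p)
  r2 <- rdm_timecourse(es, p)
  expect_identical(r1$acc, r2$acc)
  r3 <- rdm_timecourse(es, decoding_params(k = 10, K = 2, seed = 43))
  expect_false(identical(r1$acc, r3$acc))
})
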