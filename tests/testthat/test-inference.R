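# Group statistics: sign permutation, cluster correction, bootstrap
# latencies, FDR, temporal-generalization maps, behavioral coupling.

test_that("sign-permutation p-values behave at the null and under strong effects", {
  cfg <- test_config(n_perm = 1000)
  set.seed(1)
  S0 <- matrix(rnorm(14 * 50, mean = 50), 14, 50)
  p0 <- sign_permutation_pvalues(S0, cfg, seed = 1)
  expect_true(all(p0$p >= 1 / 1001 & p0$p <= 1))
  expect_equal(mean(p0$p), 0.5, tolerance = 0.1)
  expect_equal(mean(p0$null_means), 0, tolerance = 0.02) # symmetric null
  # all subjects +10 points at one time point: minimum attainable p
  S1 <- S0
  S1[, 25] <- 60
  p1 <- sign_permutation_pvalues(S1, cfg, seed = 1)
  expect_lte(p1$p[25], 0.002)
  expect_error(sign_permutation_pvalues(S0[1, , drop = FALSE], cfg), ">= 2")
  S0[2, 3] <- NA
  expect_error(sign_permutation_pvalues(S0, cfg), "NaN|NA")
})

test_that("cluster correction finds a sustained effect but not an isolated point", {
  cfg <- test_config(n_perm = 500)
  tm <- seq(-100, 500, 5)
  set.seed(2)
  base <- matrix(rnorm(12 * length(tm), mean = 50, sd = 2), 12)
  # 200-ms block of strong effect
  blk <- tm >= 150 & tm < 350
  Sb <- base
  Sb[, blk] <- Sb[, blk] + 6
  ci <- cluster_correct(sign_permutation_pvalues(Sb, cfg, seed = 3), tm, cfg)
  sig <- ci$clusters[ci$clusters$significant, ]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$start_ms, 150, tolerance = 15)
  expect_equal(sig$end_ms, 345, tolerance = 15)
  expect_equal(ci$onset_ms, 150, tolerance = 15)
  # single suprathreshold point: not significant
  Sp <- base
  Sp[, 60] <- Sp[, 60] + 6
  cip <- cluster_correct(sign_permutation_pvalues(Sp, cfg, seed = 3), tm, cfg)
  expect_false(any(cip$clusters$significant & cip$clusters$size == 1))
  # fully null input: empty cluster list is valid, onset undefined
  cin <- cluster_correct(sign_permutation_pvalues(base - 0.5, cfg, seed = 4),
                         tm, cfg)
  expect_true(is.na(cin$onset_ms) ||
                all(!cin$clusters$significant))
})

test_that("bootstrap latency CIs cover and degenerate correctly", {
  cfg <- test_config(n_perm = 300, n_boot_latency = 120)
  tm <- seq(-100, 500, 5)
  set.seed(5)
  shape <- 8 * exp(-(tm - 250)^2 / (2 * 60^2))
  S <- matrix(rnorm(12 * length(tm), 50, 1.5), 12, byrow = FALSE) +
    rep(shape, each = 12)
  bl <- bootstrap_latency_ci(S, tm, cfg, seed = 6)
  expect_equal(bl$peak_ms, 250, tolerance = 20)
  expect_true(bl$peak_ci[1] <= bl$peak_ms && bl$peak_ms <= bl$peak_ci[2])
  expect_true(bl$onset_ci[1] <= bl$onset_ms)
  # identical subjects: zero-width peak CI
  S2 <- matrix(rep(50 + shape, each = 6), 6)
  bl2 <- bootstrap_latency_ci(S2, tm, cfg, seed = 7)
  expect_equal(unname(diff(bl2$peak_ci)), 0)
  expect_equal(bl2$peak_ms, 250)
  # restricted peak window
  bl3 <- bootstrap_latency_ci(S, tm, cfg, seed = 8, peak_window = c(0, 150))
  expect_lte(bl3$peak_ms, 150)
})

test_that("latency difference test separates and centers correctly", {
  expect_lt(latency_difference_test(rnorm(500, 300, 10), 100)$p, 0.01)
  p0 <- latency_difference_test(rnorm(2000, 100, 10), 100)$p
  expect_equal(p0, 0.5, tolerance = 0.1)
  r <- latency_difference_test(c(NA, 200, 220, NA, 240), 100)
  expect_equal(r$n_undefined, 2)
  expect_equal(r$n_used, 3)
})

test_that("BH mask matches the brute-force step-up definition", {
  expect_equal(fdr_bh(rep(0.001, 7), 0.01), rep(TRUE, 7))
  # step-up by hand: only 0.005 <= 1/4 * 0.05; 0.04 > 2/4 * 0.05
  expect_equal(fdr_bh(c(0.005, 0.04, 0.2, 0.9), 0.05),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(fdr_bh(rep(1, 5), 0.05), rep(FALSE, 5))
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(fdr_bh(p, q), bf_bh(p, q))
  }
  expect_error(fdr_bh(c(0.1, NA), 0.05), "finite")
})

test_that("temporal-generalization maps control the null and find the diagonal", {
  cfg <- test_config(fdr_q = 0.05)
  set.seed(10)
  Tn <- 30
  null_tg <- lapply(1:8, function(s) matrix(rnorm(Tn^2, 50, 3), Tn))
  s0 <- tg_significance(null_tg, cfg)
  expect_lt(mean(s0$p < 0.05), 0.12)   # about 5% raw
  expect_lt(mean(s0$sig_mask), 0.01)   # about none after FDR
  diag_tg <- lapply(1:8, function(s) {
    m <- matrix(rnorm(Tn^2, 50, 3), Tn)
    for (d in -2:2) m[row(m) - col(m) == d] <- m[row(m) - col(m) == d] + 10
    m
  })
  s1 <- tg_significance(diag_tg, cfg)
  expect_gt(mean(diag(s1$sig_mask)), 0.9)
  expect_error(tg_significance(null_tg[1], cfg), ">= 2")
})

test_that("peak mismatch test is two-sided around the bootstrap distribution", {
  set.seed(11)
  boot <- rnorm(5000, 130, 8)
  expect_lt(peak_mismatch_test(boot, 495), 0.001)
  expect_gt(peak_mismatch_test(boot, 130), 0.9)
  expect_lt(peak_mismatch_test(boot, 60), 0.001)
})

test_that("behavior-MEG correlation recovers a monotone coupling", {
  set.seed(12)
  cats <- c("So1-2", "So1-3", "So2-3", "Sp1-2", "Sp1-3", "Sp2-3")
  target_rt <- c(700, 680, 720, 900, 860, 950)
  target_lat <- c(128, 126, 132, 380, 360, 395)
  mk <- function(n_sub, val, sd, var) {
    do.call(rbind, lapply(seq_len(n_sub), function(s) {
      d <- data.frame(subject = sprintf("S%02d", s), category = cats)
      d[[var]] <- val + rnorm(6, sd = sd)
      d
    }))
  }
  beh <- mk(14, target_rt, 25, "rt_ms")
  meg <- mk(14, target_lat, 12, "peak_ms")
  cfg <- test_config(n_boot_behavior = 800)
  r <- behavior_meg_correlation(beh, meg, cfg = cfg, seed = 1)
  expect_gt(r$rho, 0.7)
  expect_gt(r$ci[1], 0)
  expect_lt(r$p, 0.05)
  # perfectly monotone relation: rho = 1
  beh0 <- mk(3, target_rt, 0, "rt_ms")
  meg0 <- mk(3, sort(target_lat), 0, "peak_ms")
  r0 <- behavior_meg_correlation(beh0, meg0, cfg = test_config(n_boot_behavior = 50))
  expect_equal(r0$rho, cor(target_rt, sort(target_lat), method = "spearman"))
  # degenerate constant summaries are rejected
  megc <- mk(3, rep(100, 6), 0, "peak_ms")
  expect_error(behavior_meg_correlation(beh0, megc,
                                        cfg = test_config(n_boot_behavior = 10)),
               "constant")
  # mismatched category sets are rejected
  expect_error(behavior_meg_correlation(beh0[beh0$category != "So1-2", ], meg0,
                                        cfg = test_config(n_boot_behavior = 10)),
               "categor")
})

test_that("bootstrap CIs widen with fewer subjects on average", {
  # between-subject latency variability drives the bootstrap peak spread
  cfg <- test_config(n_perm = 150, n_boot_latency = 80)
  tm <- seq(-100, 500, 10)
  set.seed(13)
  w_big <- w_small <- numeric(5)
  for (i in 1:5) {
    S <- t(vapply(1:14, function(s)
      50 + 8 * exp(-(tm - rnorm(1, 250, 40))^2 / (2 * 60^2)) +
        rnorm(length(tm), 0, 1.5), numeric(length(tm))))
    w_big[i] <- diff(bootstrap_latency_ci(S, tm, cfg, seed = i)$peak_ci)
    w_small[i] <- diff(bootstrap_latency_ci(S[1:7, ], tm, cfg,
                                            seed = i)$peak_ci)
  }
  expect_gt(mean(w_small), mean(w_big))
})
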