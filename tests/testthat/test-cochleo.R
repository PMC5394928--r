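# Gammatone cochleograms and stimulus dissimilarity curves.

test_that("cochleogram dimensions and degenerate inputs", {
  cg <- gammatone_cochleogram(numeric(2000))
  expect_equal(dim(cg$energy), c(64, 200))
  expect_true(all(cg$energy == 0))
  expect_equal(length(cg$center_frequencies), 64)
  expect_equal(range(cg$center_frequencies), c(20, 20000), tolerance = 1e-6)
  expect_error(gammatone_cochleogram(numeric(0)), "empty")
  expect_error(gammatone_cochleogram(matrix(0, 10, 2)), "multichannel")
})

test_that("a pure tone concentrates energy at the nearest center frequency", {
  sr <- 44100
  tone <- sin(2 * pi * 1000 * seq_len(sr) / sr)
  cg <- gammatone_cochleogram(tone)
  expect_true(all(cg$energy >= 0))
  peak_cf <- cg$center_frequencies[which.max(rowSums(cg$energy))]
  nearest <- cg$center_frequencies[which.min(abs(cg$center_frequencies - 1000))]
  expect_equal(peak_cf, nearest)
})

test_that("total energy grows with input amplitude", {
  set.seed(1)
  x <- rnorm(44100) * exp(-(1:44100) / 8000)
  e1 <- sum(gammatone_cochleogram(x)$energy)
  e2 <- sum(gammatone_cochleogram(2 * x)$energy)
  expect_gt(e2, e1)
  expect_equal(e2 / e1, 4, tolerance = 1e-6)
})

test_that("dissimilarity matches a direct per-bin Pearson oracle", {
  set.seed(2)
  mats <- lapply(1:3, function(i) matrix(rexp(64 * 10), 64, 10))
  curve <- dissimilarity_timecourse(mats)
  oracle <- sapply(1:10, function(t) {
    prs <- combn(3, 2)
    mean(apply(prs, 2, function(pr) 1 - cor(mats[[pr[1]]][, t],
                                            mats[[pr[2]]][, t])))
  })
  expect_equal(curve, oracle, tolerance = 1e-12)
  # identical stimuli: zero everywhere
  expect_equal(dissimilarity_timecourse(list(mats[[1]], mats[[1]])),
               rep(0, 10), tolerance = 1e-12)
  # perfectly anticorrelated patterns: bin value 2
  a <- matrix(seq_len(64), 64, 1)
  b <- matrix(rev(seq_len(64)), 64, 1)
  expect_equal(dissimilarity_timecourse(list(a, b)), 2, tolerance = 1e-12)
  # zero-variance bins fall back to the no-information value 1
  z <- matrix(0, 64, 2); z[, 2] <- seq_len(64)
  expect_equal(dissimilarity_timecourse(list(z, z + 0))[1], 1)
  expect_error(dissimilarity_timecourse(list(a, matrix(0, 64, 3))), "shapes")
})

test_that("dissimilarity is invariant to global amplitude scaling", {
  set.seed(3)
  waves <- lapply(1:3, function(i) rnorm(30000) * exp(-(1:30000) / 5000))
  c1 <- dissimilarity_timecourse(lapply(waves, gammatone_cochleogram))
  c2 <- dissimilarity_timecourse(lapply(waves, function(w)
    gammatone_cochleogram(3.7 * w)))
  expect_equal(c1, c2, tolerance = 1e-9)
})

test_that("pooled dissimilarity separates source and space structure", {
  lab <- expand.grid(source = 1:3, space = 1:3)
  kinds <- c("pat", "tap", "bounce")
  rts <- c(0.25, 0.51, 0.68)
  cgs <- lapply(seq_len(9), function(i)
    gammatone_cochleogram(synthesize_stimulus(
      stimulus_spec(kinds[lab$source[i]], rt60 = rts[lab$space[i]]),
      seed = 20 + lab$source[i])$wave))
  dsrc <- pooled_dissimilarity(cgs, lab, "source")
  dspc <- pooled_dissimilarity(cgs, lab, "space")
  # reverberant-space differences live in the decay: later dissimilarity
  expect_gt(curve_peak(dspc), curve_peak(dsrc))
  com <- function(v) sum(seq_along(v) * v) / sum(v)
  expect_gt(com(dspc), com(dsrc))
  # identical stimuli in every cell: curves vanish wherever sound is present
  # (silent bins keep the no-information value 1 by convention)
  same <- lapply(1:9, function(i) cgs[[1]])
  active <- apply(cgs[[1]]$energy, 2, function(v) stats::sd(v) > 0)
  expect_equal(max(pooled_dissimilarity(same, lab, "space")[active]), 0)
  expect_error(pooled_dissimilarity(cgs[1:6], lab[1:6, ], "space"), "levels")
})

test_that("space dissimilarity mass moves later with longer RT60", {
  base <- synthesize_stimulus(stimulus_spec("pat", rt60 = 0.25), seed = 31)
  com <- function(v) sum(seq_along(v) * v) / sum(v)
  coms <- sapply(c(0.25, 0.51, 0.68), function(rt) {
    st <- synthesize_stimulus(stimulus_spec("pat", rt60 = rt), seed = 31)
    com(rowSums(t(gammatone_cochleogram(st$wave)$energy)))
  })
  expect_true(all(diff(coms) > 0))
})

test_that("curve peaks use bin time with earliest-bin ties", {
  expect_equal(curve_peak(c(0.1, 0.2, 0.3)), 15) # last bin of a rising curve
  expect_equal(curve_peak(rep(1, 10)), 5)        # flat: first bin
  tri <- c(seq(0, 1, length.out = 40), seq(1, 0, length.out = 40)[-1])
  expect_equal(curve_peak(tri), 200)             # bin 40 at 5-ms steps
  expect_error(curve_peak(rep(NA_real_, 4)), "NA")
})
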