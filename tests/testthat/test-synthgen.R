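# Generator: temporal kernels, topographies, epochs, stimuli, behavior.

test_that("source kernel is transient with the configured peak", {
  cfg <- generator_config(fast = TRUE)
  tm <- config_time(cfg)
  k <- component_profile("source", cfg)
  expect_equal(k[tm == -100], 0)
  expect_true(all(k[tm < cfg$source_onset] == 0))
  expect_equal(tm[which.max(k)], 130)
  expect_equal(max(k), 1)
  expect_lt(max(k[tm >= cfg$source_offset]), 0.05)
})

test_that("space kernel is sustained, peaks strictly at the configured peak", {
  cfg <- generator_config(fast = TRUE)
  tm <- config_time(cfg)
  k <- component_profile("space", cfg)
  expect_true(all(k[tm < cfg$space_onset] == 0))
  expect_equal(tm[which.max(k)], 385) # grid point nearest 386
  expect_gte(k[tm == 600], 0.5)
  expect_gte(min(k[tm >= 386 & tm <= 700]), 0.5)
  expect_lt(max(k[tm >= cfg$space_offset]), 0.05)
})

test_that("kernel rejects a peak outside the time axis", {
  cfg <- tiny_config()
  cfg$space_peak <- 900 # beyond time_end = 600
  expect_error(component_profile("space", cfg), "outside the time axis")
})

test_that("topographies are unit norm with the required geometry", {
  for (geom in c("ordinal", "equidistant")) {
    topo <- make_topographies(tiny_config(space_geometry = geom))
    expect_equal(colSums(topo$source^2), rep(1, 3), tolerance = 1e-10)
    expect_equal(colSums(topo$space^2), rep(1, 3), tolerance = 1e-10)
    ds <- as.matrix(dist(t(topo$source)))
    expect_lt(diff(range(ds[upper.tri(ds)])), 1e-6) # sources equidistant
    dp <- as.matrix(dist(t(topo$space)))
    if (geom == "ordinal") {
      expect_gt(dp[1, 3], dp[1, 2])
      expect_gt(dp[1, 3], dp[2, 3])
      expect_equal(dp[1, 2], dp[2, 3], tolerance = 1e-10)
    } else {
      expect_lt(diff(range(dp[upper.tri(dp)])), 1e-6)
    }
  }
})

test_that("epoch generation is deterministic and balanced", {
  cfg <- tiny_config()
  e1 <- generate_subject_epochs(cfg, 2)
  e2 <- generate_subject_epochs(cfg, 2)
  expect_identical(e1$data, e2$data)
  expect_true(all(condition_counts(e1) == cfg$trials_per_condition))
  e3 <- generate_subject_epochs(cfg, 3)
  expect_false(identical(e1$data, e3$data))
})

test_that("noiseless epochs match the closed-form condition templates", {
  cfg <- tiny_config(noise_sd = 0, noise_spatial_corr = 0,
                     subject_gain_sd = 0)
  topo <- make_topographies(cfg)
  es <- generate_subject_epochs(cfg, 1, topo)
  tm <- es$time_ms
  ks <- component_profile("source", cfg)
  t130 <- which.min(abs(tm - 130))
  i1 <- which(es$source == 1 & es$space == 1)
  i2 <- which(es$source == 2 & es$space == 1)
  m1 <- colMeans(es$data[i1, , t130])
  m2 <- colMeans(es$data[i2, , t130])
  expected <- cfg$snr_source * ks[t130] *
    sqrt(sum((topo$source[, 1] - topo$source[, 2])^2))
  expect_equal(sqrt(sum((m1 - m2)^2)), expected, tolerance = 1e-10)
  # outside the source window, source levels are indistinguishable
  t_pre <- which(tm == -100)
  expect_equal(es$data[i1[1], , t_pre], es$data[i2[1], , t_pre],
               tolerance = 1e-12)
})

test_that("null dataset carries no label information and unit noise variance", {
  cfg <- tiny_config(seed = 9)
  cfg$trials_per_condition <- 30L
  nul <- generate_null_dataset(cfg)
  expect_length(nul, cfg$n_subjects)
  x <- as.vector(nul[[1]]$data)
  expect_equal(var(x), cfg$noise_sd^2, tolerance = 0.05)
  expect_equal(mean(x), 0, tolerance = 0.01)
})

test_that("synthetic RIRs hit the requested reverberation time", {
  for (rt in c(0.25, 0.51, 0.68)) {
    st <- synthesize_stimulus(stimulus_spec("pat", rt60 = rt), seed = 2)
    expect_equal(measure_rt60(st$rir, st$sr), rt, tolerance = 0.05)
  }
  expect_error(stimulus_spec("pat", rt60 = 0), "rt60")
})

test_that("repeated stimuli span the repetition window and ramp linearly", {
  st <- synthesize_stimulus(stimulus_spec("tap", rt60 = 0.51,
                                          repeat_count = 10,
                                          repeat_interval = 200,
                                          ramp_ms = 1000), seed = 3)
  expect_equal(length(st$anechoic) / st$sr * 1000, 2000)
  expect_equal(length(st$wave) / st$sr * 1000, 2000)
  # triangular envelope: rms rises then falls
  thirds <- split(st$wave, cut(seq_along(st$wave), 3))
  rms <- vapply(thirds, function(x) sqrt(mean(x^2)), numeric(1))
  expect_gt(rms[2], rms[1])
  expect_gt(rms[2], rms[3])
  expect_equal(st$wave[1], 0)
  expect_equal(st$wave[length(st$wave)], 0)
})

test_that("a near-zero reverberation time reduces to the anechoic waveform", {
  st <- synthesize_stimulus(stimulus_spec("pat", rt60 = 1e-5), seed = 4)
  n <- length(st$anechoic)
  expect_gt(cor(st$wave[seq_len(n)], st$anechoic), 0.99)
})

test_that("behavior tables match the latency map targets", {
  cfg <- tiny_config(seed = 5)
  cfg$n_subjects <- 40L
  map <- default_latency_map()
  tab <- generate_behavior_table(cfg, map, rt_subject_sd = 0)
  expect_equal(nrow(tab), 40 * 6 * 36)
  counts <- table(tab$subject, tab$category)
  expect_true(all(counts == 36))
  one <- tab[tab$category == "Sp1-3", ]
  expect_equal(mean(one$rt_ms), map$rt_mean_ms[map$category == "Sp1-3"],
               tolerance = 0.03)
  expect_equal(mean(one$correct), map$accuracy[map$category == "Sp1-3"],
               tolerance = 0.05)
  map$accuracy[1] <- 1
  tab2 <- generate_behavior_table(cfg, map)
  expect_true(all(tab2$correct[tab2$category == map$category[1]] == 1))
  map$accuracy[1] <- 1.2
  expect_error(generate_behavior_table(cfg, map), "accurac")
})

test_that("gamma RT draws recover the target mean at scale", {
  cfg <- generator_config(fast = TRUE, n_subjects = 1, seed = 11)
  map <- data.frame(category = "So1-2", block = "source",
                    rt_mean_ms = 800, accuracy = 0.9, shape = 4)
  tab <- generate_behavior_table(cfg, map, trials_per_category = 1e5,
                                 rt_subject_sd = 0)
  expect_equal(mean(tab$rt_ms), 800, tolerance = 0.03)
  expect_equal(var(tab$rt_ms), 800^2 / 4, tolerance = 0.1)
})

test_that("fused simulation path equals generate + preprocess", {
  cfg <- tiny_config(seed = 7)
  fast <- simulate_preprocessed_subject(cfg, 2)
  slow <- preprocess_epochs(generate_subject_epochs(cfg, 2))
  fa <- aperm(fast$data, c(3, 1, 2))
  attributes(fa)$layout <- NULL
  expect_equal(fa, slow$data, tolerance = 1e-12)
  r1 <- rdm_timecourse(fast, decoding_params(k = 10, K = 1, seed = 3))
  r2 <- rdm_timecourse(slow, decoding_params(k = 10, K = 1, seed = 3))
  expect_identical(r1$acc, r2$acc)
})

test_that("config validation enforces the documented invariants", {
  expect_error(generator_config(trials_per_condition = 35), "divisible")
  expect_error(generator_config(n_sensors = 10), "multiple of 3")
  expect_error(generator_config(noise_spatial_corr = 1), "spatial_corr")
  expect_error(generator_config(source_onset = 200, source_peak = 100),
               "onset < peak")
})
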