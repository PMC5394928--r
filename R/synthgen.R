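# Synthetic-data generator: MEG epochs with a 3 (source) x 3 (space)
# factorial structure, impact-sound stimuli rendered through synthetic room
# impulse responses, and same-different behavioral tables.

#' Generator configuration
#'
#' Parameters of the synthetic MEG cohort.  Defaults mirror the emulated
#' study: 14 subjects, 9 conditions (3 impact-sound sources x 3 reverberant
#' space sizes), 150 trials per condition, 306 sensors grouped in triplets at
#' 102 locations, epochs from -200 to 1000 ms at 1 kHz.  The
#' source-discriminative sensor pattern is transient (onset 50 ms, peak
#' 130 ms, gone by 300 ms); the space-discriminative pattern is sustained
#' (onset 130 ms, peak 386 ms, significant energy through ~700 ms, gone by
#' 801 ms).
#'
#' `fast = TRUE` selects the documented desk-scale configuration (5-ms
#' sampling, 60 sensors at 20 locations, 10 subjects) used throughout the
#' test suite; any field can still be overridden.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param trials_per_condition trials per factorial cell (M); must be
#'   divisible by every entry of `subaverage_sizes`.
#' @param n_sensors channel count, a multiple of 3 (triplets share a
#'   location).
#' @param time_start,time_end,sampling_step epoch window and step, ms.
#' @param source_onset,source_peak,source_offset temporal support of the
#'   source-discriminative component, ms.
#' @param space_onset,space_peak,space_offset temporal support of the
#'   space-discriminative component, ms.
#' @param snr_source,snr_space signal amplitudes relative to unit sensor
#'   noise.  Defaults are calibrated so that, under the default pipeline,
#'   pooled source decoding peaks near 80% and pooled space decoding near
#'   70% group accuracy, preserving the source > space decodability gap
#'   while keeping every latency (onset, peak, grand-mean peak)
#'   recoverable; see the methods vignette.
#' @param noise_sd per-sensor noise standard deviation.
#' @param noise_spatial_corr fraction (in [0,1)) of noise variance carried by
#'   a rank-`noise_rank` spatially correlated component.
#' @param noise_rank rank of the spatially correlated noise term.
#' @param space_geometry `"ordinal"` (pattern distances grow stepwise with
#'   the size rank, d(1,3) > d(1,2) = d(2,3)) or `"equidistant"` (all three
#'   space patterns mutually equidistant; control geometry).
#' @param subject_gain_sd between-subject standard deviation of the
#'   multiplicative effect-amplitude gain.
#' @param subaverage_sizes subaveraging group sizes the per-condition trial
#'   count must divide exactly.  The default covers the sizes applied to
#'   whole condition cells (k = 10 single-condition, k = 30 pooled);
#'   cross-classification's k = 20 is applied within orthogonal levels,
#'   where leftover trials are dropped per repetition by design.
#' @param seed integer seed; all generator output is a deterministic
#'   function of (config, subject index).
#' @param fast logical; apply the desk-scale overrides before the explicit
#'   arguments.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 14,
                             trials_per_condition = 150,
                             n_sensors = 306,
                             time_start = -200, time_end = 1000,
                             sampling_step = 1,
                             source_onset = 50, source_peak = 130,
                             source_offset = 300,
                             space_onset = 130, space_peak = 386,
                             space_offset = 801,
                             snr_source = 0.16, snr_space = 0.33,
                             noise_sd = 1, noise_spatial_corr = 0.2,
                             noise_rank = 5,
                             space_geometry = c("ordinal", "equidistant"),
                             subject_gain_sd = 0.12,
                             subaverage_sizes = c(10, 30),
                             seed = 1, fast = FALSE) {
  space_geometry <- match.arg(space_geometry)
  if (isTRUE(fast)) {
    if (missing(sampling_step)) sampling_step <- 5
    if (missing(n_sensors)) n_sensors <- 60
    if (missing(n_subjects)) n_subjects <- 10
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_sources = 3L, n_spaces = 3L,
    trials_per_condition = as.integer(trials_per_condition),
    n_sensors = as.integer(n_sensors),
    time_start = time_start, time_end = time_end,
    sampling_step = sampling_step,
    source_onset = source_onset, source_peak = source_peak,
    source_offset = source_offset,
    space_onset = space_onset, space_peak = space_peak,
    space_offset = space_offset,
    snr_source = snr_source, snr_space = snr_space,
    noise_sd = noise_sd, noise_spatial_corr = noise_spatial_corr,
    noise_rank = as.integer(noise_rank),
    space_geometry = space_geometry,
    subject_gain_sd = subject_gain_sd,
    subaverage_sizes = as.integer(subaverage_sizes),
    seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  tm <- config_time(cfg)
  if (!any(tm == 0)) stopf("time axis must contain 0")
  if (is.unsorted(tm, strictly = TRUE)) stopf("time axis must be increasing")
  if (cfg$n_sensors %% 3L != 0L || cfg$n_sensors < 6L)
    stopf("n_sensors must be a multiple of 3 and >= 6")
  for (nm in c("source", "space")) {
    o <- cfg[[paste0(nm, "_onset")]]
    p <- cfg[[paste0(nm, "_peak")]]
    f <- cfg[[paste0(nm, "_offset")]]
    if (!(o < p && p < f)) stopf("%s component requires onset < peak < offset", nm)
  }
  bad <- cfg$subaverage_sizes[cfg$trials_per_condition %%
                                cfg$subaverage_sizes != 0L]
  if (length(bad))
    stopf("trials_per_condition (%d) not divisible by subaverage size(s) %s",
          cfg$trials_per_condition, paste(bad, collapse = ", "))
  if (cfg$noise_spatial_corr < 0 || cfg$noise_spatial_corr >= 1)
    stopf("noise_spatial_corr must be in [0, 1)")
  invisible(cfg)
}

#' Time axis of a generator configuration
#' @param config a `generator_config`.
#' @return numeric vector of sample times, ms.
#' @export
config_time <- function(config) {
  seq(config$time_start, config$time_end, by = config$sampling_step)
}

#' Temporal response kernels
#'
#' Unit-amplitude temporal profiles of the two condition-discriminative
#' signal components.  The source kernel is a gamma-shaped transient (sharp
#' rise, fast decay, maximum 1 exactly at `source_peak`).  The space kernel
#' is a sustained profile: fast rise after `space_onset` to a plateau, a
#' strict maximum of 1 at `space_peak`, a slow plateau decay that stays at or
#' above half maximum until ~three quarters of the way to `space_offset`,
#' then a smooth fall to zero before `space_offset`.  Both kernels are
#' identically zero throughout the prestimulus baseline.
#'
#' @param kind `"source"` or `"space"`.
#' @param config a `generator_config`.
#' @return numeric kernel sampled on `config_time(config)`.
#' @export
component_profile <- function(kind = c("source", "space"), config) {
  kind <- match.arg(kind)
  tm <- config_time(config)
  onset <- config[[paste0(kind, "_onset")]]
  peak <- config[[paste0(kind, "_peak")]]
  offset <- config[[paste0(kind, "_offset")]]
  if (peak < min(tm) || peak > max(tm))
    stopf("%s peak (%g ms) outside the time axis", kind, peak)
  if (kind == "source") {
    a <- 2.6
    tau <- (tm - onset) / (peak - onset)
    k <- ifelse(tau > 0, tau^a * exp(a * (1 - tau)), 0)
    # enforce the return to silence by `offset` with a smooth fade
    fade_from <- peak + 0.7 * (offset - peak)
    i <- tm > fade_from & tm < offset
    k[i] <- k[i] * (1 + cos(pi * (tm[i] - fade_from) / (offset - fade_from))) / 2
    k[tm >= offset] <- 0
  } else {
    k <- space_kernel(tm, onset, peak, offset)
  }
  k[tm < onset] <- 0
  k
}

# Sustained space kernel: half-cosine rise over the first 12% of
# [onset, peak], linear plateau decay 0.8 -> 0.6, cosine-squared bump of
# height (1 - plateau(peak)) centered at the peak, half-cosine fall to zero
# ending before `offset`.
space_kernel <- function(tm, onset, peak, offset) {
  rise_len <- 0.15 * (peak - onset)
  rise_end <- onset + rise_len
  fall_start <- peak + 0.757 * (offset - peak)
  fall_end <- peak + 0.973 * (offset - peak)
  hi <- 0.72
  lo <- 0.55
  sustain <- function(t) {
    v <- numeric(length(t))
    i <- t >= onset & t <= rise_end
    v[i] <- hi * (1 - cos(pi * (t[i] - onset) / rise_len)) / 2
    i <- t > rise_end & t <= fall_start
    v[i] <- hi - (hi - lo) * (t[i] - rise_end) / (fall_start - rise_end)
    i <- t > fall_start & t <= fall_end
    v[i] <- lo * (1 + cos(pi * (t[i] - fall_start) / (fall_end - fall_start))) / 2
    v
  }
  s <- sustain(tm)
  bump_h <- 1 - sustain(peak)
  w <- 0.09 * (offset - peak)
  b <- numeric(length(tm))
  i <- abs(tm - peak) <= w
  b[i] <- bump_h * cos(pi * (tm[i] - peak) / (2 * w))^2
  s + b
}

#' Sensor topographies of the factorial effects
#'
#' Builds unit-norm sensor weight maps for the three source levels and the
#' three space levels, concentrated over two lateral (temporal) sensor
#' clusters of a pseudo-helmet.  Source topographies are exactly mutually
#' equidistant.  Space topographies follow the configured geometry:
#' `"ordinal"` uses a collinear-plus-offset construction
#' (T_r = base + (r - 2) * gamma * direction, normalized) so that pattern
#' distances satisfy d(1,3) > d(1,2) = d(2,3); `"equidistant"` makes them
#' mutually equidistant like the sources.
#'
#' @param config a `generator_config`.
#' @return list with elements `source` and `space` (sensor x 3 weight
#'   matrices), `sensor_xyz` (location x 3 positions), `triplet_index`
#'   (location id per channel) and `envelope` (per-channel lateral-cluster
#'   envelope).
#' @export
make_topographies <- function(config) {
  d <- config$n_sensors
  L <- d %/% 3L
  with_seed(child_seed(config$seed, 7001L), {
    xyz <- helmet_positions(L)
    cL <- c(-1, 0, 0.35); cL <- cL / sqrt(sum(cL^2))
    cR <- c(1, 0, 0.35); cR <- cR / sqrt(sum(cR^2))
    ang <- function(p, cvec) acos(pmin(1, pmax(-1, as.vector(p %*% cvec))))
    a <- pmin(ang(xyz, cL), ang(xyz, cR))
    env_loc <- exp(-a^2 / (2 * 0.7^2))
    envelope <- rep(env_loc, each = 3L)
    triplet_index <- rep(seq_len(L), each = 3L)

    basis <- matrix(rnorm(d * 4L), d, 4L) * envelope
    basis <- qr.Q(qr(basis))[, 1:4, drop = FALSE]
    u1 <- basis[, 1]; u2 <- basis[, 2]; u3 <- basis[, 3]; u4 <- basis[, 4]

    th <- c(0, 2 * pi / 3, 4 * pi / 3)
    src <- sapply(th, function(x) cos(x) * u1 + sin(x) * u2)

    if (config$space_geometry == "ordinal") {
      gam <- 0.5
      spc <- sapply(1:3, function(r) {
        v <- u3 + (r - 2) * gam * u4
        v / sqrt(sum(v^2))
      })
    } else {
      ph <- c(pi / 6, 5 * pi / 6, 3 * pi / 2)
      spc <- sapply(ph, function(x) cos(x) * u3 + sin(x) * u4)
    }
    list(source = src, space = spc, sensor_xyz = xyz,
         triplet_index = triplet_index, envelope = envelope)
  })
}

# Deterministic quasi-uniform points on the upper hemisphere (Fibonacci
# lattice), standing in for helmet sensor-location geometry.
helmet_positions <- function(L) {
  i <- seq_len(L) - 0.5
  z <- i / L                 # heights in (0, 1): upper hemisphere
  phi <- 2 * pi * i * (3 - sqrt(5)) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Generate one subject's epochs
#'
#' Simulates the raw (unfiltered, un-baselined) epoch tensor for one subject:
#' each trial is the sum of the source-component pattern scaled by the source
#' kernel, the space-component pattern scaled by the space kernel, and sensor
#' noise (white plus a rank-limited spatially correlated term).  Output is a
#' deterministic function of `(config, subject_index)`.
#'
#' @param config a `generator_config`.
#' @param subject_index subject number (1-based).
#' @param topographies optional precomputed [make_topographies()] result
#'   (they are cohort-level and identical across subjects).
#' @return an [epoch_set()].
#' @export
generate_subject_epochs <- function(config, subject_index,
                                    topographies = NULL) {
  g <- gen_subject_dtn(config, subject_index, topographies)
  epoch_set(aperm(g$dat, c(3, 1, 2)), g$time_ms, g$source, g$space,
            triplet_index = g$triplet_index, sensor_xyz = g$sensor_xyz,
            subject_id = g$subject_id)
}

# Core simulation in sensors x time x trials orientation.
gen_subject_dtn <- function(config, subject_index, topographies = NULL) {
  M <- config$trials_per_condition
  if (M < min(config$subaverage_sizes))
    stopf("trials_per_condition smaller than the smallest subaverage size")
  topo <- topographies %||% make_topographies(config)
  tm <- config_time(config)
  Tn <- length(tm)
  d <- config$n_sensors
  ksrc <- component_profile("source", config)
  kspc <- component_profile("space", config)

  cond <- expand.grid(source = 1:3, space = 1:3)
  n_trial <- 9L * M
  source_lab <- rep(cond$source, each = M)
  space_lab <- rep(cond$space, each = M)

  with_seed(child_seed(config$seed, 11L, subject_index), {
    g_src <- max(0.2, 1 + config$subject_gain_sd * rnorm(1))
    g_spc <- max(0.2, 1 + config$subject_gain_sd * rnorm(1))

    # built sensors x time x trial (contiguous per trial), one aperm at end;
    # bulk noise comes from the compiled generator (deterministic per seed)
    c2 <- config$noise_spatial_corr
    dat <- cpp_randn(n_trial * d * Tn,
                     child_seed(config$seed, 11L, subject_index, 1L)) *
      (config$noise_sd * sqrt(1 - c2))
    dim(dat) <- c(d, Tn, n_trial)
    if (c2 > 0) {
      r <- config$noise_rank
      A <- matrix(rnorm(d * r), d, r)
      A <- A / sqrt(rowSums(A^2))
      Z <- matrix(cpp_randn(Tn * n_trial * r,
                            child_seed(config$seed, 11L, subject_index, 2L)),
                  r, Tn * n_trial)
      dim(dat) <- c(d, Tn * n_trial)
      dat <- dat + (A %*% Z) * (config$noise_sd * sqrt(c2))
      dim(dat) <- c(d, Tn, n_trial)
    }

    for (ci in seq_len(nrow(cond))) {
      tmpl <- config$snr_source * g_src *
        outer(topo$source[, cond$source[ci]], ksrc) +
        config$snr_space * g_spc *
        outer(topo$space[, cond$space[ci]], kspc)   # d x T
      idx <- which(source_lab == cond$source[ci] & space_lab == cond$space[ci])
      dat[, , idx] <- dat[, , idx, drop = FALSE] + as.vector(tmpl)
    }
    list(dat = dat, time_ms = tm, source = source_lab, space = space_lab,
         triplet_index = topo$triplet_index, sensor_xyz = topo$sensor_xyz,
         subject_id = sprintf("S%02d", subject_index))
  })
}

#' Generate and preprocess one subject in a single pass
#'
#' Equivalent to `preprocess_epochs(generate_subject_epochs(...))` but
#' performed in the simulation's native sensors x time x trials layout with
#' compiled baseline correction and filtering, avoiding large array
#' transposes.  Used by the experiment pipelines; the result decodes
#' identically to the two-step path.
#'
#' @inheritParams generate_subject_epochs
#' @param cutoff_hz,order low-pass settings (see [lowpass_30hz()]).
#' @return an [epoch_set()] whose data layout is marked internally; all
#'   decoding functions accept it.
#' @export
simulate_preprocessed_subject <- function(config, subject_index,
                                          topographies = NULL,
                                          cutoff_hz = 30, order = 4) {
  g <- gen_subject_dtn(config, subject_index, topographies)
  step_ms <- diff(g$time_ms[1:2])
  fs <- 1000 / step_ms
  if (fs < 100) stopf("sampling rate %.1f Hz too low (need >= 100 Hz)", fs)
  if (cutoff_hz >= fs / 2) stopf("cutoff must be below Nyquist")
  pre <- which(g$time_ms < 0)
  if (!length(pre)) stopf("no prestimulus samples")
  bw <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  npad <- 3L * (max(length(bw$b), length(bw$a)) - 1L) + 3L
  dat <- cpp_preprocess_cube(g$dat, pre - 1L, bw$b, bw$a, npad)
  attr(dat, "layout") <- "dtn"
  es <- structure(list(data = dat, time_ms = g$time_ms, source = g$source,
                       space = g$space, triplet_index = g$triplet_index,
                       sensor_xyz = g$sensor_xyz, subject_id = g$subject_id),
                  class = "epoch_set")
  es
}

#' Generate a full cohort
#'
#' @param config a `generator_config`.
#' @return list of [epoch_set()] objects, one per subject.
#' @export
generate_cohort <- function(config) {
  topo <- make_topographies(config)
  lapply(seq_len(config$n_subjects), function(s)
    generate_subject_epochs(config, s, topographies = topo))
}

#' Generate a null cohort (no condition effects)
#'
#' Identical to [generate_cohort()] with both effect amplitudes forced to
#' zero: labels carry no information and expected pairwise decoding accuracy
#' is 50% at every time point.
#'
#' @param config a `generator_config`.
#' @return list of [epoch_set()] objects.
#' @export
generate_null_dataset <- function(config) {
  config$snr_source <- 0
  config$snr_space <- 0
  generate_cohort(config)
}

# ---------------------------------------------------------------------------
# Stimulus synthesis

#' Stimulus specification
#'
#' @param source_kind impact-sound kind: `"pat"`, `"tap"` or `"bounce"`
#'   (they differ by damping constant and spectral tilt).
#' @param rt60 reverberation time of the space, seconds (> 0).  The emulated
#'   small/medium/large spaces use 0.25, 0.51 and 0.68 s.
#' @param duration_anechoic anechoic burst duration, ms.
#' @param sample_rate Hz.
#' @param repeat_count number of burst repetitions (1 for single-impact
#'   stimuli; 10 for the duration-controlled repeated stimuli).
#' @param repeat_interval onset-to-onset interval of repetitions, ms.
#' @param ramp_ms linear amplitude ramp duration, ms (0 = none; 1000 ramps
#'   the rendered waveform up over the first second and down over the next,
#'   truncating at 2 * ramp_ms).
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(source_kind = c("pat", "tap", "bounce"),
                          rt60 = 0.51, duration_anechoic = 176,
                          sample_rate = 44100, repeat_count = 1,
                          repeat_interval = 200, ramp_ms = 0) {
  source_kind <- match.arg(source_kind)
  if (rt60 <= 0) stopf("rt60 must be > 0")
  if (repeat_count < 1) stopf("repeat_count must be >= 1")
  structure(list(source_kind = source_kind, rt60 = rt60,
                 duration_anechoic = duration_anechoic,
                 sample_rate = sample_rate,
                 repeat_count = as.integer(repeat_count),
                 repeat_interval = repeat_interval, ramp_ms = ramp_ms),
            class = "stimulus_spec")
}

#' Synthesize a reverberant impact-sound stimulus
#'
#' The anechoic part is a damped noise burst shaped by the source kind
#' (damping constant and spectral tilt).  The room impulse response is
#' Gaussian noise with an exponential energy decay whose RT60 equals
#' `spec$rt60`.  For `repeat_count > 1` the bursts are concatenated at
#' `repeat_interval` before convolution (a train of n repetitions spans
#' n * repeat_interval ms); after convolution a linear up/down amplitude
#' ramp of `ramp_ms` is applied if requested.
#'
#' @param spec a [stimulus_spec()].
#' @param seed integer seed.
#' @return list with `wave` (rendered waveform), `anechoic` (pre-convolution
#'   train), `rir`, `sr` and `spec`; class `stimulus`.
#' @export
synthesize_stimulus <- function(spec, seed = 1) {
  sr <- spec$sample_rate
  with_seed(child_seed(seed, 23L), {
    burst <- impact_burst(spec$source_kind, spec$duration_anechoic, sr)
    if (spec$repeat_count > 1) {
      step <- round(spec$repeat_interval / 1000 * sr)
      train <- numeric(step * spec$repeat_count)
      for (i in seq_len(spec$repeat_count)) {
        at <- (i - 1) * step
        n <- min(length(burst), length(train) - at)
        train[at + seq_len(n)] <- train[at + seq_len(n)] + burst[seq_len(n)]
      }
    } else train <- burst

    rir <- synth_rir(spec$rt60, sr)
    wave <- fft_convolve(train, rir)

    if (spec$ramp_ms > 0) {
      nr <- round(spec$ramp_ms / 1000 * sr)
      wave <- wave[seq_len(min(2 * nr, length(wave)))]
      if (length(wave) < 2 * nr) wave <- c(wave, numeric(2 * nr - length(wave)))
      env <- c(seq(0, 1, length.out = nr), seq(1, 0, length.out = nr))
      wave <- wave * env
    }
    structure(list(wave = wave, anechoic = train, rir = rir, sr = sr,
                   spec = spec), class = "stimulus")
  })
}

impact_burst <- function(kind, duration_ms, sr) {
  n <- round(duration_ms / 1000 * sr)
  t <- seq_len(n) / sr * 1000 # ms
  par <- switch(kind,
                pat = list(tau = 35, tilt = 0.85),
                tap = list(tau = 12, tilt = 0.15),
                bounce = list(tau = 55, tilt = 0.6))
  x <- rnorm(n) * exp(-t / par$tau)
  # one-pole low-pass with coefficient `tilt` darkens the spectrum
  y <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- par$tilt * acc + (1 - par$tilt) * x[i]
    y[i] <- acc
  }
  y / max(abs(y))
}

synth_rir <- function(rt60, sr) {
  n <- max(32L, ceiling(1.25 * rt60 * sr))
  t <- (seq_len(n) - 1) / sr
  h <- rnorm(n) * exp(-6.9078 * t / rt60) # 60 dB energy decay over rt60
  h[1] <- abs(h[1]) # direct path arrives with positive polarity
  h / sqrt(sum(h^2))
}

fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                       stats::fft(c(h, numeric(nf - length(h)))),
                     inverse = TRUE)) / nf
  y[seq_len(n)]
}

#' Measure RT60 of an impulse response
#'
#' Schroeder backward-integration energy-decay curve with a linear fit over
#' the -5 to -25 dB range, extrapolated to 60 dB.
#'
#' @param rir impulse response (numeric vector).
#' @param sr sample rate, Hz.
#' @return estimated RT60 in seconds.
#' @export
measure_rt60 <- function(rir, sr) {
  edc <- rev(cumsum(rev(rir^2)))
  db <- 10 * log10(edc / edc[1])
  i <- which(db <= -5 & db >= -25)
  if (length(i) < 10) stopf("decay range too short to estimate RT60")
  tt <- (i - 1) / sr
  slope <- stats::coef(stats::lm(db[i] ~ tt))[2] # dB per second
  as.numeric(-60 / slope)
}

# ---------------------------------------------------------------------------
# Behavioral tables

#' Default behavioral latency map
#'
#' Target mean reaction time, accuracy and gamma shape per comparison
#' category.  Reaction times are coupled to the MEG component latencies the
#' generator encodes: source comparisons (early transient component) are
#' faster and more accurate than space comparisons (late sustained
#' component), and within a factor the most separated pair (1 vs 3) is
#' fastest and most accurate.
#'
#' @return data.frame with columns `category`, `block`, `rt_mean_ms`,
#'   `accuracy`, `shape`.
#' @export
default_latency_map <- function() {
  data.frame(
    category = c("So1-2", "So1-3", "So2-3", "Sp1-2", "Sp1-3", "Sp2-3"),
    block = rep(c("source", "space"), each = 3),
    rt_mean_ms = c(720, 690, 760, 940, 860, 990),
    accuracy = c(0.87, 0.92, 0.83, 0.71, 0.82, 0.66),
    shape = 4,
    stringsAsFactors = FALSE)
}

#' Generate a same-different behavioral table
#'
#' Per subject and comparison category, `trials_per_category` trials with
#' gamma-distributed reaction times (distribution mean equal to the mapped
#' target, scaled by a mild subject-level gain) and Bernoulli correctness at
#' the target accuracy.
#'
#' @param config a `generator_config` (supplies `n_subjects` and the seed).
#' @param latency_map data.frame as returned by [default_latency_map()].
#' @param trials_per_category trials per subject and category.
#' @param rt_subject_sd standard deviation of the multiplicative per-subject
#'   reaction-time gain.
#' @param seed optional override of `config$seed`.
#' @return data.frame with columns `subject`, `block`, `category`, `rt_ms`,
#'   `correct`.
#' @export
generate_behavior_table <- function(config,
                                    latency_map = default_latency_map(),
                                    trials_per_category = 36,
                                    rt_subject_sd = 0.08, seed = NULL) {
  if (any(latency_map$accuracy <= 0 | latency_map$accuracy > 1))
    stopf("latency_map accuracies must lie in (0, 1]")
  if (any(latency_map$rt_mean_ms <= 0)) stopf("target mean RTs must be > 0")
  seed <- seed %||% config$seed
  with_seed(child_seed(seed, 31L), {
    out <- vector("list", config$n_subjects * nrow(latency_map))
    k <- 0L
    for (s in seq_len(config$n_subjects)) {
      gain <- max(0.5, 1 + rt_subject_sd * rnorm(1))
      for (r in seq_len(nrow(latency_map))) {
        k <- k + 1L
        sh <- latency_map$shape[r]
        mu <- latency_map$rt_mean_ms[r] * gain
        out[[k]] <- data.frame(
          subject = sprintf("S%02d", s),
          block = latency_map$block[r],
          category = latency_map$category[r],
          rt_ms = rgamma(trials_per_category, shape = sh, rate = sh / mu),
          correct = as.integer(runif(trials_per_category) <=
                                 latency_map$accuracy[r]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}
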