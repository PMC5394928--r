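# Gammatone cochleograms and time-resolved stimulus dissimilarity curves
# (the low-level acoustic control model).

erb_of <- function(f) 24.7 * (4.37 * f / 1000 + 1)
erb_number <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
erb_number_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' ERB-spaced gammatone center frequencies
#' @param n number of subbands.
#' @param fmin,fmax frequency range, Hz.
#' @return numeric vector of center frequencies (Hz), increasing.
#' @export
gammatone_centers <- function(n = 64, fmin = 20, fmax = 20000) {
  erb_number_inv(seq(erb_number(fmin), erb_number(fmax), length.out = n))
}

#' Gammatone cochleogram
#'
#' Passes a mono waveform (standardized to exactly 44,100 samples at
#' 44.1 kHz by truncation or zero-padding) through a 4th-order gammatone
#' filterbank with 64 ERB-spaced center frequencies spanning 20-20,000 Hz,
#' then sums the squared filter output within overlapping 20-ms windows
#' advancing in 5-ms steps.  The standardized input yields exactly 200 time
#' bins (the tail is zero-padded).
#'
#' @param wave numeric vector (mono waveform).
#' @param sr sample rate, Hz (must be 44100).
#' @param n_bands number of gammatone subbands.
#' @param bin_step_ms,bin_width_ms analysis window step and width, ms.
#' @return object of class `cochleogram`: list with `energy` (bands x bins),
#'   `center_frequencies`, `bin_times_ms` (bin start times) and the window
#'   parameters.
#' @export
gammatone_cochleogram <- function(wave, sr = 44100, n_bands = 64,
                                  bin_step_ms = 5, bin_width_ms = 20) {
  if (is.matrix(wave) && ncol(wave) > 1) stopf("multichannel input not supported")
  wave <- as.numeric(wave)
  if (!length(wave)) stopf("empty waveform")
  n_std <- sr # one second standardized
  if (length(wave) >= n_std) wave <- wave[seq_len(n_std)]
  else wave <- c(wave, numeric(n_std - length(wave)))

  cfs <- gammatone_centers(n_bands)
  n_bins <- floor(n_std / (bin_step_ms / 1000 * sr)) # 200 for 44100 samples
  step <- n_std / n_bins
  width <- round(bin_width_ms / 1000 * sr)

  ir_len <- 4096L
  tt <- (seq_len(ir_len) - 1) / sr
  nf <- stats::nextn(n_std + ir_len, 2)
  W <- stats::fft(c(wave, numeric(nf - n_std)))
  energy <- matrix(0, n_bands, n_bins)
  for (bi in seq_len(n_bands)) {
    f <- cfs[bi]
    b <- 1.019 * erb_of(f)
    g <- tt^3 * exp(-2 * pi * b * tt) * cos(2 * pi * f * tt)
    H <- stats::fft(c(g, numeric(nf - ir_len)))
    # unit gain at the center frequency
    k <- round(f / sr * nf) + 1
    gain <- Mod(H[k])
    if (gain < 1e-30) gain <- 1
    y <- Re(stats::fft(W * H / gain, inverse = TRUE)) / nf
    y <- y[seq_len(n_std)]
    y2 <- c(y^2, numeric(width)) # zero-padded tail
    starts <- round((seq_len(n_bins) - 1) * step) + 1
    # direct window sums (a running cumulative sum cancels catastrophically
    # in the low-energy tail)
    energy[bi, ] <- vapply(starts, function(s0)
      sum(y2[s0:min(s0 + width - 1, length(y2))]), numeric(1))
  }
  # gate FFT round-off in silent bins to exact zero so that zero-variance
  # handling (and amplitude-scale invariance) is well defined
  if (max(energy) > 0) {
    energy[energy < 1e-20 * max(energy)] <- 0
  }
  structure(list(energy = energy, center_frequencies = cfs,
                 bin_times_ms = seq_len(n_bins) * bin_step_ms,
                 bin_step_ms = bin_step_ms, bin_width_ms = bin_width_ms),
            class = "cochleogram")
}

coch_energy <- function(x) if (inherits(x, "cochleogram")) x$energy else x

#' Pairwise cochleogram dissimilarity time course
#'
#' For each time bin and each stimulus pair, the 64-element subband-energy
#' vectors of the two cochleograms are Pearson-correlated and subtracted
#' from 1; the curve value is the mean over pairs.  Bins where either vector
#' has zero variance contribute dissimilarity 1 (the no-information value),
#' keeping the curve defined over silent onsets.
#'
#' @param cochleograms list of `cochleogram`s (or bands x bins matrices) of
#'   equal shape, length >= 2.
#' @param pairs optional 2-column matrix of index pairs; defaults to all
#'   unordered pairs.
#' @return numeric dissimilarity per time bin, in [0, 2].
#' @export
dissimilarity_timecourse <- function(cochleograms, pairs = NULL) {
  mats <- lapply(cochleograms, coch_energy)
  dm <- dim(mats[[1]])
  if (any(!vapply(mats, function(m) identical(dim(m), dm), logical(1))))
    stopf("cochleogram shapes differ")
  n <- length(mats)
  if (n < 2) stopf("need >= 2 cochleograms")
  if (is.null(pairs)) pairs <- t(utils::combn(n, 2))
  out <- numeric(dm[2])
  for (t in seq_len(dm[2])) {
    d <- apply(pairs, 1, function(pr) {
      a <- mats[[pr[1]]][, t]
      b <- mats[[pr[2]]][, t]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(1)
      1 - stats::cor(a, b)
    })
    out[t] <- mean(d)
  }
  out
}

#' Pooled (per-factor) dissimilarity curves
#'
#' Averages the cochleograms within each level of `factor` (3 levels), then
#' computes the dissimilarity curve across the 3 level pairs — the acoustic
#' analogue of the pooled decoding analysis.
#'
#' @param cochleograms list of 9 cochleograms.
#' @param labels data.frame with columns `source` and `space` (one row per
#'   cochleogram).
#' @param factor `"source"` or `"space"`.
#' @return numeric dissimilarity curve.
#' @export
pooled_dissimilarity <- function(cochleograms, labels,
                                 factor = c("source", "space")) {
  factor <- match.arg(factor)
  lab <- labels[[factor]]
  if (!all(1:3 %in% lab)) stopf("missing factorial levels for %s", factor)
  pooled <- lapply(1:3, function(l) {
    ms <- lapply(cochleograms[lab == l], coch_energy)
    Reduce(`+`, ms) / length(ms)
  })
  dissimilarity_timecourse(pooled)
}

#' Peak time of a dissimilarity curve
#'
#' @param curve numeric curve over time bins.
#' @param bin_step_ms bin step, ms.
#' @param bin_times_ms optional explicit bin times (start times).
#' @return time (ms) of the global maximum; ties break to the earliest bin.
#' @export
curve_peak <- function(curve, bin_step_ms = 5, bin_times_ms = NULL) {
  if (all(is.na(curve))) stopf("all-NA curve")
  tms <- bin_times_ms %||% (seq_along(curve) * bin_step_ms)
  tms[which.max(curve)]
}
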