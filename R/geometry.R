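# Categorical versus ordinal space-size model RDMs and their time-resolved
# correlation with neural decoding RDMs.

#' Model RDM for space-size coding
#'
#' 9 x 9 representational dissimilarity matrices over the factorial
#' conditions (ordering as in [condition_levels()]), depending only on the
#' space levels of the two conditions, irrespective of sound source:
#' `"categorical"` entries are 0 for same space level and 1 otherwise;
#' `"ordinal"` entries are the absolute space-rank difference (0, 1 or 2).
#' The diagonal is NA.
#'
#' @param kind `"categorical"` or `"ordinal"`.
#' @return 9 x 9 model matrix.
#' @export
build_model_rdm <- function(kind = c("categorical", "ordinal")) {
  kind <- match.arg(kind)
  sp <- condition_levels()$space
  m <- outer(sp, sp, function(a, b) abs(a - b))
  if (kind == "categorical") m <- (m >= 1) + 0
  diag(m) <- NA_real_
  m
}

#' Time-resolved model-neural RDM correlation
#'
#' Spearman rank correlation between the 36 lower-triangle entries of a
#' model RDM and of the neural decoding RDM at each time point inside the
#' analysis window (chosen in the emulated analysis as the half-open window
#' of significant space decoding, [138, 801) ms).
#'
#' @param neural an `rdm_series` (e.g. subject-mean) or a 9 x 9 x T array.
#' @param model a model RDM from [build_model_rdm()].
#' @param window_ms length-2 numeric: half-open window \[lo, hi) in ms.
#' @param time_ms time axis (taken from the `rdm_series` if omitted).
#' @return list with `rho` (per time point in the window), `time_ms`.
#' @export
model_neural_correlation <- function(neural, model, window_ms = c(138, 801),
                                     time_ms = NULL) {
  if (inherits(neural, "rdm_series")) {
    time_ms <- neural$time_ms
    arr <- neural$acc
  } else arr <- neural
  if (is.null(time_ms)) stopf("time_ms required for array input")
  idx <- which(time_ms >= window_ms[1] & time_ms < window_ms[2])
  if (!length(idx)) stopf("window outside the neural series")
  lower <- which(lower.tri(matrix(0, 9, 9)))
  mv <- model[lower]
  rho <- vapply(idx, function(t) {
    stats::cor(arr[, , t][lower], mv, method = "spearman")
  }, numeric(1))
  list(rho = rho, time_ms = time_ms[idx])
}

#' Compare ordinal and categorical model fits
#'
#' Paired t-test across the time points of the analysis window between the
#' ordinal-model and categorical-model correlation time courses (pairing by
#' time point, as in the emulated analysis).  One-sided by default (ordinal
#' fits better); identical courses give a mean difference of 0 and p = 1.
#'
#' @param rho_ordinal,rho_categorical numeric rho time courses over the same
#'   window.
#' @param alternative `"greater"` (ordinal > categorical) or `"two.sided"`.
#' @return list with `mean_diff`, `p`, `t`, `df`, `n_timepoints`.
#' @export
compare_models <- function(rho_ordinal, rho_categorical,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(rho_ordinal) != length(rho_categorical))
    stopf("mismatched windows")
  d <- rho_ordinal - rho_categorical
  if (stats::sd(d) < 1e-14) {
    return(list(mean_diff = mean(d), p = 1, t = NA_real_,
                df = length(d) - 1, n_timepoints = length(d)))
  }
  tt <- stats::t.test(rho_ordinal, rho_categorical, paired = TRUE,
                      alternative = alternative)
  list(mean_diff = unname(tt$estimate), p = tt$p.value,
       t = unname(tt$statistic), df = unname(tt$parameter),
       n_timepoints = length(d))
}
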