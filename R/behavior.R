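# Same-different behavioral analysis: comparison-category binning,
# gamma-fit mean reaction times, accuracy summaries.

canonical_category <- function(x) {
  # normalize e.g. "Sp2-1" to "Sp1-2"; same-pair labels pass through
  pre <- substr(x, 1, 2)
  rest <- substring(x, 3)
  parts <- strsplit(rest, "-", fixed = TRUE)
  vapply(seq_along(x), function(i) {
    p <- suppressWarnings(as.integer(parts[[i]]))
    if (length(p) != 2 || anyNA(p)) stopf("unknown pair label: %s", x[i])
    paste0(pre[i], min(p), "-", max(p))
  }, character(1))
}

#' Bin behavioral trials into comparison categories
#'
#' Groups trials by subject and comparison category.  The 6 "different"
#' categories (So1-2, So1-3, So2-3, Sp1-2, Sp1-3, Sp2-3) are returned for
#' analysis; same-pair trials (e.g. Sp1-1) are split out separately — they
#' contribute to accuracy bookkeeping but are excluded from the
#' different-pair reaction-time bins.
#'
#' @param table behavioral data.frame with columns `subject`, `category`,
#'   `rt_ms`, `correct`.
#' @return list with `bins` (data.frame of different-pair trials, categories
#'   normalized), `same_trials`, `categories` (the 6 category labels
#'   present).
#' @export
bin_comparison_categories <- function(table) {
  if (!nrow(table))
    return(list(bins = table, same_trials = table[0, ], categories = character(0)))
  cat0 <- canonical_category(table$category)
  lv <- t(vapply(strsplit(substring(cat0, 3), "-", fixed = TRUE),
                 as.integer, integer(2)))
  same <- lv[, 1] == lv[, 2]
  bins <- table[!same, , drop = FALSE]
  bins$category <- cat0[!same]
  list(bins = bins, same_trials = table[same, , drop = FALSE],
       categories = sort(unique(bins$category)))
}

#' Gamma-fit mean reaction time
#'
#' Maximum-likelihood gamma fit (method-of-moments initialization); the mean
#' is shape x scale.  Degenerate constant samples return the common value.
#'
#' @param rts reaction times, ms (>= 5 positive values).
#' @return fitted mean RT, ms.
#' @export
gamma_mean_rt <- function(rts) {
  rts <- as.numeric(rts)
  if (length(rts) < 5) stopf("need >= 5 reaction times")
  if (any(rts <= 0)) stopf("reaction times must be positive")
  if (stats::sd(rts) < 1e-9) return(mean(rts))
  m <- mean(rts); v <- stats::var(rts)
  start <- list(shape = m^2 / v, rate = m / v)
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(rts, "gamma", start = start,
                                    lower = c(1e-6, 1e-9))),
    error = function(e) NULL)
  if (is.null(fit)) return(m) # fall back to the moment estimate
  unname(fit$estimate["shape"] / fit$estimate["rate"])
}

#' Per-subject, per-category behavioral summary
#'
#' Mean accuracy (fraction correct, all different-pair trials) and gamma-fit
#' mean reaction time (correct different-pair trials only) per subject and
#' comparison category.
#'
#' @param table behavioral data.frame (`subject`, `category`, `rt_ms`,
#'   `correct`).
#' @return data.frame with columns `subject`, `category`, `block`,
#'   `accuracy`, `rt_ms`, `n_trials`.
#' @export
behavior_summary <- function(table) {
  b <- bin_comparison_categories(table)$bins
  if (!nrow(b)) stopf("no different-pair trials to summarize")
  groups <- split(b, list(b$subject, b$category), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    ok <- g$correct == 1
    data.frame(subject = g$subject[1], category = g$category[1],
               block = if (startsWith(g$category[1], "So")) "source" else "space",
               accuracy = mean(g$correct),
               rt_ms = if (sum(ok) >= 5) gamma_mean_rt(g$rt_ms[ok])
                       else mean(g$rt_ms[ok]),
               n_trials = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Category accuracies
#'
#' @param bins result of [bin_comparison_categories()] (or its `bins`
#'   element).
#' @return data.frame `subject`, `category`, `accuracy`.
#' @export
category_accuracy <- function(bins) {
  b <- if (is.list(bins) && !is.data.frame(bins)) bins$bins else bins
  if (!nrow(b)) stopf("empty bins")
  agg <- stats::aggregate(correct ~ subject + category, data = b, FUN = mean)
  names(agg)[3] <- "accuracy"
  agg
}
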