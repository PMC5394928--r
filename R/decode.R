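# Time-resolved pairwise SVM decoding with trial subaveraging and
# leave-one-out cross-validation, plus pooled, cross-classified, sensorwise
# and temporally generalized variants.

#' Decoding parameters
#'
#' @param k subaverage group size (trials per pseudo-trial).
#' @param K number of random subaverage repetitions averaged per accuracy.
#' @param C linear SVM regularization constant.
#' @param scale `"none"` (default; homogeneous sensor units) or `"zscore"`
#'   (per-channel standardization using training-fold statistics, for mixed
#'   magnetometer/gradiometer units).
#' @param seed integer seed controlling the random subaverage partitions.
#' @return an object of class `decoding_params`.
#' @export
decoding_params <- function(k = 10, K = 100, C = 1,
                            scale = c("none", "zscore"), seed = 1) {
  scale <- match.arg(scale)
  if (k < 1 || K < 1) stopf("k and K must be >= 1")
  structure(list(k = as.integer(k), K = as.integer(K), C = C, scale = scale,
                 seed = as.integer(seed)), class = "decoding_params")
}

#' Condition ordering of the 3 x 3 factorial design
#'
#' Conditions are indexed 1..9 in (source, space) lexicographic order:
#' condition `(s, r)` has index `(s - 1) * 3 + r`.
#'
#' @return data.frame with columns `index`, `source`, `space`.
#' @export
condition_levels <- function() {
  data.frame(index = 1:9, source = rep(1:3, each = 3), space = rep(1:3, 3))
}

# d x T x M cube of the trials selected by `idx`.  Epoch data are publicly
# trials x sensors x time; the fused simulation path stores the native
# sensors x time x trials layout (attribute "layout" == "dtn").
trials_cube <- function(epochs, idx) {
  if (identical(attr(epochs$data, "layout"), "dtn"))
    epochs$data[, , idx, drop = FALSE]
  else aperm(epochs$data[idx, , , drop = FALSE], c(2, 3, 1))
}

# channel-subset epoch set regardless of layout
subset_channels <- function(epochs, chan) {
  if (identical(attr(epochs$data, "layout"), "dtn")) {
    epochs$data <- epochs$data[chan, , , drop = FALSE]
    attr(epochs$data, "layout") <- "dtn"
  } else {
    epochs$data <- epochs$data[, chan, , drop = FALSE]
  }
  epochs$triplet_index <- epochs$triplet_index[chan]
  epochs
}

make_perms <- function(M, K) {
  matrix(unlist(lapply(seq_len(K), function(i) sample.int(M))), M, K)
}

#' Random subaveraging into pseudo-trials
#'
#' Randomly partitions the trials (rows of `x`) without replacement into
#' `floor(n / k)` disjoint groups of `k` and averages within groups; the
#' `n mod k` leftover trials are dropped for this draw.
#'
#' @param x trials x features matrix.
#' @param k group size (`k = 1` returns the trials in permuted order).
#' @param seed optional seed for the partition.
#' @return `floor(n / k)` x features matrix of pseudo-trials.
#' @export
subaverage <- function(x, k, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stopf("k (%d) exceeds the class trial count (%d)", k, n)
  G <- n %/% k
  run <- function() {
    ord <- sample.int(n)
    out <- matrix(0, G, ncol(x))
    for (g in seq_len(G))
      out[g, ] <- colMeans(x[ord[((g - 1) * k + 1):(g * k)], , drop = FALSE])
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Pairwise LOO SVM accuracy at one time point
#'
#' Leave-one-out cross-validation over pseudo-trial index: each fold holds
#' out one pseudo-trial per class jointly, trains a linear SVM (cost
#' `params$C`) on the rest and tests the held-out pair; accuracy is the
#' percentage correct over all folds and both test items.  Decision ties
#' (decision value exactly 0) are assigned to the first class.
#'
#' @param xa,xb pseudo-trial x feature matrices for the two classes (equal
#'   row counts, >= 2).
#' @param params a [decoding_params()].
#' @return accuracy in percent (chance = 50).
#' @export
pairwise_accuracy <- function(xa, xb, params = decoding_params()) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  if (nrow(xa) != nrow(xb)) stopf("classes need equal pseudo-trial counts")
  if (nrow(xa) < 2) stopf("need >= 2 pseudo-trials per class")
  if (all(abs(rbind(xa, xb) - rep(colMeans(rbind(xa, xb)),
                                  each = 2 * nrow(xa))) < 1e-12)) {
    warning("degenerate (all-identical) features: returning chance (50)")
    return(50)
  }
  cpp_loo_accuracy(xa, xb, params$C, params$scale == "zscore")
}

#' Time course of decoding accuracy for one condition pair
#'
#' @param cubeA,cubeB sensors x time x trials cubes for the two classes.
#' @param params a [decoding_params()].
#' @param average return the K-average (default) or the T x K matrix.
#' @return accuracy (%) per time point, or a T x K matrix.
#' @keywords internal
pair_course <- function(cubeA, cubeB, params, average = TRUE) {
  MA <- dim(cubeA)[3]; MB <- dim(cubeB)[3]
  if (min(MA, MB) < params$k) stopf("k exceeds the class trial count")
  pA <- make_perms(MA, params$K)
  pB <- make_perms(MB, params$K)
  acc <- cpp_pair_course(cubeA, cubeB, pA, pB, params$k, params$C,
                         params$scale == "zscore")
  if (average) rowMeans(acc) else acc
}

#' Pairwise decoding RDM time course
#'
#' For every time point and every pair of the 9 conditions, computes the
#' subaveraged LOO SVM accuracy averaged over `params$K` random subaverage
#' draws, arranged as a symmetric 9 x 9 decoding representational
#' dissimilarity matrix (RDM) per time point (diagonal undefined).  Within
#' each repetition every condition is subaveraged once and the resulting
#' pseudo-trials are shared across all pairs involving that condition.
#'
#' @param epochs a preprocessed [epoch_set()] with all 9 conditions.
#' @param params a [decoding_params()] (whole-RDM analysis uses k = 10,
#'   K = 100 at full scale).
#' @return object of class `rdm_series`: list with `acc` (9 x 9 x T array,
#'   %), `time_ms` and `condition` (the ordering table).
#' @export
rdm_timecourse <- function(epochs, params = decoding_params(k = 10, K = 100)) {
  lev <- condition_levels()
  cubes <- lapply(seq_len(9), function(ci) {
    idx <- which(epochs$source == lev$source[ci] & epochs$space == lev$space[ci])
    trials_cube(epochs, idx)
  })
  Tn <- length(epochs$time_ms)
  acc <- array(NA_real_, dim = c(9, 9, Tn))
  if (params$scale == "zscore") {
    for (a in 1:8) for (b in (a + 1):9) {
      course <- with_seed(child_seed(params$seed, 101L, a, b),
                          pair_course(cubes[[a]], cubes[[b]], params))
      acc[a, b, ] <- course
      acc[b, a, ] <- course
    }
  } else {
    # each condition is subaveraged once per repetition; the partition is
    # shared across all pairs involving that condition
    perms <- with_seed(child_seed(params$seed, 131L),
                       lapply(cubes, function(cc)
                         make_perms(dim(cc)[3], params$K)))
    courses <- cpp_rdm_course(cubes, perms, params$k, params$C) # T x 36
    pr <- 0L
    for (a in 1:8) for (b in (a + 1):9) {
      pr <- pr + 1L
      acc[a, b, ] <- courses[, pr]
      acc[b, a, ] <- courses[, pr]
    }
  }
  structure(list(acc = acc, time_ms = epochs$time_ms, condition = lev),
            class = "rdm_series")
}

#' Grand-mean decoding time course
#'
#' Mean of the 36 pairwise accuracies of an RDM series at each time point
#' (the single-sound decoding time course).
#'
#' @param rdms an `rdm_series`.
#' @return numeric accuracy course (%).
#' @export
grand_mean_timecourse <- function(rdms) {
  lower <- which(lower.tri(matrix(0, 9, 9)))
  apply(rdms$acc, 3, function(m) mean(m[lower]))
}

#' Pooled 3-class pairwise decoding
#'
#' Pools trials across the orthogonal factor (3M trials per class) and
#' decodes every pair of the three levels of `factor`; at full scale the
#' pooled analysis uses k = 30, K = 300.
#'
#' @param epochs a preprocessed [epoch_set()].
#' @param factor the decoded factor, `"source"` or `"space"`.
#' @param params a [decoding_params()].
#' @return list with `pairs` (3 x T accuracy matrix, rows "1-2", "1-3",
#'   "2-3"), `mean` (their average), `time_ms`, `factor`.
#' @export
pooled_decode <- function(epochs, factor = c("source", "space"),
                          params = decoding_params(k = 30, K = 300)) {
  factor <- match.arg(factor)
  lab <- epochs[[factor]]
  cubes <- lapply(1:3, function(l) trials_cube(epochs, which(lab == l)))
  prs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  out <- matrix(NA_real_, 3, length(epochs$time_ms),
                dimnames = list(c("1-2", "1-3", "2-3"), NULL))
  for (i in 1:3) {
    a <- prs[i, 1]; b <- prs[i, 2]
    out[i, ] <- with_seed(child_seed(params$seed, 211L, match(factor, c("source", "space")), a, b),
                          pair_course(cubes[[a]], cubes[[b]], params))
  }
  list(pairs = out, mean = colMeans(out), time_ms = epochs$time_ms,
       factor = factor)
}

#' Cross-classification across the orthogonal factor
#'
#' Trains classifiers to discriminate a pair of `factor` levels on trials
#' from two levels of the orthogonal factor (2M training trials per class,
#' subaveraged within each orthogonal level separately) and tests them on
#' pseudo-trials from the held-out third level.  All nine held-out-level x
#' decoded-pair combinations are averaged; at full scale k = 20, K = 150.
#'
#' @param epochs a preprocessed [epoch_set()] with the full 3 x 3 factorial.
#' @param factor the decoded factor, `"source"` or `"space"`.
#' @param params a [decoding_params()].
#' @return list with `mean` (accuracy course over the 9 combinations),
#'   `combinations` (9 x T matrix), `time_ms`, `factor`.
#' @export
cross_decode <- function(epochs, factor = c("source", "space"),
                         params = decoding_params(k = 20, K = 150)) {
  factor <- match.arg(factor)
  orth <- setdiff(c("source", "space"), factor)
  dl <- epochs[[factor]]
  ol <- epochs[[orth]]
  if (any(condition_counts(epochs) == 0)) stopf("empty factorial cell")
  rn <- as.vector(t(outer(1:3, c("1-2", "1-3", "2-3"),
                          function(h, p) sprintf("holdout%d_%s", h, p))))
  if (params$scale == "zscore") {
    prs <- rbind(c(1, 2), c(1, 3), c(2, 3))
    combos <- matrix(NA_real_, 9, length(epochs$time_ms))
    row <- 0L
    for (h in 1:3) {
      tr_lv <- setdiff(1:3, h)
      for (i in 1:3) {
        a <- prs[i, 1]; b <- prs[i, 2]
        row <- row + 1L
        cube <- function(dv, ov) trials_cube(epochs, which(dl == dv & ol == ov))
        tA1 <- cube(a, tr_lv[1]); tA2 <- cube(a, tr_lv[2])
        tB1 <- cube(b, tr_lv[1]); tB2 <- cube(b, tr_lv[2])
        teA <- cube(a, h); teB <- cube(b, h)
        combos[row, ] <- with_seed(
          child_seed(params$seed, 307L, match(factor, c("source", "space")),
                     h, a, b), {
            K <- params$K
            acc <- cpp_cross_course(
              tA1, tA2, tB1, tB2, teA, teB,
              make_perms(dim(tA1)[3], K), make_perms(dim(tA2)[3], K),
              make_perms(dim(tB1)[3], K), make_perms(dim(tB2)[3], K),
              make_perms(dim(teA)[3], K), make_perms(dim(teB)[3], K),
              params$k, params$C, TRUE)
            rowMeans(acc)
          })
      }
    }
  } else {
    # each factorial cell subaveraged once per repetition, pseudo-trials
    # shared across the nine train/test combinations
    cells <- vector("list", 9L)
    for (dv in 1:3) for (ov in 1:3)
      cells[[(dv - 1L) * 3L + ov]] <-
        trials_cube(epochs, which(dl == dv & ol == ov))
    perms <- with_seed(
      child_seed(params$seed, 307L, match(factor, c("source", "space"))),
      lapply(cells, function(cc) make_perms(dim(cc)[3], params$K)))
    combos <- t(cpp_cross_factor(cells, perms, params$k, params$C))
  }
  rownames(combos) <- rn
  list(mean = colMeans(combos), combinations = combos,
       time_ms = epochs$time_ms, factor = factor)
}

#' Sensorwise decoding
#'
#' Repeats the whole-helmet pairwise RDM analysis at each sensor-triplet
#' location, using only that location's 3 channels as the pattern vector,
#' and returns the grand-mean (all condition pairs) accuracy course per
#' location.
#'
#' @param epochs a preprocessed [epoch_set()] with a `triplet_index`.
#' @param params a [decoding_params()].
#' @return locations x time accuracy matrix (%).
#' @export
sensorwise_decode <- function(epochs, params = decoding_params(k = 10, K = 100)) {
  if (is.null(epochs$triplet_index)) stopf("epochs lack a triplet map")
  locs <- sort(unique(epochs$triplet_index))
  out <- matrix(NA_real_, length(locs), length(epochs$time_ms))
  for (li in seq_along(locs)) {
    chan <- which(epochs$triplet_index == locs[li])
    sub <- subset_channels(epochs, chan)
    p <- params
    p$seed <- child_seed(params$seed, 401L, li)
    out[li, ] <- grand_mean_timecourse(rdm_timecourse(sub, p))
  }
  rownames(out) <- paste0("loc", locs)
  out
}

#' Temporal generalization matrix
#'
#' Pooled decoding of `factor` in which the classifier trained at time t
#' (per LOO fold) is tested on the held-out pseudo-trials at every time t'.
#' Rows index training time, columns testing time; the diagonal equals the
#' standard pooled time course up to Monte-Carlo error.
#'
#' @param epochs a preprocessed [epoch_set()].
#' @param factor the decoded factor.
#' @param params a [decoding_params()] (z-scoring is not supported here).
#' @return T x T accuracy matrix (%), averaged over the 3 level pairs and
#'   `params$K` repetitions.
#' @export
temporal_generalization <- function(epochs, factor = c("source", "space"),
                                    params = decoding_params(k = 30, K = 100)) {
  factor <- match.arg(factor)
  lab <- epochs[[factor]]
  cubes <- lapply(1:3, function(l) trials_cube(epochs, which(lab == l)))
  prs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  Tn <- length(epochs$time_ms)
  acc <- matrix(0, Tn, Tn)
  for (i in 1:3) {
    a <- prs[i, 1]; b <- prs[i, 2]
    acc <- acc + with_seed(
      child_seed(params$seed, 503L, match(factor, c("source", "space")), a, b), {
        MA <- dim(cubes[[a]])[3]; MB <- dim(cubes[[b]])[3]
        cpp_tempgen_course(cubes[[a]], cubes[[b]],
                           make_perms(MA, params$K), make_perms(MB, params$K),
                           params$k, params$C)
      })
  }
  acc / 3
}
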