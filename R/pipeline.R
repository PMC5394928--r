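# End-to-end orchestration of the simulated experiments: generation,
# preprocessing, decoding in all modes, group inference, model comparison
# and behavior coupling.

#' Per-subject, per-category MEG decoding summary
#'
#' Peak latency and peak accuracy of each subject's pooled pairwise decoding
#' course for the 6 comparison categories (3 source pairs from pooled source
#' decoding, 3 space pairs from pooled space decoding), with the peak search
#' restricted to the stimulus window.
#'
#' @param pooled_source,pooled_space lists of per-subject `pairs` matrices
#'   (3 x T) from [pooled_decode()].
#' @param time_ms time axis.
#' @param peak_window peak search window, ms.
#' @return data.frame `subject`, `category`, `peak_ms`, `peak_acc`.
#' @export
meg_category_summary <- function(pooled_source, pooled_space, time_ms,
                                 peak_window = c(0, Inf)) {
  win <- which(time_ms >= peak_window[1] & time_ms <= peak_window[2])
  one <- function(mat, prefix, subj) {
    do.call(rbind, lapply(rownames(mat), function(rn) {
      v <- mat[rn, win]
      data.frame(subject = subj,
                 category = paste0(prefix, sub("-", "-", rn)),
                 peak_ms = time_ms[win[which.max(v)]],
                 peak_acc = max(v), stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, c(
    lapply(seq_along(pooled_source), function(s)
      one(pooled_source[[s]], "So", sprintf("S%02d", s))),
    lapply(seq_along(pooled_space), function(s)
      one(pooled_space[[s]], "Sp", sprintf("S%02d", s)))))
  rownames(out) <- NULL
  out
}

#' Run the simulated single-impact experiment
#'
#' Streams the cohort subject by subject (generate, baseline-correct,
#' low-pass filter, decode), then performs group inference.  Stages are
#' selectable; everything is deterministic given the configuration seed.
#'
#' @param config a [generator_config()].
#' @param modes subset of `c("single", "pooled", "cross", "models",
#'   "behavior")`.
#' @param params_single,params_pooled,params_cross [decoding_params()] for
#'   the corresponding analyses.
#' @param infer_cfg a [test_config()].
#' @param peak_window peak search window, ms.
#' @param null_effects zero both effect amplitudes (null-mode run).
#' @return result bundle: list with per-subject decoding courses, group
#'   inference per mode, model comparison, behavior coupling and a manifest.
#' @export
run_experiment1 <- function(config,
                            modes = c("single", "pooled", "cross", "models",
                                      "behavior"),
                            params_single = decoding_params(k = 10, K = 20),
                            params_pooled = decoding_params(k = 30, K = 30),
                            params_cross = decoding_params(k = 20, K = 30),
                            infer_cfg = test_config(n_perm = 500,
                                                    n_boot_latency = 200,
                                                    n_boot_behavior = 2000),
                            peak_window = c(0, Inf),
                            null_effects = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  if ("models" %in% modes && !("single" %in% modes))
    stopf("mode 'models' requires mode 'single'")
  if ("behavior" %in% modes && !("pooled" %in% modes))
    stopf("mode 'behavior' requires mode 'pooled'")
  if (null_effects) {
    config$snr_source <- 0
    config$snr_space <- 0
  }
  topo <- make_topographies(config)
  N <- config$n_subjects
  Tn <- length(config_time(config))

  res <- list(config = config, time_ms = config_time(config),
              manifest = list(seed = config$seed, modes = modes,
                              params = list(single = params_single,
                                            pooled = params_pooled,
                                            cross = params_cross),
                              infer = infer_cfg, started = Sys.time()))
  single_grand <- matrix(NA_real_, N, Tn)
  rdm_sum <- array(0, dim = c(9, 9, Tn))
  pooled_src <- vector("list", N); pooled_spc <- vector("list", N)
  cross_src <- matrix(NA_real_, N, Tn); cross_spc <- matrix(NA_real_, N, Tn)

  for (s in seq_len(N)) {
    es <- simulate_preprocessed_subject(config, s, topographies = topo)
    if ("single" %in% modes) {
      p <- params_single; p$seed <- child_seed(config$seed, 1L, s)
      rdm <- rdm_timecourse(es, p)
      single_grand[s, ] <- grand_mean_timecourse(rdm)
      rdm_sum <- rdm_sum + rdm$acc
      res$subject_rdm[[s]] <- rdm$acc
    }
    if ("pooled" %in% modes) {
      p <- params_pooled; p$seed <- child_seed(config$seed, 2L, s)
      pooled_src[[s]] <- pooled_decode(es, "source", p)$pairs
      p$seed <- child_seed(config$seed, 3L, s)
      pooled_spc[[s]] <- pooled_decode(es, "space", p)$pairs
    }
    if ("cross" %in% modes) {
      p <- params_cross; p$seed <- child_seed(config$seed, 4L, s)
      cross_src[s, ] <- cross_decode(es, "source", p)$mean
      p$seed <- child_seed(config$seed, 5L, s)
      cross_spc[s, ] <- cross_decode(es, "space", p)$mean
    }
    rm(es)
  }

  tms <- res$time_ms
  infer_one <- function(courses, tag) {
    perm <- sign_permutation_pvalues(courses, infer_cfg,
                                     seed = child_seed(config$seed, 9L, tag))
    cluster_correct(perm, tms, infer_cfg, peak_window)
  }

  if ("single" %in% modes) {
    res$single <- list(courses = single_grand,
                       mean = colMeans(single_grand),
                       inference = infer_one(single_grand, 1L))
    res$mean_rdm <- rdm_sum / N
  }
  if ("pooled" %in% modes) {
    res$pooled <- list()
    for (f in c("source", "space")) {
      lst <- if (f == "source") pooled_src else pooled_spc
      courses <- do.call(rbind, lapply(lst, colMeans))
      res$pooled[[f]] <- list(subject_pairs = lst, courses = courses,
                              mean = colMeans(courses),
                              inference = infer_one(courses,
                                                    if (f == "source") 2L else 3L))
    }
  }
  if ("cross" %in% modes) {
    res$cross <- list(
      source = list(courses = cross_src, mean = colMeans(cross_src),
                    inference = infer_one(cross_src, 4L)),
      space = list(courses = cross_spc, mean = colMeans(cross_spc),
                   inference = infer_one(cross_spc, 5L)))
  }
  if ("models" %in% modes) {
    mean_rdm <- list(acc = res$mean_rdm, time_ms = tms)
    class(mean_rdm) <- "rdm_series"
    rho_o <- model_neural_correlation(mean_rdm, build_model_rdm("ordinal"))
    rho_c <- model_neural_correlation(mean_rdm, build_model_rdm("categorical"))
    res$models <- list(rho_ordinal = rho_o, rho_categorical = rho_c,
                       comparison = compare_models(rho_o$rho, rho_c$rho))
  }
  if ("behavior" %in% modes) {
    btab <- generate_behavior_table(config)
    bsum <- behavior_summary(btab)
    msum <- meg_category_summary(lapply(pooled_src, identity),
                                 lapply(pooled_spc, identity), tms,
                                 peak_window = c(0, max(tms)))
    res$behavior <- list(
      table = btab, summary = bsum, meg_summary = msum,
      rt_latency = behavior_meg_correlation(
        bsum, msum, "rt_ms", "peak_ms", infer_cfg,
        seed = child_seed(config$seed, 41L)),
      acc_acc = behavior_meg_correlation(
        bsum, msum, "accuracy", "peak_acc", infer_cfg,
        seed = child_seed(config$seed, 43L)))
  }
  res$manifest$finished <- Sys.time()
  res
}

#' Configuration for the duration-controlled repeated-impact experiment
#'
#' Same generator, with the epoch window extended to -200..2500 ms (2701
#' time points at 1-ms sampling) and 16 subjects.
#'
#' @param fast desk-scale overrides (5-ms step, 60 sensors).
#' @param ... further [generator_config()] overrides.
#' @return a `generator_config`.
#' @export
experiment2_config <- function(fast = FALSE, ...) {
  args <- list(...)
  defaults <- list(n_subjects = 16, time_end = 2500)
  if (fast) defaults <- c(defaults, list(sampling_step = 5, n_sensors = 60))
  do.call(generator_config, utils::modifyList(defaults, args))
}

#' Run the simulated repeated-impact experiment
#'
#' Same pipeline as [run_experiment1()] on the extended epochs; peak
#' searches are restricted to the 0-2000 ms window during which the
#' repeated stimulus is playing.
#'
#' @param config a `generator_config`, typically [experiment2_config()].
#' @param ... passed to [run_experiment1()].
#' @return result bundle (see [run_experiment1()]).
#' @export
run_experiment2 <- function(config = experiment2_config(), ...) {
  run_experiment1(config, peak_window = c(0, 2000), ...)
}

#' Load a run configuration from a YAML file
#'
#' The file may carry `generator`, `decode` and `inference` sections; fields
#' map directly onto [generator_config()], [decoding_params()] and
#' [test_config()] arguments.  A `seed` entry (top level or inside
#' `generator`) is required.
#'
#' @param path YAML file path.
#' @return list with elements `generator`, `decode`, `inference`.
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- y$generator %||% list()
  if (!is.null(y$seed)) gen$seed <- y$seed
  if (is.null(gen$seed)) stopf("config must set a seed")
  list(generator = do.call(generator_config, gen),
       decode = do.call(decoding_params, y$decode %||% list()),
       inference = do.call(test_config, y$inference %||% list()))
}

#' Export accuracy time courses to CSV
#'
#' @param courses matrix (rows = series) or vector of accuracies.
#' @param time_ms time axis.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_timecourse_csv <- function(courses, time_ms, path) {
  m <- if (is.matrix(courses)) t(courses) else matrix(courses)
  df <- data.frame(time_ms = time_ms, m)
  names(df)[-1] <- if (is.matrix(courses) && !is.null(rownames(courses)))
    rownames(courses) else paste0("series", seq_len(ncol(m)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
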