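# Shared fixtures: desk-scale configurations, hand-built epoch sets, and an
# independent brute-force maximum-margin solver used as the SVM oracle.

tiny_config <- function(...) {
  generator_config(fast = TRUE, n_subjects = 4, n_sensors = 12,
                   sampling_step = 10, time_end = 600,
                   trials_per_condition = 30, subaverage_sizes = c(10, 30),
                   ...)
}

# epoch set with known content: trials x sensors x time filled from a
# function of (trial, sensor, time index)
manual_epochs <- function(n_per_cond = 2, d = 6, time_ms = seq(-100, 200, 20),
                          fill = function(i, s, t) 0, noise_sd = 0,
                          seed = 1) {
  lev <- expand.grid(source = 1:3, space = 1:3)
  n <- nrow(lev) * n_per_cond
  Tn <- length(time_ms)
  set.seed(seed)
  dat <- array(rnorm(n * d * Tn, sd = max(noise_sd, 1e-12)), c(n, d, Tn))
  for (i in seq_len(n)) for (s in seq_len(d))
    dat[i, s, ] <- dat[i, s, ] + vapply(seq_len(Tn),
                                        function(t) fill(i, s, t), numeric(1))
  epoch_set(dat, time_ms,
            source = rep(lev$source, each = n_per_cond),
            space = rep(lev$space, each = n_per_cond),
            triplet_index = rep(seq_len(d %/% 3), each = 3))
}

# Hard-margin maximum-margin separator by active-set enumeration: for every
# candidate support set (mixed-class subsets of size 2..d+1), solve the KKT
# equality system and keep the solution that satisfies dual feasibility and
# all margin constraints.  Valid when the data are separable with a margin
# wide enough that the box constraint of a C = 1 soft-margin SVM is
# inactive (sum of alphas = ||w||^2 << C).
bf_max_margin <- function(X, y) {
  n <- nrow(X)
  d <- ncol(X)
  best <- NULL
  for (sz in 2:min(n, d + 1)) {
    for (S in utils::combn(n, sz, simplify = FALSE)) {
      ys <- y[S]
      if (length(unique(ys)) < 2) next
      G <- outer(ys, ys) * (X[S, , drop = FALSE] %*% t(X[S, , drop = FALSE]))
      A <- rbind(cbind(G, ys), c(ys, 0))
      rhs <- c(rep(1, sz), 0)
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      lam <- sol[seq_len(sz)]
      b <- sol[sz + 1]
      if (any(lam < -1e-9)) next
      w <- drop(t(X[S, , drop = FALSE]) %*% (lam * ys))
      marg <- y * (X %*% w + b)
      if (all(marg >= 1 - 1e-7)) {
        cand <- list(w = w, b = b, normw = sum(w^2))
        if (is.null(best) || cand$normw > best$normw - 1e-12) {
          # the optimum is unique; keep any fully feasible KKT point
          best <- cand
        }
      }
    }
  }
  best
}

# exhaustive LOO accuracy using the brute-force separator
bf_loo_accuracy <- function(Xa, Xb) {
  G <- nrow(Xa)
  correct <- 0
  for (f in seq_len(G)) {
    X <- rbind(Xa[-f, , drop = FALSE], Xb[-f, , drop = FALSE])
    y <- c(rep(1, G - 1), rep(-1, G - 1))
    m <- bf_max_margin(X, y)
    if (is.null(m)) stop("oracle: training fold not separable")
    fA <- sum(m$w * Xa[f, ]) + m$b
    fB <- sum(m$w * Xb[f, ]) + m$b
    if (fA >= 0) correct <- correct + 1
    if (fB < 0) correct <- correct + 1
  }
  100 * correct / (2 * G)
}

# brute-force Benjamini-Hochberg step-up by direct definition
bf_bh <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0
  for (k in seq_len(n)) if (ps[k] <= k / n * q) kmax <- k
  rej <- logical(n)
  if (kmax > 0) rej[o[seq_len(kmax)]] <- TRUE
  rej
}
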