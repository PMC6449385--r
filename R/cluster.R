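#' Remove each subject's mean time course
#'
#' Subtracts, from every trial, the across-trials mean time course of the
#' subject who produced it. This plays the role of the behavioral model's
#' subject-specific intercept in the mass-univariate regression: after
#' demeaning, between-subject offsets cannot masquerade as condition
#' effects.
#'
#' @param data numeric matrix, trials x time.
#' @param subjects vector of subject identifiers, one per trial.
#' @return demeaned matrix of the same shape.
#' @export
subject_demean <- function(data, subjects) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(subjects))
  for (s in unique(subjects)) {
    ix <- which(subjects == s)
    mu <- colMeans(data[ix, , drop = FALSE])
    data[ix, ] <- sweep(data[ix, , drop = FALSE], 2, mu)
  }
  data
}

#' Per-timepoint ordinary least squares on single trials
#'
#' Fits, independently at every sample, an OLS regression of the trial
#' values on the design predictors (each rescaled to \[0, 1\], plus an
#' intercept) and returns beta weights and Wald t statistics per
#' (timepoint, predictor). Degrees of freedom are n - p - 1 for p
#' predictors.
#'
#' @param data numeric matrix, trials x time (voltage or band power,
#'   subject-demeaned for the repeated-measures use case).
#' @param design data.frame of numeric predictor columns (dummy-coded
#'   factors welcome), one row per trial.
#' @return list with `beta` and `t` (predictors x time matrices, intercept
#'   excluded), `df`, and `predictors`.
#' @export
sliding_ols <- function(data, design) {
  data <- as.matrix(data)
  design <- as.data.frame(design)
  n <- nrow(data)
  stopifnot(nrow(design) == n, ncol(design) >= 1)
  if (n <= ncol(design) + 1) stop("need n_trials > n_predictors + 1")
  Xs <- vapply(design, function(col) standardize01(col)$x, numeric(n))
  X <- cbind(`(Intercept)` = 1, Xs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- ols_tmat(data, X)
  keep <- -1L  # drop intercept row
  list(beta = fit$beta[keep, , drop = FALSE],
       t = fit$t[keep, , drop = FALSE],
       df = fit$df, predictors = colnames(Xs))
}

# core OLS engine shared with the permutation loop: X already includes the
# intercept and is full rank
ols_tmat <- function(Y, X) {
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(XtXinv), sigma2))
  tmat <- B / se
  rownames(B) <- rownames(tmat) <- colnames(X)
  list(beta = B, t = tmat, df = df)
}

#' Form temporal clusters from a t-statistic series
#'
#' Thresholds the per-timepoint t series at the two-sided critical value
#' for `alpha_cluster`, groups contiguous suprathreshold samples of equal
#' sign into clusters, computes each cluster's mass (signed sum of t),
#' and discards clusters shorter than `min_duration` (the 50 ms rule).
#'
#' @param t_series numeric vector of t statistics over time.
#' @param times time axis (s), same length.
#' @param df degrees of freedom for the critical value.
#' @param alpha_cluster cluster-forming alpha (two-sided).
#' @param min_duration minimum temporal extent (s); a cluster of k samples
#'   spans k / sampling_rate seconds.
#' @param valid optional logical mask; invalid samples cannot enter a
#'   cluster (wavelet edge handling).
#' @return data.frame with one row per cluster (`start`, `end` sample
#'   indices, `t_start`, `t_end`, `n_samples`, `duration`, `mass`,
#'   `sign`), with per-cluster sample details in the `"detail"` attribute.
#' @export
form_clusters <- function(t_series, times, df, alpha_cluster = 0.05,
                          min_duration = 0.05, valid = NULL) {
  stopifnot(length(t_series) == length(times))
  dt <- stats::median(diff(times))
  thr <- stats::qt(1 - alpha_cluster / 2, df)
  state <- sign(t_series) * (abs(t_series) > thr)
  if (!is.null(valid)) state[!valid] <- 0
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values != 0 & r$lengths * dt >= min_duration)
  rows <- lapply(keep, function(k) {
    ix <- starts[k]:ends[k]
    data.frame(start = starts[k], end = ends[k],
               t_start = times[starts[k]], t_end = times[ends[k]],
               n_samples = length(ix), duration = length(ix) * dt,
               mass = sum(t_series[ix]), sign = r$values[k])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), t_start = numeric(0),
               t_end = numeric(0), n_samples = integer(0),
               duration = numeric(0), mass = numeric(0), sign = numeric(0))
  attr(out, "detail") <- lapply(keep, function(k) {
    ix <- starts[k]:ends[k]
    list(samples = ix, times = times[ix], t = t_series[ix])
  })
  out
}

#' Cluster-mass permutation test for one predictor
#'
#' The multiple-comparison-safe inference for the sliding regression.
#' The observed t series for the predictor of interest is clustered with
#' [form_clusters()]; the null distribution is built by permuting that
#' predictor's column within each subject (other covariates fixed),
#' refitting the full model, and recording the maximum absolute cluster
#' mass over time. Each observed cluster's p-value is
#' `(1 + #(null max >= |mass|)) / (n_perm + 1)`, so it can never be
#' exactly zero. Positive and negative clusters compete against a single
#' null of absolute maxima.
#'
#' @param data numeric matrix, trials x time.
#' @param design data.frame of predictors, one row per trial.
#' @param subjects subject identifier per trial. Subjects with fewer than
#'   2 trials are excluded (their labels cannot be permuted) with a
#'   warning.
#' @param predictor name of the design column to test.
#' @param n_perm number of permutations.
#' @param seed RNG seed (fixed seed gives a reproducible null).
#' @param alpha_cluster,min_duration cluster-forming parameters, see
#'   [form_clusters()].
#' @param times time axis (s).
#' @param valid optional validity mask over time.
#' @param demean if `TRUE` (default), [subject_demean()] is applied first;
#'   set to `FALSE` when the data are already demeaned.
#' @return object of class `cluster_test`: the [form_clusters()] frame
#'   augmented with `p_perm`, plus elements `null_max` (permutation
#'   distribution), `t_series`, `times`, `df`.
#' @export
permutation_cluster_test <- function(data, design, subjects, predictor,
                                     times, n_perm = 1000, seed = 1L,
                                     alpha_cluster = 0.05,
                                     min_duration = 0.05, valid = NULL,
                                     demean = TRUE) {
  data <- as.matrix(data)
  design <- as.data.frame(design)
  stopifnot(predictor %in% names(design))
  tab <- table(subjects)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("excluding subject(s) with < 2 trials: ",
            paste(small, collapse = ", "))
    keep <- !(subjects %in% small)
    data <- data[keep, , drop = FALSE]
    design <- design[keep, , drop = FALSE]
    subjects <- subjects[keep]
  }
  if (demean) data <- subject_demean(data, subjects)

  n <- nrow(data)
  Xs <- vapply(design, function(col) standardize01(col)$x, numeric(n))
  X <- cbind(`(Intercept)` = 1, Xs)
  if (qr(X)$rank < ncol(X)) stop("design is rank deficient")
  jcol <- which(colnames(Xs) == predictor) + 1L

  fit <- ols_tmat(data, X)
  tobs <- fit$t[jcol, ]
  clusters <- form_clusters(tobs, times, fit$df, alpha_cluster,
                            min_duration, valid)

  # null loop needs only the maximum |cluster mass|, not full inventories
  dt <- stats::median(diff(times))
  thr <- stats::qt(1 - alpha_cluster / 2, fit$df)
  min_len <- ceiling(min_duration / dt)
  max_mass <- function(tser) {
    state <- sign(tser) * (abs(tser) > thr)
    if (!is.null(valid)) state[!valid] <- 0
    r <- rle(state)
    keep <- r$values != 0 & r$lengths >= min_len
    if (!any(keep)) return(0)
    ends <- cumsum(r$lengths)
    cs <- c(0, cumsum(tser))
    max(abs(cs[ends[keep] + 1] - cs[ends[keep] - r$lengths[keep] + 1]))
  }
  subj_ix <- split(seq_len(n), subjects)
  set.seed(seed)
  null_max <- numeric(n_perm)
  Xp <- X
  for (b in seq_len(n_perm)) {
    col <- X[, jcol]
    for (ix in subj_ix) col[ix] <- col[ix][sample.int(length(ix))]
    Xp[, jcol] <- col
    fb <- ols_tmat(data, Xp)
    null_max[b] <- max_mass(fb$t[jcol, ])
  }
  clusters$p_perm <- vapply(clusters$mass, function(m) {
    (1 + sum(null_max >= abs(m))) / (n_perm + 1)
  }, numeric(1))
  structure(list(clusters = clusters, null_max = null_max,
                 t_series = tobs, times = times, df = fit$df,
                 predictor = predictor, n_perm = n_perm),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> predictor '%s', %d permutation(s), %d cluster(s)\n",
              x$predictor, x$n_perm, nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment for cluster p-values
#'
#' Applied across the family of tests actually run: all labels for the
#' time-domain analysis, all labels x bands for the frequency-domain
#' analysis.
#'
#' @param p vector of permutation p-values.
#' @return adjusted p-values (same order).
#' @export
fdr_stepdown <- function(p) stats::p.adjust(p, method = "BH")

#' Fraction of significant cluster mass inside a time window
#'
#' Summarizes where in the trial the significant clusters live: 100 times
#' the summed absolute in-window mass over the total summed absolute
#' mass, across all supplied clusters (e.g. all labels). A cluster's
#' in-window mass is the (signed) sum of its t values at samples falling
#' inside the window, taken in absolute value.
#'
#' @param tests a `cluster_test`, or a list of them (one per label), whose
#'   clusters are pooled.
#' @param window `c(t0, t1)` in seconds.
#' @param only_significant if not `NULL`, keep clusters with
#'   `p_perm < only_significant` (and `p_fdr` when present).
#' @return percentage in \[0, 100\] (`NaN` when there is no cluster mass).
#' @export
cluster_mass_fraction <- function(tests, window, only_significant = NULL) {
  if (inherits(tests, "cluster_test")) tests <- list(tests)
  tot <- 0; inw <- 0
  for (ct in tests) {
    cl <- ct$clusters
    det <- attr(cl, "detail")
    keep <- seq_len(nrow(cl))
    if (!is.null(only_significant) && nrow(cl)) {
      pv <- if (!is.null(cl$p_fdr)) cl$p_fdr else cl$p_perm
      keep <- which(pv < only_significant)
    }
    for (k in keep) {
      tvals <- det[[k]]$t
      tt <- det[[k]]$times
      tot <- tot + abs(sum(tvals))
      sel <- tt >= window[1] & tt <= window[2]
      inw <- inw + abs(sum(tvals[sel]))
    }
  }
  100 * inw / tot
}
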