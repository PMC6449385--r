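#' Integrated ON-OFF theta difference over a cluster window
#'
#' The per-subject EEG biomarker: the trapezoidal integral of the
#' (DBS ON - DBS OFF) theta power difference wave over the time window in
#' which the group analysis found a significant cluster. Units are dB
#' times seconds.
#'
#' @param theta_on,theta_off numeric vectors: a subject's trial-averaged
#'   theta time courses (dB) in one label, ON and OFF.
#' @param times time axis (s).
#' @param window `c(t0, t1)` integration window (s), typically the extent
#'   of the significant group-level cluster.
#' @return scalar, dB.s.
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' integrate_theta_difference(rep(1, 101), rep(0, 101), t, c(0.25, 0.75))
#' @export
integrate_theta_difference <- function(theta_on, theta_off, times, window) {
  stopifnot(length(theta_on) == length(times),
            length(theta_off) == length(times))
  ix <- which(times >= window[1] & times <= window[2])
  if (length(ix) < 2) stop("integration window contains < 2 samples")
  trapz_int(times[ix], (theta_on - theta_off)[ix])
}

#' Fisher-Z p-value for a Pearson correlation
#'
#' Two-sided normal test of `z = atanh(r) * sqrt(n - 3)`.
#'
#' @param r Pearson correlation.
#' @param n number of pairs (>= 4).
#' @return two-sided p-value.
#' @examples
#' fisher_z_pvalue(0.76, 8)  # ~0.03
#' @export
fisher_z_pvalue <- function(r, n) {
  if (n < 4) stop("Fisher-Z test needs n >= 4")
  if (abs(r) >= 1) return(0)
  z <- atanh(r) * sqrt(n - 3)
  2 * stats::pnorm(-abs(z))
}

#' Pearson correlation with Fisher-Z significance
#'
#' @param x,y numeric vectors without missing pairs, length >= 4.
#' @return list with `r`, `n`, and two-sided `p` from the Fisher-Z
#'   transform.
#' @export
pearson_fisher <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  r <- stats::cor(x, y)
  list(r = r, n = n, p = fisher_z_pvalue(r, n))
}

#' Robust straight-line fit (Huber M-estimation)
#'
#' Display-oriented robust regression: Huber M-estimator with the standard
#' 1.345 tuning constant, resistant to a single gross outlier that would
#' swing an OLS line.
#'
#' @param x,y numeric vectors.
#' @return list with `slope` and `intercept`.
#' @export
robust_line <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  fit <- MASS::rlm(y[ok] ~ x[ok], psi = MASS::psi.huber, k = 1.345,
                   maxit = 100)
  co <- unname(stats::coef(fit))
  list(intercept = co[1], slope = co[2])
}

#' Generate reusable bootstrap resampling indices
#'
#' @param n number of subjects.
#' @param n_boot resamples.
#' @param seed RNG seed.
#' @return n_boot x n integer matrix of row indices.
#' @export
bootstrap_draws <- function(n, n_boot = 1000, seed = 1L) {
  set.seed(seed)
  matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
}

#' Percentile bootstrap confidence interval over subjects
#'
#' Resamples rows of the subject table with replacement and returns the
#' percentile interval of the statistic. Supplying the same `draws`
#' matrix to several statistics evaluates them on identical resamples,
#' the way correlation and AUC intervals are meant to share draws.
#'
#' @param statistic function taking a data.frame and returning a scalar
#'   (may return `NA` for degenerate resamples; those are dropped).
#' @param table subject-level data.frame.
#' @param n_boot resamples (ignored when `draws` is given).
#' @param seed RNG seed (ignored when `draws` is given).
#' @param level confidence level.
#' @param draws optional index matrix from [bootstrap_draws()].
#' @return list with `lo`, `hi`, `estimate` (statistic on the original
#'   table), `boot` (the resample values), and `draws`.
#' @export
bootstrap_ci <- function(statistic, table, n_boot = 1000, seed = 1L,
                         level = 0.95, draws = NULL) {
  n <- nrow(table)
  if (is.null(draws)) draws <- bootstrap_draws(n, n_boot, seed)
  vals <- apply(draws, 1, function(ix) {
    tryCatch(statistic(table[ix, , drop = FALSE]), error = function(e) NA_real_)
  })
  a <- (1 - level) / 2
  qs <- stats::quantile(vals, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(lo = qs[1], hi = qs[2], estimate = statistic(table), boot = vals,
       draws = draws)
}

#' ROC curve and AUC via the rank identity
#'
#' The AUC is computed as the normalized Mann-Whitney U using midranks,
#' so ties contribute 1/2; this equals the probability that a random
#' positive case scores above a random negative one. The curve is swept
#' over all observed thresholds.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical (or 0/1) class labels. Pairs with missing labels
#'   are dropped.
#' @return list with `auc` and `curve` (data.frame of `threshold`, `fpr`,
#'   `tpr`).
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative cases")
  rk <- rank(scores)  # midranks for ties
  auc <- (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(h) mean(scores[!labels] >= h), numeric(1)),
    tpr = vapply(thr, function(h) mean(scores[labels] >= h), numeric(1)))
  list(auc = auc, curve = curve)
}

#' Assemble the subject-level biomarker table from pipeline outputs
#'
#' Computes, per subject, the mean ON-OFF RT difference from the
#' QC-filtered trial table and the integrated ON-OFF theta difference
#' over a cluster window from per-subject theta time courses, and joins
#' the clinical table.
#'
#' @param trials QC-filtered trial table (with `rt`, `dbs_state`,
#'   `subject_id`).
#' @param theta_by_subject named list: per subject, a list with `on` and
#'   `off` theta time courses (dB).
#' @param times time axis for the theta courses.
#' @param window integration window (s).
#' @param clinical data.frame with `subject_id`, `madrs_baseline`,
#'   `madrs_followup` (and optionally `hypomania`).
#' @return data.frame, one row per subject, with `delta_rt`,
#'   `delta_theta`, `madrs_change`, `responder`, `hypomania`.
#' @export
subject_biomarkers <- function(trials, theta_by_subject, times, window,
                               clinical) {
  subj <- sort(unique(trials$subject_id))
  delta_rt <- vapply(subj, function(s) {
    tt <- trials[trials$subject_id == s, ]
    mean(tt$rt[tt$dbs_state == "ON"]) - mean(tt$rt[tt$dbs_state == "OFF"])
  }, numeric(1))
  delta_theta <- vapply(subj, function(s) {
    th <- theta_by_subject[[s]]
    integrate_theta_difference(th$on, th$off, times, window)
  }, numeric(1))
  out <- data.frame(subject_id = subj, delta_rt = delta_rt,
                    delta_theta = delta_theta)
  out <- merge(out, clinical, by = "subject_id", all.x = TRUE)
  out$madrs_change <- out$madrs_followup - out$madrs_baseline
  out$responder <- (out$madrs_baseline - out$madrs_followup) /
    out$madrs_baseline >= 0.5
  out
}
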