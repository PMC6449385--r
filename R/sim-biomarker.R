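#' Simulate a per-subject clinical biomarker table
#'
#' Generates one row per subject linking the DBS-induced change in induced
#' theta power to the change in depression severity (MADRS). The
#' population correlation between the theta change and the fractional
#' MADRS improvement equals `config$biomarker_r`. Responders are labelled
#' by the clinical-trial rule: at least a 50\% drop from the baseline
#' MADRS. A hypomania flag is included (one subject may be missing it, as
#' clinical records sometimes are).
#'
#' @param config a [sim_config()]; `n_subjects` must be at least 4.
#' @param delta_theta optional numeric vector of observed per-subject
#'   ON-OFF integrated theta values (e.g. measured from simulated epochs by
#'   the pipeline). When supplied, the clinical outcomes are generated
#'   conditionally on these values at the target correlation; when absent,
#'   theta changes are drawn as standard normal deviates.
#' @return data.frame (`subject_id`, `delta_theta`, `delta_rt`,
#'   `madrs_baseline`, `madrs_followup`, `madrs_change`, `responder`,
#'   `hypomania`).
#' @examples
#' bm <- simulate_cohort_biomarker(sim_config(seed = 4, n_subjects = 8))
#' cor(bm$delta_theta, bm$madrs_change)
#' @export
simulate_cohort_biomarker <- function(config, delta_theta = NULL) {
  stopifnot(inherits(config, "sim_config"))
  r <- config$biomarker_r
  if (abs(r) > 1) stop("biomarker_r must lie in [-1, 1]")
  n <- config$n_subjects
  if (n < 4) stop("need at least 4 subjects for biomarker simulation")
  set.seed(config$seed + 15485863L)

  if (is.null(delta_theta)) {
    z_theta <- stats::rnorm(n)
    delta_theta <- z_theta  # dB.s units, centred at 0
  } else {
    stopifnot(length(delta_theta) == n)
    s <- stats::sd(delta_theta)
    z_theta <- if (is.na(s) || s == 0) rep(0, n) else
      (delta_theta - mean(delta_theta)) / s
  }
  z_noise <- stats::rnorm(n)
  # improvement fraction correlated with theta change at the target r;
  # positive theta change (ON > OFF) is generated as LESS improvement,
  # i.e. positively correlated with the signed MADRS change
  z_impr <- r * z_theta + sqrt(max(0, 1 - r^2)) * z_noise
  improvement <- pmin(1, pmax(-0.2, 0.5 - 0.25 * z_impr))

  baseline <- round(pmin(50, pmax(20, stats::rnorm(n, 37, 4))))
  followup <- round(baseline * (1 - improvement))
  hypo <- stats::runif(n) < 0.3
  if (n > 4) hypo[sample.int(n, 1)] <- NA  # one subject lacks records

  data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    delta_theta = delta_theta,
    delta_rt = stats::rnorm(n, config$effect_dbs, 25),
    madrs_baseline = baseline,
    madrs_followup = followup,
    madrs_change = followup - baseline,
    responder = (baseline - followup) / baseline >= 0.5,
    hypomania = hypo
  )
}
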