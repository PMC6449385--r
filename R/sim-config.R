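#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic-data module. Defaults emulate the
#' study conditions the pipeline is designed for: a within-subject DBS
#' ON/OFF conflict-task experiment in which interference slows responses by
#' about 224 ms, stimulation speeds them by about 34 ms, and non-phase-locked
#' prefrontal theta bursts are potentiated by both cognitive conflict and
#' stimulation.
#'
#' @param seed integer seed; a fixed seed makes every generator output
#'   bit-identical across runs.
#' @param n_subjects number of subjects in the cohort.
#' @param n_blocks_per_state task blocks per DBS state (each block holds
#'   `n_control + n_interference` trials).
#' @param n_control,n_interference trials of each type per block. The task
#'   design uses 72 + 72 = 144-trial blocks.
#' @param sampling_rate Hz for synthetic ROI label time courses. The default
#'   1450/3 mirrors a 1450 Hz acquisition after downsampling by 3. Must
#'   exceed twice the highest analysis frequency (50 Hz).
#' @param rt_shape gamma shape parameter for reaction times
#'   (dimensionless; larger = less skewed).
#' @param rt_intercept ms; population mean RT for a control trial, DBS OFF.
#' @param effect_interference ms added to the mean RT on interference trials.
#' @param effect_dbs ms added to the mean RT when DBS is ON (negative =
#'   speeding). OFF is the baseline level.
#' @param subject_sd ms; SD of the per-subject random intercept.
#' @param error_rate,miss_rate injected fractions of error and missing
#'   (no-response) trials.
#' @param theta_freq Hz; center frequency of the induced theta burst.
#' @param theta_burst_gain_interference dB added to burst amplitude on
#'   interference trials.
#' @param theta_burst_gain_dbs dB added to burst amplitude when DBS is ON.
#' @param burst_amplitude baseline burst amplitude, arbitrary units.
#' @param theta_gain_subject_sd dB; SD of a per-subject deviation added to
#'   the DBS burst gain, so that the ON-OFF theta change varies across
#'   subjects as real cohorts do.
#' @param burst_duration s; length of the Hanning burst envelope.
#' @param burst_onset s after the image onset at which the burst starts
#'   (the number stimulus appears 0.4 s after the image).
#' @param erp_amplitude amplitude of the phase-locked evoked component,
#'   arbitrary units matched to the noise scale.
#' @param noise_sd SD of the 1/f background noise, same units.
#' @param noise_exponent spectral slope of the background (power ~ 1/f^a).
#' @param biomarker_r target population correlation, in \[-1, 1\], between
#'   the per-subject ON-OFF theta change and MADRS improvement.
#' @param label_names character vector of ROI label identifiers.
#'
#' @return object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_subjects = 4)
#' cfg$effect_interference
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 14L,
                       n_blocks_per_state = 1L,
                       n_control = 72L,
                       n_interference = 72L,
                       sampling_rate = 1450 / 3,
                       rt_shape = 10,
                       rt_intercept = 600,
                       effect_interference = 224,
                       effect_dbs = -34,
                       subject_sd = 80,
                       error_rate = 0.017,
                       miss_rate = 0.005,
                       theta_freq = 6,
                       theta_burst_gain_interference = 3,
                       theta_burst_gain_dbs = 2,
                       burst_amplitude = 8,
                       theta_gain_subject_sd = 1,
                       burst_duration = 0.3,
                       burst_onset = 0.5,
                       erp_amplitude = 5,
                       noise_sd = 10,
                       noise_exponent = 1,
                       biomarker_r = 0.76,
                       label_names = c("rACC", "dACC", "mCC",
                                       "dmPFC", "DLPFC", "VLPFC")) {
  cfg <- list(
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    n_blocks_per_state = as.integer(n_blocks_per_state),
    n_control = as.integer(n_control),
    n_interference = as.integer(n_interference),
    sampling_rate = sampling_rate,
    rt_shape = rt_shape,
    rt_intercept = rt_intercept,
    effect_interference = effect_interference,
    effect_dbs = effect_dbs,
    subject_sd = subject_sd,
    error_rate = error_rate,
    miss_rate = miss_rate,
    theta_freq = theta_freq,
    theta_burst_gain_interference = theta_burst_gain_interference,
    theta_burst_gain_dbs = theta_burst_gain_dbs,
    burst_amplitude = burst_amplitude,
    theta_gain_subject_sd = theta_gain_subject_sd,
    burst_duration = burst_duration,
    burst_onset = burst_onset,
    erp_amplitude = erp_amplitude,
    noise_sd = noise_sd,
    noise_exponent = noise_exponent,
    biomarker_r = biomarker_r,
    label_names = label_names
  )
  if (cfg$rt_shape <= 0) stop("rt_shape must be > 0")
  if (cfg$sampling_rate <= 2 * 50) {
    stop("sampling_rate must exceed twice the highest analysis frequency (50 Hz)")
  }
  if (abs(cfg$biomarker_r) > 1) stop("biomarker_r must lie in [-1, 1]")
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d subjects, %d block(s)/state, %d+%d trials/block\n",
              x$n_subjects, x$n_blocks_per_state, x$n_control,
              x$n_interference))
  cat(sprintf("  RT: gamma(shape=%.3g), mean %.3g ms, interference %+.3g ms, DBS ON %+.3g ms\n",
              x$rt_shape, x$rt_intercept, x$effect_interference, x$effect_dbs))
  cat(sprintf("  theta burst: %.3g Hz, gains interference %+.3g dB / DBS %+.3g dB\n",
              x$theta_freq, x$theta_burst_gain_interference,
              x$theta_burst_gain_dbs))
  cat(sprintf("  labels: %s\n", paste(x$label_names, collapse = ", ")))
  invisible(x)
}
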