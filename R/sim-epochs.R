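#' 1/f background noise by spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain so that its power
#' spectrum falls off as 1/f^exponent, then rescaled to the requested
#' standard deviation. Used as the stochastic background of every synthetic
#' trace.
#'
#' @param n samples.
#' @param exponent spectral slope (power ~ 1/f^exponent); 0 gives white
#'   noise.
#' @param sd target standard deviation.
#' @return numeric vector of length `n`.
#' @keywords internal
pink_noise <- function(n, exponent = 1, sd = 1) {
  if (n == 0) return(numeric(0))
  w <- stats::rnorm(n)
  if (exponent == 0) return(w * sd / stats::sd(w))
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))             # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)               # symmetric frequency index
  W <- W / f^(exponent / 2)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

# Hanning-windowed theta burst evaluated on an absolute time axis.
theta_burst <- function(t_abs, onset, duration, freq, amplitude, phase) {
  env <- numeric(length(t_abs))
  inside <- t_abs >= onset & t_abs <= onset + duration
  u <- (t_abs[inside] - onset) / duration
  env[inside] <- 0.5 * (1 - cos(2 * pi * u))
  amplitude * env * sin(2 * pi * freq * t_abs + phase)
}

# Phase-locked evoked waveform (identical across trials within condition).
# Two smooth bumps after the number-stimulus onset at 0.4 s; the later bump
# is larger on interference trials. Spectral content is well below 15 Hz.
evoked_waveform <- function(t_abs, amplitude, interference) {
  g <- function(mu, s) exp(-(t_abs - mu)^2 / (2 * s^2))
  amp2 <- amplitude * (1 + 0.5 * interference)
  amplitude * g(0.55, 0.05) - amp2 * g(0.75, 0.09)
}

#' Simulate epoched ROI time courses for a trial table
#'
#' Each trial's trace per label is the sum of three components that the
#' downstream spectral pipeline is designed to separate:
#' \itemize{
#'   \item 1/f background noise (independent per trial and label);
#'   \item a phase-locked evoked waveform, identical across trials within a
#'     condition, which survives trial averaging (the ERP);
#'   \item a theta-band burst with an independent uniform random phase per
#'     trial, whose amplitude gain (in dB) depends on the interference
#'     level and the DBS state. The random phase makes the burst cancel in
#'     the trial mean, so it is invisible in the ERP but carries induced
#'     power.
#' }
#' The epoch timeline places the distractor-image onset at t = 0 and the
#' number stimulus at t = 0.4 s; the response occurs at 0.4 s + RT.
#'
#' @param trials trial table with RTs (see [simulate_rts()]).
#' @param config a [sim_config()].
#' @param lock `"stimulus"` or `"response"`. Response-locked epochs are cut
#'   around each trial's realized response; trials without a response are
#'   dropped.
#' @param window epoch window (s) relative to the lock event. The
#'   stimulus-locked default covers the full trial; the window must contain
#'   the baseline (-0.5, -0.1) s for stimulus-locked data.
#' @return an [epoch_array()] with `trials` as `trial_meta`.
#' @examples
#' cfg <- sim_config(seed = 3, n_subjects = 1, n_control = 6,
#'                   n_interference = 6, label_names = "dACC")
#' ep <- simulate_epochs(simulate_rts(simulate_trials(cfg), cfg), cfg)
#' dim(ep$data)
#' @export
simulate_epochs <- function(trials, config, lock = "stimulus",
                            window = if (lock == "stimulus") c(-1.5, 3.4)
                                     else c(-1.5, 1.5)) {
  stopifnot(inherits(config, "sim_config"))
  lock <- match.arg(lock, c("stimulus", "response"))
  if (lock == "stimulus" && (window[1] > -0.5 || window[2] < -0.1)) {
    stop("stimulus-locked window must contain the baseline (-0.5, -0.1) s")
  }
  if (diff(window) <= 0.4) stop("epoch window too short")

  if (lock == "response") {
    keep <- !is.na(trials$rt)
    trials <- trials[keep, , drop = FALSE]
  }
  fs <- config$sampling_rate
  times <- seq(window[1], window[2], by = 1 / fs)
  nt <- length(times)
  n <- nrow(trials)
  nl <- length(config$label_names)

  set.seed(config$seed + 224737L + (lock == "response"))
  subj <- sort(unique(trials$subject_id))
  subj_gain <- stats::rnorm(length(subj), 0, config$theta_gain_subject_sd)
  names(subj_gain) <- subj

  data <- array(0, dim = c(n, nl, nt))
  for (i in seq_len(n)) {
    interf <- trials$interference[i] == "interference"
    on <- trials$dbs_state[i] == "ON"
    gain_db <- config$theta_burst_gain_interference * interf +
      (config$theta_burst_gain_dbs + subj_gain[trials$subject_id[i]]) * on
    amp <- config$burst_amplitude * 10^(gain_db / 20)
    t_abs <- if (lock == "stimulus") times else
      times + 0.4 + trials$rt[i] / 1000
    ev <- evoked_waveform(t_abs, config$erp_amplitude, interf)
    for (l in seq_len(nl)) {
      phase <- stats::runif(1, 0, 2 * pi)
      data[i, l, ] <- pink_noise(nt, config$noise_exponent,
                                 config$noise_sd) +
        ev +
        theta_burst(t_abs, config$burst_onset, config$burst_duration,
                    config$theta_freq, amp, phase)
    }
  }
  epoch_array(data, times, fs, lock, trials, config$label_names)
}

#' Simulate a continuous resting-state recording
#'
#' Resting traces contain 1/f background plus ongoing theta-band activity
#' whose statistics do not depend on the DBS state: with the default
#' generator, DBS ON and OFF resting segments are exchangeable, matching
#' the observation that stimulation changes task-induced rather than
#' resting theta.
#'
#' @param config a [sim_config()].
#' @param n_seconds duration of the recording.
#' @param dbs_state `"ON"` or `"OFF"` (affects only the random stream, not
#'   the generating distribution).
#' @param theta_amplitude amplitude of the ongoing theta rhythm; pass a
#'   different value per state to create a real resting difference.
#' @return matrix labels x samples with attributes `sampling_rate` and
#'   `dbs_state`.
#' @export
simulate_resting <- function(config, n_seconds = 60, dbs_state = "OFF",
                             theta_amplitude = config$burst_amplitude / 2) {
  stopifnot(inherits(config, "sim_config"))
  dbs_state <- match.arg(dbs_state, c("OFF", "ON"))
  fs <- config$sampling_rate
  n <- round(n_seconds * fs)
  set.seed(config$seed + 389117L + 31L * (dbs_state == "ON"))
  nl <- length(config$label_names)
  out <- matrix(0, nl, n, dimnames = list(config$label_names, NULL))
  t <- seq_len(n) / fs
  for (l in seq_len(nl)) {
    # theta envelope wanders but decorrelates within ~1 s, so successive
    # 1-s epochs are close to independent samples of theta power
    hw <- round(0.15 * fs)
    kern <- stats::dnorm(seq(-hw, hw), sd = 0.08 * fs)
    env <- abs(stats::convolve(stats::rnorm(n + 2 * hw), kern,
                               type = "filter")[seq_len(n)])
    env <- env / stats::sd(env)
    out[l, ] <- pink_noise(n, config$noise_exponent, config$noise_sd) +
      theta_amplitude * env *
        sin(2 * pi * config$theta_freq * t + stats::runif(1, 0, 2 * pi))
  }
  attr(out, "sampling_rate") <- fs
  attr(out, "dbs_state") <- dbs_state
  out
}

#' Simulate null band-power time courses for calibration studies
#'
#' Generates trial-by-time matrices of temporally autocorrelated power
#' values with per-subject offsets and a randomized within-subject design,
#' but no condition effect whatsoever. This is the null world used to
#' calibrate the family-wise error rate of the cluster-mass permutation
#' machinery: temporal autocorrelation is what makes that calibration
#' non-trivial, and the generator mimics the smoothness that band-averaged
#' wavelet power inherits from the wavelet length.
#'
#' @param n_subjects,n_trials_per_subject cohort shape.
#' @param n_time samples per trial.
#' @param fs sampling rate (Hz) of the synthetic power time course.
#' @param smooth_sd s; SD of the Gaussian kernel that autocorrelates the
#'   noise (default roughly matches a 3-cycle theta wavelet).
#' @param subject_sd SD of per-subject offsets.
#' @param seed RNG seed.
#' @return list with `data` (trials x time), `design` (data.frame with
#'   `interference` and `dbs` columns, randomized, effect-free),
#'   `subjects`, `times`.
#' @export
simulate_null_power <- function(n_subjects = 8, n_trials_per_subject = 100,
                                n_time = 225, fs = 150, smooth_sd = 0.08,
                                subject_sd = 1, seed = 1L) {
  set.seed(seed)
  n <- n_subjects * n_trials_per_subject
  subjects <- rep(sprintf("S%02d", seq_len(n_subjects)),
                  each = n_trials_per_subject)
  hw <- max(1L, round(3 * smooth_sd * fs))
  kern <- stats::dnorm(seq(-hw, hw), sd = smooth_sd * fs)
  kern <- kern / sqrt(sum(kern^2))  # preserve noise variance
  raw <- matrix(stats::rnorm(n * (n_time + 2 * hw)), nrow = n)
  sm <- t(apply(raw, 1, function(x) {
    stats::convolve(x, kern, type = "filter")[seq_len(n_time)]
  }))
  offs <- stats::rnorm(n_subjects, 0, subject_sd)
  data <- sm + offs[rep(seq_len(n_subjects), each = n_trials_per_subject)]
  design <- data.frame(
    interference = as.numeric(stats::runif(n) < 0.5),
    dbs = unlist(lapply(seq_len(n_subjects), function(s) {
      sample(rep(0:1, length.out = n_trials_per_subject))
    })))
  list(data = data, design = design, subjects = subjects,
       times = seq_len(n_time) / fs)
}
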