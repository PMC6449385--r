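#' Reject epochs containing amplitude artifacts
#'
#' Removes any trial in which the absolute signal exceeds `threshold` in
#' any label at any sample (residual artifacts such as muscle activity).
#'
#' @param epochs an [epoch_array()].
#' @param threshold amplitude threshold (same units as the data; the
#'   conventional scalp-EEG value is 150 microvolts).
#' @return list with `epochs` (cleaned) and `rejected` (integer indices of
#'   removed trials).
#' @export
amplitude_reject <- function(epochs, threshold = 150) {
  stopifnot(inherits(epochs, "epoch_array"))
  mx <- apply(abs(epochs$data), 1, max)
  rejected <- which(mx > threshold)
  keep <- setdiff(seq_len(dim(epochs$data)[1]), rejected)
  list(epochs = subset_epochs(epochs, keep), rejected = rejected)
}

# Group index for per-condition operations: one integer per trial plus the
# group table. Grouping columns are taken from trial_meta.
erp_groups <- function(epochs, group_by) {
  meta <- epochs$trial_meta
  if (is.null(meta)) stop("epoch_array has no trial_meta; cannot group")
  missing <- setdiff(group_by, names(meta))
  if (length(missing)) stop("grouping columns not in trial_meta: ",
                            paste(missing, collapse = ", "))
  key <- interaction(meta[group_by], drop = TRUE, lex.order = TRUE)
  groups <- unique(meta[group_by])
  groups <- groups[order(interaction(groups, drop = TRUE,
                                     lex.order = TRUE)), , drop = FALSE]
  rownames(groups) <- NULL
  list(index = as.integer(key), groups = groups)
}

#' Compute event-related potentials (trial means) per group
#'
#' Averages trials within each combination of the grouping columns
#' (default: subject x DBS state x interference level), separately per
#' label. This is the phase-locked (evoked) component of the signal.
#'
#' @param epochs an [epoch_array()] with `trial_meta`.
#' @param group_by character vector of metadata columns defining the ERP
#'   groups.
#' @return list with `erp` (array groups x labels x time), `groups`
#'   (data.frame describing each group), and `index` (group of each
#'   trial).
#' @export
compute_erp <- function(epochs,
                        group_by = c("subject_id", "dbs_state",
                                     "interference")) {
  stopifnot(inherits(epochs, "epoch_array"))
  g <- erp_groups(epochs, group_by)
  d <- dim(epochs$data)
  ng <- nrow(g$groups)
  erp <- array(0, dim = c(ng, d[2], d[3]))
  for (k in seq_len(ng)) {
    ix <- which(g$index == k)
    erp[k, , ] <- apply(epochs$data[ix, , , drop = FALSE], c(2, 3), mean)
  }
  list(erp = erp, groups = g$groups, index = g$index)
}

#' Remove the phase-locked (evoked) component from every trial
#'
#' Subtracts each trial's group ERP (subject x condition x label mean)
#' from that trial, leaving the non-phase-locked (induced) signal. After
#' subtraction, the group mean of the output is zero at every sample, so
#' any remaining oscillatory power is induced rather than evoked.
#'
#' @param epochs an [epoch_array()].
#' @param erps result of [compute_erp()]; computed internally if `NULL`.
#' @param group_by grouping columns (used only when `erps` is `NULL`).
#' @return an [epoch_array()] of induced activity.
#' @export
subtract_erp <- function(epochs, erps = NULL,
                         group_by = c("subject_id", "dbs_state",
                                      "interference")) {
  stopifnot(inherits(epochs, "epoch_array"))
  if (is.null(erps)) erps <- compute_erp(epochs, group_by)
  data <- epochs$data
  for (i in seq_len(dim(data)[1])) {
    data[i, , ] <- data[i, , ] - erps$erp[erps$index[i], , ]
  }
  epoch_array(data, epochs$times, epochs$sampling_rate, epochs$lock,
              epochs$trial_meta, epochs$label_names)
}

#' Default wavelet frequency grid
#'
#' 25 logarithmically spaced (base-10 grid, endpoints included) base
#' frequencies from 2 to 50 Hz.
#' @param n number of frequencies.
#' @param range frequency range (Hz).
#' @return numeric vector of frequencies.
#' @export
morlet_freq_grid <- function(n = 25, range = c(2, 50)) {
  10^seq(log10(range[1]), log10(range[2]), length.out = n)
}

#' Morlet wavelet time-frequency decomposition of single trials
#'
#' Convolves every trial and label with complex Morlet wavelets (unit
#' energy, `n_cycles` cycles at each base frequency) and returns the
#' squared magnitude as per-trial power. Epoch edges are handled by
#' reflect-padding, and samples within `(n_cycles/2)/f` of either epoch
#' end are flagged invalid in a frequency-by-time validity mask rather
#' than silently returned.
#'
#' @param epochs an [epoch_array()]; the epoch must be long enough for the
#'   slowest wavelet (3 cycles at 2 Hz = 1.5 s).
#' @param freqs base frequencies (Hz), default [morlet_freq_grid()].
#' @param n_cycles wavelet cycles (constant across frequencies).
#' @return object of class `tfr_power`: list with `power` (trials x freqs
#'   x labels x time), `freqs`, `times`, `sampling_rate`, `valid` (freqs x
#'   time logical mask), `trial_meta`, `label_names`.
#' @export
morlet_tfr <- function(epochs, freqs = morlet_freq_grid(), n_cycles = 3) {
  stopifnot(inherits(epochs, "epoch_array"))
  fs <- epochs$sampling_rate
  nt <- length(epochs$times)
  if (nt / fs < n_cycles / min(freqs)) {
    stop(sprintf("epoch (%.2f s) shorter than the slowest wavelet (%.2f s)",
                 nt / fs, n_cycles / min(freqs)))
  }
  d <- dim(epochs$data)

  # wavelets on a common padded grid
  sds <- n_cycles / (2 * pi * freqs)
  half <- ceiling(3.5 * sds * fs)
  pad <- min(max(half), nt - 1)       # reflect-pad cannot exceed epoch
  nfft <- stats::nextn(nt + 2 * pad, 2)
  wfft <- matrix(0 + 0i, length(freqs), nfft)
  for (j in seq_along(freqs)) {
    h <- min(half[j], pad)
    tw <- (-h:h) / fs
    w <- exp(2i * pi * freqs[j] * tw) * exp(-tw^2 / (2 * sds[j]^2))
    w <- w / sqrt(sum(Mod(w)^2) / fs)  # unit energy
    buf <- complex(length.out = nfft)
    buf[1:(h + 1)] <- w[(h + 1):(2 * h + 1)]
    buf[(nfft - h + 1):nfft] <- w[1:h]
    wfft[j, ] <- stats::fft(buf)
  }

  power <- array(NA_real_, dim = c(d[1], length(freqs), d[2], nt))
  for (i in seq_len(d[1])) {
    for (l in seq_len(d[2])) {
      x <- epochs$data[i, l, ]
      xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(nt - pad):(nt - 1)]))
      xf <- stats::fft(c(xp, numeric(nfft - length(xp))))
      for (j in seq_along(freqs)) {
        conv <- stats::fft(xf * wfft[j, ], inverse = TRUE) / nfft
        power[i, j, l, ] <- Mod(conv[(pad + 1):(pad + nt)])^2
      }
    }
  }

  edge <- (n_cycles / 2) / freqs
  valid <- outer(edge, epochs$times, function(e, t) {
    t >= min(epochs$times) + e & t <= max(epochs$times) - e
  })
  structure(list(power = power, freqs = freqs, times = epochs$times,
                 sampling_rate = fs, valid = valid,
                 trial_meta = epochs$trial_meta,
                 label_names = epochs$label_names,
                 n_cycles = n_cycles),
            class = "tfr_power")
}

#' @export
print.tfr_power <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tfr_power> %d trials x %d freqs (%.3g-%.3g Hz) x %d labels x %d samples%s\n",
    d[1], d[2], min(x$freqs), max(x$freqs), d[3], d[4],
    if (isTRUE(attr(x, "db"))) " [dB re baseline]" else ""))
  invisible(x)
}

#' Normalize per-trial power to decibels relative to a pre-stimulus baseline
#'
#' Baseline power is the mean power over the baseline window, averaged
#' across the trials of each subject-by-DBS-state group (so ON and OFF
#' each have their own baseline per subject), separately per frequency and
#' label. Every sample is then expressed as 10*log10(power / baseline).
#' Response-locked data have no pre-stimulus period of their own; pass the
#' `baseline_power` attribute from the stimulus-locked call to reuse the
#' same baseline.
#'
#' @param tfr a `tfr_power` object from [morlet_tfr()].
#' @param baseline baseline window (s), default (-0.5, -0.1).
#' @param group_by metadata columns defining the baseline groups.
#' @param baseline_power optional precomputed baseline array (groups x
#'   freqs x labels) with its `groups` attribute, as returned in the
#'   output's `baseline_power` element.
#' @return a `tfr_power` object in dB with a `baseline_power` element.
#' @export
db_normalize <- function(tfr, baseline = c(-0.5, -0.1),
                         group_by = c("subject_id", "dbs_state"),
                         baseline_power = NULL) {
  stopifnot(inherits(tfr, "tfr_power"))
  d <- dim(tfr$power)
  ep <- list(trial_meta = tfr$trial_meta)
  g <- erp_groups(structure(ep, class = "epoch_array"), group_by)
  if (is.null(baseline_power)) {
    bix <- which(tfr$times >= baseline[1] & tfr$times <= baseline[2])
    if (length(bix) == 0) {
      stop("baseline window not covered by the epoch; supply baseline_power")
    }
    bp <- array(NA_real_, dim = c(nrow(g$groups), d[2], d[3]))
    for (k in seq_len(nrow(g$groups))) {
      ix <- which(g$index == k)
      bp[k, , ] <- apply(tfr$power[ix, , , bix, drop = FALSE],
                         c(2, 3), mean)
    }
    attr(bp, "groups") <- g$groups
  } else {
    bp <- baseline_power
    stopifnot(identical(dim(bp)[2:3], d[2:3]))
  }
  out <- tfr
  for (k in seq_len(dim(bp)[1])) {
    ix <- which(g$index == k)
    for (j in seq_len(d[2])) {
      for (l in seq_len(d[3])) {
        out$power[ix, j, l, ] <- 10 * log10(tfr$power[ix, j, l, ] /
                                              bp[k, j, l])
      }
    }
  }
  out$baseline_power <- bp
  attr(out, "db") <- TRUE
  out
}

#' Average dB power within canonical frequency bands
#'
#' Collapses the frequency axis to named bands (theta 4-8, alpha 8-15,
#' beta 15-30 Hz by default) by averaging the grid frequencies that fall
#' inside each band. A band sample is valid only where every contributing
#' frequency is outside the wavelet edge region.
#'
#' @param tfr a `tfr_power` object (typically dB-normalized).
#' @param bands named list of `c(lo, hi)` intervals (Hz, inclusive).
#' @return object of class `band_power`: list with `power` (trials x
#'   bands x labels x time), `bands`, `times`, `valid` (bands x time),
#'   `trial_meta`, `label_names`.
#' @export
band_average <- function(tfr,
                         bands = list(theta = c(4, 8), alpha = c(8, 15),
                                      beta = c(15, 30))) {
  stopifnot(inherits(tfr, "tfr_power"))
  d <- dim(tfr$power)
  nb <- length(bands)
  power <- array(NA_real_, dim = c(d[1], nb, d[3], d[4]))
  valid <- matrix(TRUE, nb, d[4])
  for (b in seq_len(nb)) {
    jx <- which(tfr$freqs >= bands[[b]][1] & tfr$freqs <= bands[[b]][2])
    if (length(jx) == 0) stop("no grid frequency inside band ",
                              names(bands)[b])
    power[, b, , ] <- apply(tfr$power[, jx, , , drop = FALSE],
                            c(1, 3, 4), mean)
    valid[b, ] <- apply(tfr$valid[jx, , drop = FALSE], 2, all)
  }
  structure(list(power = power, bands = bands, times = tfr$times,
                 sampling_rate = tfr$sampling_rate, valid = valid,
                 trial_meta = tfr$trial_meta,
                 label_names = tfr$label_names),
            class = "band_power")
}

#' Time-domain ERP preprocessing: crop, low-pass, downsample
#'
#' Prepares epochs for the time-domain (evoked potential) analysis:
#' crops to (-0.5, 2.0) s for stimulus-locked or (-1.0, 1.0) s for
#' response-locked epochs, low-pass filters at 15 Hz (4th-order
#' Butterworth applied forward-backward, so no phase distortion), and
#' downsamples by a factor of 3.
#'
#' @param epochs an [epoch_array()].
#' @param window crop window; defaults depend on `epochs$lock`.
#' @param lp_cutoff low-pass corner frequency (Hz).
#' @param decimate integer downsampling factor.
#' @return an [epoch_array()] at `sampling_rate / decimate`.
#' @export
erp_pipeline <- function(epochs,
                         window = if (epochs$lock == "stimulus")
                           c(-0.5, 2.0) else c(-1.0, 1.0),
                         lp_cutoff = 15, decimate = 3L) {
  stopifnot(inherits(epochs, "epoch_array"))
  fs <- epochs$sampling_rate
  cix <- which(epochs$times >= window[1] & epochs$times <= window[2])
  bf <- signal::butter(4, lp_cutoff / (fs / 2), type = "low")
  d <- dim(epochs$data)
  keep <- seq(1, length(cix), by = decimate)
  out <- array(0, dim = c(d[1], d[2], length(keep)))
  for (i in seq_len(d[1])) {
    for (l in seq_len(d[2])) {
      filt <- signal::filtfilt(bf, epochs$data[i, l, ])
      out[i, l, ] <- filt[cix][keep]
    }
  }
  epoch_array(out, epochs$times[cix][keep], fs / decimate, epochs$lock,
              epochs$trial_meta, epochs$label_names)
}

#' Bootstrap confidence band for the grand-mean ERP
#'
#' Resamples trials with replacement within each subject (preserving each
#' subject's trial count), averages to subject means and then to the grand
#' mean, and returns the percentile band over resamples.
#'
#' @param epochs an [epoch_array()] (typically after [erp_pipeline()]).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @param level confidence level.
#' @return list with `mean` (labels x time grand mean), `lo`, `hi`
#'   (percentile bounds, same shape).
#' @export
erp_bootstrap_ci <- function(epochs, n_boot = 1000, seed = 1L,
                             level = 0.95) {
  stopifnot(inherits(epochs, "epoch_array"))
  meta <- epochs$trial_meta
  subj <- factor(meta$subject_id)
  d <- dim(epochs$data)
  subj_levels <- levels(subj)
  subj_mean <- function(index_list) {
    sm <- array(0, dim = c(length(subj_levels), d[2], d[3]))
    for (s in seq_along(subj_levels)) {
      ix <- index_list[[s]]
      sm[s, , ] <- apply(epochs$data[ix, , , drop = FALSE], c(2, 3), mean)
    }
    apply(sm, c(2, 3), mean)
  }
  orig <- split(seq_len(d[1]), subj)
  gm <- subj_mean(orig)
  set.seed(seed)
  draws <- array(0, dim = c(n_boot, d[2], d[3]))
  for (b in seq_len(n_boot)) {
    res <- lapply(orig, function(ix) sample(ix, length(ix), replace = TRUE))
    draws[b, , ] <- subj_mean(res)
  }
  a <- (1 - level) / 2
  list(mean = gm,
       lo = apply(draws, c(2, 3), stats::quantile, probs = a),
       hi = apply(draws, c(2, 3), stats::quantile, probs = 1 - a))
}
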