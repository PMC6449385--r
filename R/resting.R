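# cache DPSS tapers across calls (keyed by length/bandwidth/count)
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the eigenvectors of the standard symmetric tridiagonal
#' matrix whose top eigenvectors are the DPSS sequences. Tapers are
#' normalized to unit energy.
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product.
#' @param k number of tapers (default `2*nw - 1`).
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  tvec <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * tvec) / 2)^2 * cos(2 * pi * w)
  diag_off <- tvec[-1] * (n - tvec[-1]) / 2
  A <- matrix(0, n, n)
  diag(A) <- diag_main
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  eg <- eigen(A, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  tap <- sweep(tap, 2, sqrt(colSums(tap^2)), "/")
  # polarity convention: symmetric tapers positive on average
  sgn <- ifelse(colSums(tap) < 0, -1, 1)
  tap <- sweep(tap, 2, sgn, "*")
  .dpss_cache[[key]] <- tap
  tap
}

#' Multitaper power spectral density of a single segment
#'
#' Averages direct spectral estimates over DPSS tapers (time-bandwidth 4,
#' 7 tapers by default).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @param fmax highest frequency returned (Hz).
#' @return data.frame with `freq` (Hz) and `psd`.
#' @export
multitaper_psd <- function(x, fs, nw = 4, k = 2 * nw - 1, fmax = 30) {
  n <- length(x)
  tap <- dpss_tapers(n, nw, k)
  nf <- floor(n / 2) + 1
  acc <- numeric(nf)
  for (j in seq_len(k)) {
    sp <- stats::fft(x * tap[, j])[seq_len(nf)]
    acc <- acc + Mod(sp)^2 / fs
  }
  freq <- (seq_len(nf) - 1) * fs / n
  keep <- freq <= fmax
  data.frame(freq = freq[keep], psd = acc[keep] / k)
}

#' Compare resting-state theta power between DBS states
#'
#' Cuts `n_epochs` non-overlapping segments of `epoch_len` seconds from
#' each continuous trace, computes a multitaper PSD (0-30 Hz) per
#' segment, averages power within the theta band, and tests the ON vs OFF
#' distributions with the two-sided Mann-Whitney U-test.
#'
#' @param trace_on,trace_off numeric vectors (continuous single-channel
#'   recordings).
#' @param fs sampling rate (Hz).
#' @param epoch_len segment length (s).
#' @param n_epochs segments per condition; the traces must be long enough.
#' @param band theta band limits (Hz).
#' @param nw,k multitaper parameters.
#' @return list with `theta_on`, `theta_off` (per-epoch band means), `U`
#'   (Mann-Whitney statistic) and `p` (two-sided).
#' @export
resting_theta_compare <- function(trace_on, trace_off, fs, epoch_len = 1,
                                  n_epochs = 60, band = c(4, 8), nw = 4,
                                  k = 2 * nw - 1) {
  cut_epochs <- function(x) {
    len <- floor(epoch_len * fs)
    need <- len * n_epochs
    if (length(x) < need) {
      stop(sprintf("trace too short: need %d samples for %d epochs, have %d",
                   need, n_epochs, length(x)))
    }
    matrix(x[seq_len(need)], nrow = len)
  }
  theta_of <- function(seg) {
    psd <- multitaper_psd(seg, fs, nw, k)
    mean(psd$psd[psd$freq >= band[1] & psd$freq <= band[2]])
  }
  on_e <- cut_epochs(trace_on)
  off_e <- cut_epochs(trace_off)
  theta_on <- apply(on_e, 2, theta_of)
  theta_off <- apply(off_e, 2, theta_of)
  wt <- stats::wilcox.test(theta_on, theta_off, exact = FALSE)
  list(theta_on = theta_on, theta_off = theta_off,
       U = unname(wt$statistic), p = wt$p.value)
}
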