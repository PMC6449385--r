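#' Construct an epoch array
#'
#' The container every spectral and cluster operation works on: a numeric
#' array of epoched ROI-label time courses with its time axis and aligned
#' per-trial metadata.
#'
#' @param data numeric array, trials x labels x time.
#' @param times numeric vector of times (s) relative to the lock event;
#'   length must equal `dim(data)[3]`.
#' @param sampling_rate Hz.
#' @param lock `"stimulus"` (image onset at t = 0) or `"response"`.
#' @param trial_meta data.frame with one row per trial, aligned by row
#'   order with the first array dimension.
#' @param label_names character vector naming the second dimension.
#' @return object of class `epoch_array`.
#' @export
epoch_array <- function(data, times, sampling_rate, lock = "stimulus",
                        trial_meta = NULL, label_names = NULL) {
  stopifnot(length(dim(data)) == 3, length(times) == dim(data)[3])
  lock <- match.arg(lock, c("stimulus", "response"))
  if (is.null(label_names)) {
    label_names <- dimnames(data)[[2]] %||% paste0("L", seq_len(dim(data)[2]))
  }
  stopifnot(length(label_names) == dim(data)[2])
  if (!is.null(trial_meta)) stopifnot(nrow(trial_meta) == dim(data)[1])
  dimnames(data) <- list(NULL, label_names, NULL)
  structure(list(data = data, times = as.numeric(times),
                 sampling_rate = sampling_rate, lock = lock,
                 trial_meta = trial_meta, label_names = label_names),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> %d trials x %d labels x %d samples, %s-locked\n",
              d[1], d[2], d[3], x$lock))
  cat(sprintf("  %.3f .. %.3f s @ %.2f Hz; labels: %s\n",
              min(x$times), max(x$times), x$sampling_rate,
              paste(x$label_names, collapse = ", ")))
  invisible(x)
}

#' Subset an epoch array by trial
#' @param epochs an [epoch_array()].
#' @param keep logical or integer index over trials.
#' @return the subsetted `epoch_array`.
#' @export
subset_epochs <- function(epochs, keep) {
  stopifnot(inherits(epochs, "epoch_array"))
  meta <- epochs$trial_meta
  if (!is.null(meta)) meta <- meta[keep, , drop = FALSE]
  epoch_array(epochs$data[keep, , , drop = FALSE], epochs$times,
              epochs$sampling_rate, epochs$lock, meta, epochs$label_names)
}

#' Write an epoch array to a directory (flat text + JSON sidecar)
#'
#' The array is stored as a delimited text matrix (`data.csv`, one row per
#' trial-and-label, one column per sample), the trial metadata as
#' `trial_meta.csv`, and the axes/attributes as a JSON sidecar
#' (`sidecar.json`: times, sampling rate, lock event, label names, array
#' dimensions).
#'
#' @param epochs an [epoch_array()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epoch_array <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_array"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  utils::write.table(flat, file.path(dir, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(epochs$trial_meta)) {
    utils::write.csv(epochs$trial_meta, file.path(dir, "trial_meta.csv"),
                     row.names = FALSE)
  }
  sidecar <- list(dims = d, times = epochs$times,
                  sampling_rate = epochs$sampling_rate, lock = epochs$lock,
                  label_names = epochs$label_names,
                  row_order = "trial-major (trial 1 labels 1..L, trial 2 ...)")
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an epoch array written by [write_epoch_array()]
#' @param dir directory containing `data.csv` and `sidecar.json`.
#' @return an [epoch_array()].
#' @export
read_epoch_array <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                            simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "data.csv"), sep = ","))
  d <- sc$dims
  data <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  meta_path <- file.path(dir, "trial_meta.csv")
  meta <- if (file.exists(meta_path)) utils::read.csv(meta_path) else NULL
  epoch_array(data, sc$times, sc$sampling_rate, sc$lock, meta,
              sc$label_names)
}
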