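# Small shared fixtures, all built in code.

tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_subjects = 4L, n_control = 12L,
             n_interference = 12L, sampling_rate = 1450 / 12,
             label_names = "VLPFC", ...)
}

# single-label epoch array from an explicit trials x time matrix
mat_epochs <- function(mat, fs, t0 = -1.5, meta = NULL) {
  times <- t0 + (seq_len(ncol(mat)) - 1) / fs
  epoch_array(array(mat, dim = c(nrow(mat), 1, ncol(mat))), times, fs,
              trial_meta = meta, label_names = "L1")
}

# trial-mean dB of a per-trial dB array slice: undo the log, average the
# power ratios across trials, re-log (the baseline contract is defined on
# the trial-mean ratio, not on the mean of per-trial logs)
mean_db <- function(db_values) 10 * log10(mean(10^(db_values / 10)))
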