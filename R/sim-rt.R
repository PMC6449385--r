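#' Build the full cohort trial table (no responses yet)
#'
#' Lays out the within-subject design: every subject performs
#' `n_blocks_per_state` blocks with DBS ON and the same number with DBS
#' OFF, each block an independently pseudo-randomized sequence from
#' [generate_trial_sequence()].
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `subject_id`, `block_id`, `dbs_state`
#'   (factor OFF/ON, OFF = baseline), plus the per-trial design columns.
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- list()
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (state in c("ON", "OFF")) {  # ON first, matching the session order
      for (b in seq_len(config$n_blocks_per_state)) {
        k <- k + 1L
        blk <- generate_trial_sequence(config$n_control,
                                       config$n_interference,
                                       seed = config$seed + 7919L * k)
        blk$subject_id <- sprintf("S%02d", s)
        blk$block_id <- sprintf("S%02d_%s_B%d", s, state, b)
        blk$dbs_state <- state
        out[[k]] <- blk
      }
    }
  }
  df <- do.call(rbind, out)
  df$dbs_state <- factor(df$dbs_state, levels = c("OFF", "ON"))
  rownames(df) <- NULL
  df
}

#' Simulate gamma-distributed reaction times for a trial table
#'
#' Draws each reaction time from a gamma distribution with fixed shape and
#' an identity-link mean, mirroring the generative model the behavioral
#' analysis assumes:
#' mean = intercept + interference effect + DBS effect (ON only) +
#' subject intercept. A configurable fraction of error and missing trials
#' is injected, and `post_error` is recomputed from the realized errors.
#'
#' @param trials trial table from [simulate_trials()] (or any table with
#'   `subject_id`, `block_id`, `interference`, `dbs_state`, `trial_index`).
#' @param config a [sim_config()].
#' @return the trial table with `rt` (ms, NA when missing), `correct`, and
#'   `post_error` columns filled.
#' @examples
#' cfg <- sim_config(seed = 2, n_subjects = 2)
#' tt <- simulate_rts(simulate_trials(cfg), cfg)
#' tapply(tt$rt, tt$interference, mean, na.rm = TRUE)
#' @export
simulate_rts <- function(trials, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 104729L)
  subj <- sort(unique(trials$subject_id))
  subj_int <- stats::rnorm(length(subj), 0, config$subject_sd)
  names(subj_int) <- subj

  mu <- config$rt_intercept +
    config$effect_interference * (trials$interference == "interference") +
    config$effect_dbs * (trials$dbs_state == "ON") +
    subj_int[trials$subject_id]
  if (any(mu <= 0)) {
    bad <- which(mu <= 0)[1]
    stop(sprintf(
      "implied mean RT is non-positive (%.1f ms) at row %d (subject %s)",
      mu[bad], bad, trials$subject_id[bad]))
  }
  n <- nrow(trials)
  trials$rt <- stats::rgamma(n, shape = config$rt_shape,
                             scale = mu / config$rt_shape)
  u <- stats::runif(n)
  missing <- u < config$miss_rate
  errors <- !missing & u < config$miss_rate + config$error_rate
  trials$rt[missing] <- NA_real_
  trials$correct <- !errors & !missing
  trials$correct[missing] <- NA

  # post_error: previous trial within the same block was an error
  trials$post_error <- FALSE
  prev_err <- c(FALSE, errors[-n])
  same_block <- c(FALSE, trials$block_id[-n] == trials$block_id[-1])
  trials$post_error <- prev_err & same_block
  trials
}
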