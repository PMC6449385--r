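#' Reduced-size demonstration configuration
#'
#' A cohort sized so the full end-to-end pipeline runs in minutes on one
#' CPU: fewer subjects, half-length blocks, two ROI labels, and a lower
#' synthetic sampling rate. Statistical structure (effect sizes, noise,
#' burst gains) is identical to [sim_config()] defaults.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
demo_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_subjects = 6L, n_control = 36L,
               n_interference = 36L, sampling_rate = 1450 / 6,
               label_names = c("dACC", "VLPFC"))
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage in sequence on data from the synthetic generator:
#' trial simulation, behavioral QC and gamma-GLM selection, epoch
#' simulation and artifact rejection, ERP subtraction, Morlet
#' decomposition with dB baselining and band averaging, cluster-mass
#' permutation tests per label for the DBS and interference predictors
#' with FDR correction across labels, the resting-state control
#' comparison, and the subject-level biomarker stage (integrated theta
#' change vs clinical improvement, robust line, bootstrap CIs, ROC/AUC).
#'
#' @param config a [sim_config()]; [demo_config()] gives a fast default.
#' @param n_perm permutations per cluster test.
#' @param n_boot bootstrap resamples for biomarker CIs.
#' @param out_dir optional directory; when given, result tables are
#'   written as CSV/JSON along with a `run_info.json` recording package
#'   version, seed, and the full configuration.
#' @param skip character vector of stages to skip (`"biomarker"`,
#'   `"resting"`, `"erp"`).
#' @return list of class `dbstheta_report` with elements `behavior`,
#'   `clusters`, `cluster_table`, `mass_fraction`, `erp`, `resting`,
#'   `biomarker`, `config`.
#' @export
run_all <- function(config = demo_config(), n_perm = 200, n_boot = 500,
                    out_dir = NULL, skip = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  report <- list(config = config)

  ## ---- behavior -------------------------------------------------------
  trials <- simulate_rts(simulate_trials(config), config)
  qc <- qc_filter(trials)
  sel <- stepwise_aic(qc$trials)
  err_on <- sum(!trials$correct[trials$dbs_state == "ON"], na.rm = TRUE)
  err_off <- sum(!trials$correct[trials$dbs_state == "OFF"], na.rm = TRUE)
  n_on <- sum(trials$dbs_state == "ON" & !is.na(trials$correct))
  n_off <- sum(trials$dbs_state == "OFF" & !is.na(trials$correct))
  report$behavior <- list(
    qc = qc$report, selected_terms = sel$terms, fit = sel$fit,
    aic_trace = sel$trace,
    error_rate_p = binomial_error_test(err_on, n_on, err_off, n_off))

  ## ---- spectral -------------------------------------------------------
  epochs <- simulate_epochs(qc$trials, config)
  rej <- amplitude_reject(epochs)
  induced <- subtract_erp(rej$epochs)
  tfr <- db_normalize(morlet_tfr(induced))
  bp <- band_average(tfr)
  report$n_rejected <- length(rej$rejected)

  ## ---- cluster statistics --------------------------------------------
  meta <- bp$trial_meta
  design <- data.frame(
    interference = as.numeric(meta$interference == "interference"),
    dbs = as.numeric(meta$dbs_state == "ON"),
    valence = meta$valence, arousal = meta$arousal,
    trial_number = meta$trial_index)
  design$dbs_x_interference <- design$dbs * design$interference
  theta_b <- which(names(bp$bands) == "theta")
  tests <- list()
  rows <- list()
  for (l in seq_along(bp$label_names)) {
    for (pred in c("interference", "dbs")) {
      ct <- permutation_cluster_test(
        bp$power[, theta_b, l, ], design, meta$subject_id, pred,
        times = bp$times, n_perm = n_perm, seed = config$seed,
        valid = bp$valid[theta_b, ])
      key <- paste(bp$label_names[l], "theta", pred, sep = ".")
      tests[[key]] <- ct
      if (nrow(ct$clusters)) {
        cl <- ct$clusters
        cl$label <- bp$label_names[l]; cl$band <- "theta"
        cl$predictor <- pred
        rows[[key]] <- cl
      }
    }
  }
  cluster_table <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(cluster_table)) {
    # FDR across labels within each predictor family
    cluster_table$p_fdr <- NA_real_
    for (pred in unique(cluster_table$predictor)) {
      ix <- cluster_table$predictor == pred
      cluster_table$p_fdr[ix] <- fdr_stepdown(cluster_table$p_perm[ix])
    }
    rownames(cluster_table) <- NULL
  }
  report$clusters <- tests
  report$cluster_table <- cluster_table

  mean_rt_s <- mean(qc$trials$rt, na.rm = TRUE) / 1000
  interf_tests <- tests[grepl("\\.interference$", names(tests))]
  report$mass_fraction <- cluster_mass_fraction(
    interf_tests, c(0.4, 0.4 + mean_rt_s), only_significant = 0.05)
  report$mean_rt_s <- mean_rt_s

  ## ---- time-domain ERP ------------------------------------------------
  if (!"erp" %in% skip) {
    ep <- erp_pipeline(rej$epochs)
    report$erp <- list(
      epochs_info = list(sampling_rate = ep$sampling_rate,
                         n_samples = length(ep$times)),
      ci = erp_bootstrap_ci(ep, n_boot = n_boot, seed = config$seed))
  }

  ## ---- resting-state control -----------------------------------------
  if (!"resting" %in% skip) {
    on <- simulate_resting(config, 60, "ON")
    off <- simulate_resting(config, 60, "OFF")
    report$resting <- resting_theta_compare(
      on[1, ], off[1, ], attr(on, "sampling_rate"))
  }

  ## ---- biomarker ------------------------------------------------------
  if (!"biomarker" %in% skip) {
    # integration window: the most significant DBS theta cluster, else the
    # decision-period default
    win <- c(config$burst_onset, config$burst_onset + config$burst_duration)
    if (!is.null(cluster_table)) {
      dbs_cl <- cluster_table[cluster_table$predictor == "dbs", ]
      if (nrow(dbs_cl)) {
        best <- dbs_cl[which.min(dbs_cl$p_perm), ]
        win <- c(best$t_start, best$t_end)
      }
    }
    lab <- if ("VLPFC" %in% bp$label_names)
      which(bp$label_names == "VLPFC") else length(bp$label_names)
    subj <- sort(unique(meta$subject_id))
    theta_by_subject <- lapply(subj, function(s) {
      list(on = colMeans(bp$power[meta$subject_id == s &
                                    meta$dbs_state == "ON", theta_b,
                                  lab, , drop = TRUE]),
           off = colMeans(bp$power[meta$subject_id == s &
                                     meta$dbs_state == "OFF", theta_b,
                                   lab, , drop = TRUE]))
    })
    names(theta_by_subject) <- subj
    dtheta <- vapply(subj, function(s) {
      th <- theta_by_subject[[s]]
      integrate_theta_difference(th$on, th$off, bp$times, win)
    }, numeric(1))
    clin <- simulate_cohort_biomarker(config, delta_theta = unname(dtheta))
    clin$subject_id <- subj
    bm <- subject_biomarkers(
      qc$trials, theta_by_subject, bp$times, win,
      clin[, c("subject_id", "madrs_baseline", "madrs_followup",
               "hypomania")])
    corr <- pearson_fisher(bm$delta_theta, bm$madrs_change)
    draws <- bootstrap_draws(nrow(bm), n_boot, config$seed)
    r_ci <- bootstrap_ci(function(d) {
      if (stats::sd(d$delta_theta) == 0 || stats::sd(d$madrs_change) == 0)
        return(NA_real_)
      stats::cor(d$delta_theta, d$madrs_change)
    }, bm, draws = draws)
    auc <- roc_auc(bm$delta_theta, !bm$responder)
    auc_ci <- bootstrap_ci(function(d) {
      if (length(unique(d$responder)) < 2) return(NA_real_)
      roc_auc(d$delta_theta, !d$responder)$auc
    }, bm, draws = draws)
    report$biomarker <- list(
      table = bm, window = win, label = bp$label_names[lab],
      correlation = corr, r_ci = r_ci[c("lo", "hi")],
      line = robust_line(bm$delta_theta, bm$madrs_change),
      auc = auc$auc, auc_ci = auc_ci[c("lo", "hi")])
  }

  class(report) <- "dbstheta_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.dbstheta_report <- function(x, ...) {
  cat("<dbstheta_report>\n")
  co <- x$behavior$fit$coefficients
  cat("  behavior:", x$behavior$qc$n_kept, "trials after QC; terms:",
      paste(x$behavior$selected_terms, collapse = ", "), "\n")
  for (i in seq_len(nrow(co))) {
    cat(sprintf("    %-16s %8.1f ms  (t = %6.1f, p = %.3g)\n",
                co$term[i], co$estimate[i], co$t[i], co$p[i]))
  }
  if (!is.null(x$cluster_table)) {
    sig <- sum(x$cluster_table$p_fdr < 0.05)
    cat(sprintf("  clusters: %d found, %d significant after FDR\n",
                nrow(x$cluster_table), sig))
  } else cat("  clusters: none\n")
  if (is.finite(x$mass_fraction)) {
    cat(sprintf("  %.1f%% of significant interference theta mass in the decision period\n",
                x$mass_fraction))
  }
  if (!is.null(x$resting)) {
    cat(sprintf("  resting theta ON vs OFF: U = %.0f, p = %.3f\n",
                x$resting$U, x$resting$p))
  }
  if (!is.null(x$biomarker)) {
    b <- x$biomarker
    cat(sprintf("  biomarker (%s, %.2f-%.2f s): r = %.2f (p = %.3f), AUC = %.2f [%.2f, %.2f]\n",
                b$label, b$window[1], b$window[2], b$correlation$r,
                b$correlation$p, b$auc, b$auc_ci$lo, b$auc_ci$hi))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits tidy CSV tables (GLM coefficients, cluster inventory, biomarker
#' table), a JSON cluster inventory, and `run_info.json` with the package
#' version, seed, and configuration.
#'
#' @param report a `dbstheta_report` from [run_all()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$behavior$fit$coefficients,
                   file.path(out_dir, "glm_coefficients.csv"),
                   row.names = FALSE)
  if (!is.null(report$cluster_table)) {
    ct <- report$cluster_table
    utils::write.csv(ct, file.path(out_dir, "cluster_inventory.csv"),
                     row.names = FALSE)
    jsonlite::write_json(ct, file.path(out_dir, "cluster_inventory.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(report$biomarker)) {
    utils::write.csv(report$biomarker$table,
                     file.path(out_dir, "biomarker_table.csv"),
                     row.names = FALSE)
  }
  cfg <- unclass(report$config)
  jsonlite::write_json(
    list(package = "dbstheta",
         version = as.character(utils::packageVersion("dbstheta")),
         seed = cfg$seed, config = cfg),
    file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
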