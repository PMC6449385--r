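#' Trial-level quality control for reaction-time analysis
#'
#' Applies the behavioral exclusion rules in order: (1) trials with a
#' missing response, (2) error trials, (3) post-error trials (the trial
#' immediately after an error within the same block), and (4) outlier RTs.
#' Outliers are defined per subject by fitting a gamma distribution to
#' that subject's remaining RTs, pooling DBS ON and OFF runs, and removing
#' trials whose fitted density value falls below `likelihood_cutoff`. The
#' density is evaluated with RT expressed in seconds, which puts typical
#' density values near 1 and makes the 0.005 cutoff a far-tail rule.
#'
#' @param trials trial table with `rt` (ms), `correct`, `post_error`,
#'   `subject_id` columns.
#' @param likelihood_cutoff gamma density value below which a trial is an
#'   outlier.
#' @param rt_unit unit of the `rt` column; densities are always evaluated
#'   on seconds.
#' @param min_trials subjects with fewer valid trials than this get no
#'   outlier removal (the gamma fit would be unstable); a warning is
#'   emitted.
#' @return list with `trials` (the filtered table) and `report` (counts
#'   and fractions removed per rule, overall and per subject).
#' @examples
#' cfg <- sim_config(seed = 5, n_subjects = 2)
#' qc <- qc_filter(simulate_rts(simulate_trials(cfg), cfg))
#' qc$report$n_removed
#' @export
qc_filter <- function(trials, likelihood_cutoff = 0.005, rt_unit = "ms",
                      min_trials = 10) {
  stopifnot(all(c("rt", "correct", "post_error", "subject_id") %in%
                  names(trials)))
  n0 <- nrow(trials)
  missing <- is.na(trials$rt) | is.na(trials$correct)
  error <- !missing & !trials$correct
  post <- !missing & !error & trials$post_error
  keep <- !(missing | error | post)
  kept <- trials[keep, , drop = FALSE]

  scale <- if (rt_unit == "ms") 1000 else 1
  outlier <- rep(FALSE, nrow(kept))
  for (s in unique(kept$subject_id)) {
    ix <- which(kept$subject_id == s)
    x <- kept$rt[ix] / scale
    if (length(ix) < min_trials) {
      warning(sprintf(
        "subject %s has %d valid trials (< %d): outlier removal skipped",
        s, length(ix), min_trials))
      next
    }
    fit <- tryCatch(suppressWarnings(MASS::fitdistr(x, "gamma")),
                    error = function(e) NULL)
    if (is.null(fit)) next
    dens <- stats::dgamma(x, shape = fit$estimate["shape"],
                          rate = fit$estimate["rate"])
    outlier[ix] <- dens < likelihood_cutoff
  }
  out <- kept[!outlier, , drop = FALSE]
  report <- list(
    n_input = n0,
    n_missing = sum(missing),
    n_error = sum(error),
    n_post_error = sum(post),
    n_outlier = sum(outlier),
    n_removed = n0 - nrow(out),
    n_kept = nrow(out),
    fraction_removed = (n0 - nrow(out)) / max(1, n0),
    likelihood_cutoff = likelihood_cutoff
  )
  list(trials = out, report = report)
}

# Build the numeric design columns used by both the behavioral GLM and the
# sliding EEG regression. Main effects are rescaled to [0, 1]; interaction
# columns are products of rescaled mains, so a coefficient's natural-unit
# value is estimate / prod(ranges of its parents).
build_design <- function(trials, terms) {
  base_cols <- list(
    interference = as.numeric(trials$interference == "interference"),
    dbs = as.numeric(trials$dbs_state == "ON"),
    valence = trials$valence,
    arousal = trials$arousal,
    trial_number = trials$trial_index
  )
  mains <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  cols <- list(); ranges <- c()
  for (m in mains) {
    if (is.null(base_cols[[m]])) stop("unknown predictor: ", m)
    s <- standardize01(base_cols[[m]])
    cols[[m]] <- s$x
    ranges[m] <- s$range
  }
  X <- matrix(0, nrow(trials), length(terms),
              dimnames = list(NULL, terms))
  term_range <- numeric(length(terms)); names(term_range) <- terms
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    X[, tm] <- Reduce(`*`, cols[parts])
    term_range[tm] <- prod(ranges[parts])
  }
  list(X = X, ranges = term_range)
}

#' Fit the gamma reaction-time GLM
#'
#' Maximum-likelihood gamma regression of RT with an identity link: the
#' conditional mean RT is a linear (additive, in ms) function of the
#' predictors, while the skewed trial-to-trial variability follows a gamma
#' distribution. Predictors are rescaled to \[0, 1\] for fitting and
#' coefficients reported back in natural units. Between-subject RT
#' differences are absorbed by a per-subject intercept: a fixed intercept
#' per subject with the default `engine = "glm"`, or a gaussian random
#' intercept with `engine = "glmer"` (lme4). The two give materially
#' identical fixed-effect estimates on well-behaved data; the
#' fixed-intercept route is the default because it is fast and numerically
#' robust with the identity link.
#'
#' @param trials QC-filtered trial table.
#' @param fixed_terms character vector of predictors among `interference`,
#'   `dbs`, `valence`, `arousal`, `trial_number`, plus interactions written
#'   `"a:b"`.
#' @param engine `"glm"` (per-subject fixed intercepts) or `"glmer"`
#'   (random intercept).
#' @param response name of the response column (ms).
#' @return object of class `rt_fit`: list with `coefficients` (a
#'   data.frame with natural-unit estimates, SEs, Wald t and two-sided p
#'   per fixed term), `aic`, `n_obs`, `converged`, `engine`, and the
#'   underlying `fit`.
#' @export
fit_gamma_glm <- function(trials, fixed_terms = c("interference", "dbs"),
                          engine = c("glm", "glmer"), response = "rt") {
  engine <- match.arg(engine)
  y <- trials[[response]]
  stopifnot(all(is.finite(y)), all(y > 0))
  if (length(fixed_terms) == 0) {
    des <- list(X = matrix(numeric(0), length(y), 0), ranges = numeric(0))
    df <- data.frame(row.names = seq_along(y))
  } else {
    des <- build_design(trials, fixed_terms)
    df <- as.data.frame(des$X)
    names(df) <- gsub(":", "_x_", names(df), fixed = TRUE)
  }
  term_cols <- names(df)
  df$.y <- y
  df$.subject <- factor(trials$subject_id)

  converged <- TRUE
  rhs <- if (length(term_cols)) paste(term_cols, collapse = " + ") else NULL
  if (engine == "glm") {
    subj_term <- if (nlevels(df$.subject) > 1) ".y ~ 0 + .subject" else
      ".y ~ 1"
    form <- stats::as.formula(paste(c(subj_term, rhs), collapse = " + "))
    fit <- stats::glm(form, data = df,
                      family = stats::Gamma(link = "identity"),
                      mustart = df$.y)
    converged <- fit$converged
    sm <- summary(fit)$coefficients
    rows <- sm[term_cols, , drop = FALSE]
    aic <- stats::AIC(fit)
    n_obs <- stats::nobs(fit)
  } else {
    form <- stats::as.formula(paste(
      c(".y ~ (1 | .subject)", rhs), collapse = " + "))
    fit <- tryCatch(
      lme4::glmer(form, data = df,
                  family = stats::Gamma(link = "identity"),
                  mustart = df$.y,
                  control = lme4::glmerControl(
                    check.conv.grad = lme4::.makeCC("warning", 2e-3))),
      warning = function(w) {
        converged <<- FALSE
        suppressWarnings(
          lme4::glmer(form, data = df,
                      family = stats::Gamma(link = "identity"),
                      mustart = df$.y))
      })
    sm <- stats::coef(summary(fit))
    rows <- sm[term_cols, , drop = FALSE]
    colnames(rows) <- c("Estimate", "Std. Error", "t value", "Pr(>|t|)")[
      seq_len(ncol(rows))]
    if (ncol(rows) == 3) {
      rows <- cbind(rows,
                    "Pr(>|t|)" = 2 * stats::pnorm(-abs(rows[, "t value"])))
    }
    aic <- stats::AIC(fit)
    n_obs <- stats::nobs(fit)
  }

  est_std <- rows[, "Estimate"]
  se_std <- rows[, "Std. Error"]
  coefs <- data.frame(
    term = fixed_terms,
    estimate = est_std / des$ranges,
    se = se_std / des$ranges,
    t = rows[, "t value"],
    p = rows[, ncol(rows)],
    estimate_std = est_std,
    row.names = NULL
  )
  structure(list(coefficients = coefs, aic = aic, n_obs = n_obs,
                 converged = converged, engine = engine, fit = fit,
                 terms = fixed_terms),
            class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("<rt_fit> gamma/identity GLM (%s), n = %d, AIC = %.1f%s\n",
              x$engine, x$n_obs, x$aic,
              if (x$converged) "" else "  [DID NOT CONVERGE]"))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Forward stepwise model selection by AIC
#'
#' Starting from the nuisance-only model (per-subject intercepts plus any
#' `nuisance_terms`), repeatedly adds the candidate term that yields the
#' largest AIC decrease, until no remaining candidate decreases AIC.
#' Interaction candidates are only eligible once both parent main effects
#' are in the model. Ties are broken by candidate list order, so selection
#' is deterministic. Candidates whose fit fails or is rank-deficient are
#' skipped and recorded in the log.
#'
#' @param trials QC-filtered trial table.
#' @param candidate_terms terms to consider (mains and `"a:b"`
#'   interactions).
#' @param nuisance_terms terms always kept in the model (default the
#'   trial-number fatigue regressor).
#' @param engine passed to [fit_gamma_glm()].
#' @return list with `terms` (selected, including nuisance), `fit` (the
#'   final [fit_gamma_glm()] object), `trace` (data.frame of AIC at each
#'   step), and `log` (skipped candidates).
#' @export
stepwise_aic <- function(trials,
                         candidate_terms = c("interference", "dbs",
                                             "valence", "arousal",
                                             "interference:dbs"),
                         nuisance_terms = "trial_number",
                         engine = "glm") {
  current <- nuisance_terms
  fit_cur <- fit_gamma_glm(trials, current, engine = engine)
  trace <- data.frame(step = 0L, added = "(nuisance)", aic = fit_cur$aic)
  log <- character(0)
  remaining <- setdiff(candidate_terms, current)
  step <- 0L
  repeat {
    step <- step + 1L
    best_aic <- fit_cur$aic; best_term <- NULL; best_fit <- NULL
    for (tm in remaining) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      if (length(parts) > 1 && !all(parts %in% current)) next
      f <- tryCatch(fit_gamma_glm(trials, c(current, tm), engine = engine),
                    error = function(e) NULL)
      if (is.null(f) || any(!is.finite(f$coefficients$estimate))) {
        log <- c(log, sprintf("step %d: candidate '%s' not identifiable, skipped",
                              step, tm))
        next
      }
      if (f$aic < best_aic) {
        best_aic <- f$aic; best_term <- tm; best_fit <- f
      }
    }
    if (is.null(best_term)) break
    current <- c(current, best_term)
    fit_cur <- best_fit
    remaining <- setdiff(remaining, best_term)
    trace <- rbind(trace, data.frame(step = step, added = best_term,
                                     aic = best_aic))
  }
  list(terms = current, fit = fit_cur, trace = trace, log = log)
}

#' Exact test for equal error rates between DBS states
#'
#' Conditional binomial test: given the total number of errors, the ON
#' errors are binomial with success probability equal to the ON share of
#' trials under the null of equal error probability. Two-sided p-value by
#' summing outcome probabilities no larger than the observed one.
#'
#' @param errors_on,n_on errors and trials in the ON state.
#' @param errors_off,n_off errors and trials in the OFF state.
#' @return two-sided p-value.
#' @examples
#' binomial_error_test(2, 100, 2, 100)  # 1
#' @export
binomial_error_test <- function(errors_on, n_on, errors_off, n_off) {
  stopifnot(errors_on >= 0, errors_off >= 0, n_on >= errors_on,
            n_off >= errors_off)
  m <- errors_on + errors_off
  if (m == 0) return(1)
  p0 <- n_on / (n_on + n_off)
  stats::binom.test(errors_on, m, p = p0)$p.value
}
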