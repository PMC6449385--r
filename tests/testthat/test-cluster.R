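test_that("subject demeaning removes offsets and is idempotent", {
  set.seed(51)
  d <- rbind(matrix(rnorm(5 * 40), 5) + 10, matrix(rnorm(5 * 40), 5) - 3)
  subj <- rep(c("A", "B"), each = 5)
  dm <- subject_demean(d, subj)
  expect_lt(max(abs(colMeans(dm[subj == "A", ]))), 1e-12)
  expect_lt(max(abs(colMeans(dm[subj == "B", ]))), 1e-12)
  expect_equal(subject_demean(dm, subj), dm)
  # single subject: equivalent to grand-mean removal
  one <- matrix(rnorm(4 * 20), 4) + 7
  expect_equal(subject_demean(one, rep("A", 4)),
               sweep(one, 2, colMeans(one)))
})

test_that("sliding OLS matches lm() on a small fixture and noiseless limit", {
  set.seed(52)
  n <- 6
  des <- data.frame(interference = c(0, 1, 0, 1, 0, 1),
                    arousal = c(2, 5, 7, 3, 8, 4))
  y <- matrix(rnorm(n * 3), n)
  out <- sliding_ols(y, des)
  for (tp in 1:3) {
    x1 <- standardize01(des$interference)$x
    x2 <- standardize01(des$arousal)$x
    lmfit <- summary(lm(y[, tp] ~ x1 + x2))
    expect_equal(unname(out$beta[, tp]),
                 unname(coef(lmfit)[2:3, "Estimate"]), tolerance = 1e-10)
    expect_equal(unname(out$t[, tp]),
                 unname(coef(lmfit)[2:3, "t value"]), tolerance = 1e-10)
  }
  expect_equal(out$df, n - 3)
  # noiseless limit: beta -> 2, |t| enormous
  y2 <- matrix(2 * des$interference + rnorm(n, sd = 1e-8), n, 1)
  out2 <- sliding_ols(y2, des["interference"])
  expect_equal(unname(out2$beta[1, 1]), 2, tolerance = 1e-5)
  expect_gt(abs(out2$t[1, 1]), 1e5)
  # permuting rows jointly leaves estimates unchanged
  p <- sample(n)
  out3 <- sliding_ols(y[p, ], des[p, ])
  expect_equal(out3$beta, out$beta, tolerance = 1e-10)
  # rank deficiency names the collinear column
  des_bad <- cbind(des, dup = des$interference)
  expect_error(sliding_ols(y, des_bad), "dup")
})

test_that("cluster formation applies the threshold, sign, and 50 ms rules", {
  fs <- 1450 / 3
  dt <- 1 / fs
  nt <- 400
  times <- (seq_len(nt) - 1) * dt
  df <- 100
  thr <- qt(0.975, df)
  tser <- rep(0, nt)
  # run A: 30 samples (62 ms) positive; run B: 20 samples (41 ms) negative
  tser[50:79] <- thr + 1
  tser[200:219] <- -(thr + 2)
  cl <- form_clusters(tser, times, df)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$mass, 30 * (thr + 1), tolerance = 1e-10)
  expect_equal(cl$sign, 1)
  # 25 samples ~ 51.7 ms passes; 23 samples ~ 47.6 ms fails
  tser2 <- rep(0, nt); tser2[10:34] <- thr + 0.5; tser2[100:122] <- thr + 0.5
  cl2 <- form_clusters(tser2, times, df)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$start, 10)
  # no suprathreshold samples: empty
  expect_equal(nrow(form_clusters(rep(0, nt), times, df)), 0)
  # sign change splits clusters
  tser3 <- rep(0, nt); tser3[50:99] <- thr + 1; tser3[100:149] <- -(thr + 1)
  expect_equal(nrow(form_clusters(tser3, times, df)), 2)
})

test_that("permutation p matches exhaustive enumeration on a 6-trial fixture", {
  fs <- 100
  nt <- 30
  times <- (seq_len(nt) - 1) / fs
  set.seed(53)
  dbs <- c(1, 0, 1, 0, 1, 0)
  data <- outer(dbs, c(rep(1, 15), rep(0, 15))) * 2 +
    matrix(rnorm(6 * nt, sd = 0.8), 6)
  des <- data.frame(dbs = dbs)
  ct <- permutation_cluster_test(data, des, rep("S01", 6), "dbs",
                                 times = times, n_perm = 1000, seed = 7,
                                 min_duration = 0.05, demean = FALSE)
  expect_gt(nrow(ct$clusters), 0)
  # oracle: all 20 distinct ON-position assignments
  obs_mass <- max(abs(ct$clusters$mass))
  fit_mass <- function(perm_dbs) {
    d2 <- data.frame(dbs = perm_dbs)
    o <- sliding_ols(data, d2)
    cl <- form_clusters(o$t[1, ], times, o$df, min_duration = 0.05)
    if (nrow(cl)) max(abs(cl$mass)) else 0
  }
  null_exact <- apply(utils::combn(6, 3), 2, function(ix) {
    v <- rep(0, 6); v[ix] <- 1; fit_mass(v)
  })
  p_exact <- mean(null_exact >= obs_mass - 1e-10)
  p_obs <- min(ct$clusters$p_perm)
  expect_lt(abs(p_obs - p_exact), 0.03 + 1 / (ct$n_perm + 1))
})

test_that("permutation p is never zero and clusters ignore the seed", {
  np <- simulate_null_power(n_subjects = 4, n_trials_per_subject = 20,
                            n_time = 100, seed = 4)
  # inject a strong effect so a cluster exists
  eff <- np$design$dbs * outer(rep(1, 80), c(rep(0, 40), rep(2, 30),
                                             rep(0, 30)))
  ct1 <- permutation_cluster_test(np$data + eff, np$design, np$subjects,
                                  "dbs", times = np$times, n_perm = 150,
                                  seed = 1)
  ct2 <- permutation_cluster_test(np$data + eff, np$design, np$subjects,
                                  "dbs", times = np$times, n_perm = 150,
                                  seed = 99)
  expect_true(all(ct1$clusters$p_perm > 0))
  expect_equal(ct1$clusters$mass, ct2$clusters$mass)
  expect_equal(ct1$clusters$start, ct2$clusters$start)
  # p varies only within binomial noise
  expect_lt(max(abs(ct1$clusters$p_perm - ct2$clusters$p_perm)), 0.12)
})

test_that("subjects with fewer than two trials are excluded with a warning", {
  np <- simulate_null_power(n_subjects = 3, n_trials_per_subject = 10,
                            n_time = 80, seed = 6)
  subj <- np$subjects
  subj[1] <- "S99"  # singleton subject
  expect_warning(
    permutation_cluster_test(np$data, np$design, subj, "dbs",
                             times = np$times, n_perm = 20, seed = 1),
    "S99")
})

test_that("BH adjustment matches the hand calculation", {
  expect_equal(fdr_stepdown(0.04), 0.04)
  expect_equal(fdr_stepdown(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.005, 0.04, 0.2)
  expect_equal(fdr_stepdown(p), c(0.015, 0.06, 0.2))
  expect_equal(fdr_stepdown(rep(0.07, 5)), rep(0.07, 5))
  # adjusted never below raw
  set.seed(54)
  praw <- runif(20)
  expect_true(all(fdr_stepdown(praw) >= praw))
})

test_that("cluster mass fraction: all-in, none-in, and half-overlap", {
  fs <- 100
  nt <- 200
  times <- (seq_len(nt) - 1) / fs
  df <- 50
  thr <- qt(0.975, df)
  tser <- rep(0, nt)
  tser[51:150] <- thr + 1   # uniform cluster over 0.50..1.49 s
  cl <- form_clusters(tser, times, df)
  fake <- structure(list(clusters = cl), class = "cluster_test")
  attr(fake$clusters, "detail") <- attr(cl, "detail")
  expect_equal(cluster_mass_fraction(fake, c(0, 2)), 100)
  expect_equal(cluster_mass_fraction(fake, c(1.6, 2)), 0)
  half <- cluster_mass_fraction(fake, c(0.5, times[100]))
  expect_equal(half, 50, tolerance = 1)
})
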