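test_that("trial sequences have exact counts and no run-of-three", {
  s <- generate_trial_sequence(72, 72, seed = 1)
  expect_equal(nrow(s), 144)
  expect_equal(sum(s$interference == "control"), 72)
  expect_equal(sum(s$interference == "interference"), 72)
  expect_equal(count_sequence_violations(s), 0L)
  # several seeds, exhaustive window scan
  for (sd in 2:6) {
    expect_equal(count_sequence_violations(
      generate_trial_sequence(36, 36, seed = sd)), 0L)
  }
})

test_that("trial sequence edge cases: empty, infeasible, determinism", {
  expect_equal(nrow(generate_trial_sequence(0, 0, character(0), seed = 9)), 0)
  expect_error(
    generate_trial_sequence(5, 0, valences = "neutral", seed = 1,
                            max_sweeps = 30),
    "infeasible")
  a <- generate_trial_sequence(20, 20, seed = 42)
  b <- generate_trial_sequence(20, 20, seed = 42)
  expect_identical(a, b)
})

test_that("split_images halves the set and beats random splits", {
  set.seed(10)
  r <- data.frame(valence = runif(144, 1, 9), arousal = runif(144, 1, 9))
  sp <- split_images(r)
  expect_equal(length(sp$set1), 72)
  expect_equal(length(sp$set2), 72)
  expect_equal(sort(c(sp$set1, sp$set2)), 1:144)
  rand_obj <- replicate(1000, {
    ix <- sample(144, 72)
    split_objective(r, ix, setdiff(1:144, ix))
  })
  expect_lte(sp$objective, min(rand_obj))
})

test_that("split_images: identical ratings give objective 0, brute force on 6", {
  same <- data.frame(valence = rep(5, 8), arousal = rep(5, 8))
  expect_equal(split_images(same)$objective, 0)
  expect_error(split_images(data.frame(valence = 1:3, arousal = 1:3)),
               "even")
  set.seed(3)
  r6 <- data.frame(valence = runif(6, 1, 9), arousal = runif(6, 1, 9))
  best <- min(apply(utils::combn(6, 3), 2, function(ix) {
    split_objective(r6, ix, setdiff(1:6, ix))
  }))
  expect_equal(split_images(r6)$objective, best, tolerance = 1e-12)
})

test_that("simulated RTs carry the configured interference and DBS effects", {
  cfg <- sim_config(seed = 11, n_subjects = 18, n_control = 72,
                    n_interference = 72, error_rate = 0, miss_rate = 0,
                    subject_sd = 0)
  tt <- simulate_rts(simulate_trials(cfg), cfg)   # > 5000 trials
  d_int <- mean(tt$rt[tt$interference == "interference"]) -
    mean(tt$rt[tt$interference == "control"])
  se <- sqrt(2) * sd(tt$rt) / sqrt(nrow(tt) / 2)
  expect_lt(abs(d_int - 224), 3 * se)
  d_dbs <- mean(tt$rt[tt$dbs_state == "ON"]) -
    mean(tt$rt[tt$dbs_state == "OFF"])
  expect_lt(abs(d_dbs - (-34)), 3 * se)
})

test_that("null DBS effect yields no ON/OFF RT difference", {
  cfg <- sim_config(seed = 12, n_subjects = 10, effect_dbs = 0,
                    subject_sd = 0, error_rate = 0, miss_rate = 0)
  tt <- simulate_rts(simulate_trials(cfg), cfg)
  p <- t.test(tt$rt[tt$dbs_state == "ON"], tt$rt[tt$dbs_state == "OFF"])$p.value
  expect_gt(p, 0.001)
})

test_that("RT marginals follow the gamma CV law and pass goodness of fit", {
  for (shape in c(10, 200)) {
    cfg <- sim_config(seed = 13, n_subjects = 12, rt_shape = shape,
                      effect_interference = 0, effect_dbs = 0,
                      subject_sd = 0, error_rate = 0, miss_rate = 0)
    tt <- simulate_rts(simulate_trials(cfg), cfg)
    cv2 <- var(tt$rt) / mean(tt$rt)^2
    expect_equal(cv2, 1 / shape, tolerance = 0.15)
    p <- ks.test(tt$rt, "pgamma", shape = shape,
                 scale = cfg$rt_intercept / shape)$p.value
    expect_gt(p, 0.001)
  }
})

test_that("non-positive implied mean RT raises a named error", {
  cfg <- sim_config(seed = 14, n_subjects = 2, rt_intercept = 10,
                    effect_dbs = -50, subject_sd = 0)
  expect_error(simulate_rts(simulate_trials(cfg), cfg), "non-positive")
})

test_that("generator outputs are bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 77)
  t1 <- simulate_rts(simulate_trials(cfg), cfg)
  t2 <- simulate_rts(simulate_trials(cfg), cfg)
  expect_identical(t1, t2)
  e1 <- simulate_epochs(t1, cfg)
  e2 <- simulate_epochs(t2, cfg)
  expect_identical(e1$data, e2$data)
})

test_that("random-phase bursts cancel in the trial average", {
  cfg <- sim_config(seed = 15, n_subjects = 1, n_control = 200,
                    n_interference = 200, sampling_rate = 1450 / 12,
                    label_names = "L", noise_sd = 0, erp_amplitude = 0,
                    error_rate = 0, miss_rate = 0)
  ep <- simulate_epochs(simulate_rts(simulate_trials(cfg), cfg), cfg,
                        window = c(-0.6, 1.2))
  avg <- colMeans(ep$data[, 1, ])
  burst_rms <- cfg$burst_amplitude / sqrt(2)
  # 400 random phases: mean amplitude ~ burst/sqrt(n), allow 3x
  expect_lt(max(abs(avg)), 3 * burst_rms / sqrt(400) * 3)
})

test_that("cohort biomarker table respects the target correlation", {
  cfg0 <- sim_config(seed = 16, n_subjects = 10000, biomarker_r = 0)
  bm0 <- simulate_cohort_biomarker(cfg0)
  expect_lt(abs(cor(bm0$delta_theta, bm0$madrs_change)), 0.03)

  r_hats <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, n_subjects = 8, biomarker_r = 0.76)
    bm <- simulate_cohort_biomarker(cfg)
    cor(bm$delta_theta, bm$madrs_change)
  }, numeric(1))
  expect_lt(abs(mean(r_hats) - 0.76), 0.1)
})

test_that("perfect biomarker linkage gives perfect responder separation", {
  cfg <- sim_config(seed = 17, n_subjects = 12, biomarker_r = 1)
  bm <- simulate_cohort_biomarker(cfg)
  expect_true(length(unique(bm$responder)) == 2)
  expect_equal(roc_auc(bm$delta_theta, !bm$responder)$auc, 1)
  expect_error(sim_config(biomarker_r = 1.2), "biomarker_r")
})

test_that("null power generator has no condition effect and subject offsets", {
  np <- simulate_null_power(n_subjects = 4, n_trials_per_subject = 30,
                            seed = 2)
  expect_equal(dim(np$data), c(120, 225))
  d <- mean(np$data[np$design$dbs == 1, ]) -
    mean(np$data[np$design$dbs == 0, ])
  expect_lt(abs(d), 0.2)
})
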