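test_that("amplitude rejection removes exactly the spiking epochs", {
  fs <- 100
  mat <- matrix(0, 6, 200)
  ep <- mat_epochs(mat, fs)
  expect_length(amplitude_reject(ep)$rejected, 0)
  mat[3, 50] <- 151
  expect_equal(amplitude_reject(mat_epochs(mat, fs))$rejected, 3L)
  mat[5, 10] <- -200; mat[1, 199] <- 160
  out <- amplitude_reject(mat_epochs(mat, fs))
  expect_equal(out$rejected, c(1L, 3L, 5L))
  expect_equal(dim(out$epochs$data)[1], 3)
  # boundary: exactly 150 is kept
  mat2 <- matrix(0, 2, 50); mat2[1, 5] <- 150
  expect_length(amplitude_reject(mat_epochs(mat2, fs))$rejected, 0)
})

test_that("ERP computation: identical trials, single trials, phase cancellation", {
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  meta <- data.frame(subject_id = "S01", dbs_state = "ON",
                     interference = rep(c("control", "interference"),
                                        c(40, 1)))
  set.seed(31)
  mat <- matrix(NA_real_, 41, length(t))
  for (i in 1:40) mat[i, ] <- sin(2 * pi * 6 * t + runif(1, 0, 2 * pi))
  mat[41, ] <- cos(2 * pi * 3 * t)
  ep <- mat_epochs(mat, fs, t0 = 0, meta = meta)
  erp <- compute_erp(ep)
  # random-phase group: ERP shrinks toward 0; singleton group equals trial
  expect_lt(max(abs(erp$erp[1, 1, ])), 3 / sqrt(40))
  i_single <- which(erp$groups$interference == "interference")
  expect_equal(erp$erp[i_single, 1, ], mat[41, ])
  # identical trials: ERP equals any trial
  same <- mat_epochs(matrix(rep(sin(2 * pi * 2 * t), 5), 5, byrow = TRUE),
                     fs, t0 = 0,
                     meta = data.frame(subject_id = "S01",
                                       dbs_state = "OFF",
                                       interference = "control")[rep(1, 5), ])
  expect_equal(compute_erp(same)$erp[1, 1, ], sin(2 * pi * 2 * t))
})

test_that("ERP subtraction zeroes group means and spares induced power", {
  cfg <- sim_config(seed = 32, n_subjects = 2, n_control = 30,
                    n_interference = 30, sampling_rate = 1450 / 12,
                    label_names = "L", noise_sd = 0.5)
  ep <- simulate_epochs(simulate_rts(simulate_trials(cfg), cfg), cfg,
                        window = c(-0.6, 1.2))
  ind <- subtract_erp(ep)
  erp_after <- compute_erp(ind)
  expect_lt(max(abs(erp_after$erp)), 1e-10)
  # subtracting a zero ERP is the identity
  erps <- compute_erp(ep)
  erps$erp[] <- 0
  expect_equal(subtract_erp(ep, erps)$data, ep$data)
})

test_that("ERP subtraction removes evoked power, keeps induced bursts", {
  # pure-evoked fixture: big ERP, small noise, no bursts
  cfg_ev <- sim_config(seed = 33, n_subjects = 2, n_control = 40,
                       n_interference = 40, sampling_rate = 1450 / 12,
                       label_names = "L", noise_sd = 0.2,
                       erp_amplitude = 10, burst_amplitude = 0)
  ep <- simulate_epochs(simulate_rts(simulate_trials(cfg_ev), cfg_ev),
                        cfg_ev, window = c(-0.6, 1.5))
  win <- ep$times > 0.4 & ep$times < 1.0
  pow_before <- mean(ep$data[, 1, win]^2)
  ind <- subtract_erp(ep)
  pow_after <- mean(ind$data[, 1, win]^2)
  expect_lt(pow_after, 0.05 * pow_before)

  # pure-induced fixture: bursts survive subtraction nearly unchanged
  cfg_in <- sim_config(seed = 34, n_subjects = 2, n_control = 40,
                       n_interference = 40, sampling_rate = 1450 / 12,
                       label_names = "L", noise_sd = 0.2,
                       erp_amplitude = 0, burst_amplitude = 8,
                       theta_burst_gain_interference = 0,
                       theta_burst_gain_dbs = 0)
  ep2 <- simulate_epochs(simulate_rts(simulate_trials(cfg_in), cfg_in),
                         cfg_in, window = c(-0.6, 1.5))
  bwin <- ep2$times >= 0.5 & ep2$times <= 0.8
  p_before <- mean(ep2$data[, 1, bwin]^2)
  p_after <- mean(subtract_erp(ep2)$data[, 1, bwin]^2)
  expect_lt(abs(p_after - p_before) / p_before, 0.05)
})

test_that("Morlet response to a pure sinusoid matches the closed form", {
  fs <- 1450 / 6
  times <- seq(-1.5, 2, by = 1 / fs)
  x <- sin(2 * pi * 6 * times)
  ep <- epoch_array(array(x, dim = c(1, 1, length(times))), times, fs)
  tfr <- morlet_tfr(ep)
  j <- which.min(abs(tfr$freqs - 6))
  interior <- tfr$valid[j, ] & times > -1 & times < 1.5
  # power at the nearest grid frequency is the maximum across frequencies
  mean_by_freq <- vapply(seq_along(tfr$freqs), function(k) {
    mean(tfr$power[1, k, 1, tfr$valid[k, ] & interior])
  }, numeric(1))
  expect_equal(which.max(mean_by_freq), j)
  # constant over interior time
  cv <- sd(tfr$power[1, j, 1, interior]) / mean(tfr$power[1, j, 1, interior])
  expect_lt(cv, 0.01)
  # amplitude doubling quadruples power (+6.02 dB)
  ep2 <- epoch_array(array(2 * x, dim = c(1, 1, length(times))), times, fs)
  tfr2 <- morlet_tfr(ep2)
  expect_equal(mean(tfr2$power[1, j, 1, interior] /
                      tfr$power[1, j, 1, interior]), 4, tolerance = 1e-8)
  # zero signal, zero power
  ep0 <- epoch_array(array(0, dim = c(1, 1, length(times))), times, fs)
  expect_equal(max(morlet_tfr(ep0)$power), 0)
  # too-short epoch errors
  short <- epoch_array(array(0, dim = c(1, 1, 100)),
                       seq_len(100) / fs, fs)
  expect_error(morlet_tfr(short), "shorter")
})

test_that("default frequency grid is 25 log-spaced points from 2 to 50 Hz", {
  f <- morlet_freq_grid()
  expect_length(f, 25)
  expect_equal(f[1], 2)
  expect_equal(f[25], 50)
  expect_equal(diff(log10(f)), rep(diff(log10(c(2, 50))) / 24, 24),
               tolerance = 1e-12)
})

test_that("dB normalization: step response, baseline zero, scale invariance", {
  # hand-built tfr: power 1 before t=0, 10x after, one subject/state
  fs <- 100
  times <- seq(-1, 1, by = 1 / fs)
  pw <- array(1, dim = c(4, 2, 1, length(times)))
  pw[, , , times > 0] <- 10
  tfr <- structure(list(power = pw, freqs = c(5, 6), times = times,
                        sampling_rate = fs,
                        valid = matrix(TRUE, 2, length(times)),
                        trial_meta = data.frame(subject_id = "S01",
                                                dbs_state = "OFF")[rep(1, 4), ],
                        label_names = "L", n_cycles = 3),
                   class = "tfr_power")
  db <- db_normalize(tfr)
  expect_equal(db$power[, , , times > 0], array(10, dim = c(4, 2, sum(times > 0))))
  expect_equal(max(abs(db$power[, , , times <= -0.6])), 0)
  # stationary signal ~ 0 dB everywhere in the trial-mean
  expect_equal(mean_db(db$power[, 1, 1, times < 0]), 0, tolerance = 1e-10)
  # global rescaling of a trial set leaves dB unchanged
  tfr2 <- tfr; tfr2$power <- tfr$power * 7.3
  expect_equal(db_normalize(tfr2)$power, db$power, tolerance = 1e-12)
})

test_that("band averaging equals the hand-computed in-band mean", {
  fs <- 100
  times <- seq(-1, 1, by = 1 / fs)
  freqs <- morlet_freq_grid()
  set.seed(35)
  pw <- array(rexp(2 * length(freqs) * 1 * length(times)),
              dim = c(2, length(freqs), 1, length(times)))
  tfr <- structure(list(power = pw, freqs = freqs, times = times,
                        sampling_rate = fs,
                        valid = matrix(TRUE, length(freqs), length(times)),
                        trial_meta = NULL, label_names = "L", n_cycles = 3),
                   class = "tfr_power")
  bp <- band_average(tfr)
  jx <- which(freqs >= 4 & freqs <= 8)
  expect_equal(bp$power[1, 1, 1, ],
               colMeans(pw[1, jx, 1, ]), tolerance = 1e-12)
  # single frequency inside a band: identity
  bp1 <- band_average(tfr, bands = list(six = c(5.8, 5.9)))
  j6 <- which(freqs >= 5.8 & freqs <= 5.9)
  expect_length(j6, 1)
  expect_equal(bp1$power[2, 1, 1, ], pw[2, j6, 1, ])
})

test_that("time-domain pipeline crops, filters, and downsamples as specified", {
  fs <- 1450 / 3
  times <- seq(-1.5, 3.4, by = 1 / fs)
  n <- 3
  dc <- matrix(5, n, length(times))
  meta <- data.frame(subject_id = sprintf("S%02d", 1:3))
  ep <- mat_epochs(dc, fs, t0 = -1.5, meta = meta)
  ep$lock <- "stimulus"
  out <- erp_pipeline(ep)
  expect_equal(out$sampling_rate, fs / 3)
  expect_true(all(out$times >= -0.5 & out$times <= 2.0))
  n_crop <- sum(times >= -0.5 & times <= 2.0)
  expect_equal(length(out$times), floor((n_crop - 1) / 3) + 1)
  # DC passes the low-pass unchanged
  expect_equal(out$data[1, 1, ], rep(5, length(out$times)),
               tolerance = 1e-6)
  # 20 Hz is strongly attenuated by the 15 Hz 4th-order zero-phase filter
  s20 <- matrix(sin(2 * pi * 20 * times), n, length(times), byrow = TRUE)
  out20 <- erp_pipeline(mat_epochs(s20, fs, t0 = -1.5, meta = meta))
  mid <- out20$times > 0 & out20$times < 1.5
  expect_lt(max(abs(out20$data[1, 1, mid])), 0.15)
  # bootstrap band brackets the mean
  ci <- erp_bootstrap_ci(out, n_boot = 50, seed = 1)
  expect_true(all(ci$lo <= ci$mean + 1e-9 & ci$mean <= ci$hi + 1e-9))
})

test_that("wavelet power grows monotonically with signal variance", {
  fs <- 1450 / 12
  times <- seq(-1.5, 1, by = 1 / fs)
  set.seed(36)
  base <- rnorm(length(times))
  tot <- vapply(c(0.5, 1, 2, 4), function(s) {
    ep <- epoch_array(array(s * base, dim = c(1, 1, length(times))),
                      times, fs)
    tfr <- morlet_tfr(ep)
    sum(tfr$power[1, , 1, ][tfr$valid])
  }, numeric(1))
  expect_true(all(diff(tot) > 0))
})

test_that("multitaper PSD peaks at the sinusoid frequency; tapers orthonormal", {
  fs <- 250
  t <- seq_len(fs) / fs
  x <- sin(2 * pi * 10 * t) + rnorm(fs, sd = 0.1)
  psd <- multitaper_psd(x, fs)
  expect_equal(psd$freq[which.max(psd$psd)], 10, tolerance = 1.1)
  expect_lte(max(psd$freq), 30)
  tap <- dpss_tapers(200, 4, 7)
  expect_equal(crossprod(tap), diag(7), tolerance = 1e-8)
})

test_that("Mann-Whitney resting comparison matches exhaustive enumeration", {
  # 4-vs-4 fixture via traces engineered to give known epoch thetas is
  # brittle; instead check the U statistic identity on the returned values
  cfg <- sim_config(seed = 37, label_names = "Fz", sampling_rate = 1450 / 6)
  on <- simulate_resting(cfg, 5, "ON")
  off <- simulate_resting(cfg, 5, "OFF")
  rc <- resting_theta_compare(on[1, ], off[1, ],
                              attr(on, "sampling_rate"), n_epochs = 4)
  u_hand <- 0
  for (a in rc$theta_on) for (b in rc$theta_off) {
    u_hand <- u_hand + (a > b) + 0.5 * (a == b)
  }
  expect_equal(rc$U, u_hand)
  # exhaustive 4-vs-4 rank enumeration: p from all 70 assignments
  pooled <- c(rc$theta_on, rc$theta_off)
  combs <- utils::combn(8, 4)
  u_all <- apply(combs, 2, function(ix) {
    u <- 0
    for (a in pooled[ix]) for (b in pooled[-ix]) {
      u <- u + (a > b) + 0.5 * (a == b)
    }
    u
  })
  p_exact <- mean(abs(u_all - 8) >= abs(rc$U - 8))
  p_wilcox <- stats::wilcox.test(rc$theta_on, rc$theta_off,
                                 exact = TRUE)$p.value
  expect_equal(p_exact, p_wilcox, tolerance = 1e-10)
  # a genuine amplitude difference is detected at n = 60
  on2 <- simulate_resting(cfg, 61, "ON")
  off2 <- simulate_resting(cfg, 61, "OFF")
  rc2 <- resting_theta_compare(2 * on2[1, ], off2[1, ],
                               attr(on2, "sampling_rate"))
  expect_lt(rc2$p, 0.01)
})
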