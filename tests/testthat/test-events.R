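# Event detection: adaptive mid-swing peaks, AVGS initial contact, fused
# IC/TC localization, and the dual-detector mid-stance blend.

test_that("mid-swing detection finds adaptive-threshold peaks and dedups", {
  fs <- 200; t <- seq(0, 3.4, by = 1 / fs)
  set.seed(2)
  bump <- function(c) 8 * exp(-(t - c)^2 / (2 * 0.05^2))
  wx <- bump(1.0) + bump(1.75) + bump(2.5) + rnorm(length(t), sd = 0.1)
  msw <- detect_msw(wx, t)
  expect_length(msw, 3)
  expect_equal(msw, c(1.0, 1.75, 2.5), tolerance = 1.5 / fs)

  # two equal-height peaks 0.1 s apart: one survives (ties -> earlier)
  wx2 <- numeric(length(t))
  wx2[t %in% c(1.0, 1.1)] <- 5
  wx2 <- wx2 + bump(2.5)
  msw2 <- detect_msw(wx2, t)
  expect_length(msw2, 2)
  expect_equal(msw2[1], 1.0)

  expect_error(detect_msw(numeric(300), seq(0, by = 1 / fs, length.out = 300)),
               "no complete stride")
  expect_error(detect_msw(numeric(10), (0:9) / fs), "shorter")
})

test_that("AVGS IC finds the negative peak and interpolated zero crossing", {
  fs <- 200; t <- seq(0, 1, by = 1 / fs)
  # positive lobe ending at exactly t = 0.50, negative dip with min at 0.55
  wx <- ifelse(t <= 0.5, sin(pi * t / 0.5),
               ifelse(t <= 0.6, -sin(pi * (t - 0.5) / 0.1), 0))
  r <- detect_ic_avgs(wx, t, window = c(0.1, 0.9), search_frac = 1)
  expect_equal(r$ic_zerocross, 0.50, tolerance = 0.5 / fs)
  expect_equal(r$ic_negpeak, 0.55, tolerance = 1 / fs)
  expect_length(r$flags, 0)

  # strictly positive signal: no crossing, fallback flagged
  r2 <- detect_ic_avgs(abs(wx) + 0.1, t, window = c(0.1, 0.9))
  expect_true("no_zero_crossing" %in% r2$flags)
  expect_true(is.na(r2$ic_zerocross))
})

test_that("fused IC is the weighted combination of its two candidates", {
  fs <- 1000; t <- seq(0, 1, by = 1 / fs)
  # kinematic: linear descent crossing zero at exactly 0.50
  wx <- 0.5 - t
  # kinetic: |a_ap| peak at exactly 0.48
  a_ap <- -10 * exp(-(t - 0.48)^2 / (2 * 0.01^2))
  r <- detect_ic_fused(wx, a_ap, t, ic_coarse = 0.5, stride_duration = 0.8,
                       w_acc = 0.7)
  expect_equal(r$ic_kinematic, 0.50, tolerance = 1e-9)
  expect_equal(r$ic_kinetic, 0.48, tolerance = 1e-9)
  expect_equal(r$ic, 0.7 * 0.48 + 0.3 * 0.50, tolerance = 1e-9)

  # coincident candidates: any weighting returns the common time
  a_ap2 <- -10 * exp(-(t - 0.50)^2 / (2 * 0.01^2))
  for (w in c(0, 0.3, 1)) {
    r2 <- detect_ic_fused(wx, a_ap2, t, 0.5, 0.8, w_acc = w)
    expect_equal(r2$ic, 0.50, tolerance = 1e-9)
  }
  # degenerate weighting (1, 0): acceleration peak exactly
  r3 <- detect_ic_fused(wx, a_ap, t, 0.5, 0.8, w_acc = 1)
  expect_equal(r3$ic, 0.48, tolerance = 1e-9)

  # no kinematic candidate: kinetic alone, flagged
  r4 <- detect_ic_fused(abs(wx) + 1, a_ap, t, 0.5, 0.8)
  expect_equal(r4$ic, 0.48, tolerance = 1e-9)
  expect_true("ic_no_kinematic_candidate" %in% r4$flags)
})

test_that("fused TC averages the propulsive peak and the inflection", {
  fs <- 1000; t <- seq(0, 1.2, by = 1 / fs)
  ic <- 0.4; sd_ <- 0.8
  # toe-off dip with min at 0.82; propulsive accel peak at exactly 0.80
  wx <- -3 * exp(-(t - 0.82)^2 / (2 * 0.04^2))
  a_ap <- 10 * exp(-(t - 0.80)^2 / (2 * 0.02^2))
  pure_acc <- detect_tc_fused(wx, a_ap, t, ic, sd_, w_acc = 1)
  pure_gyr <- detect_tc_fused(wx, a_ap, t, ic, sd_, w_acc = 0)
  expect_equal(pure_acc$tc, 0.80, tolerance = 1e-9)
  expect_equal(pure_acc$tc_avgs, 0.82, tolerance = 1.5 / fs)
  mixed <- detect_tc_fused(wx, a_ap, t, ic, sd_, w_acc = 0.7)
  expect_equal(mixed$tc, 0.7 * pure_acc$tc + 0.3 * pure_gyr$tc,
               tolerance = 1e-9)
  expect_gt(mixed$tc, ic)
  # explicit arithmetic on known candidate times
  expect_equal(0.7 * 0.80 + 0.3 * 0.82, 0.806)
})

test_that("fused events track simulator truth within tight tolerances", {
  sim <- simulate_run(quiet_profile(n_strides = 6, seed = 14))
  ev <- detect_events(sim$recording, method = "mfdged")
  s <- ev$strides
  tr <- sim$truth$strides
  m <- min(nrow(s) - 1, nrow(tr))
  # noise-free: fused IC and TC within 2 samples (10 ms) of ground truth
  expect_lt(max(abs(s$ic[1:m] - tr$ic[1:m])), 0.010)
  expect_lt(max(abs(s$tc[1:m] - tr$tc[1:m])), 0.010)
  # contact duration recovered within 15 ms
  expect_lt(max(abs((s$tc[1:m] - s$ic[1:m]) - tr$ct[1:m])), 0.015)

  # moderate sensor noise: still within 3 samples
  pn <- gait_profile(n_strides = 6, seed = 14, sigma_acc = 0.3,
                     sigma_gyr = 0.05, gyro_bias = 0.005, stride_cv = 0)
  simn <- simulate_run(pn)
  evn <- detect_events(simn$recording, method = "mfdged")
  sn <- evn$strides
  mn <- min(nrow(sn) - 1, nrow(tr))
  expect_lt(max(abs(sn$ic[1:mn] - simn$truth$strides$ic[1:mn])), 0.015)
  expect_lt(max(abs(sn$tc[1:mn] - simn$truth$strides$tc[1:mn])), 0.015)
})

test_that("mid-stance blend matches an exhaustive brute-force oracle", {
  fs <- 200
  set.seed(8)
  for (rep in 1:5) {
    n <- 200
    t <- seq(0, by = 1 / fs, length.out = n)
    gyr <- matrix(rnorm(3 * n, sd = 0.3), n, 3)
    acc_h <- matrix(rnorm(2 * n, sd = 0.5), n, 2)
    ic <- 0.1; tc <- 0.8
    prev <- if (rep == 1) NULL else runif(1, 0, 0.5)
    got <- detect_ms(gyr, acc_h, t, ic, tc, prev_var = prev)
    want <- ms_bruteforce_oracle(gyr, acc_h, t, ic, tc, prev)
    expect_equal(got$ms, want$ms, tolerance = 1e-12)
    expect_equal(got$t_omega, want$t_omega)
    expect_equal(got$t_v, want$t_v)
    expect_equal(got$w, want$w)
    expect_gte(got$w, 0); expect_lte(got$w, 1)
  }
})

test_that("mid-stance handles initialization, ties and short stances", {
  fs <- 200; n <- 200
  t <- seq(0, by = 1 / fs, length.out = n)
  gyr0 <- matrix(0, n, 3)                      # all-zero gyro energy
  set.seed(9)
  acc_h <- matrix(rnorm(2 * n, sd = 0.5), n, 2)
  # first stride: weight initializes to 1, so ms = t_omega
  r <- detect_ms(gyr0, acc_h, t, 0.1, 0.8, prev_var = NULL)
  expect_equal(r$w, 1)
  expect_equal(r$ms, r$t_omega)
  # zero energy everywhere: earliest window center wins the tie
  ct <- 0.7
  sel0 <- t[t >= 0.1 + 0.1 * ct]
  win <- round(0.3 * ct * fs)
  expect_equal(r$t_omega, sel0[1] + (win - 1) / (2 * fs), tolerance = 1e-9)
  # unchanged variance between strides gives weight 1
  r2 <- detect_ms(gyr0, acc_h, t, 0.1, 0.8, prev_var = r$var)
  expect_equal(r2$w, 1)
  # stance too short: midpoint with a flag
  r3 <- detect_ms(gyr0, acc_h, t, 0.1, 0.13, prev_var = NULL)
  expect_true("ms_stance_too_short" %in% r3$flags)
  expect_equal(r3$ms, 0.115)
})

test_that("event ordering holds on every detected stride", {
  for (pat in c("rearfoot", "forefoot")) {
    sim <- simulate_run(gait_profile(n_strides = 5, seed = 77,
                                     strike_pattern = pat))
    ev <- detect_events(sim$recording, method = "mfdged")
    s <- ev$strides
    k <- seq_len(nrow(s))
    expect_true(all(ev$msw[k] < s$ic & s$ic < s$ms & s$ms < s$tc &
                      s$tc < ev$msw[k + 1]))
  }
})
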