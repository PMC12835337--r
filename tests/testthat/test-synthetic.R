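# Simulator contracts: determinism, trajectory self-consistency, signal
# morphology, and the strike-pattern failure mode it is designed to emulate.

test_that("identical seeds give bit-identical recordings", {
  p <- gait_profile(n_strides = 4, seed = 101)
  a <- simulate_run(p)
  b <- simulate_run(p)
  expect_identical(a$recording$acc, b$recording$acc)
  expect_identical(a$recording$gyr, b$recording$gyr)
  expect_identical(a$truth$strides, b$truth$strides)
  c_ <- simulate_run(gait_profile(n_strides = 4, seed = 102))
  expect_false(identical(a$recording$acc, c_$recording$acc))
})

test_that("noise-free trajectory is self-consistent with its ground truth", {
  sim <- simulate_run(quiet_profile(n_strides = 6, seed = 31))
  tr <- sim$truth
  # double integration of the true acceleration between true mid-stance
  # anchors reproduces the stride length almost exactly
  for (j in seq_len(nrow(tr$strides) - 1)) {
    iv <- integrate_velocity(tr$acc_n_true, tr$t,
                             c(tr$strides$ms[j], tr$strides$ms[j + 1]))
    d <- stride_displacement(iv$v, iv$t)
    expect_equal(d$sl, tr$strides$sl[j], tolerance = 1e-4)
  }
  # truth satisfies the event ordering invariants
  s <- tr$strides
  expect_true(all(s$ic < s$ms & s$ms < s$tc & s$tc < s$ic_next))
  expect_true(all(diff(tr$msw) > 0))
})

test_that("mid-swing peaks are conserved and stance is quasi-stationary", {
  p <- quiet_profile(n_strides = 6, seed = 41)
  sim <- simulate_run(p)
  rec <- sim$recording
  wx_f <- butterworth_lowpass(rec$gyr[, 1], rec$fs)
  msw <- detect_msw(wx_f, rec$t)
  expect_length(msw, p$n_strides + 2)   # one per simulated gait cycle
  expect_equal(msw, sim$truth$msw, tolerance = 0.005)

  gn <- sqrt(rowSums(rec$gyr^2))
  s <- sim$truth$strides
  for (j in seq_len(nrow(s))) {
    stance <- rec$t >= s$ic[j] & rec$t <= s$tc[j]
    # middle third of stance is perfectly still without noise
    core <- rec$t >= s$ic[j] + s$ct[j] / 3 & rec$t <= s$tc[j] - s$ct[j] / 3
    expect_true(all(gn[core] < 0.0436))
    expect_gt(mean(gn[stance] < 0.0436), 0.55)
  }
})

test_that("ground-truth 25 N crossings bracket the stance and tighten with mass", {
  sim <- simulate_run(quiet_profile(n_strides = 4, seed = 51, mass_kg = 75))
  s <- sim$truth$strides
  expect_true(all(s$vgrf_on > s$ic & s$vgrf_on < s$tc))
  expect_true(all(s$vgrf_off > s$vgrf_on & s$vgrf_off < s$tc + 1e-12))
  heavy <- simulate_run(quiet_profile(n_strides = 4, seed = 51,
                                      mass_kg = 75000))$truth$strides
  expect_true(all(heavy$vgrf_on - heavy$ic < s$vgrf_on - s$ic))
  expect_lt(max(heavy$vgrf_on - heavy$ic), 1e-3)
})

test_that("strike pattern changes morphology but not the ground truth", {
  p <- gait_profile(n_strides = 4, seed = 61)
  rf <- simulate_strike_pattern_shift(p, "rearfoot")
  ff <- simulate_strike_pattern_shift(p, "forefoot")
  expect_equal(rf$truth$strides$ic, ff$truth$strides$ic)
  expect_equal(rf$truth$strides$tc, ff$truth$strides$tc)
  expect_equal(rf$truth$strides$sl, ff$truth$strides$sl)
  expect_false(identical(rf$recording$gyr[, 1], ff$recording$gyr[, 1]))
})

test_that("forefoot signals advance the AVGS trigger; fusion stays closer", {
  sim <- simulate_run(quiet_profile(n_strides = 8, seed = 71,
                                    strike_pattern = "forefoot"))
  tr <- sim$truth$strides
  ev_a <- detect_events(sim$recording, method = "avgs")$strides
  ev_f <- detect_events(sim$recording, method = "mfdged")$strides
  m <- min(nrow(ev_a) - 1, nrow(tr))
  err_a <- ev_a$ic[1:m] - tr$ic[1:m]
  err_f <- ev_f$ic[1:m] - tr$ic[1:m]
  expect_true(all(err_a < 0))              # AVGS triggers early
  expect_gte(mean(abs(err_f) <= abs(err_a)), 0.9)

  # rearfoot: both methods land close to the true contact
  simr <- simulate_run(quiet_profile(n_strides = 8, seed = 71))
  tra <- simr$truth$strides
  ra <- detect_events(simr$recording, method = "avgs")$strides
  rf_ <- detect_events(simr$recording, method = "mfdged")$strides
  mr <- min(nrow(ra) - 1, nrow(tra))
  expect_lt(max(abs(ra$ic[1:mr] - tra$ic[1:mr])), 0.015)
  expect_lt(max(abs(rf_$ic[1:mr] - tra$ic[1:mr])), 0.010)
})

test_that("profile validation rejects impossible gaits", {
  expect_error(gait_profile(contact_time = 0.8, stride_time = 0.74))
  expect_error(gait_profile(n_strides = 0))
  expect_error(gait_profile(stride_length = -1))
})
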