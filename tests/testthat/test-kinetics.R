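test_that("symmetric rates stay at equilibrium and absorbing export empties the cytoplasm", {
  kin <- translocation_kinetics(k_in_base = 0.1, k_in_stim = 0.1,
                                k_out = 0.1, t_stim = 1e9)
  tr <- simulate_kinetics(kin, seq(0, 200, by = 20))
  expect_equal(tr$ci_true, rep(1, nrow(tr)), tolerance = 1e-12)

  kin0 <- translocation_kinetics(k_in_base = 0.2, k_in_stim = 0.2,
                                 k_out = 0, t_stim = 1e9)
  tr0 <- simulate_kinetics(kin0, c(0, 50, 500))
  expect_lt(tr0$C[3], 1e-12)
  expect_equal(tr0$N[3] * kin0$vol_ratio, kin0$c_total, tolerance = 1e-9)
})

test_that("stimulus step matches a fine-step Euler oracle and reaches k_in/k_out", {
  # sampling points deliberately avoid t == t_stim (the instant of the
  # step is convention-dependent between integrators)
  times <- c(0, 10, 25, 60, 120, 300)
  kin <- translocation_kinetics(k_in_base = 0.05, k_in_stim = 0.20,
                                k_out = 0.1, t_stim = 30, vol_ratio = 1)
  tr <- simulate_kinetics(kin, times)
  orc <- euler_kinetics(0.05, 0.20, 0.1, 30, 1, 1, times, dt = 1e-3)
  expect_equal(tr$N, orc[, 1], tolerance = 1e-3)
  expect_equal(tr$C, orc[, 2], tolerance = 1e-3)
  # long-time N/C within 1% of k_in_stim / k_out = 2
  expect_equal(tr$ci_true[length(times)], 2, tolerance = 0.01)
})

test_that("mass is conserved to 1e-9 relative across random parameter draws", {
  set.seed(11)
  for (i in 1:20) {
    kin <- translocation_kinetics(
      k_in_base = runif(1, 0, 0.3), k_in_stim = runif(1, 0, 0.3),
      k_out = runif(1, 0.01, 0.3), t_stim = runif(1, 10, 100),
      vol_ratio = runif(1, 0.2, 2), c_total = runif(1, 0.5, 3))
    tr <- simulate_kinetics(kin, sort(runif(8, 0, 400)))
    mass <- kin$vol_ratio * tr$N + tr$C
    expect_lt(max(abs(mass - kin$c_total)) / kin$c_total, 1e-9)
  }
})

test_that("invalid inputs are rejected", {
  kin <- translocation_kinetics()
  expect_error(simulate_kinetics(kin, c(0, 10, 10)), "strictly increasing")
  expect_error(simulate_kinetics(kin, c(-5, 10)), ">= 0")
  expect_error(translocation_kinetics(k_out = -1), "k_out")
  expect_error(translocation_kinetics(vol_ratio = 0), "vol_ratio")
})

test_that("optional post-stimulus relaxation produces rise then partial decline", {
  kin <- translocation_kinetics(k_in_base = 0.004, k_in_stim = 0.08,
                                k_out = 0.02, t_stim = 600,
                                k_in_late = 0.03, tau_relax = 300)
  tr <- simulate_kinetics(kin, seq(0, 2400, by = 120))
  post <- tr$ci_true[tr$t_s >= 600]
  peak <- max(post)
  expect_gt(peak, tr$ci_true[1] * 2)       # clear rise
  expect_lt(post[length(post)], peak)      # partial decline
  expect_gt(post[length(post)], tr$ci_true[1])  # stays above baseline
})
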