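test_that("noiseless rendering hits exact compartment means and the CI formula", {
  rnd <- make_single_cell(N = 2, C = 1)
  fr <- get_frame(rnd$stack, 1, "reporter")
  nuc <- rnd$truth$nuclei == 1
  cyto <- rnd$truth$cells == 1 & !nuc
  expect_equal(mean(fr[nuc]), 210)
  expect_equal(mean(fr[cyto]), 110)
  comp <- build_compartments(rnd$truth$cells, rnd$truth$nuclei)
  m <- measure_frame(fr, comp, 10)
  expect_equal(m$ci, 2)
})

test_that("rendering is linear in gain and deterministic under a fixed seed", {
  r1 <- make_single_cell(gain = 100)
  r2 <- make_single_cell(gain = 200)
  f1 <- get_frame(r1$stack, 1, "reporter")
  f2 <- get_frame(r2$stack, 1, "reporter")
  nuc <- r1$truth$nuclei == 1
  expect_equal(mean(f2[nuc]) - 10, 2 * (mean(f1[nuc]) - 10))

  a <- make_single_cell(noise = c(0.5, 2), seed = 99L)
  b <- make_single_cell(noise = c(0.5, 2), seed = 99L)
  expect_identical(a$stack$intensities, b$stack$intensities)
  c_ <- make_single_cell(noise = c(0.5, 2), seed = 100L)
  expect_false(identical(a$stack$intensities, c_$stack$intensities))
})

test_that("scene geometry is validated", {
  expect_error(synthetic_scene(
    data.frame(cy = c(30, 40), cx = c(30, 40), r_cell = 20, r_nuc = 8),
    shape = c(80L, 80L)), "overlap")
  expect_error(synthetic_scene(
    data.frame(cy = 30, cx = 30, r_cell = 10, r_nuc = 12)), "radius")
  rnd <- make_single_cell()
  expect_error(render_timelapse(
    synthetic_scene(data.frame(cy = 32, cx = 32, r_cell = 20, r_nuc = 8)),
    list(data.frame(t_s = 0, N = 1, C = 1),
         data.frame(t_s = 0, N = 1, C = 1))), "per cell")
})

test_that("FRAP simulator honours its closed form, phases and determinism", {
  spec <- frap_sim_spec(mobile_fraction = 0.7, k_true = 3, noise_sd = 0,
                        line_rate_hz = 400)
  sim <- simulate_frap_record(spec, seed = 1)
  tr <- extract_traces(sim$record)
  post <- tr[tr$phase == "post", ]
  t <- post$t_acq_s - post$t_acq_s[1]
  y <- post$i_frap / mean(tr$i_frap[tr$phase == "pre"])
  y_exact <- (1 - spec$bleach_depth) +
    spec$bleach_depth * spec$mobile_fraction * (1 - exp(-spec$k_true * t))
  expect_lt(max(abs(y - y_exact)), 1e-9)

  # mobile_fraction = 1: full recovery asymptote at 1
  sim1 <- simulate_frap_record(frap_sim_spec(mobile_fraction = 1,
                                             noise_sd = 0, k_true = 8),
                               seed = 1)
  fit1 <- fit_one_phase(double_normalize(extract_traces(sim1$record)))
  expect_equal(fit1$plateau, 1, tolerance = 1e-6)

  # bleach_depth = 0: flat trace, amplitude ~ 0
  sim0 <- simulate_frap_record(frap_sim_spec(bleach_depth = 0,
                                             noise_sd = 0), seed = 1)
  fit0 <- fit_one_phase(double_normalize(extract_traces(sim0$record)))
  expect_lt(fit0$a, 1e-8)

  # determinism
  sa <- simulate_frap_record(frap_sim_spec(), seed = 5)
  sb <- simulate_frap_record(frap_sim_spec(), seed = 5)
  expect_identical(sa$record$kymogram, sb$record$kymogram)
})

test_that("FRAP spec invariants are enforced", {
  expect_error(frap_sim_spec(mobile_fraction = 1.2), "mobile_fraction")
  expect_error(frap_sim_spec(k_true = 0), "k_true")
  expect_error(frap_sim_spec(line_len_px = 16L, bleach_halfwidth_px = 8L),
               "wider than the line")
  expect_error(frap_sim_spec(pre_s = 0), "pre_s")
})
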