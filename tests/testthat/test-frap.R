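test_that("trace extraction background-corrects per line and flags bleach lines", {
  rec <- make_const_record(roi_val = 100, ref_val = 200, bg_val = 20)
  tr <- extract_traces(rec)
  expect_equal(unique(tr$i_frap), 80)
  expect_equal(unique(tr$i_ref), 180)
  expect_equal(sum(tr$phase == "bleach"), 5L)
  expect_true(all(tr$flagged[tr$phase == "bleach"]))
  expect_false(any(tr$flagged[tr$phase != "bleach"]))
})

test_that("record invariants are enforced", {
  kym <- matrix(1, 32, 30)
  ph <- list(pre = c(1L, 10L), bleach = c(11L, 12L), post = c(13L, 30L))
  expect_error(frap_record(kym, 0.01, ph,
                           list(bleach = c(10, 20), background = 15)),
               "disjoint")
  expect_error(frap_record(kym, 0.01, ph,
                           list(bleach = c(10, 40), background = 1:2)),
               "wider")
  expect_error(frap_record(kym, 0.01,
                           list(pre = c(1L, 10L), bleach = c(12L, 13L),
                                post = c(14L, 30L)),
                           list(bleach = c(10, 20), background = 1:2)),
               "contiguous")
  expect_error(frap_record(kym, 0.01, ph,
                           list(bleach = c(10, 20), background = NULL)),
               "background")
})

test_that("double normalization: pre-level 1, reduction with constant reference, scale invariance", {
  sim <- simulate_frap_record(frap_sim_spec(noise_sd = 0), seed = 1)
  tr <- extract_traces(sim$record)
  rec <- double_normalize(tr)
  expect_equal(mean(attr(rec, "pre_y")), 1, tolerance = 1e-12)

  # constant reference: y reduces to I_FRAP / I_FRAP_Pre
  pre_mean <- mean(tr$i_frap[tr$phase == "pre"])
  post <- tr$phase == "post"
  expect_equal(rec$y, tr$i_frap[post] / pre_mean, tolerance = 1e-12)

  # global rescale of the whole kymogram leaves y identical
  rec2 <- sim$record
  rec2$kymogram <- rec2$kymogram * 3.7
  # note: background region scales too, so correction stays consistent
  y2 <- double_normalize(extract_traces(rec2))
  expect_equal(y2$y, rec$y, tolerance = 1e-12)
})

test_that("double normalization cancels an imposed global exponential bleach to 1e-9", {
  s0 <- frap_sim_spec(noise_sd = 0, acq_bleach_rate = 0,
                      mobile_fraction = 0.75, k_true = 4)
  sb <- frap_sim_spec(noise_sd = 0, acq_bleach_rate = 0.4,
                      mobile_fraction = 0.75, k_true = 4)
  y0 <- double_normalize(extract_traces(simulate_frap_record(s0, 1)$record))
  yb <- double_normalize(extract_traces(simulate_frap_record(sb, 1)$record))
  expect_lt(max(abs(y0$y - yb$y)), 1e-9)
})

test_that("one-phase fit recovers exact parameters on a noiseless curve", {
  t <- seq(0, 3, by = 0.001)
  y <- 0.2 + 0.6 * (1 - exp(-5 * t))
  fit <- fit_one_phase(data.frame(t = t, y = y))
  expect_true(fit$converged)
  expect_equal(fit$i0, 0.2, tolerance = 1e-6)
  expect_equal(fit$a, 0.6, tolerance = 1e-6)
  expect_equal(fit$k, 5, tolerance = 1e-6)
  expect_equal(fit$t_half_s, log(2) / 5, tolerance = 1e-6)
  # exact identities of every emitted fit
  expect_equal(fit$t_half_s * fit$k, log(2))
  expect_equal(fit$immobile_fraction_pct, 100 * (1 - fit$i0 - fit$a))
  expect_error(fit_one_phase(data.frame(t = 0:5 / 5, y = rep(1, 6))),
               ">= 10")
  expect_error(fit_one_phase(data.frame(t = 1:20 / 10, y = rnorm(20))),
               "start at 0")
})

test_that("immobile fraction reads the plateau and flags over-recovery", {
  fit <- fit_one_phase(data.frame(t = seq(0, 3, 0.01),
                                  y = 0.2 + 0.6 * (1 - exp(-5 * seq(0, 3,
                                                                    0.01)))))
  imf <- immobile_fraction(fit)
  expect_equal(imf$pct, 20, tolerance = 1e-5)
  expect_false(imf$over_recovery)
  full <- fit_one_phase(data.frame(t = seq(0, 3, 0.01),
                                   y = 0.4 + 0.6 * (1 - exp(-5 * seq(0, 3,
                                                                     0.01)))))
  expect_equal(immobile_fraction(full)$pct, 0, tolerance = 1e-5)
})

test_that("mobility comparison: identical groups ns, distinct mobile fractions ****", {
  fits_a <- lapply(1:6, function(i) {
    sim <- simulate_frap_record(frap_sim_spec(mobile_fraction = 1,
                                              k_true = 6), seed = i)
    fit_one_phase(double_normalize(extract_traces(sim$record)))
  })
  fits_b <- lapply(1:6, function(i) {
    sim <- simulate_frap_record(frap_sim_spec(mobile_fraction = 0.82,
                                              k_true = 6), seed = 100 + i)
    fit_one_phase(double_normalize(extract_traces(sim$record)))
  })
  same <- compare_mobility(fits_a, fits_a)
  expect_true(all(same$stars == "ns"))
  diff <- compare_mobility(fits_a, fits_b)
  if_row <- diff[diff$metric == "immobile_fraction_pct", ]
  expect_lte(if_row$p, 1e-4)
  # swapping the groups flips t, keeps p
  swapped <- compare_mobility(fits_b, fits_a)
  expect_equal(swapped$p, diff$p)
  expect_equal(swapped$t, -diff$t)
  expect_error(compare_mobility(fits_a[1], fits_b), ">= 2")
})
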