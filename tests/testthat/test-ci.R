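test_that("compute_ci evaluates the formula and flags bad denominators", {
  expect_equal(as.numeric(compute_ci(210, 110, 10)), 2)
  expect_equal(as.numeric(compute_ci(150, 150, 20)), 1)   # homogeneous
  expect_equal(as.numeric(compute_ci(10, 110, 10)), 0)    # f_nuc == bg
  # denominator at epsilon: invalid, kept as NA, not dropped
  ci <- compute_ci(c(210, 50), c(110, 10), 10)
  expect_equal(attr(ci, "valid"), c(TRUE, FALSE))
  expect_true(is.na(ci[2]))
  expect_length(ci, 2L)
})

test_that("whole-cell-minus-nucleus equals the cytoplasm-mask mean exactly", {
  set.seed(13)
  for (i in 1:10) {
    rnd <- make_single_cell(noise = c(0.5, 2), seed = i)
    fr <- get_frame(rnd$stack, 1, "reporter")
    comp <- build_compartments(rnd$truth$cells, rnd$truth$nuclei)
    m <- measure_frame(fr, comp, 10)
    direct <- mean(fr[comp$cells[[1]]$cytoplasm])
    expect_lt(abs(m$f_cyto - direct), 1e-12)
  }
})

test_that("CI is invariant under affine intensity transforms to 1e-12", {
  rnd <- make_single_cell(noise = c(0.5, 2), seed = 3)
  fr <- get_frame(rnd$stack, 1, "reporter")
  comp <- build_compartments(rnd$truth$cells, rnd$truth$nuclei)
  bg <- estimate_background(fr, rnd$truth$cells)
  ci0 <- measure_frame(fr, comp, bg)$ci
  for (tf in list(c(3.7, 0), c(1, 25), c(0.4, 7))) {
    g <- tf[1]; o <- tf[2]
    ci1 <- measure_frame(fr * g + o, comp, bg * g + o)$ci
    expect_lt(abs(ci1 - ci0) / abs(ci0), 1e-12)
  }
})

test_that("min-max normalization maps extremes, preserves rank, is idempotent", {
  v <- normalize_minmax(c(0.2, 0.5, 0.8))
  expect_equal(as.numeric(v), c(0, 0.5, 1))
  expect_equal(attr(v, "ci_min"), 0.2)
  expect_equal(attr(v, "ci_max"), 0.8)
  set.seed(4)
  x <- rnorm(50)
  n1 <- as.numeric(normalize_minmax(x))
  expect_equal(order(n1), order(x))
  expect_equal(as.numeric(normalize_minmax(n1)), n1)       # idempotent
  expect_equal(as.numeric(normalize_minmax(3 * x - 2)), n1) # affine invariant
  expect_error(normalize_minmax(rep(1, 5)), "distinct")
})

test_that("summarize_conditions reproduces printed fold-change, delta and ratio", {
  tab <- published_ci_table("15min")
  s <- summarize_conditions(tab, "Baseline", reference_group = "IF:ERK1/2")
  loc <- s[s$group == "rERK2-LOC", ]
  serum <- loc[tolower(loc$label) == "serum", ]
  expect_equal(round(serum$fold_change, 2), 7.50)
  expect_equal(round(serum$delta, 3), 0.416)
  expect_equal(round(serum$cross_ratio, 2), 5.70)
  base <- loc[loc$label == "Baseline", ]
  expect_equal(base$fold_change, 1)
  expect_equal(base$delta, 0)
  # every printed fold-change in the reporter group reproduces within the
  # uncertainty propagated from the 3-dp rounding of the printed means
  printed <- c(serum = 7.50, fgf4 = 7.94, u0126 = 1.30,
               `u0126+serum` = 1.28, `u0126+fgf4` = 1.75,
               `dmso+serum` = 5.52, `dmso+fgf4` = 5.60)
  rows <- loc[match(names(printed), tolower(loc$label)), ]
  bound <- rows$fold_change * (5e-4 / rows$mean_ci + 5e-4 / 0.064) + 0.005
  expect_true(all(abs(rows$fold_change - printed) <= bound))
})

test_that("summarize_conditions validates inputs and flags undefined folds", {
  df <- data.frame(group = "g", label = c("a", "b"), mean_ci = c(0, 0.5))
  expect_error(summarize_conditions(df, "zz"), "baseline")
  s <- summarize_conditions(df, "a")
  expect_true(all(s$fold_undefined))
  # per-cell route agrees with precomputed-mean route
  set.seed(6)
  cells <- data.frame(group = "g",
                      label = rep(c("base", "stim"), each = 20),
                      ci = c(rnorm(20, 0.1, 0.02), rnorm(20, 0.5, 0.02)))
  s2 <- summarize_conditions(cells, "base")
  man <- tapply(cells$ci, cells$label, mean)
  expect_equal(s2$mean_ci[s2$label == "stim"], unname(man["stim"]))
  expect_equal(s2$fold_change[s2$label == "stim"],
               unname(man["stim"] / man["base"]))
  expect_equal(s2$sem[s2$label == "base"],
               sd(cells$ci[cells$label == "base"]) / sqrt(20))
})

test_that("response metrics split the rise into decline and above-baseline parts", {
  m <- response_metrics(0.582, peak = 0.880, plateau = 0.719)
  expect_equal(round(m$pct_decline_from_peak), 54)
  expect_equal(round(m$pct_above_baseline), 46)
  expect_equal(m$pct_decline_from_peak + m$pct_above_baseline, 100)
  expect_equal(response_metrics(0.5, peak = 0.9,
                                plateau = 0.9)$pct_decline_from_peak, 0)
  expect_equal(response_metrics(0.5, peak = 0.9,
                                plateau = 0.5)$pct_decline_from_peak, 100)
  expect_false(response_metrics(0.9, peak = 0.6, plateau = 0.5)$defined)
})

test_that("response metrics work on a time series with windows", {
  t <- seq(0, 2400, by = 120)
  ci <- ifelse(t < 600, 0.58,
               0.58 + 0.3 * exp(-(t - 600) / 500) *
                 (1 - exp(-(t - 600) / 120)) / 0.6)
  ser <- data.frame(t_s = t, ci = ci)
  m <- response_metrics(ser, t_stim = 600)
  expect_equal(m$baseline_ci, 0.58)
  expect_gt(m$peak_ci, m$plateau_ci)
  expect_gt(m$plateau_ci, m$baseline_ci)
  expect_gt(m$time_to_peak_s, 0)
  expect_equal(m$pct_decline_from_peak + m$pct_above_baseline, 100)
  expect_error(response_metrics(ser), "t_stim")
})

test_that("tracking a static synthetic cell yields a flat, complete series", {
  cells <- data.frame(cy = 32, cx = 32, r_cell = 18, r_nuc = 8)
  scene <- synthetic_scene(cells, shape = c(64L, 64L), noise = c(0, 0),
                           frame_interval_s = 60)
  trj <- data.frame(t_s = c(0, 60, 120), N = 1.5, C = 1)
  rnd <- render_timelapse(scene, trj, seed = 1)
  tl <- track_timelapse(rnd$stack)
  expect_equal(length(unique(tl$track_id)), 1L)
  expect_equal(nrow(tl), 3L)
  expect_false(any(tl$missing))
  expect_equal(tl$ci, rep(1.5, 3), tolerance = 1e-9)
  expect_equal(tl$t_s, c(0, 60, 120))
})
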