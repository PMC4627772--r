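test_that("nucleus segmentation finds constructed disks and tolerates blanks", {
  img <- matrix(5, 80, 80)
  d1 <- nucytoloc:::disk_mask(c(80L, 80L), 20, 20, 8)
  d2 <- nucytoloc:::disk_mask(c(80L, 80L), 60, 55, 10)
  img[d1] <- 100; img[d2] <- 120
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 2L)
  expect_warning(blank <- segment_nuclei(matrix(7, 40, 40)), "constant")
  expect_equal(max(blank), 0L)
})

test_that("segmentation masks are invariant under positive intensity scaling", {
  rnd <- make_single_cell(noise = c(0.5, 2), seed = 17)
  nucf <- get_frame(rnd$stack, 1, "nuclear_marker")
  expect_identical(segment_nuclei(nucf), segment_nuclei(nucf * 3.5))
})

test_that("noiseless synthetic nuclei segment with IoU >= 0.9 and cells contain their nuclei", {
  cells <- layout_cells(3, shape = c(100L, 150L), r_cell = 20, r_nuc = 9,
                        seed = 2)
  scene <- synthetic_scene(cells, shape = c(100L, 150L), noise = c(0, 0))
  trj <- data.frame(t_s = 0, N = 2, C = 1)
  rnd <- render_timelapse(scene, trj, seed = 1)
  nuclei <- segment_nuclei(get_frame(rnd$stack, 1, "nuclear_marker"))
  cellsm <- segment_cells(get_frame(rnd$stack, 1, "reporter"), nuclei)
  for (k in 1:3) {
    expect_gte(matched_iou(nuclei, rnd$truth$nuclei, k), 0.9)
    expect_gte(matched_iou(cellsm, rnd$truth$cells, k), 0.9)
  }
  # every cell contains its seed nucleus
  for (k in seq_len(max(nuclei))) {
    expect_true(all(cellsm[nuclei == k] == k))
  }
  expect_equal(max(segment_cells(get_frame(rnd$stack, 1, "reporter"),
                                 matrix(0L, 100, 150))), 0L)
})

test_that("touching cells are split along the equidistant boundary", {
  # two bright cells sharing a flat interface; nuclei offset to each side
  img <- matrix(2, 90, 120)
  left <- nucytoloc:::disk_mask(c(90L, 120L), 45, 40, 24)
  right <- nucytoloc:::disk_mask(c(90L, 120L), 45, 80, 24)
  img[left | right] <- 100
  nuc <- matrix(0L, 90, 120)
  nuc[nucytoloc:::disk_mask(c(90L, 120L), 45, 38, 8)] <- 1L
  nuc[nucytoloc:::disk_mask(c(90L, 120L), 45, 82, 8)] <- 2L
  lab <- segment_cells(img, nuc)
  expect_equal(sort(unique(lab[lab > 0])), c(1L, 2L))
  # Euclidean nearest-centroid oracle on the foreground (valid here since
  # the union of the two disks is convex along the seed axis)
  fg <- which(left | right, arr.ind = TRUE)
  d1 <- (fg[, 1] - 45)^2 + (fg[, 2] - 38)^2
  d2 <- (fg[, 1] - 45)^2 + (fg[, 2] - 82)^2
  oracle <- ifelse(d1 < d2, 1L, ifelse(d2 < d1, 2L, NA))
  got <- lab[cbind(fg[, 1], fg[, 2])]
  ok <- !is.na(oracle)
  expect_gt(mean(got[ok] == oracle[ok]), 0.97)
})

test_that("compartments are exact set differences with degenerate cells excluded", {
  cells <- matrix(0L, 9, 9); cells[3:7, 3:7] <- 1L
  nuc <- matrix(0L, 9, 9); nuc[4:6, 4:6] <- 1L
  comp <- build_compartments(cells, nuc)
  expect_length(comp$cells, 1L)
  expect_length(comp$cells[[1]]$cytoplasm, 16L)   # 25 - 9
  expect_setequal(comp$cells[[1]]$cytoplasm,
                  setdiff(which(cells == 1L), which(nuc == 1L)))

  comp2 <- build_compartments(cells, cells)       # nucleus == cell
  expect_length(comp2$cells, 0L)
  expect_equal(comp2$excluded$reason, "empty cytoplasm")

  two_cells <- matrix(0L, 9, 9)
  two_cells[1:9, 1:4] <- 1L; two_cells[1:9, 6:9] <- 2L
  wide_nuc <- matrix(0L, 9, 9); wide_nuc[4:6, 3:7] <- 1L
  expect_error(build_compartments(two_cells, wide_nuc), "spans")
})

test_that("background estimation: outside-cells mean, user ROI, and failure mode", {
  rnd <- make_single_cell()                        # uniform background 10
  fr <- get_frame(rnd$stack, 1, "reporter")
  expect_equal(estimate_background(fr, rnd$truth$cells), 10)
  roi <- matrix(FALSE, nrow(fr), ncol(fr)); roi[1:2, 1:2] <- TRUE
  fr2 <- fr; fr2[1:2, 1:2] <- 12.5
  expect_equal(estimate_background(fr2, method = "roi", roi = roi), 12.5)
  all_cells <- matrix(1L, 8, 8)
  expect_error(estimate_background(matrix(1, 8, 8), all_cells),
               "no background pixels")
})

test_that("noisy background estimate is unbiased within 2% over 100 seeds", {
  errs <- vapply(1:100, function(i) {
    rnd <- make_single_cell(noise = c(0.5, 2), shape = c(48L, 48L),
                            r_cell = 14, r_nuc = 8, seed = i)
    fr <- get_frame(rnd$stack, 1, "reporter")
    estimate_background(fr, rnd$truth$cells) / 10 - 1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)
  expect_lt(max(abs(errs)), 0.1)
})
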