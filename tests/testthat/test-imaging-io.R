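test_that("stack write/read round trip is bit-exact including metadata", {
  set.seed(21)
  a <- array(runif(2 * 2 * 8 * 8) * 4095, dim = c(2, 2, 8, 8))
  st <- image_stack(a, list(reporter = 1, nuclear_marker = 2),
                    pixel_size_um = 0.5, frame_times_s = c(0, 120))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  st2 <- read_stack(path)
  expect_identical(st2$intensities, st$intensities)
  expect_equal(st2$pixel_size_um, 0.5)
  expect_equal(st2$frame_times_s, c(0, 120))
  expect_equal(st2$channel_roles$reporter, 1L)
})

test_that("a TIFF without channel metadata demands channel_roles", {
  path <- withr::local_tempfile(fileext = ".tif")
  nucytoloc:::write_tiff_pages(path, list(matrix(1:12, 3, 4) * 1.0))
  expect_error(read_stack(path), "channel_roles")
  st <- read_stack(path, channel_roles = list(reporter = 1))
  expect_equal(dim(st$intensities), c(1L, 1L, 3L, 4L))
})

test_that("the TIFF codec interoperates with Python tifffile", {
  # python + tifffile are part of the target environment; this is the
  # independent oracle for the hand-rolled codec, so it must actually run
  set.seed(31)
  a <- array(runif(1 * 2 * 6 * 5) * 100, dim = c(1, 2, 6, 5))
  st <- image_stack(a, list(reporter = 1, nuclear_marker = 2), 0.5, 0)
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(path))
  write_stack(st, path)
  csv_out <- tempfile(fileext = ".csv")
  py <- tempfile(fileext = ".py")
  on.exit(unlink(c(csv_out, py)), add = TRUE)
  writeLines(c("import tifffile, numpy as np",
               sprintf("a = tifffile.imread(r'%s')", path),
               "a = a.reshape(a.shape[0], -1)",
               sprintf("np.savetxt(r'%s', a, delimiter=',')", csv_out)),
             py)
  status <- system2("python", py, stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  back <- as.matrix(utils::read.csv(csv_out, header = FALSE))
  # tifffile stacks pages [page, y, x]; page 1 = frame 1 reporter
  expect_equal(as.numeric(t(back))[1:30],
               as.numeric(t(get_frame(st, 1, "reporter"))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("max_project equals the brute-force per-pixel maximum", {
  expect_equal(max_project(list(matrix(c(1, 3, 2, 0), 2, 2))),
               matrix(c(1, 3, 2, 0), 2, 2))  # single plane: identity
  planes <- list(matrix(c(1, 3), 1, 2), matrix(c(3, 0), 1, 2))
  expect_equal(max_project(planes), matrix(c(3, 3), 1, 2))
  set.seed(5)
  arr <- array(rnorm(10 * 7 * 9), dim = c(10, 7, 9))
  brute <- matrix(-Inf, 7, 9)
  for (z in 1:10) for (y in 1:7) for (x in 1:9) {
    brute[y, x] <- max(brute[y, x], arr[z, y, x])
  }
  expect_equal(max_project(arr), brute)
  expect_error(max_project(list()), "max_project needs")
})

test_that("colocalization scatter behaves at the correlation extremes", {
  set.seed(8)
  a <- matrix(runif(100 * 100), 100)
  res <- colocalization_scatter(a, a)
  expect_equal(res$pearson_r, 1)
  res2 <- colocalization_scatter(a, -a + 3)
  expect_equal(res2$pearson_r, -1)
  b <- matrix(runif(100 * 100), 100)
  res3 <- colocalization_scatter(a, b)
  expect_lt(abs(res3$pearson_r), 0.05)
  expect_equal(sum(res3$histogram), 100 * 100)
  const <- colocalization_scatter(a, matrix(1, 100, 100))
  expect_true(const$constant)
  expect_true(is.na(const$pearson_r))
})
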