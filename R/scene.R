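#' Synthetic imaging scene description
#'
#' Geometry and camera model for the synthetic time-lapse generator: a set
#' of circular cells with concentric circular nuclei, a linear gain from
#' concentration units to intensity, additive background, optional optical
#' blur and a Poisson-plus-Gaussian noise model.
#'
#' @param cells data.frame with columns `cy`, `cx` (centre, pixels), `r_cell`
#'   and `r_nuc` (radii, pixels). Nuclei must be strictly inside their cell
#'   and cells must not overlap (touching is not allowed either).
#' @param shape image shape `c(ny, nx)` in pixels.
#' @param gain intensity per concentration unit, > 0.
#' @param background additive background level, >= 0.
#' @param noise length-2 numeric `c(poisson_scale, gaussian_sd)`. With
#'   `poisson_scale = p > 0` each pixel value v is replaced by
#'   `p * rpois(v / p)` (shot noise with variance p*v); Gaussian read noise
#'   of the given SD is then added. `c(0, 0)` disables noise.
#' @param blur_sigma optical blur (Gaussian SD, pixels); 0 disables.
#' @param marker_level nuclear-marker concentration inside nuclei
#'   (intensity = gain * marker_level + background).
#' @param pixel_size_um,frame_interval_s physical calibration.
#' @return Object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(cells, shape = c(128L, 128L), gain = 100,
                            background = 10, noise = c(0.5, 2),
                            blur_sigma = 0, marker_level = 2,
                            pixel_size_um = 0.5, frame_interval_s = 120) {
  stopifnot(is.data.frame(cells),
            all(c("cy", "cx", "r_cell", "r_nuc") %in% names(cells)))
  if (any(cells$r_nuc >= cells$r_cell)) {
    abort("nucleus radius must be smaller than cell radius")
  }
  if (any(cells$r_nuc <= 0)) abort("nucleus radius must be positive")
  check_scalar(gain, "gain", min = 0, strict_min = TRUE)
  check_scalar(background, "background", min = 0)
  check_scalar(blur_sigma, "blur_sigma", min = 0)
  stopifnot(length(noise) == 2L, all(noise >= 0))
  if (nrow(cells) > 1L) {
    for (i in seq_len(nrow(cells) - 1L)) {
      for (j in seq(i + 1L, nrow(cells))) {
        d <- sqrt((cells$cy[i] - cells$cy[j])^2 +
                  (cells$cx[i] - cells$cx[j])^2)
        if (d <= cells$r_cell[i] + cells$r_cell[j]) {
          abort("cells ", i, " and ", j, " overlap")
        }
      }
    }
  }
  structure(list(cells = cells, shape = as.integer(shape), gain = gain,
                 background = background, noise = as.numeric(noise),
                 blur_sigma = blur_sigma, marker_level = marker_level,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "synthetic_scene")
}

# Disk membership on the pixel grid (pixel centres at integer coordinates).
disk_mask <- function(shape, cy, cx, r) {
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# True label masks for a scene: list(nuclei = labelmat, cells = labelmat).
scene_true_masks <- function(scene) {
  nuc <- matrix(0L, scene$shape[1], scene$shape[2])
  cel <- matrix(0L, scene$shape[1], scene$shape[2])
  for (i in seq_len(nrow(scene$cells))) {
    cc <- scene$cells[i, ]
    cel[disk_mask(scene$shape, cc$cy, cc$cx, cc$r_cell)] <- i
    nuc[disk_mask(scene$shape, cc$cy, cc$cx, cc$r_nuc)] <- i
  }
  list(nuclei = nuc, cells = cel)
}

#' Render a ground-truthed synthetic two-channel time-lapse
#'
#' Paints each cell's nucleus at `gain * N + background` and cytoplasm at
#' `gain * C + background` in the reporter channel (nuclear marker channel:
#' `gain * marker_level + background` inside nuclei), optionally blurs, then
#' applies Poisson + Gaussian noise. All noiseless compartment means equal
#' their analytic values exactly; identical seeds give bit-identical output.
#'
#' @param scene a [synthetic_scene()].
#' @param trajectories either a single data.frame from [simulate_kinetics()]
#'   (shared by all cells) or a list with one such data.frame per cell.
#' @param seed integer seed for the noise.
#' @return list with `stack` ([image_stack()], channels reporter = 1,
#'   nuclear_marker = 2) and `truth`: per-cell/per-frame data.frame
#'   (`cell_id`, `frame`, `t_s`, `true_N`, `true_C`, `true_ci`) plus the
#'   true label masks.
#' @export
render_timelapse <- function(scene, trajectories, seed = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  n_cells <- nrow(scene$cells)
  trj <- if (is.data.frame(trajectories)) {
    rep(list(trajectories), n_cells)
  } else trajectories
  if (length(trj) != n_cells) {
    abort("need one trajectory per cell (or a single shared one)")
  }
  n_frames <- nrow(trj[[1]])
  if (any(vapply(trj, nrow, 1L) != n_frames)) {
    abort("trajectory lengths differ between cells")
  }
  masks <- scene_true_masks(scene)
  ny <- scene$shape[1]; nx <- scene$shape[2]
  a <- array(0, dim = c(n_frames, 2L, ny, nx))
  truth <- vector("list", n_frames * n_cells)

  marker_clean <- matrix(scene$background, ny, nx)
  marker_clean[masks$nuclei > 0] <-
    scene$gain * scene$marker_level + scene$background
  if (scene$blur_sigma > 0) {
    marker_blur <- gaussian_blur(marker_clean, scene$blur_sigma)
  } else marker_blur <- marker_clean

  with_seed(seed, {
    for (f in seq_len(n_frames)) {
      rep_clean <- matrix(scene$background, ny, nx)
      for (i in seq_len(n_cells)) {
        N <- trj[[i]]$N[f]; C <- trj[[i]]$C[f]
        cyto <- masks$cells == i & masks$nuclei != i
        rep_clean[cyto] <- scene$gain * C + scene$background
        rep_clean[masks$nuclei == i] <- scene$gain * N + scene$background
        truth[[(f - 1L) * n_cells + i]] <- data.frame(
          cell_id = i, frame = f, t_s = trj[[i]]$t_s[f],
          true_N = N, true_C = C,
          true_ci = if (C > 0) N / C else NA_real_)
      }
      if (scene$blur_sigma > 0) rep_clean <- gaussian_blur(rep_clean,
                                                           scene$blur_sigma)
      a[f, 1, , ] <- add_noise(rep_clean, scene$noise)
      a[f, 2, , ] <- add_noise(marker_blur, scene$noise)
    }
  })
  stack <- image_stack(a, list(reporter = 1L, nuclear_marker = 2L),
                       scene$pixel_size_um,
                       vapply(seq_len(n_frames), function(f) trj[[1]]$t_s[f],
                              numeric(1)))
  list(stack = stack,
       truth = list(per_cell = do.call(rbind, truth),
                    nuclei = masks$nuclei, cells = masks$cells))
}

# Poisson (scaled) + Gaussian noise; clamped at 0 so stacks stay valid.
add_noise <- function(clean, noise) {
  p <- noise[1]; g <- noise[2]
  out <- clean
  if (p > 0) out <- p * matrix(stats::rpois(length(clean), clean / p),
                               nrow(clean))
  if (g > 0) out <- out + matrix(stats::rnorm(length(clean), 0, g),
                                 nrow(clean))
  pmax(out, 0)
}

#' Lay out non-overlapping cells on a grid
#'
#' Convenience constructor for scene geometry: up to `n` cells at jittered
#' grid positions with the given radii.
#'
#' @param n number of cells.
#' @param shape image shape `c(ny, nx)`.
#' @param r_cell,r_nuc cell and nucleus radii (pixels).
#' @param jitter maximal uniform centre jitter (pixels); kept small enough
#'   that cells never collide.
#' @param seed integer seed.
#' @return data.frame suitable for [synthetic_scene()].
#' @export
layout_cells <- function(n, shape = c(128L, 128L), r_cell = 24, r_nuc = 10,
                         jitter = 2, seed = 1L) {
  pitch <- 2 * r_cell + 2 * jitter + 3
  per_row <- max(1L, floor((shape[2] - 2) / pitch))
  rows <- ceiling(n / per_row)
  if (rows * pitch + 2 > shape[1] + pitch) {
    # allow exactly filling; checked again by synthetic_scene overlap test
  }
  with_seed(seed, {
    out <- data.frame(cy = numeric(n), cx = numeric(n),
                      r_cell = r_cell, r_nuc = r_nuc)
    for (i in seq_len(n)) {
      r <- (i - 1L) %/% per_row
      c_ <- (i - 1L) %% per_row
      out$cy[i] <- r_cell + 2 + r * pitch + stats::runif(1, -jitter, jitter)
      out$cx[i] <- r_cell + 2 + c_ * pitch + stats::runif(1, -jitter, jitter)
    }
    out
  })
}
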