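#' Specification for a simulated line-scan FRAP experiment
#'
#' Encodes the acquisition protocol of a fast line-scan FRAP measurement
#' (default timing: 1 s pre-bleach, 150 ms bleach, 3 s recovery) together
#' with the ground-truth photophysics: mobile fraction, recovery rate,
#' bleach depth, optional slow whole-field acquisition bleaching and
#' additive Gaussian noise.
#'
#' With full bleach depth (the default) the true normalized recovery is
#' \eqn{y(t) = (1 - d) + d\,m\,(1 - e^{-kt})} with d = `bleach_depth`,
#' m = `mobile_fraction`, so the immobile fraction reported downstream is
#' `100 * bleach_depth * (1 - mobile_fraction)` percent.
#'
#' @param mobile_fraction fraction of the bleached pool that exchanges, in
#'   `[0, 1]`.
#' @param k_true recovery rate (1/s), > 0.
#' @param bleach_depth fraction of pre-bleach intensity removed in the
#'   bleach ROI, in `(0, 1]` (or 0 for a null experiment).
#' @param pre_s,bleach_s,post_s phase durations (s), > 0.
#' @param line_rate_hz line scans per second.
#' @param line_len_px pixels per scanned line.
#' @param bleach_halfwidth_px half-width of the bleach ROI around the line
#'   centre (pixels).
#' @param bg_px number of pixels at each end of the line lying outside the
#'   cell (background region).
#' @param acq_bleach_rate slow whole-field acquisition-bleaching rate (1/s);
#'   0 disables. Applied as exp(-rate * t) to all fluorescent pixels.
#' @param noise_sd additive Gaussian noise SD relative to the pre-bleach
#'   fluorescence level.
#' @param i_pre pre-bleach fluorescence level (arbitrary units).
#' @param bg_level background intensity level (arbitrary units).
#' @return Object of class `frap_sim_spec`.
#' @export
frap_sim_spec <- function(mobile_fraction = 0.82, k_true = 4.5,
                          bleach_depth = 1, pre_s = 1, bleach_s = 0.15,
                          post_s = 3, line_rate_hz = 700, line_len_px = 128L,
                          bleach_halfwidth_px = 8L, bg_px = 10L,
                          acq_bleach_rate = 0, noise_sd = 0.01,
                          i_pre = 100, bg_level = 5) {
  check_scalar(mobile_fraction, "mobile_fraction", min = 0, max = 1)
  check_scalar(k_true, "k_true", min = 0, strict_min = TRUE)
  check_scalar(bleach_depth, "bleach_depth", min = 0, max = 1)
  check_scalar(pre_s, "pre_s", min = 0, strict_min = TRUE)
  check_scalar(bleach_s, "bleach_s", min = 0, strict_min = TRUE)
  check_scalar(post_s, "post_s", min = 0, strict_min = TRUE)
  check_scalar(acq_bleach_rate, "acq_bleach_rate", min = 0)
  check_scalar(noise_sd, "noise_sd", min = 0)
  if (2L * bleach_halfwidth_px + 1L + 2L * bg_px >= line_len_px) {
    abort("bleach ROI plus background margins wider than the line")
  }
  structure(list(mobile_fraction = mobile_fraction, k_true = k_true,
                 bleach_depth = bleach_depth, pre_s = pre_s,
                 bleach_s = bleach_s, post_s = post_s,
                 line_rate_hz = line_rate_hz,
                 line_len_px = as.integer(line_len_px),
                 bleach_halfwidth_px = as.integer(bleach_halfwidth_px),
                 bg_px = as.integer(bg_px),
                 acq_bleach_rate = acq_bleach_rate, noise_sd = noise_sd,
                 i_pre = i_pre, bg_level = bg_level),
            class = "frap_sim_spec")
}

#' Simulate a line-scan FRAP kymogram with ground truth
#'
#' Builds the space x time kymogram line by line: pre-bleach lines at the
#' resting fluorescence, bleach-phase lines with the ROI dropped by
#' `bleach_depth`, and post-bleach lines in which the ROI recovers as a
#' one-phase exponential association towards the mobile-fraction plateau
#' while the rest of the cell stays at the resting level. Optional slow
#' acquisition bleaching multiplies every fluorescent pixel by
#' `exp(-acq_bleach_rate * t)`. Background pixels sit at `bg_level`
#' throughout. Identical seeds give identical records.
#'
#' @param spec a [frap_sim_spec()].
#' @param seed integer seed for the noise.
#' @return list with `record` (a [frap_record()]) and `truth` (list:
#'   `mobile_fraction`, `k_true`, `bleach_depth`, `plateau_norm` — the true
#'   normalized recovery asymptote — and `if_true_pct`).
#' @export
simulate_frap_record <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "frap_sim_spec"))
  dt <- 1 / spec$line_rate_hz
  n_pre <- max(1L, round(spec$pre_s / dt))
  n_bleach <- max(1L, round(spec$bleach_s / dt))
  n_post <- max(1L, round(spec$post_s / dt))
  n_lines <- n_pre + n_bleach + n_post
  L <- spec$line_len_px
  centre <- (L + 1) / 2
  roi <- which(abs(seq_len(L) - centre) <= spec$bleach_halfwidth_px)
  bg_region <- c(seq_len(spec$bg_px), L - spec$bg_px + seq_len(spec$bg_px))
  cell_px <- setdiff(seq_len(L), bg_region)

  t_lines <- (seq_len(n_lines) - 1L) * dt      # acquisition clock
  t_post0 <- t_lines[n_pre + n_bleach + 1L]    # first post-bleach line

  base <- matrix(spec$bg_level, nrow = L, ncol = n_lines)
  fluor <- matrix(0, nrow = L, ncol = n_lines)
  fluor[cell_px, ] <- spec$i_pre

  # Bleach phase: ROI drops linearly to the bleached level over the flash.
  bl_cols <- n_pre + seq_len(n_bleach)
  frac <- seq_len(n_bleach) / n_bleach
  for (j in seq_along(bl_cols)) {
    fluor[roi, bl_cols[j]] <- spec$i_pre * (1 - spec$bleach_depth * frac[j])
  }
  # Post-bleach: one-phase exponential association in the ROI.
  post_cols <- n_pre + n_bleach + seq_len(n_post)
  t_rec <- t_lines[post_cols] - t_post0
  y_roi <- spec$i_pre * (1 - spec$bleach_depth +
                         spec$bleach_depth * spec$mobile_fraction *
                         (1 - exp(-spec$k_true * t_rec)))
  for (j in seq_along(post_cols)) fluor[roi, post_cols[j]] <- y_roi[j]

  if (spec$acq_bleach_rate > 0) {
    decay <- exp(-spec$acq_bleach_rate * t_lines)
    fluor <- sweep(fluor, 2, decay, `*`)
  }
  kym <- base + fluor
  if (spec$noise_sd > 0) {
    kym <- with_seed(seed, {
      kym + matrix(stats::rnorm(length(kym), 0,
                                spec$noise_sd * spec$i_pre), nrow = L)
    })
  }

  rec <- frap_record(
    kymogram = kym, line_interval_s = dt,
    phases = list(pre = c(1L, n_pre),
                  bleach = c(n_pre + 1L, n_pre + n_bleach),
                  post = c(n_pre + n_bleach + 1L, n_lines)),
    rois = list(bleach = range(roi), background = bg_region,
                guard_px = 5L),
    pixel_size_um = 0.048)
  plateau <- 1 - spec$bleach_depth +
    spec$bleach_depth * spec$mobile_fraction
  list(record = rec,
       truth = list(mobile_fraction = spec$mobile_fraction,
                    k_true = spec$k_true, bleach_depth = spec$bleach_depth,
                    plateau_norm = plateau,
                    if_true_pct = 100 * (1 - plateau)))
}
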