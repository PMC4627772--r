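# Shared fixture builders and independent oracles (built in code; no
# binary files).

# One-cell noiseless scene with forced concentrations N, C.
make_single_cell <- function(N = 2, C = 1, shape = c(64L, 64L), r_cell = 20,
                             r_nuc = 8, noise = c(0, 0), gain = 100,
                             background = 10, blur_sigma = 0, seed = 1L) {
  cells <- data.frame(cy = shape[1] / 2, cx = shape[2] / 2,
                      r_cell = r_cell, r_nuc = r_nuc)
  scene <- synthetic_scene(cells, shape = shape, gain = gain,
                           background = background, noise = noise,
                           blur_sigma = blur_sigma)
  trj <- data.frame(t_s = 0, N = N, C = C, ci_true = N / C)
  render_timelapse(scene, trj, seed = seed)
}

# Independent fine-step forward-Euler integrator for the two-compartment
# exchange model (oracle for simulate_kinetics; deliberately not RK4).
euler_kinetics <- function(k_in_base, k_in_stim, k_out, t_stim, vol_ratio,
                           c_total, times, dt = 5e-4) {
  r0 <- if (k_out > 0) k_in_base / k_out else Inf
  if (is.finite(r0)) {
    C <- c_total / (1 + vol_ratio * r0); N <- r0 * C
  } else {
    N <- c_total / vol_ratio; C <- 0
  }
  out <- matrix(NA_real_, length(times), 2)
  t <- 0
  for (i in seq_along(times)) {
    while (t < times[i] - 1e-12) {
      h <- min(dt, times[i] - t)
      kin <- if (t < t_stim) k_in_base else k_in_stim
      flux <- kin * C - k_out * N
      N <- N + h * flux
      C <- C - h * vol_ratio * flux
      t <- t + h
    }
    out[i, ] <- c(N, C)
  }
  out
}

# Best-overlap IoU between a predicted label mask and a truth label mask.
matched_iou <- function(pred, truth, label) {
  tmask <- truth == label
  cand <- unique(pred[tmask])
  cand <- cand[cand != 0]
  if (length(cand) == 0L) return(0)
  max(vapply(cand, function(k) {
    pm <- pred == k
    sum(pm & tmask) / sum(pm | tmask)
  }, numeric(1)))
}

# Constant-row kymogram record: bleach ROI rows at `roi_val`, background
# margin rows at `bg_val`, everything else at `ref_val`.
make_const_record <- function(n_px = 64L, n_lines = 60L, roi_val = 100,
                              ref_val = 200, bg_val = 20) {
  kym <- matrix(ref_val, n_px, n_lines)
  roi <- (n_px / 2 - 5):(n_px / 2 + 5)
  bg <- c(1:6, (n_px - 5):n_px)
  kym[roi, ] <- roi_val
  kym[bg, ] <- bg_val
  frap_record(kym, line_interval_s = 0.005,
              phases = list(pre = c(1L, 20L), bleach = c(21L, 25L),
                            post = c(26L, n_lines)),
              rois = list(bleach = range(roi), background = bg,
                          guard_px = 3L))
}
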