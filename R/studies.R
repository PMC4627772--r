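# Monte-Carlo recovery studies quantifying how well the analysis pipelines
# recover the synthetic generators' ground truth. Used by the acceptance
# tests and the acceptance report; exported so users can rerun them at
# other settings.

#' FRAP parameter-recovery study
#'
#' Simulates `n_seeds` kymograms from one spec, runs the full analysis
#' (trace extraction, double normalization, one-phase fit) on each, and
#' summarizes the recovery error of the immobile fraction (percentage
#' points) and the rate constant (relative).
#'
#' @param spec a [frap_sim_spec()].
#' @param n_seeds number of simulated records.
#' @param seed0 base seed; record i uses `seed0 + i`.
#' @return list: `per_seed` data.frame (`seed`, `k_est`, `if_est_pct`,
#'   `converged`), `median_if_abs_error_pct`, `median_k_rel_error`,
#'   `if_true_pct`, `k_true`.
#' @export
frap_recovery_study <- function(spec = frap_sim_spec(), n_seeds = 50L,
                                seed0 = 0L) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    sim <- simulate_frap_record(spec, seed = seed0 + i)
    fit <- fit_one_phase(double_normalize(extract_traces(sim$record)))
    data.frame(seed = seed0 + i, k_est = fit$k,
               if_est_pct = fit$immobile_fraction_pct,
               converged = fit$converged)
  })
  per_seed <- do.call(rbind, rows)
  truth <- simulate_frap_record(spec, seed = seed0 + 1L)$truth
  list(per_seed = per_seed,
       median_if_abs_error_pct =
         stats::median(abs(per_seed$if_est_pct - truth$if_true_pct)),
       median_k_rel_error =
         stats::median(abs(per_seed$k_est - truth$k_true) / truth$k_true),
       if_true_pct = truth$if_true_pct, k_true = truth$k_true)
}

#' CI noise-robustness study
#'
#' Renders `n_seeds` noisy single-frame scenes with known nuclear and
#' cytoplasmic concentrations, measures the per-cell CI over the true
#' compartment masks, and summarizes the relative error against the true
#' N/C ratio.
#'
#' @param n_true,c_true true nuclear and cytoplasmic concentrations.
#' @param r_nuc nucleus radius (pixels); the relative-error bound in the
#'   acceptance criteria is stated for radii >= 8 px.
#' @param r_cell,shape scene geometry.
#' @param gain,background,noise camera model (see [synthetic_scene()]).
#' @param n_seeds number of rendered scenes.
#' @param seed0 base seed.
#' @return list: `per_seed` data.frame (`seed`, `ci`, `rel_error`),
#'   `max_rel_error`, `median_rel_error`, `ci_true`.
#' @export
ci_noise_study <- function(n_true = 2, c_true = 1, r_nuc = 8, r_cell = 20,
                           shape = c(64L, 64L), gain = 100, background = 10,
                           noise = c(0.5, 2), n_seeds = 100L, seed0 = 0L) {
  cells <- data.frame(cy = shape[1] / 2, cx = shape[2] / 2,
                      r_cell = r_cell, r_nuc = r_nuc)
  scene <- synthetic_scene(cells, shape = shape, gain = gain,
                           background = background, noise = noise)
  trj <- data.frame(t_s = 0, N = n_true, C = c_true,
                    ci_true = n_true / c_true)
  ci_true <- n_true / c_true
  rows <- lapply(seq_len(n_seeds), function(i) {
    rnd <- render_timelapse(scene, trj, seed = seed0 + i)
    comp <- build_compartments(rnd$truth$cells, rnd$truth$nuclei)
    frame <- get_frame(rnd$stack, 1, "reporter")
    bg <- estimate_background(frame, rnd$truth$cells)
    m <- measure_frame(frame, comp, bg)
    data.frame(seed = seed0 + i, ci = m$ci[1],
               rel_error = abs(m$ci[1] - ci_true) / ci_true)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       max_rel_error = max(per_seed$rel_error),
       median_rel_error = stats::median(per_seed$rel_error),
       ci_true = ci_true)
}
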