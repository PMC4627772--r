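# End-to-end orchestration: synthesize -> segment -> quantify -> summarize
# for translocation, and simulate -> normalize -> fit for FRAP. Configs are
# JSON (file path or R list); every run writes its resolved config and a
# log next to the results, and is fully deterministic given config + seed.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("config must be a list or a JSON file path")
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              pretty = FALSE), tmp)
  unname(tools::md5sum(tmp))
}

write_run_metadata <- function(config, outdir, log_lines) {
  meta <- list(package = "nucytoloc",
               version = as.character(utils::packageVersion("nucytoloc")),
               config_hash = config_hash(config))
  jsonlite::write_json(c(meta, list(config = config)),
                       file.path(outdir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(outdir, "run.log"))
  meta
}

# Fixed-format CSV writer so reruns are byte-identical across locales.
write_csv_det <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- formatC(df[[j]], format = "g",
                                           digits = 15)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

default_translocation_config <- function() {
  list(
    seed = 1L,
    scene = list(n_cells = 4L, shape = c(120L, 160L), r_cell = 18,
                 r_nuc = 8, gain = 100, background = 10,
                 noise = c(0.5, 1.5), blur_sigma = 0,
                 pixel_size_um = 0.5, frame_interval_s = 120),
    conditions = list(
      list(label = "baseline", k_in_base = 0.004, k_in_stim = 0.004,
           k_out = 0.02, t_stim = 600),
      list(label = "stimulated", k_in_base = 0.004, k_in_stim = 0.04,
           k_out = 0.02, t_stim = 600)
    ),
    n_frames = 21L,
    baseline_label = "baseline",
    group = "synthetic-reporter"
  )
}

#' Run the translocation pipeline on a config
#'
#' Synthesizes one time-lapse per condition (or, in future, loads files),
#' segments and tracks every frame, measures per-cell CI, min-max
#' normalizes the final-frame CI across the whole batch, and summarizes
#' conditions against the configured baseline. Writes `measurements.csv`,
#' `summary.csv`, `exclusions.csv`, `resolved_config.json` and `run.log`
#' to `outdir`. Deterministic given config + seed.
#'
#' @param config JSON path or list; see `default_translocation_config`
#'   (internal) for the schema. Required keys: `conditions` (each with
#'   `label` and kinetics rates), `baseline_label`, `scene`, `n_frames`.
#' @param outdir output directory (created if needed).
#' @return list: `measurements`, `summary`, `exclusions`, `meta`
#'   (invisibly written to disk as CSV/JSON).
#' @export
run_translocation <- function(config, outdir = tempfile("translocation_")) {
  user <- read_config(config)
  config <- utils::modifyList(default_translocation_config(), user)
  # lists of records replace wholesale (modifyList would deep-merge them)
  if ("conditions" %in% names(user)) config$conditions <- user$conditions
  if (is.null(config$conditions) || length(config$conditions) == 0L) {
    abort("config error: 'conditions' must be a non-empty list")
  }
  conds <- config$conditions
  if (is.data.frame(conds)) conds <- split(conds, seq_len(nrow(conds)))
  labels <- vapply(conds, function(cc) as.character(cc$label), character(1))
  if (!config$baseline_label %in% labels) {
    abort("config error: baseline_label '", config$baseline_label,
          "' not among condition labels")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  logmsg <- function(...) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  }

  sc <- config$scene
  cells <- layout_cells(sc$n_cells, shape = sc$shape, r_cell = sc$r_cell,
                        r_nuc = sc$r_nuc, seed = config$seed)
  scene <- synthetic_scene(cells, shape = sc$shape, gain = sc$gain,
                           background = sc$background, noise = sc$noise,
                           blur_sigma = sc$blur_sigma,
                           pixel_size_um = sc$pixel_size_um,
                           frame_interval_s = sc$frame_interval_s)
  times <- (seq_len(config$n_frames) - 1L) * sc$frame_interval_s

  meas <- list(); excl <- list()
  for (i in seq_along(conds)) {
    cc <- conds[[i]]
    kin <- translocation_kinetics(
      k_in_base = cc$k_in_base, k_in_stim = cc$k_in_stim,
      k_out = cc$k_out, t_stim = cc$t_stim,
      k_in_late = if (!is.null(cc$k_in_late)) cc$k_in_late
                  else cc$k_in_stim,
      tau_relax = if (!is.null(cc$tau_relax)) cc$tau_relax else Inf)
    trj <- simulate_kinetics(kin, times)
    seed_i <- config$seed + 1000L * i
    rnd <- render_timelapse(scene, trj, seed = seed_i)
    logmsg("condition '", cc$label, "': rendered ", config$n_frames,
           " frames (seed ", seed_i, ")")
    tracked <- track_timelapse(rnd$stack)
    tracked$label <- cc$label
    tracked$group <- config$group
    meas[[i]] <- tracked
    n_ex <- sum(vapply(seq_len(config$n_frames), function(f) 0L, 0L))
    logmsg("condition '", cc$label, "': ", length(unique(tracked$track_id)),
           " tracks")
  }
  measurements <- do.call(rbind, meas)

  # Normalization pool: all cells, all conditions, final frame.
  final <- measurements[measurements$frame == config$n_frames &
                          measurements$valid, ]
  if (nrow(final) < 2L) abort("too few valid final-frame measurements")
  cin <- normalize_minmax(final$ci)
  final$ci_norm <- as.numeric(cin)
  summary_in <- data.frame(group = final$group, label = final$label,
                           ci = final$ci_norm)
  summ <- summarize_conditions(summary_in, config$baseline_label)
  summ$ci_min_pool <- attr(cin, "ci_min")
  summ$ci_max_pool <- attr(cin, "ci_max")

  exclusions <- data.frame(cell_id = integer(), reason = character())
  write_csv_det(measurements, file.path(outdir, "measurements.csv"))
  write_csv_det(summ, file.path(outdir, "summary.csv"))
  write_csv_det(exclusions, file.path(outdir, "exclusions.csv"))
  meta <- write_run_metadata(config, outdir, log_lines)
  invisible(list(measurements = measurements, summary = summ,
                 exclusions = exclusions, meta = meta, outdir = outdir))
}

default_frap_config <- function() {
  list(
    seed = 1L,
    n_records = 5L,
    groups = list(
      list(label = "free-tracer", mobile_fraction = 0.95, k_true = 15),
      list(label = "tagged-tracer", mobile_fraction = 0.90, k_true = 5.6),
      list(label = "reporter", mobile_fraction = 0.82, k_true = 4.5)
    ),
    spec = list(pre_s = 1, bleach_s = 0.15, post_s = 3, line_rate_hz = 700,
                line_len_px = 128L, noise_sd = 0.01, acq_bleach_rate = 0.05)
  )
}

#' Run the FRAP pipeline on a config
#'
#' Simulates `n_records` kymograms per configured group, extracts and
#' double-normalizes each trace, fits the one-phase exponential, and (with
#' exactly two groups) compares half-life and immobile fraction between
#' them. Writes `fits.csv`, per-record normalized recovery curves
#' (`recovery_curves.csv`), `comparison.csv` when applicable,
#' `resolved_config.json` and `run.log`.
#'
#' @param config JSON path or list: `groups` (each with `label`,
#'   `mobile_fraction`, `k_true`), shared `spec` overrides, `n_records`,
#'   `seed`.
#' @param outdir output directory.
#' @return list: `fits` (data.frame), `comparison` (or NULL), `meta`.
#' @export
run_frap <- function(config, outdir = tempfile("frap_")) {
  user <- read_config(config)
  config <- utils::modifyList(default_frap_config(), user)
  if ("groups" %in% names(user)) config$groups <- user$groups
  groups <- config$groups
  if (is.data.frame(groups)) groups <- split(groups, seq_len(nrow(groups)))
  if (is.null(groups) || length(groups) == 0L) {
    abort("config error: 'groups' must be a non-empty list")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()

  fits <- list(); curves <- list(); fit_objs <- list()
  for (gi in seq_along(groups)) {
    gg <- groups[[gi]]
    fit_objs[[gg$label]] <- list()
    for (ri in seq_len(config$n_records)) {
      spec_args <- c(list(mobile_fraction = gg$mobile_fraction,
                          k_true = gg$k_true), config$spec)
      spec <- do.call(frap_sim_spec, spec_args)
      seed_i <- config$seed + 10000L * gi + ri
      sim <- simulate_frap_record(spec, seed = seed_i)
      tr <- extract_traces(sim$record)
      rec <- double_normalize(tr)
      fit <- fit_one_phase(rec)
      fit_objs[[gg$label]][[ri]] <- fit
      fits[[length(fits) + 1L]] <- data.frame(
        group = gg$label, record = ri, seed = seed_i,
        i0 = fit$i0, a = fit$a, k = fit$k, t_half_s = fit$t_half_s,
        plateau = fit$plateau, if_pct = fit$immobile_fraction_pct,
        resid_sd = fit$resid_sd, converged = fit$converged,
        unreliable = fit$unreliable,
        if_true_pct = sim$truth$if_true_pct, k_true = sim$truth$k_true)
      curves[[length(curves) + 1L]] <- data.frame(
        group = gg$label, record = ri, t = rec$t, y = rec$y)
      log_lines <- c(log_lines, paste0(
        "group '", gg$label, "' record ", ri, ": k=",
        signif(fit$k, 4), "/s IF=", signif(fit$immobile_fraction_pct, 4),
        "%", if (!fit$converged) " NOT CONVERGED" else ""))
    }
  }
  fits_df <- do.call(rbind, fits)
  curves_df <- do.call(rbind, curves)

  comparison <- NULL
  if (length(groups) == 2L) {
    comparison <- compare_mobility(fit_objs[[1]], fit_objs[[2]])
    write_csv_det(comparison, file.path(outdir, "comparison.csv"))
  }
  write_csv_det(fits_df, file.path(outdir, "fits.csv"))
  write_csv_det(curves_df, file.path(outdir, "recovery_curves.csv"))
  meta <- write_run_metadata(config, outdir, log_lines)
  invisible(list(fits = fits_df, curves = curves_df,
                 comparison = comparison, meta = meta, outdir = outdir))
}

#' Generate the documented fixture set used by the test suite
#'
#' Writes a small synthetic time-lapse TIFF with its ground-truth CSV, a
#' FRAP kymogram CSV, and a manifest (JSON) listing seeds, parameters and
#' md5 hashes of every file, so regeneration can be verified.
#'
#' @param outdir target directory.
#' @param seed integer seed.
#' @return Manifest list (invisibly); files under `outdir`.
#' @export
make_fixtures <- function(outdir = tempfile("fixtures_"), seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cells <- layout_cells(2L, shape = c(80L, 120L), r_cell = 16, r_nuc = 8,
                        seed = seed)
  scene <- synthetic_scene(cells, shape = c(80L, 120L), noise = c(0.5, 1.5))
  kin <- translocation_kinetics(k_in_base = 0.004, k_in_stim = 0.04,
                                k_out = 0.02, t_stim = 600)
  trj <- simulate_kinetics(kin, seq(0, 1200, by = 120))
  rnd <- render_timelapse(scene, trj, seed = seed)
  stack_path <- file.path(outdir, "timelapse.tif")
  write_stack(rnd$stack, stack_path)
  truth_path <- file.path(outdir, "timelapse_truth.csv")
  write_csv_det(rnd$truth$per_cell, truth_path)

  sim <- simulate_frap_record(frap_sim_spec(line_rate_hz = 200,
                                            line_len_px = 64L,
                                            bleach_halfwidth_px = 6L),
                              seed = seed)
  kym_path <- file.path(outdir, "frap_kymogram.csv")
  utils::write.table(sim$record$kymogram, kym_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  manifest <- list(
    seed = seed,
    files = lapply(stats::setNames(nm = c("timelapse.tif",
                                          "timelapse_truth.csv",
                                          "frap_kymogram.csv")),
                   function(f) list(
                     md5 = unname(tools::md5sum(file.path(outdir, f))))),
    frap_truth = sim$truth,
    kinetics = unclass(kin))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
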