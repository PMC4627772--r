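#' Nucleo-cytoplasmic concentration index (CI)
#'
#' The background-corrected ratio of mean nuclear to mean cytoplasmic
#' fluorescence: \deqn{CI = (F_{nuc} - BG) / (F_{cyto} - BG)}
#' A CI of 1 means homogeneous distribution; above 1, nuclear accumulation.
#' Measurements whose denominator is at or below `epsilon` are marked
#' invalid (`NA` with the `valid` attribute `FALSE`), never silently
#' dropped.
#'
#' @param f_nuc,f_cyto mean reporter intensity over the nucleus and the
#'   cytoplasm (vectors recycle).
#' @param bg background intensity level.
#' @param epsilon positive guard on the denominator; default `1e-6` times
#'   the intensity range of the inputs (floor `1e-12`).
#' @return Numeric vector of CI values (`NA` where invalid) with a logical
#'   attribute `valid`.
#' @export
compute_ci <- function(f_nuc, f_cyto, bg, epsilon = NULL) {
  n <- max(length(f_nuc), length(f_cyto), length(bg))
  f_nuc <- rep_len(as.numeric(f_nuc), n)
  f_cyto <- rep_len(as.numeric(f_cyto), n)
  bg <- rep_len(as.numeric(bg), n)
  if (is.null(epsilon)) {
    rng <- diff(range(c(f_nuc, f_cyto, bg), finite = TRUE))
    epsilon <- max(1e-6 * rng, 1e-12)
  }
  denom <- f_cyto - bg
  valid <- is.finite(denom) & denom > epsilon & is.finite(f_nuc)
  ci <- ifelse(valid, (f_nuc - bg) / denom, NA_real_)
  attr(ci, "valid") <- valid
  ci
}

#' Measure per-cell CI on one frame
#'
#' `f_nuc` is the mean reporter intensity over the nucleus mask; `f_cyto`
#' is computed by subtracting the nuclear intensity from the whole-cell
#' intensity, `(sum(cell) - sum(nucleus)) / (area(cell) - area(nucleus))`,
#' which is algebraically the cytoplasm-mask mean.
#'
#' @param frame 2-D reporter-channel matrix.
#' @param compartments a [build_compartments()] result.
#' @param bg background level (scalar), e.g. from [estimate_background()].
#' @param epsilon passed to [compute_ci()].
#' @return data.frame: `cell_id`, `f_nuc`, `f_cyto`, `bg`, `ci`, `valid`.
#'   Cells excluded upstream are absent here but listed in
#'   `compartments$excluded`.
#' @export
measure_frame <- function(frame, compartments, bg, epsilon = NULL) {
  stopifnot(is.matrix(frame), inherits(compartments, "cell_compartments"),
            all(dim(frame) == compartments$dim))
  rows <- lapply(compartments$cells, function(cc) {
    sum_cell <- sum(frame[cc$cell])
    sum_nuc <- sum(frame[cc$nucleus])
    f_nuc <- sum_nuc / length(cc$nucleus)
    f_cyto <- (sum_cell - sum_nuc) /
      (length(cc$cell) - length(cc$nucleus))
    data.frame(cell_id = cc$cell_id, f_nuc = f_nuc, f_cyto = f_cyto,
               bg = bg)
  })
  if (length(rows) == 0L) {
    return(data.frame(cell_id = integer(), f_nuc = numeric(),
                      f_cyto = numeric(), bg = numeric(), ci = numeric(),
                      valid = logical()))
  }
  out <- do.call(rbind, rows)
  ci <- compute_ci(out$f_nuc, out$f_cyto, out$bg, epsilon)
  out$ci <- as.numeric(ci)
  out$valid <- attr(ci, "valid")
  out
}

#' Track per-cell CI through a time-lapse
#'
#' Segments every frame (nuclei from the nuclear-marker channel, cells by
#' seeded growth on the reporter channel), links labels across frames by
#' nearest centroid (default max displacement 10 px/frame), and measures
#' the CI of every tracked cell at every frame. Frames where a track is not
#' found are recorded as missing (`NA` ci, `missing = TRUE`), never
#' interpolated.
#'
#' @param stack an [image_stack()] with reporter and nuclear_marker roles.
#' @param min_area_px nucleus size filter passed to [segment_nuclei()].
#' @param max_disp_px maximum per-frame centroid displacement for linking.
#' @param bg_method,bg_roi background estimation, see
#'   [estimate_background()].
#' @return data.frame: `track_id`, `frame`, `t_s`, `f_nuc`, `f_cyto`, `bg`,
#'   `ci`, `valid`, `missing`; ordered by track then time.
#' @export
track_timelapse <- function(stack, min_area_px = 20L, max_disp_px = 10,
                            bg_method = "outside_cells", bg_roi = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(stack$channel_roles$nuclear_marker)) {
    abort("stack needs a nuclear_marker channel for tracking")
  }
  n_frames <- dim(stack$intensities)[1]
  comp_list <- vector("list", n_frames)
  meas_list <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    nucf <- get_frame(stack, f, "nuclear_marker")
    repf <- get_frame(stack, f, "reporter")
    nuclei <- segment_nuclei(nucf, min_area_px)
    cells <- segment_cells(repf, nuclei)
    comp <- build_compartments(cells, nuclei)
    bg <- estimate_background(repf, cells, method = bg_method, roi = bg_roi)
    comp_list[[f]] <- comp
    meas_list[[f]] <- measure_frame(repf, comp, bg)
  }
  if (all(vapply(comp_list, function(cc) length(cc$cells), 1L) == 0L)) {
    abort("no cells tracked in any frame")
  }
  maps <- link_labels(comp_list, max_disp_px)
  rows <- list()
  for (f in seq_len(n_frames)) {
    m <- meas_list[[f]]
    if (nrow(m) == 0L) next
    m$track_id <- unname(maps[[f]][as.character(m$cell_id)])
    m$frame <- f
    m$t_s <- stack$frame_times_s[f]
    rows[[length(rows) + 1L]] <- m
  }
  long <- do.call(rbind, rows)
  # Fill gaps with explicit missing rows.
  tracks <- sort(unique(long$track_id))
  full <- expand.grid(track_id = tracks, frame = seq_len(n_frames))
  full$t_s <- stack$frame_times_s[full$frame]
  out <- merge(full, long[, c("track_id", "frame", "f_nuc", "f_cyto", "bg",
                              "ci", "valid")],
               by = c("track_id", "frame"), all.x = TRUE)
  out$missing <- is.na(out$ci) & is.na(out$f_nuc)
  out$valid[out$missing] <- FALSE
  out[order(out$track_id, out$frame), ]
}

#' Min-max normalize CI values to CI-bar
#'
#' Maps CI values across the whole experiment batch to `[0, 1]`:
#' `(x - min) / (max - min)`, where 0 and 1 are respectively the minimal
#' and maximal CI obtained in the batch. The pool's `(min, max)` is stored
#' with the result for traceability (normalized values from different pools
#' are not comparable).
#'
#' @param ci_values numeric vector with at least two distinct finite
#'   values (the normalization is undefined otherwise: error).
#' @return Numeric vector in `[0, 1]` with attributes `ci_min`, `ci_max`.
#' @export
normalize_minmax <- function(ci_values) {
  v <- ci_values[is.finite(ci_values)]
  if (length(unique(v)) < 2L) {
    abort("min-max normalization undefined: need >= 2 distinct values")
  }
  lo <- min(v); hi <- max(v)
  out <- (ci_values - lo) / (hi - lo)
  attr(out, "ci_min") <- lo
  attr(out, "ci_max") <- hi
  out
}

#' Condition-level CI-bar summary with fold-changes and baseline deltas
#'
#' Reproduces the derived columns of a condition table: per reporter group
#' and treatment, mean CI-bar +- SEM and n; `fold_change` = mean /
#' group-baseline mean; `delta` = mean - group-baseline mean; and, when a
#' reference group is given, `cross_ratio` = delta / delta of the matching
#' treatment row of the reference group (treatment labels matched
#' case-insensitively). The baseline row of each group has fold_change 1
#' and delta 0 by construction.
#'
#' @param data data.frame with columns `group` (reporter group), `label`
#'   (treatment) and either per-cell `ci` values or precomputed `mean_ci`
#'   (+ optional `sem`, `n`) rows, e.g. means transcribed from a printed
#'   table.
#' @param baseline_label treatment label serving as each group's baseline;
#'   must be present in every group.
#' @param reference_group optional group name whose deltas are the
#'   denominators of `cross_ratio`.
#' @return data.frame: `group`, `label`, `n`, `mean_ci`, `sem`,
#'   `fold_change`, `delta`, `cross_ratio`, `fold_undefined`. Full
#'   precision; round for display (the conventional table shows two
#'   decimals).
#' @export
summarize_conditions <- function(data, baseline_label,
                                 reference_group = NULL) {
  stopifnot(is.data.frame(data), all(c("group", "label") %in% names(data)))
  norm_lab <- function(x) tolower(trimws(as.character(x)))
  if ("ci" %in% names(data)) {
    split_idx <- split(seq_len(nrow(data)),
                       list(data$group, data$label), drop = TRUE)
    rows <- lapply(split_idx, function(ii) {
      v <- data$ci[ii]
      v <- v[is.finite(v)]
      if (length(v) == 0L) return(NULL)
      data.frame(group = data$group[ii[1]], label = data$label[ii[1]],
                 n = length(v), mean_ci = mean(v),
                 sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                       else NA_real_)
    })
    tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  } else if ("mean_ci" %in% names(data)) {
    tab <- data
    if (!"sem" %in% names(tab)) tab$sem <- NA_real_
    if (!"n" %in% names(tab)) tab$n <- NA_integer_
    tab <- tab[, c("group", "label", "n", "mean_ci", "sem")]
  } else {
    abort("data must carry either per-cell 'ci' or precomputed 'mean_ci'")
  }
  rownames(tab) <- NULL

  groups <- unique(tab$group)
  for (g in groups) {
    if (!any(tab$group == g & norm_lab(tab$label) == norm_lab(baseline_label))) {
      abort("baseline label '", baseline_label, "' missing in group '", g,
            "'")
    }
  }
  tab$fold_change <- NA_real_
  tab$delta <- NA_real_
  tab$fold_undefined <- FALSE
  for (g in groups) {
    sel <- tab$group == g
    base_mean <- tab$mean_ci[sel & norm_lab(tab$label) ==
                               norm_lab(baseline_label)][1]
    tab$delta[sel] <- tab$mean_ci[sel] - base_mean
    if (base_mean == 0) {
      tab$fold_undefined[sel] <- TRUE
    } else {
      tab$fold_change[sel] <- tab$mean_ci[sel] / base_mean
    }
  }
  tab$cross_ratio <- NA_real_
  if (!is.null(reference_group)) {
    if (!reference_group %in% groups) {
      abort("reference_group '", reference_group, "' not present")
    }
    ref <- tab[tab$group == reference_group, ]
    for (i in seq_len(nrow(tab))) {
      if (tab$group[i] == reference_group) next
      j <- which(norm_lab(ref$label) == norm_lab(tab$label[i]))
      if (length(j) == 1L && is.finite(ref$delta[j]) && ref$delta[j] != 0 &&
          norm_lab(tab$label[i]) != norm_lab(baseline_label)) {
        tab$cross_ratio[i] <- tab$delta[i] / ref$delta[j]
      }
    }
  }
  tab
}

#' Stimulus-response metrics of a CI time course
#'
#' Characterizes a rise-then-partial-decline response: baseline (mean over
#' the pre-stimulus window), peak (post-stimulus maximum), plateau (mean
#' over the final window), and the complementary percentages
#' \deqn{decline = 100 (peak - plateau)/(peak - baseline), \quad
#'       above = 100 (plateau - baseline)/(peak - baseline)}
#' both expressed relative to the stimulation-induced rise, so they sum to
#' 100.
#'
#' Call it either with a time series (`data.frame` with `t_s` and `ci`,
#' plus `t_stim`), or directly with the three characteristic levels.
#'
#' @param x a data.frame time series, or the baseline CI level (scalar).
#' @param peak,plateau with scalar `x`: the peak and plateau CI levels.
#' @param t_stim series mode: stimulus time (s).
#' @param plateau_window series mode: `c(lo, hi)` time window (s) for the
#'   plateau mean; default the last quarter of the recording.
#' @return list: `baseline_ci`, `peak_ci`, `plateau_ci`, `time_to_peak_s`
#'   (series mode, else NA), `pct_decline_from_peak`, `pct_above_baseline`,
#'   `defined` (FALSE when peak <= baseline).
#' @export
response_metrics <- function(x, peak = NULL, plateau = NULL, t_stim = NULL,
                             plateau_window = NULL) {
  if (is.data.frame(x)) {
    stopifnot(all(c("t_s", "ci") %in% names(x)))
    if (is.null(t_stim)) abort("series mode needs t_stim")
    pre <- x$ci[x$t_s < t_stim & is.finite(x$ci)]
    post <- x[x$t_s >= t_stim & is.finite(x$ci), ]
    if (length(pre) == 0L || nrow(post) == 0L) {
      abort("need samples both before and after t_stim")
    }
    if (is.null(plateau_window)) {
      t_end <- max(x$t_s)
      plateau_window <- c(t_end - 0.25 * (t_end - t_stim), t_end)
    }
    baseline <- mean(pre)
    ipk <- which.max(post$ci)
    peak <- post$ci[ipk]
    time_to_peak <- post$t_s[ipk] - t_stim
    pl <- x$ci[x$t_s >= plateau_window[1] & x$t_s <= plateau_window[2] &
                 is.finite(x$ci)]
    if (length(pl) == 0L) abort("empty plateau window")
    plateau <- mean(pl)
  } else {
    baseline <- x
    if (is.null(peak) || is.null(plateau)) {
      abort("level mode needs baseline, peak and plateau")
    }
    time_to_peak <- NA_real_
  }
  rise <- peak - baseline
  defined <- is.finite(rise) && rise > 0
  decl <- if (defined) 100 * (peak - plateau) / rise else NA_real_
  above <- if (defined) 100 * (plateau - baseline) / rise else NA_real_
  list(baseline_ci = baseline, peak_ci = peak, plateau_ci = plateau,
       time_to_peak_s = time_to_peak,
       pct_decline_from_peak = decl, pct_above_baseline = above,
       defined = defined)
}

#' Compare CI between treatment groups
#'
#' Two groups: two-tailed unpaired t-test. Three or more: one-way ANOVA,
#' and when a control label is given, Dunnett many-to-one comparisons
#' against it with adjusted p-values. Stars: ns > 0.05, * <= 0.05,
#' ** <= 0.01, *** <= 0.001, **** <= 0.0001.
#'
#' @param data data.frame with numeric `ci` and `label`.
#' @param control label of the control/baseline group (required for
#'   Dunnett; ignored in the two-group case).
#' @return list: `method`, `anova` (data.frame F/df/p, multi-group),
#'   `comparisons` (data.frame label, diff, statistic, p, stars).
#' @export
compare_groups <- function(data, control = NULL) {
  stopifnot(is.data.frame(data), all(c("ci", "label") %in% names(data)))
  data <- data[is.finite(data$ci), ]
  labs <- unique(as.character(data$label))
  if (length(labs) < 2L) abort("need >= 2 groups")
  sizes <- table(as.character(data$label))
  if (any(sizes < 2L)) {
    abort("every group needs n >= 2 (violated by: ",
          paste(names(sizes)[sizes < 2L], collapse = ", "), ")")
  }
  if (length(labs) == 2L) {
    a <- data$ci[data$label == labs[1]]
    b <- data$ci[data$label == labs[2]]
    tt <- stats::t.test(a, b, var.equal = FALSE)
    return(list(method = "two-tailed unpaired t-test", anova = NULL,
                comparisons = data.frame(
                  label = paste(labs[1], "vs", labs[2]),
                  diff = mean(a) - mean(b),
                  statistic = unname(tt$statistic), p = tt$p.value,
                  stars = p_stars(tt$p.value))))
  }
  if (is.null(control) || !control %in% labs) {
    abort("Dunnett comparisons need a control label present in the data")
  }
  fit <- stats::aov(ci ~ label, data = transform(data,
                                                 label = factor(label)))
  an <- stats::anova(fit)
  anova_df <- data.frame(F = an[1, "F value"], df1 = an[1, "Df"],
                         df2 = an[2, "Df"], p = an[1, "Pr(>F)"])
  dn <- dunnett_test(data$ci, as.character(data$label), control)
  dn$stars <- p_stars(dn$p_adj)
  list(method = "one-way ANOVA + Dunnett vs control", anova = anova_df,
       comparisons = dn)
}
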