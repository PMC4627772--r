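#' Line-scan FRAP record
#'
#' Container for a kymogram (space along the scanned line in rows, time in
#' columns) with its acquisition bookkeeping: phase column ranges
#' (pre-bleach, bleach, post-bleach, contiguous and in order) and pixel
#' ranges along the line for the bleach ROI and the background region. The
#' reference region is derived, not stored: all line pixels excluding the
#' bleach ROI widened by a guard band, and excluding the background region.
#'
#' @param kymogram numeric matrix, rows = line pixels, cols = time lines.
#' @param line_interval_s time between successive lines (s).
#' @param phases list with `pre`, `bleach`, `post`, each `c(first, last)`
#'   column index; must tile `1..ncol` contiguously in order.
#' @param rois list with `bleach = c(first, last)` row range,
#'   `background` = integer row indices, and optional `guard_px`
#'   (default 5).
#' @param pixel_size_um pixel size along the line (micrometres).
#' @return Object of class `frap_record`.
#' @export
frap_record <- function(kymogram, line_interval_s, phases, rois,
                        pixel_size_um = 0.048) {
  stopifnot(is.matrix(kymogram))
  check_scalar(line_interval_s, "line_interval_s", min = 0, strict_min = TRUE)
  for (ph in c("pre", "bleach", "post")) {
    if (is.null(phases[[ph]]) || length(phases[[ph]]) != 2L) {
      abort("phases$", ph, " must be c(first, last)")
    }
  }
  p <- phases
  if (!(p$pre[1] == 1L && p$bleach[1] == p$pre[2] + 1L &&
        p$post[1] == p$bleach[2] + 1L && p$post[2] == ncol(kymogram))) {
    abort("phases must be contiguous, ordered pre/bleach/post and cover ",
          "all columns")
  }
  if (is.null(rois$bleach) || length(rois$bleach) != 2L) {
    abort("rois$bleach must be c(first, last)")
  }
  if (is.null(rois$background) || length(rois$background) == 0L) {
    abort("rois$background must be a non-empty set of line pixels")
  }
  if (is.null(rois$guard_px)) rois$guard_px <- 5L
  bleach_px <- seq(rois$bleach[1], rois$bleach[2])
  if (any(bleach_px %in% rois$background)) {
    abort("bleach ROI and background region must be disjoint")
  }
  if (rois$bleach[1] < 1L || rois$bleach[2] > nrow(kymogram)) {
    abort("bleach ROI wider than the scanned line")
  }
  structure(list(kymogram = kymogram, line_interval_s = line_interval_s,
                 phases = phases, rois = rois,
                 pixel_size_um = pixel_size_um),
            class = "frap_record")
}

#' @export
print.frap_record <- function(x, ...) {
  cat(sprintf("<frap_record> %d px x %d lines @ %.4g ms/line\n",
              nrow(x$kymogram), ncol(x$kymogram),
              1000 * x$line_interval_s))
  cat(sprintf("  phases: pre %d-%d, bleach %d-%d, post %d-%d\n",
              x$phases$pre[1], x$phases$pre[2], x$phases$bleach[1],
              x$phases$bleach[2], x$phases$post[1], x$phases$post[2]))
  invisible(x)
}

# Row indices of the derived reference region.
reference_pixels <- function(record) {
  L <- nrow(record$kymogram)
  guard <- record$rois$guard_px
  excl <- seq(max(1L, record$rois$bleach[1] - guard),
              min(L, record$rois$bleach[2] + guard))
  setdiff(setdiff(seq_len(L), excl), record$rois$background)
}

#' Extract background-corrected FRAP and reference traces
#'
#' Per time line: mean over the bleach ROI and over the reference region,
#' each minus the same line's background-region mean. Bleach-phase lines
#' are flagged (`phase == "bleach"`) and excluded from fitting downstream;
#' lines whose corrected intensity is negative are flagged too.
#'
#' @param record a [frap_record()].
#' @return data.frame: `line`, `t_acq_s` (acquisition clock), `phase`,
#'   `i_frap`, `i_ref` (background-corrected), `flagged`.
#' @export
extract_traces <- function(record) {
  stopifnot(inherits(record, "frap_record"))
  ref_px <- reference_pixels(record)
  if (length(ref_px) == 0L) abort("empty reference region")
  bl_px <- seq(record$rois$bleach[1], record$rois$bleach[2])
  bg_px <- record$rois$background
  kym <- record$kymogram
  bg <- colMeans(kym[bg_px, , drop = FALSE])
  i_frap <- colMeans(kym[bl_px, , drop = FALSE]) - bg
  i_ref <- colMeans(kym[ref_px, , drop = FALSE]) - bg
  n <- ncol(kym)
  phase <- rep("post", n)
  phase[seq(record$phases$pre[1], record$phases$pre[2])] <- "pre"
  phase[seq(record$phases$bleach[1], record$phases$bleach[2])] <- "bleach"
  data.frame(line = seq_len(n),
             t_acq_s = (seq_len(n) - 1L) * record$line_interval_s,
             phase = phase, i_frap = i_frap, i_ref = i_ref,
             flagged = phase == "bleach" | i_frap < 0 | i_ref < 0)
}

#' Double-normalize a FRAP trace
#'
#' Applies the double-normalization formula
#' \deqn{y(t) = \frac{I_{Ref,Pre}}{I_{Ref}(t)} \cdot
#'              \frac{I_{FRAP}(t)}{I_{FRAP,Pre}}}
#' where the `Pre` quantities are means over the full pre-bleach phase.
#' Dividing by the reference trace cancels overall acquisition bleaching;
#' scaling by the pre-bleach means makes the pre-bleach level 1 by
#' construction. Bleach-phase lines are dropped; time is re-zeroed at the
#' first post-bleach line.
#'
#' @param traces data.frame from [extract_traces()].
#' @return Object of class `normalized_recovery`: data.frame `t`, `y` (post
#'   phase only) plus attributes `i_frap_pre`, `i_ref_pre` and the pre-phase
#'   normalized values (`pre_y`).
#' @export
double_normalize <- function(traces) {
  req <- c("t_acq_s", "phase", "i_frap", "i_ref")
  stopifnot(is.data.frame(traces), all(req %in% names(traces)))
  pre <- traces[traces$phase == "pre", ]
  if (nrow(pre) == 0L) abort("pre-bleach phase is empty")
  i_frap_pre <- mean(pre$i_frap)
  i_ref_pre <- mean(pre$i_ref)
  if (i_frap_pre <= 0 || i_ref_pre <= 0) {
    abort("non-positive pre-bleach mean; check background region")
  }
  keep <- traces$phase != "bleach"
  if (any(traces$i_ref[keep] <= 0)) {
    abort("reference trace non-positive at a retained line")
  }
  y_all <- (i_ref_pre / traces$i_ref) * (traces$i_frap / i_frap_pre)
  post <- traces$phase == "post"
  t0 <- min(traces$t_acq_s[post])
  out <- data.frame(t = traces$t_acq_s[post] - t0, y = y_all[post])
  structure(out, class = c("normalized_recovery", "data.frame"),
            i_frap_pre = i_frap_pre, i_ref_pre = i_ref_pre,
            pre_y = y_all[traces$phase == "pre"])
}

#' Fit a one-phase exponential association to a recovery curve
#'
#' Nonlinear least squares of \eqn{I(t) = I_0 + A\,(1 - e^{-kt})} to the
#' post-bleach samples. Initialization: `I0` = mean of the first 5 samples,
#' plateau = mean of the last 10 percent, `k` from a log-linear regression
#' of `plateau - y` on `t`. Bounds: `I0` in `[0, 1.2]`, `A` in `[0, 1.5]`,
#' `k` in `(1e-4, 1e4)`. Non-convergence is reported via the `converged`
#' flag, never silently replaced by defaults.
#'
#' @param recovery a [double_normalize()] result (or data.frame with `t`,
#'   `y`, `t[1] == 0`).
#' @return Object of class `recovery_fit`: `i0`, `a`, `k`, `t_half_s`
#'   (= ln 2 / k), `plateau` (= i0 + a), `immobile_fraction_pct`
#'   (= 100 (1 - plateau)), `resid_sd`, `converged`, `n`, `unreliable`
#'   (residual SD > 0.1 or plateau > 1.2).
#' @export
fit_one_phase <- function(recovery) {
  stopifnot(is.data.frame(recovery), all(c("t", "y") %in% names(recovery)))
  t <- recovery$t; y <- recovery$y
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 10L) abort("need >= 10 post-bleach samples")
  if (abs(t[1]) > 1e-9) abort("recovery time must start at 0")

  i0_0 <- mean(y[seq_len(min(5L, length(y)))])
  n_tail <- max(10L, ceiling(0.1 * length(y)))
  plateau_0 <- mean(y[seq(length(y) - n_tail + 1L, length(y))])
  resid0 <- plateau_0 - y
  pos <- resid0 > 0 & t > 0
  k_0 <- if (sum(pos) >= 3L) {
    fitl <- stats::lm(log(resid0[pos]) ~ t[pos])
    max(1e-3, min(1e3, -unname(stats::coef(fitl)[2])))
  } else 1
  a_0 <- max(1e-3, plateau_0 - i0_0)
  start <- list(i0 = min(max(i0_0, 0), 1.2), a = min(a_0, 1.5), k = k_0)

  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    stats::nls(y ~ i0 + a * (1 - exp(-k * t)), data = df, start = start,
               algorithm = "port",
               lower = c(i0 = 0, a = 0, k = 1e-4),
               upper = c(i0 = 1.2, a = 1.5, k = 1e4),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    converged <- TRUE
    resid <- stats::resid(fit)
  } else {
    # Fallback: bounded quasi-Newton on the residual sum of squares.
    sse <- function(p) {
      sum((y - (p[1] + p[2] * (1 - exp(-p[3] * t))))^2)
    }
    op <- stats::optim(unlist(start), sse, method = "L-BFGS-B",
                       lower = c(0, 0, 1e-4), upper = c(1.2, 1.5, 1e4))
    cf <- stats::setNames(op$par, c("i0", "a", "k"))
    converged <- op$convergence == 0
    resid <- y - (cf[1] + cf[2] * (1 - exp(-cf[3] * t)))
  }
  i0 <- unname(cf["i0"]); a <- unname(cf["a"]); k <- unname(cf["k"])
  plateau <- i0 + a
  resid_sd <- stats::sd(resid)
  structure(list(i0 = i0, a = a, k = k, t_half_s = log(2) / k,
                 plateau = plateau,
                 immobile_fraction_pct = 100 * (1 - plateau),
                 resid_sd = resid_sd, converged = converged,
                 n = length(t),
                 unreliable = resid_sd > 0.1 || plateau > 1.2),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(
    "<recovery_fit> I0=%.4g A=%.4g k=%.4g/s t1/2=%.4g s IF=%.2f%%%s\n",
    x$i0, x$a, x$k, x$t_half_s, x$immobile_fraction_pct,
    if (!x$converged) " [NOT CONVERGED]"
    else if (x$unreliable) " [unreliable]" else ""))
  invisible(x)
}

#' Immobile fraction of a fitted recovery
#'
#' `100 * (1 - plateau)` percent, the non-exchanging pool measured between
#' the recovery asymptote and the pre-bleach level (normalized to 1). A
#' plateau above 1 (over-recovery) gives a negative value, which is
#' retained and flagged rather than clipped.
#'
#' @param fit a converged [fit_one_phase()] result.
#' @return list `pct` (numeric), `over_recovery` (logical flag).
#' @export
immobile_fraction <- function(fit) {
  stopifnot(inherits(fit, "recovery_fit"))
  if (!fit$converged) abort("fit did not converge; no immobile fraction")
  list(pct = fit$immobile_fraction_pct, over_recovery = fit$plateau > 1)
}

#' Compare recovery half-life and immobile fraction between two groups
#'
#' Two-tailed unpaired t-tests on `t_half_s` and on the immobile fraction,
#' with group means +- SEM and significance stars.
#'
#' @param fits_a,fits_b lists of [fit_one_phase()] results (>= 2 each).
#' @return data.frame, one row per metric: means, SEMs, n, t, p, stars.
#' @export
compare_mobility <- function(fits_a, fits_b) {
  pull <- function(fits, what) {
    vapply(fits, function(f) {
      stopifnot(inherits(f, "recovery_fit"))
      f[[what]]
    }, numeric(1))
  }
  if (length(fits_a) < 2L || length(fits_b) < 2L) {
    abort("need >= 2 fits per group")
  }
  one <- function(metric, va, vb) {
    tt <- stats::t.test(va, vb, var.equal = FALSE)
    data.frame(metric = metric,
               mean_a = mean(va), sem_a = stats::sd(va) / sqrt(length(va)),
               n_a = length(va),
               mean_b = mean(vb), sem_b = stats::sd(vb) / sqrt(length(vb)),
               n_b = length(vb),
               t = unname(tt$statistic), p = tt$p.value,
               stars = p_stars(tt$p.value))
  }
  rbind(one("t_half_s", pull(fits_a, "t_half_s"), pull(fits_b, "t_half_s")),
        one("immobile_fraction_pct",
            pull(fits_a, "immobile_fraction_pct"),
            pull(fits_b, "immobile_fraction_pct")))
}
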