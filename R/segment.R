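#' Segment nuclei from a nuclear-marker frame
#'
#' Live-cell nuclei are stained (e.g. Hoechst) and imaged in a dedicated
#' channel; nuclei are the bright connected regions above an automatic Otsu
#' threshold, hole-filled and size-filtered. Labels are renumbered 1..K in
#' deterministic raster order.
#'
#' @param frame 2-D numeric matrix (nuclear-marker channel).
#' @param min_area_px minimum object area in pixels; smaller components are
#'   discarded.
#' @return An integer label matrix (0 = background). A constant frame yields
#'   an empty mask with a warning, not an error.
#' @export
segment_nuclei <- function(frame, min_area_px = 20L) {
  stopifnot(is.matrix(frame))
  thr <- otsu_threshold(frame)
  if (is.na(thr)) return(matrix(0L, nrow(frame), ncol(frame)))
  bw <- fill_holes(frame > thr)
  lab <- label_components(bw, connectivity = 4L)
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_area_px)
  out <- matrix(0L, nrow(frame), ncol(frame))
  for (k in seq_along(keep)) out[lab == keep[k]] <- k
  out
}

#' Segment whole cells around nucleus seeds
#'
#' The reporter channel is thresholded (Otsu) to a cell foreground, holes
#' are filled, and each foreground pixel is assigned to the geodesically
#' nearest nucleus seed (distance-based seeded watershed). Each cell label
#' equals its seed nucleus label and contains its nucleus.
#'
#' @param frame 2-D reporter-channel matrix.
#' @param nuclei integer label matrix of nucleus seeds, same shape.
#' @return Integer label matrix of cells. With no nuclei, an all-zero mask.
#' @export
segment_cells <- function(frame, nuclei) {
  stopifnot(is.matrix(frame), is.matrix(nuclei),
            all(dim(frame) == dim(nuclei)))
  if (max(nuclei) == 0L) return(matrix(0L, nrow(frame), ncol(frame)))
  thr <- otsu_threshold(frame)
  if (is.na(thr)) abort("constant reporter frame: cannot segment cells")
  fg <- fill_holes(frame > thr)
  for (k in seq_len(max(nuclei))) {
    if (any(nuclei == k) && !any(fg[nuclei == k])) {
      abort("nucleus seed ", k, " lies entirely outside the reporter ",
            "foreground")
    }
  }
  seeded_grow(fg, nuclei)
}

#' Per-cell nucleus / cell / cytoplasm compartments
#'
#' Pairs each nucleus with the cell that contains it and derives the
#' cytoplasm as the exact set difference cell minus nucleus. Cells whose
#' cytoplasm (or nucleus) would be empty are excluded and reported with a
#' reason rather than silently dropped. A nucleus overlapping two cells is
#' an error (upstream segmentation is inconsistent).
#'
#' @param cells,nuclei integer label matrices of equal shape; cell label k
#'   corresponds to nucleus label k when both derive from [segment_cells()],
#'   but the pairing is re-derived here from containment.
#' @return An object of class `cell_compartments`: list with `dim`, `cells`
#'   (per valid cell: `cell_id`, pixel index vectors `nucleus`, `cell`,
#'   `cytoplasm`, and a `centroid`), and `excluded` (data.frame of cell_id +
#'   reason).
#' @export
build_compartments <- function(cells, nuclei) {
  stopifnot(is.matrix(cells), is.matrix(nuclei),
            all(dim(cells) == dim(nuclei)))
  out <- list(); excl <- list()
  nuc_ids <- setdiff(sort(unique(as.vector(nuclei))), 0L)
  for (nid in nuc_ids) {
    nuc_idx <- which(nuclei == nid)
    host <- unique(cells[nuc_idx])
    host <- host[host != 0L]
    if (length(host) > 1L) {
      abort("nucleus ", nid, " spans ", length(host), " cells")
    }
    if (length(host) == 0L) {
      excl[[length(excl) + 1L]] <-
        data.frame(cell_id = nid, reason = "nucleus outside any cell")
      next
    }
    cell_idx <- which(cells == host)
    if (!all(nuc_idx %in% cell_idx)) {
      # part of the nucleus in background: clip to the cell
      nuc_idx <- intersect(nuc_idx, cell_idx)
    }
    cyto_idx <- setdiff(cell_idx, nuc_idx)
    if (length(nuc_idx) == 0L) {
      excl[[length(excl) + 1L]] <-
        data.frame(cell_id = nid, reason = "empty nucleus")
      next
    }
    if (length(cyto_idx) == 0L) {
      excl[[length(excl) + 1L]] <-
        data.frame(cell_id = nid, reason = "empty cytoplasm")
      next
    }
    rc <- arrayInd(cell_idx, dim(cells))
    out[[length(out) + 1L]] <- list(cell_id = nid, nucleus = nuc_idx,
                                    cell = cell_idx, cytoplasm = cyto_idx,
                                    centroid = c(mean(rc[, 1]), mean(rc[, 2])))
  }
  structure(list(dim = dim(cells), cells = out,
                 excluded = if (length(excl)) do.call(rbind, excl)
                            else data.frame(cell_id = integer(),
                                            reason = character())),
            class = "cell_compartments")
}

#' @export
print.cell_compartments <- function(x, ...) {
  cat(sprintf("<cell_compartments> %d valid cell(s), %d excluded\n",
              length(x$cells), nrow(x$excluded)))
  invisible(x)
}

#' Estimate the image background level
#'
#' Default method: mean intensity of all pixels outside a 3-px dilation of
#' every cell mask (the margin avoids contamination by the diffraction
#' halo). Alternative: mean over an explicit user background ROI, matching
#' manual quantification where background is taken outside the cell.
#'
#' @param frame 2-D intensity matrix.
#' @param cells integer label matrix of cells (ignored for `method="roi"`).
#' @param method `"outside_cells"` (default) or `"roi"`.
#' @param roi for `method="roi"`: logical matrix or integer pixel indices.
#' @param dilate_px safety margin around cells, in pixels.
#' @return Background level (numeric scalar, >= 0 for valid imaging data).
#' @export
estimate_background <- function(frame, cells = NULL,
                                method = c("outside_cells", "roi"),
                                roi = NULL, dilate_px = 3L) {
  method <- match.arg(method)
  stopifnot(is.matrix(frame))
  if (method == "roi") {
    if (is.null(roi)) abort("method='roi' requires a roi")
    idx <- if (is.logical(roi)) which(roi) else as.integer(roi)
    if (length(idx) == 0L) abort("empty background ROI")
    return(mean(frame[idx]))
  }
  if (is.null(cells)) abort("method='outside_cells' requires a cell mask")
  bg_mask <- !binary_dilate(cells > 0, r = dilate_px)
  if (!any(bg_mask)) abort("no background pixels outside dilated cells")
  mean(frame[bg_mask])
}

#' Pixelwise colocalization between two channels
#'
#' Joint 2-D histogram of paired pixel intensities and their Pearson
#' correlation, as in whole-image red/green scatter plots used to assess
#' co-expression of two fluorophores.
#'
#' @param channel_a,channel_b numeric matrices of equal shape.
#' @param mask optional logical matrix restricting the pixel set.
#' @param n_bins histogram bins per axis.
#' @return list with `histogram` (n_bins x n_bins counts, a-bins in rows),
#'   `breaks_a`, `breaks_b`, `pearson_r` (NA with `constant = TRUE` flag if
#'   either channel is constant), `n` pixels used.
#' @export
colocalization_scatter <- function(channel_a, channel_b, mask = NULL,
                                   n_bins = 64L) {
  stopifnot(is.matrix(channel_a), is.matrix(channel_b),
            all(dim(channel_a) == dim(channel_b)))
  idx <- if (is.null(mask)) seq_along(channel_a) else which(mask)
  a <- as.numeric(channel_a[idx]); b <- as.numeric(channel_b[idx])
  const <- stats::sd(a) == 0 || stats::sd(b) == 0
  r <- if (const) NA_real_ else stats::cor(a, b)
  brk <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi <= lo) hi <- lo + 1
    seq(lo, hi, length.out = n_bins + 1L)
  }
  ba <- brk(a); bb <- brk(b)
  ia <- pmin(findInterval(a, ba, rightmost.closed = TRUE), n_bins)
  ib <- pmin(findInterval(b, bb, rightmost.closed = TRUE), n_bins)
  h <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(ia, levels = seq_len(n_bins)),
               factor(ib, levels = seq_len(n_bins)))
  h[] <- as.integer(tab)
  list(histogram = h, breaks_a = ba, breaks_b = bb,
       pearson_r = r, constant = const, n = length(a))
}

# Link per-frame segmentation labels across frames by nearest centroid.
# `comp_list` is a list of cell_compartments (one per frame); returns for
# each frame an integer map from frame-local cell_id to a persistent track
# id. Max displacement per frame defaults to 10 px; ties broken by smallest
# distance, then lowest existing track id.
link_labels <- function(comp_list, max_disp_px = 10) {
  stopifnot(length(comp_list) >= 1L)
  tracks <- list()   # track id -> last centroid
  maps <- vector("list", length(comp_list))
  next_id <- 1L
  for (f in seq_along(comp_list)) {
    cells <- comp_list[[f]]$cells
    map <- integer(0)
    if (length(cells) > 0L) {
      cand <- list()
      for (ci in seq_along(cells)) {
        cen <- cells[[ci]]$centroid
        for (tid in seq_along(tracks)) {
          if (is.null(tracks[[tid]])) next
          d <- sqrt(sum((cen - tracks[[tid]])^2))
          if (d <= max_disp_px) {
            cand[[length(cand) + 1L]] <- c(ci = ci, tid = tid, d = d)
          }
        }
      }
      assigned_cell <- integer(0); assigned_track <- integer(0)
      if (length(cand) > 0L) {
        cm <- do.call(rbind, cand)
        cm <- cm[order(cm[, "d"], cm[, "tid"]), , drop = FALSE]
        for (r in seq_len(nrow(cm))) {
          ci <- cm[r, "ci"]; tid <- cm[r, "tid"]
          if (ci %in% assigned_cell || tid %in% assigned_track) next
          assigned_cell <- c(assigned_cell, ci)
          assigned_track <- c(assigned_track, tid)
          map[as.character(cells[[ci]]$cell_id)] <- tid
          tracks[[tid]] <- cells[[ci]]$centroid
        }
      }
      for (ci in seq_along(cells)) {
        if (!(ci %in% assigned_cell)) {
          map[as.character(cells[[ci]]$cell_id)] <- next_id
          tracks[[next_id]] <- cells[[ci]]$centroid
          next_id <- next_id + 1L
        }
      }
    }
    maps[[f]] <- map
  }
  maps
}
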