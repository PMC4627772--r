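# Vectorised image-morphology primitives on plain numeric matrices,
# convention: m[row, col] = m[y, x], 0-based pixel centres documented at the
# user level, 1-based indexing internally (standard R).
#
# These exist because no image-processing package is available in the target
# environment; they are deliberately small, deterministic and fully tested.

# Shift a matrix by (dy, dx), filling vacated cells with `fill`.
shift_mat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
  ok_y <- ys >= 1 & ys <= nr; ok_x <- xs >= 1 & xs <= nc
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

NEIGH4 <- cbind(dy = c(-1L, 1L, 0L, 0L), dx = c(0L, 0L, -1L, 1L))
NEIGH8 <- cbind(dy = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
                dx = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))

#' Otsu's automatic intensity threshold
#'
#' Maximises between-class variance on a 256-bin histogram of the intensity
#' range. The returned threshold is in original intensity units; pixels
#' strictly above it are foreground. Binning on the normalised range makes
#' the induced foreground mask invariant under positive affine rescaling of
#' the input.
#'
#' @param x numeric matrix or vector of intensities.
#' @param n_bins number of histogram bins.
#' @return threshold (numeric scalar), or `NA` with a warning when the input
#'   is constant and no threshold exists.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) abort("no finite pixels")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    warning("constant image: no Otsu threshold exists")
    return(NA_real_)
  }
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1L)
  h <- tabulate(bin + 1L, nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)  # first max: deterministic tie-break
  lo + (k / n_bins) * (hi - lo)
}

# Connected-component labelling by iterative minimum-label propagation.
# Returns an integer matrix with labels 1..K in raster order of each
# component's first pixel; 0 = background.
label_components <- function(bw, connectivity = 4L) {
  stopifnot(is.matrix(bw))
  bw <- bw != 0
  if (!any(bw)) return(matrix(0L, nrow(bw), ncol(bw)))
  neigh <- if (connectivity == 8L) NEIGH8 else NEIGH4
  lab <- matrix(seq_along(bw), nrow(bw), ncol(bw))
  lab[!bw] <- Inf
  repeat {
    new <- lab
    for (i in seq_len(nrow(neigh))) {
      new <- pmin(new, shift_mat(lab, neigh[i, 1], neigh[i, 2], fill = Inf))
    }
    new[!bw] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!bw] <- 0
  ids <- unique(lab[lab > 0])           # raster order (column-major in R,
  ids <- ids[order(ids)]                # but stable and deterministic)
  out <- matrix(0L, nrow(bw), ncol(bw))
  for (k in seq_along(ids)) out[lab == ids[k]] <- k
  out
}

# Fill holes: foreground plus any background region not connected to the
# image border (4-connectivity background).
fill_holes <- function(bw) {
  bw <- bw != 0
  reach <- matrix(FALSE, nrow(bw), ncol(bw))
  border <- matrix(FALSE, nrow(bw), ncol(bw))
  border[1, ] <- TRUE; border[nrow(bw), ] <- TRUE
  border[, 1] <- TRUE; border[, ncol(bw)] <- TRUE
  reach <- border & !bw
  repeat {
    grown <- reach
    for (i in seq_len(nrow(NEIGH4))) {
      grown <- grown | shift_mat(reach, NEIGH4[i, 1], NEIGH4[i, 2],
                                 fill = FALSE)
    }
    grown <- grown & !bw
    if (identical(grown, reach)) break
    reach <- grown
  }
  bw | (!bw & !reach)
}

# Binary dilation by `r` pixels (8-connected structuring element applied r
# times, i.e. a (2r+1) square).
binary_dilate <- function(bw, r = 1L) {
  bw <- bw != 0
  for (j in seq_len(r)) {
    grown <- bw
    for (i in seq_len(nrow(NEIGH8))) {
      grown <- grown | shift_mat(bw, NEIGH8[i, 1], NEIGH8[i, 2], fill = FALSE)
    }
    bw <- grown
  }
  bw
}

# Separable Gaussian blur with edge replication; kernel radius 3*sigma.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_axis <- function(m, along_rows) {
    if (!along_rows) m <- t(m)
    n <- nrow(m)
    idx_pad <- c(rep(1L, r), seq_len(n), rep(n, r))
    mp <- m[idx_pad, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * mp[seq_len(n) + (i - 1L), , drop = FALSE]
    }
    if (!along_rows) t(out) else out
  }
  blur_axis(blur_axis(img, TRUE), FALSE)
}

# Multi-source geodesic region growing on a foreground mask (the
# distance-transform flavour of seeded watershed): every foreground pixel is
# assigned the label of the geodesically nearest seed; equidistant ties go to
# the lowest label. Deterministic Bellman-Ford style propagation.
seeded_grow <- function(fg, seeds) {
  stopifnot(is.matrix(fg), is.matrix(seeds), all(dim(fg) == dim(seeds)))
  fg <- fg != 0 | seeds > 0
  lab <- matrix(0, nrow(fg), ncol(fg))
  lab[] <- ifelse(seeds > 0, seeds, Inf)
  dist <- matrix(Inf, nrow(fg), ncol(fg))
  dist[seeds > 0] <- 0
  repeat {
    cand_d <- dist
    cand_l <- lab
    for (i in seq_len(nrow(NEIGH4))) {
      nd <- shift_mat(dist, NEIGH4[i, 1], NEIGH4[i, 2], fill = Inf) + 1
      nl <- shift_mat(lab,  NEIGH4[i, 1], NEIGH4[i, 2], fill = Inf)
      better <- nd < cand_d | (nd == cand_d & nl < cand_l)
      cand_d[better] <- nd[better]
      cand_l[better] <- nl[better]
    }
    upd <- fg & (cand_d < dist | (cand_d == dist & cand_l < lab))
    if (!any(upd)) break
    dist[upd] <- cand_d[upd]
    lab[upd] <- cand_l[upd]
  }
  lab[!fg | !is.finite(lab)] <- 0
  storage.mode(lab) <- "integer"
  lab
}
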