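#' Multi-channel, multi-frame image stack with physical calibration
#'
#' The in-memory container for time-lapse data: a 4-D array indexed
#' `[frame, channel, y, x]`, a channel-role map naming which channel is the
#' reporter and which the nuclear marker, the pixel size in micrometres and
#' the acquisition time of every frame in seconds.
#'
#' @param intensities numeric 4-D array `[frame, channel, y, x]`, finite and
#'   non-negative.
#' @param channel_roles named list/vector mapping roles to channel indices,
#'   e.g. `list(reporter = 1, nuclear_marker = 2)`. Must name at least the
#'   `reporter` channel.
#' @param pixel_size_um pixel size (micrometres), > 0.
#' @param frame_times_s acquisition times (s), strictly increasing, length
#'   equal to the frame axis.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(intensities, channel_roles, pixel_size_um,
                        frame_times_s) {
  if (!is.array(intensities) || length(dim(intensities)) != 4L) {
    abort("intensities must be a 4-D array [frame, channel, y, x]")
  }
  if (anyNA(intensities) || any(!is.finite(intensities)) ||
      any(intensities < 0)) {
    abort("intensities must be finite and >= 0")
  }
  if (is.null(channel_roles) || length(channel_roles) == 0L ||
      is.null(names(channel_roles)) || !("reporter" %in% names(channel_roles))) {
    abort("channel_roles must name the 'reporter' channel ",
          "(and usually 'nuclear_marker')")
  }
  roles <- lapply(channel_roles, as.integer)
  if (any(unlist(roles) < 1L | unlist(roles) > dim(intensities)[2])) {
    abort("channel_roles index outside channel axis")
  }
  check_scalar(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  if (!is.numeric(frame_times_s) ||
      length(frame_times_s) != dim(intensities)[1]) {
    abort("frame_times_s length must equal the number of frames")
  }
  if (length(frame_times_s) > 1L && any(diff(frame_times_s) <= 0)) {
    abort("frame_times_s must be strictly increasing")
  }
  structure(list(intensities = intensities, channel_roles = roles,
                 pixel_size_um = pixel_size_um,
                 frame_times_s = as.numeric(frame_times_s)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<image_stack> %d frame(s) x %d channel(s) x %d x %d px\n", d[1], d[2],
    d[3], d[4]))
  cat("  roles: ",
      paste(names(x$channel_roles), unlist(x$channel_roles),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat(sprintf("  pixel %.3g um, t = [%g, %g] s\n", x$pixel_size_um,
              x$frame_times_s[1], x$frame_times_s[length(x$frame_times_s)]))
  invisible(x)
}

# Extract one frame of one channel (by role name or index) as a matrix.
get_frame <- function(stack, frame, channel = "reporter") {
  stopifnot(inherits(stack, "image_stack"))
  ch <- if (is.character(channel)) {
    idx <- stack$channel_roles[[channel]]
    if (is.null(idx)) abort("unknown channel role: ", channel)
    idx
  } else as.integer(channel)
  matrix(stack$intensities[frame, ch, , ],
         nrow = dim(stack$intensities)[3])
}

#' Write an image stack to a multi-page TIFF
#'
#' Pages are ordered frame-major, channel within frame (frame 1 channel 1,
#' frame 1 channel 2, frame 2 channel 1, ...). Channel roles, pixel size and
#' frame times are stored as JSON in the ImageDescription tag and restored
#' by [read_stack()], so a write/read round trip preserves intensities
#' exactly (32-bit float samples) and all metadata.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$intensities)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (f in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      pages[[k]] <- get_frame(stack, f, ch)
      k <- k + 1L
    }
  }
  meta <- list(format = "nucytoloc-stack", version = 1L,
               n_frames = d[1], n_channels = d[2],
               channel_roles = stack$channel_roles,
               pixel_size_um = stack$pixel_size_um,
               frame_times_s = stack$frame_times_s,
               page_order = "frame_major")
  write_tiff_pages(path, pages,
                   description = jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                  digits = NA))
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' Reads files written by [write_stack()] (metadata in the first page's
#' ImageDescription) or plain grayscale TIFFs, in which case the metadata
#' must be supplied through `channel_roles`, `pixel_size_um`,
#' `frame_times_s` and `n_channels`.
#'
#' @param path TIFF file path.
#' @param channel_roles,pixel_size_um,frame_times_s,n_channels sidecar
#'   metadata for TIFFs without an embedded description; an error is raised
#'   when channel roles are available from neither source.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_roles = NULL, pixel_size_um = NULL,
                       frame_times_s = NULL, n_channels = NULL) {
  tf <- read_tiff_pages(path)
  meta <- NULL
  if (!is.null(tf$description) && nzchar(tf$description) &&
      startsWith(trimws(tf$description), "{")) {
    meta <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e) NULL)
  }
  if (!is.null(meta) && identical(meta$format, "nucytoloc-stack")) {
    n_ch <- meta$n_channels
    roles <- as.list(meta$channel_roles)
    px <- meta$pixel_size_um
    times <- meta$frame_times_s
  } else {
    n_ch <- n_channels
    roles <- channel_roles
    px <- pixel_size_um
    times <- frame_times_s
  }
  if (is.null(roles)) {
    abort("TIFF has no embedded channel metadata; supply channel_roles ",
          "(and n_channels, pixel_size_um, frame_times_s)")
  }
  if (is.null(n_ch)) n_ch <- length(roles)
  n_pages <- length(tf$pages)
  if (n_pages %% n_ch != 0) abort("page count not divisible by n_channels")
  n_frames <- n_pages / n_ch
  if (is.null(px)) px <- 1
  if (is.null(times)) times <- seq_len(n_frames) - 1
  h <- nrow(tf$pages[[1]]); wdt <- ncol(tf$pages[[1]])
  a <- array(0, dim = c(n_frames, n_ch, h, wdt))
  k <- 1L
  for (f in seq_len(n_frames)) {
    for (ch in seq_len(n_ch)) {
      a[f, ch, , ] <- tf$pages[[k]]
      k <- k + 1L
    }
  }
  image_stack(a, roles, px, times)
}

#' Maximum-intensity projection
#'
#' Collapses a stack of planes to a single frame by the per-pixel maximum,
#' as used to flatten confocal z-stacks before quantification.
#'
#' @param x a numeric 3-D array `[plane, y, x]`, a list of matrices, or an
#'   [image_stack()] (projected across frames for one channel).
#' @param channel for `image_stack` input, the channel role or index.
#' @return A numeric matrix.
#' @export
max_project <- function(x, channel = "reporter") {
  planes <- if (inherits(x, "image_stack")) {
    lapply(seq_len(dim(x$intensities)[1]), function(f) get_frame(x, f, channel))
  } else if (is.array(x) && length(dim(x)) == 3L) {
    lapply(seq_len(dim(x)[1]), function(i) matrix(x[i, , ], nrow = dim(x)[2]))
  } else if (is.list(x) && length(x) > 0L && all(vapply(x, is.matrix, TRUE))) {
    x
  } else {
    abort("max_project needs a 3-D array, list of matrices, or image_stack")
  }
  if (length(planes) == 0L) abort("no planes to project")
  Reduce(pmax, planes)
}
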