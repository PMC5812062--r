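# Hologram processing: background removal, numerical reconstruction,
# focus consolidation into a composite image.

#' Ensemble-averaged background frame
#'
#' Pixel-wise mean over a sequence of holograms. With many frames the
#' (moving) particle signatures average out, leaving the static intensity
#' nonuniformities (vignetting, beam profile) that are subtracted before
#' reconstruction.
#'
#' @param holograms a list of `hologram` objects, or of plain intensity
#'   matrices with identical dimensions; at least 2.
#' @return matrix of the mean intensity.
#' @export
ensemble_background <- function(holograms) {
  mats <- lapply(holograms, function(h)
    if (inherits(h, "hologram")) h$intensity else h)
  if (length(mats) < 2L)
    stop("at least 2 holograms are required to form an ensemble background")
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("holograms have mixed dimensions")
  Reduce(`+`, mats) / length(mats)
}

#' Background-subtract a hologram
#'
#' Division-free subtraction re-centred to the mean background level:
#' `h - background + mean(background)`. A frame equal to its background
#' maps to a constant; background nonuniformities (vignette, gradients)
#' present in the ensemble average are removed.
#'
#' @param h a `hologram` or intensity matrix.
#' @param background matrix from [ensemble_background()] with matching
#'   dimensions.
#' @return matrix of the filtered frame.
#' @export
normalize_hologram <- function(h, background) {
  m <- if (inherits(h, "hologram")) h$intensity else h
  if (!identical(dim(m), dim(background)))
    stop("hologram and background dimensions differ")
  m - background + mean(background)
}

#' Reconstruct a hologram into a stack of refocused planes
#'
#' Back-propagates the (background-subtracted) frame with the
#' angular-spectrum kernel to every retained depth given by
#' [plane_offsets()]: one amplitude plane per depth, with planes inside
#' the window margins excluded. In-focus particles appear as compact
#' low-amplitude silhouettes with sharp boundaries; out-of-focus particles
#' are diffuse.
#'
#' @param frame matrix with dimensions equal to `optics$sensor_px`
#'   (a `hologram` object is also accepted).
#' @param optics an [optical_config()].
#' @return an object of class `reconstruction_stack`: list with `z`
#'   (plane depths, m) and `planes` (list of amplitude matrices).
#' @export
reconstruct_stack <- function(frame, optics = NULL) {
  if (inherits(frame, "hologram")) {
    if (is.null(optics)) optics <- frame$optics
    frame <- frame$intensity
  }
  stopifnot(inherits(optics, "optical_config"))
  if (!identical(dim(frame), as.integer(optics$sensor_px)) &&
      !all(dim(frame) == optics$sensor_px))
    stop("frame dimensions do not match optics$sensor_px")
  zs <- plane_offsets(optics)
  ft <- stats::fft(frame + 0i)
  nr <- nrow(frame); nc <- ncol(frame)
  fx <- fft_freq(nc, optics$pixel_pitch)
  fy <- fft_freq(nr, optics$pixel_pitch)
  arg <- 1 / optics$wavelength^2 - outer(fy^2, fx^2, `+`)
  kz <- sqrt(pmax(arg, 0))
  ev <- arg < 0
  planes <- lapply(zs, function(z) {
    H <- exp(-2i * pi * z * kz)
    H[ev] <- 0 + 0i
    Mod(stats::fft(ft * H, inverse = TRUE)) / (nr * nc)
  })
  structure(list(z = zs, planes = planes, optics = optics),
            class = "reconstruction_stack")
}

#' @export
print.reconstruction_stack <- function(x, ...) {
  cat(sprintf("reconstruction stack: %d planes, z = %.1f .. %.1f mm (step %.0f um), %d x %d px\n",
              length(x$z), min(x$z) * 1e3, max(x$z) * 1e3,
              diff(x$z[1:2]) * 1e6, nrow(x$planes[[1]]), ncol(x$planes[[1]])))
  invisible(x)
}

#' Default focus threshold for consolidation
#'
#' In-focus opaque particles reconstruct as near-zero-amplitude
#' silhouettes against an order-unity background, while out-of-focus
#' diffraction rings only graze low amplitudes in a few pixels. The
#' default threshold is therefore a fixed fraction (0.35) of the robust
#' background level (median amplitude over a subsample of planes):
#' scale-free, and low enough that only in-focus silhouette pixels are
#' counted. A `mean - k * mad` rule is also available but sits too close
#' to the background in fringe-rich frames.
#'
#' @param stack a [reconstruct_stack()] result.
#' @param method `"fraction"` (default) or `"robust"` (`mean - k * mad`).
#' @param fraction background fraction for `"fraction"` (default 0.35).
#' @param k mad multiplier for `"robust"` (default 3).
#' @return scalar threshold.
#' @export
focus_threshold <- function(stack, method = c("fraction", "robust"),
                            fraction = 0.35, k = 3) {
  method <- match.arg(method)
  idx <- unique(round(seq(1, length(stack$planes), length.out = 5)))
  v <- unlist(lapply(stack$planes[idx], as.vector), use.names = FALSE)
  if (method == "fraction") fraction * stats::median(v)
  else mean(v) - k * stats::mad(v)
}

#' Consolidate a reconstruction stack into a composite image
#'
#' Splits the frame into `window_size` x `window_size` sub-windows. In
#' `"window"` mode each sub-window is taken from the plane with the
#' maximum count of pixels below `threshold` (the in-focus plane); ties
#' are broken by lower mean amplitude in the window, then by smaller z.
#' Sub-windows with no below-threshold pixel anywhere default to the first
#' plane. `"minimum"` mode is the simple per-pixel minimum over planes.
#'
#' Keeping windows small lets the chosen focus plane vary along large
#' particles that span several windows, preserving sharp edges in the
#' composite.
#'
#' @param stack a [reconstruct_stack()] result.
#' @param window_size sub-window side in pixels; must divide both image
#'   dimensions (default 128).
#' @param threshold focus threshold; defaults to [focus_threshold()].
#' @param mode `"window"` (sub-window focus selection) or `"minimum"`
#'   (per-pixel minimum fallback).
#' @return an object of class `composite_image`: list with `image`
#'   (matrix), `depth_index` (matrix of chosen plane indices per
#'   sub-window; NA in `"minimum"` mode), `z` (plane depths), `window_size`.
#' @export
consolidate <- function(stack, window_size = 128L, threshold = NULL,
                        mode = c("window", "minimum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "reconstruction_stack"))
  nr <- nrow(stack$planes[[1]]); nc <- ncol(stack$planes[[1]])
  if (mode == "minimum") {
    img <- Reduce(pmin, stack$planes)
    return(structure(list(image = img, depth_index = NULL, z = stack$z,
                          window_size = NA_integer_, optics = stack$optics),
                     class = "composite_image"))
  }
  nwr <- n_subwindows(nr, window_size)
  nwc <- n_subwindows(nc, window_size)
  if (is.null(threshold)) threshold <- focus_threshold(stack)
  np <- length(stack$planes)
  # per plane, per window: count of below-threshold pixels and mean amplitude
  counts <- array(0, c(nwr, nwc, np))
  means <- array(0, c(nwr, nwc, np))
  rg <- rep(seq_len(nwr), each = window_size)
  cg <- rep(seq_len(nwc), each = window_size)
  for (k in seq_len(np)) {
    P <- stack$planes[[k]]
    B <- rowsum((P < threshold) + 0, rg)
    counts[, , k] <- t(rowsum(t(B), cg))
    M <- rowsum(P, rg)
    means[, , k] <- t(rowsum(t(M), cg)) / window_size^2
  }
  depth_index <- matrix(1L, nwr, nwc)
  for (i in seq_len(nwr)) for (j in seq_len(nwc)) {
    cn <- counts[i, j, ]
    if (max(cn) == 0) { depth_index[i, j] <- 1L; next }
    best <- which(cn == max(cn))
    if (length(best) > 1L) {
      mn <- means[i, j, best]
      best <- best[mn == min(mn)]   # lower mean amplitude, then smaller z
    }
    depth_index[i, j] <- best[1L]
  }
  img <- matrix(0, nr, nc)
  for (i in seq_len(nwr)) for (j in seq_len(nwc)) {
    rr <- ((i - 1) * window_size + 1):(i * window_size)
    cc <- ((j - 1) * window_size + 1):(j * window_size)
    img[rr, cc] <- stack$planes[[depth_index[i, j]]][rr, cc]
  }
  structure(list(image = img, depth_index = depth_index, z = stack$z,
                 window_size = as.integer(window_size),
                 threshold = threshold, optics = stack$optics),
            class = "composite_image")
}

#' @export
print.composite_image <- function(x, ...) {
  cat(sprintf("composite image %d x %d px", nrow(x$image), ncol(x$image)))
  if (!is.null(x$depth_index))
    cat(sprintf(", %d x %d sub-windows of %d px",
                nrow(x$depth_index), ncol(x$depth_index), x$window_size))
  cat("\n")
  invisible(x)
}
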