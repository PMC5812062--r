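# Composite-image segmentation: smoothing, thresholding, 8-connected
# component extraction with filled ("hole-closed") pixel sets.

#' 2 x 2 box low-pass filter
#'
#' Smallest-kernel smoothing applied to the composite before segmentation:
#' each output pixel is the mean of a 2 x 2 neighbourhood (replicated at
#' the image border, so the mean intensity is preserved and a constant
#' image is unchanged). A single unit impulse spreads to four pixels of
#' amplitude 0.25.
#'
#' @param image numeric matrix.
#' @return smoothed matrix of the same dimensions.
#' @export
lowpass_2x2 <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  r2 <- c(2:nr, nr)            # replicate last row/col
  c2 <- c(2:nc, nc)
  (image + image[r2, ] + image[, c2] + image[r2, c2]) / 4
}

# 8-connected labelling: EBImage::bwlabel (4-connected) plus a pass that
# merges labels touching diagonally.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  p1 <- rbind(cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
              cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  p1 <- p1[p1[, 1] > 0 & p1[, 2] > 0 & p1[, 1] != p1[, 2], , drop = FALSE]
  if (nrow(p1) == 0L) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(p1))) {
    a <- find(p1[k, 1]); b <- find(p1[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Default segmentation threshold (Otsu)
#'
#' @param image numeric matrix (composite amplitude image).
#' @return scalar threshold from Otsu's method on the image histogram.
#' @export
otsu_threshold <- function(image) {
  mx <- max(image)
  if (mx <= 0) return(0)
  as.numeric(EBImage::otsu(EBImage::Image(image / mx), range = c(0, 1))) * mx
}

#' Segment a composite image into particle regions
#'
#' Binary-thresholds the image (particles are darker than the threshold)
#' and extracts 8-connected components; components smaller than `min_px`
#' pixels are discarded as unreliable. For each region the raw pixel set
#' and the "filled" pixel set (interior holes closed, via
#' `EBImage::fillHull`) are both recorded; filled area is the basis of the
#' equivalent spherical diameter.
#'
#' @param composite a [consolidate()] result, or a plain numeric matrix.
#' @param threshold intensity threshold; pixels strictly below it are
#'   foreground. The default is 0.45 x the median image value: composites
#'   have an order-unity background with near-zero particle silhouettes,
#'   and a background-relative cut excludes the surrounding diffraction
#'   halo that a histogram-based (Otsu) threshold absorbs into the
#'   particle. Pass [otsu_threshold()] explicitly to use Otsu.
#' @param min_px minimum component size in pixels (default 5).
#' @return list of regions (class `particle_regions`); each region is a
#'   list with `px` and `filled_px` (2-column row/col matrices), `dims`.
#'   An empty list is a valid result. Attribute `threshold` records the
#'   value used.
#' @export
segment_composite <- function(composite, threshold = NULL, min_px = 5L) {
  img <- if (inherits(composite, "composite_image")) composite$image else composite
  if (is.null(threshold)) threshold <- 0.45 * stats::median(img)
  if (threshold < min(img) || threshold > max(img) + 1e-12)
    if (threshold > max(img)) threshold <- max(img)  # clamp into range
  mask <- img < threshold
  lab <- label8(mask)
  out <- regions_from_labels(lab, min_px)
  attr(out, "threshold") <- threshold
  attr(out, "composite") <- if (inherits(composite, "composite_image")) composite else NULL
  out
}

# build region list from a label matrix, dropping components < min_px
regions_from_labels <- function(lab, min_px = 5L) {
  nl <- max(lab)
  dims <- dim(lab)
  regions <- list()
  if (nl > 0L) {
    filled_lab <- EBImage::fillHull(lab)
    filled_lab <- matrix(as.integer(filled_lab), dims[1], dims[2])
    idx <- which(lab > 0)
    sp <- split(idx, lab[idx])
    fidx <- which(filled_lab > 0)
    fsp <- split(fidx, filled_lab[fidx])
    for (nm in names(sp)) {
      px_i <- sp[[nm]]
      if (length(px_i) < min_px) next
      px <- cbind(row = (px_i - 1L) %% dims[1] + 1L,
                  col = (px_i - 1L) %/% dims[1] + 1L)
      f_i <- fsp[[nm]]
      fpx <- cbind(row = (f_i - 1L) %% dims[1] + 1L,
                   col = (f_i - 1L) %/% dims[1] + 1L)
      regions[[length(regions) + 1L]] <-
        list(px = px, filled_px = fpx, dims = dims)
    }
  }
  structure(regions, class = "particle_regions")
}

# boundary pixels of a region: members with fewer than 8 in-region neighbours
region_boundary <- function(region) {
  px <- region$px
  nr2 <- region$dims[1] + 2
  key <- px[, 1] + nr2 * as.numeric(px[, 2])
  inside <- rep(TRUE, nrow(px))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nk <- (px[, 1] + dr) + nr2 * as.numeric(px[, 2] + dc)
    inside <- inside & (nk %in% key)
  }
  b <- px[!inside, , drop = FALSE]
  if (nrow(b) == 0L) px else b
}
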