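# Depth-binned particle statistics: sub-sampling, concentration profiles,
# aspect-ratio breakdowns, log-binned size distributions with segmented
# Junge slopes, depth-resolved orientation PDFs.

#' Sub-sample a hologram sequence to avoid repeat counting
#'
#' At a 15 Hz frame rate and 5-6 cm/s descent the platform advances only
#' 3.3-4 mm between frames, less than the 9.4 mm field of view, so
#' consecutive frames image overlapping volumes. Every third hologram is
#' kept on downcasts and every second on (faster) upcasts, starting at the
#' first.
#'
#' @param holograms ordered sequence (list, vector or data frame).
#' @param cast `"down"` (stride 3) or `"up"` (stride 2).
#' @return the sub-sampled sequence, same type as the input.
#' @export
subsample_cast <- function(holograms, cast = c("down", "up")) {
  cast <- match.arg(cast)
  stride <- if (cast == "down") 3L else 2L
  n <- if (is.data.frame(holograms)) nrow(holograms) else length(holograms)
  keep <- seq(1L, n, by = stride)
  if (is.data.frame(holograms)) holograms[keep, , drop = FALSE]
  else holograms[keep]
}

#' Depth-binned particle concentration profile
#'
#' `Pv = P / (n V)` per depth bin: particle count over (number of
#' holograms in the bin x sample volume per hologram).
#'
#' @param particles particle data frame (needs `depth_m`).
#' @param holograms data frame with one row per processed hologram and a
#'   `depth_m` column (used for the per-bin hologram count `n`).
#' @param bin_height bin height (m), default 0.2.
#' @param volume_ml sample volume per hologram (mL), default 3.53.
#' @return data frame with `depth_m` (bin centre), `P` (particles), `n`
#'   (holograms), `Pv` (particles/mL); bins without holograms are omitted.
#' @export
concentration_profile <- function(particles, holograms, bin_height = 0.2,
                                  volume_ml = 3.53) {
  stopifnot("depth_m" %in% names(particles), "depth_m" %in% names(holograms),
            volume_ml > 0)
  hb <- floor(holograms$depth_m / bin_height)
  pb <- floor(particles$depth_m / bin_height)
  ub <- sort(unique(hb))
  P <- vapply(ub, function(k) sum(pb == k), numeric(1))
  n <- vapply(ub, function(k) sum(hb == k), numeric(1))
  data.frame(depth_m = (ub + 0.5) * bin_height, P = P, n = n,
             Pv = P / (n * volume_ml))
}

#' Aspect-ratio-resolved concentration breakdown
#'
#' Particles are grouped into aspect-ratio classes (defaults `(1,3]`,
#' `(3,6]`, `(6,10]`, `(10,Inf)`) and depth bins; each cell is the
#' percentage of that class's total count found in that depth bin, so
#' every class column sums to 100% over depth. Classes with no particles
#' at all give an all-zero, flagged column.
#'
#' @param particles particle data frame (needs `depth_m`,
#'   `aspect_ratio`).
#' @param bin_height depth bin height (m).
#' @param r_breaks aspect-ratio class breaks (left-open).
#' @return list with `percent` (depth-bin x class matrix), `counts`,
#'   `depth_m` (bin centres), `empty_class` (logical per class).
#' @export
concentration_by_aspect <- function(particles, bin_height = 0.2,
                                    r_breaks = c(1, 3, 6, 10, Inf)) {
  stopifnot(all(c("depth_m", "aspect_ratio") %in% names(particles)))
  cls <- cut(particles$aspect_ratio, breaks = r_breaks, right = TRUE)
  b <- floor(particles$depth_m / bin_height)
  ub <- sort(unique(b))
  counts <- vapply(levels(cls), function(lv)
    vapply(ub, function(k) sum(b == k & cls == lv, na.rm = TRUE),
           numeric(1)), numeric(length(ub)))
  counts <- matrix(counts, nrow = length(ub),
                   dimnames = list(NULL, levels(cls)))
  tot <- colSums(counts)
  pct <- sweep(counts, 2, ifelse(tot == 0, 1, tot), "/") * 100
  list(percent = pct, counts = counts, depth_m = (ub + 0.5) * bin_height,
       empty_class = tot == 0)
}

#' Log-binned particle size distribution
#'
#' Counts of equivalent spherical diameter `D` in logarithmically spaced
#' bins over `range` (default 11.6-1000 um, the resolvable span at 5 px
#' minimum area and the sensor field of view), divided by the sampled
#' volume and by each bin's width: densities in L^-1 um^-1. Particles
#' outside the range are excluded and their count logged.
#'
#' @param particles particle data frame (needs `equiv_diam_um`), or a
#'   numeric vector of diameters (um).
#' @param volume_l total sampled volume (L).
#' @param n_bins number of bins (default 24).
#' @param range `c(Dmin, Dmax)` (um).
#' @return object of class `size_distribution`: `breaks`, `centers`
#'   (geometric), `width`, `counts`, `density` (L^-1 um^-1),
#'   `n_excluded`, `volume_l`.
#' @export
build_psd <- function(particles, volume_l, n_bins = 24L,
                      range = c(11.6, 1000)) {
  D <- if (is.data.frame(particles)) particles$equiv_diam_um else particles
  stopifnot(volume_l > 0, n_bins >= 2L, range[1] > 0, range[1] < range[2])
  breaks <- exp(seq(log(range[1]), log(range[2]), length.out = n_bins + 1L))
  inside <- D >= range[1] & D <= range[2]
  n_excluded <- sum(!inside)
  cnt <- graphics::hist(D[inside], breaks = breaks, plot = FALSE)$counts
  width <- diff(breaks)
  structure(list(breaks = breaks, centers = sqrt(breaks[-1] * breaks[-(n_bins + 1L)]),
                 width = width, counts = cnt,
                 density = cnt / (volume_l * width),
                 n_excluded = n_excluded, volume_l = volume_l),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("size distribution: %d bins over %.1f-%.0f um, %d particles (%d excluded), %.3g L\n",
              length(x$counts), min(x$breaks), max(x$breaks),
              sum(x$counts), x$n_excluded, x$volume_l))
  invisible(x)
}

#' @export
plot.size_distribution <- function(x, ...) {
  keep <- x$density > 0
  graphics::plot(x$centers[keep], x$density[keep], log = "xy",
                 xlab = "D (um)", ylab = "n(D)  (L^-1 um^-1)", ...)
}

#' Fit a Junge (power-law) slope to a size distribution
#'
#' Least-squares slope of `log10 n(D)` against `log10 D` over the occupied
#' bins lying fully inside `size_range` (bins straddling a range edge -
#' e.g. the knee of a segmented distribution - are excluded, since they
#' mix both regimes), returned as the positive exponent `gamma` of
#' `n(D) = n0 (D / D0)^-gamma`. At least 4 occupied bins are required,
#' otherwise a no-fit result is returned.
#'
#' @param psd a [build_psd()] result.
#' @param size_range `c(Dmin, Dmax)` (um) restricting the fit; default the
#'   whole distribution.
#' @return object of class `junge_fit`: `gamma`, `n0` (density at `D0`),
#'   `D0` (geometric mid-range), `n_bins`, `ok`.
#' @export
fit_junge <- function(psd, size_range = NULL) {
  stopifnot(inherits(psd, "size_distribution"))
  if (is.null(size_range)) size_range <- range(psd$breaks)
  nb <- length(psd$counts)
  sel <- psd$breaks[-(nb + 1L)] >= size_range[1] * (1 - 1e-9) &
    psd$breaks[-1] <= size_range[2] * (1 + 1e-9) &
    psd$density > 0
  if (sum(sel) < 4L)
    return(structure(list(gamma = NA_real_, n0 = NA_real_, D0 = NA_real_,
                          n_bins = sum(sel), ok = FALSE),
                     class = "junge_fit"))
  D0 <- sqrt(size_range[1] * size_range[2])
  lx <- log10(psd$centers[sel] / D0)
  ly <- log10(psd$density[sel])
  co <- stats::coef(stats::lm(ly ~ lx))
  structure(list(gamma = -co[[2]], n0 = 10^co[[1]], D0 = D0,
                 n_bins = sum(sel), ok = TRUE),
            class = "junge_fit")
}

#' @export
print.junge_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("Junge fit: gamma = %.3f (n0 = %.3g L^-1 um^-1 at D0 = %.1f um, %d bins)\n",
                x$gamma, x$n0, x$D0, x$n_bins))
  else
    cat(sprintf("Junge fit: insufficient occupied bins (%d < 4)\n", x$n_bins))
  invisible(x)
}

#' Two-segment Junge fit around a distribution knee
#'
#' Field size distributions often show two power-law ranges separated by a
#' knee (around 250 um here: shear coagulation below, settling-dominated
#' dynamics above). Fits [fit_junge()] separately below and above the
#' knee.
#'
#' @param psd a [build_psd()] result.
#' @param knee_um knee diameter (um), default 250.
#' @param lower_min_um lower edge of the shallow segment (um), default 50
#'   (the segment below is noise-prone).
#' @return list with elements `below` and `above`, each a `junge_fit`.
#' @export
fit_junge_segmented <- function(psd, knee_um = 250, lower_min_um = 50) {
  list(below = fit_junge(psd, c(lower_min_um, knee_um)),
       above = fit_junge(psd, c(knee_um, max(psd$breaks))))
}

#' Depth-resolved orientation probability density map
#'
#' Per depth bin, the histogram of pitch-corrected orientation angles over
#' nine 20-degree bins spanning (-90, +90], normalized to a density per
#' degree (so each depth bin's PDF integrates to 1). Only particles with
#' aspect ratio above `r_min` (default 3) enter, since near-round
#' particles carry no meaningful orientation. Depth bins with fewer than
#' `low_count` particles are flagged: a couple of randomly oriented
#' particles can produce spuriously high PDF values there.
#'
#' @param particles particle data frame (needs `depth_m`, `theta_deg`,
#'   `aspect_ratio`).
#' @param bin_height depth bin height (m).
#' @param r_min minimum aspect ratio (exclusive), default 3.
#' @param low_count low-count flag threshold (default 30).
#' @return object of class `orientation_pdf_map`: data frame with
#'   `depth_m`, `angle_deg` (bin centre), `pdf` (per degree), `count`,
#'   `low_count_flag`.
#' @export
orientation_pdf <- function(particles, bin_height = 3, r_min = 3,
                            low_count = 30L) {
  stopifnot(all(c("depth_m", "theta_deg", "aspect_ratio") %in%
                  names(particles)))
  sel <- particles$aspect_ratio > r_min
  p <- particles[sel, , drop = FALSE]
  edges <- seq(-90, 90, by = 20)
  centers <- (edges[-1] + edges[-10]) / 2
  b <- floor(p$depth_m / bin_height)
  ub <- sort(unique(b))
  rows <- lapply(ub, function(k) {
    th <- p$theta_deg[b == k]
    cnt <- vapply(seq_len(9), function(i)
      sum(th > edges[i] & th <= edges[i + 1]), numeric(1))
    tot <- sum(cnt)
    data.frame(depth_m = (k + 0.5) * bin_height, angle_deg = centers,
               pdf = if (tot > 0) cnt / (tot * 20) else rep(0, 9),
               count = cnt, low_count_flag = tot < low_count)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(depth_m = numeric(0), angle_deg = numeric(0),
               pdf = numeric(0), count = numeric(0),
               low_count_flag = logical(0))
  class(out) <- c("orientation_pdf_map", "data.frame")
  attr(out, "r_min") <- r_min
  out
}
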