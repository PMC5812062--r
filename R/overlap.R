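# Separation of particles overlapping in projection, using the per-pixel
# amplitude-versus-depth information retained in the reconstruction stack.

# local contrast profile of a region: per-plane variance of the amplitude
# over the region dilated by a few pixels. At the focus plane the
# neighbourhood is maximally bimodal (dark silhouette against bright
# background); defocus blurs both ways and lowers the variance. Unlike
# mean darkness, this also localizes large opaque particles whose shadow
# interior stays dark over many planes.
region_focus_profile <- function(region, stack, dilate = 3L) {
  m <- matrix(FALSE, region$dims[1], region$dims[2])
  m[region$px] <- TRUE
  md <- EBImage::dilate(m, EBImage::makeBrush(2L * dilate + 1L, "box"))
  idx <- which(as.logical(md))
  vapply(stack$planes, function(P) stats::var(P[idx]), numeric(1))
}

# mean darkness profile (used for reporting; focus selection uses the
# contrast profile)
region_depth_profile <- function(region, stack) {
  idx <- region$px[, 1] + nrow(stack$planes[[1]]) * (region$px[, 2] - 1L)
  vapply(stack$planes, function(P) mean(P[idx]), numeric(1))
}

#' Best-focus depth of a region
#'
#' The plane maximizing the local amplitude contrast (variance over the
#' region dilated by a few pixels): opaque particles reconstruct as dark,
#' sharp-edged silhouettes against a bright background exactly in focus,
#' so the in-focus plane has the most bimodal neighbourhood histogram.
#'
#' @param region a segmented region.
#' @param stack the [reconstruct_stack()] the region was segmented from.
#' @return list with `z` (m) and `plane` (index).
#' @export
region_depth <- function(region, stack) {
  prof <- region_focus_profile(region, stack)
  k <- which.max(prof)
  list(z = stack$z[k], plane = k)
}

# re-extract a region from its own best-focus plane: the sub-window
# composite may have rendered it from a nearby (slightly defocused) plane,
# biasing the outline. Re-segments the bounding box at the focus plane and
# keeps every component overlapping the original pixels (so re-split chain
# cells stay together); falls back to the original region if nothing
# segments there.
refine_region <- function(region, stack, seg_threshold, min_px = 5L) {
  zd <- region_depth(region, stack)
  P <- stack$planes[[zd$plane]]
  nr <- region$dims[1]; nc <- region$dims[2]
  rr <- range(region$px[, 1]); cr <- range(region$px[, 2])
  rr <- c(max(1L, rr[1] - 4L), min(nr, rr[2] + 4L))
  cr <- c(max(1L, cr[1] - 4L), min(nc, cr[2] + 4L))
  sub <- matrix(FALSE, nr, nc)
  crop <- lowpass_2x2(P[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE])
  sub[rr[1]:rr[2], cr[1]:cr[2]] <- crop < seg_threshold
  regs <- regions_from_labels(label8(sub), min_px)
  if (length(regs) == 0L) return(list(region = region, z = zd))
  key0 <- region$px[, 1] + nr * as.numeric(region$px[, 2] - 1L)
  ov <- vapply(regs, function(rg) {
    key <- rg$px[, 1] + nr * as.numeric(rg$px[, 2] - 1L)
    sum(key %in% key0)
  }, numeric(1))
  keep <- which(ov >= min_px)
  if (length(keep) == 0L) return(list(region = region, z = zd))
  if (length(keep) == 1L) {
    out <- regs[[keep]]
  } else {
    px <- do.call(rbind, lapply(regs[keep], `[[`, "px"))
    m <- matrix(FALSE, nr, nc)
    m[px] <- TRUE
    filled <- EBImage::fillHull(m)
    f_i <- which(as.logical(filled))
    out <- list(px = px,
                filled_px = cbind(row = (f_i - 1L) %% nr + 1L,
                                  col = (f_i - 1L) %/% nr + 1L),
                dims = region$dims)
  }
  out$chain_flag <- isTRUE(region$chain_flag)
  list(region = out, z = zd)
}

# local maxima of a focus (contrast) profile, separated by >= min_sep
# planes, strongest first
profile_maxima <- function(prof, min_sep = 4L) {
  n <- length(prof)
  cand <- which(vapply(seq_len(n), function(i) {
    lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
    prof[i] == max(prof[lo:hi]) && any(prof[lo:hi] < prof[i])
  }, logical(1)))
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[order(-prof[cand])]
  keep <- integer(0)
  for (k in cand)
    if (all(abs(k - keep) >= min_sep)) keep <- c(keep, k)
  keep
}

# local variance map with a (2k+1)^2 box, via integral images; NA border
box_variance <- function(M, k = 4L) {
  n1 <- 2L * k + 1L
  pad <- function(A) {
    B <- matrix(0, nrow(A) + 1L, ncol(A) + 1L)
    B[-1, -1] <- A
    t(apply(apply(B, 2, cumsum), 1, cumsum))
  }
  S <- pad(M); S2 <- pad(M^2)
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(NA_real_, nr, nc)
  if (nr < n1 || nc < n1) return(out)
  i <- (k + 1L):(nr - k); j <- (k + 1L):(nc - k)
  sums <- S[i + k + 1L, j + k + 1L] - S[i - k, j + k + 1L] -
    S[i + k + 1L, j - k] + S[i - k, j - k]
  sums2 <- S2[i + k + 1L, j + k + 1L] - S2[i - k, j + k + 1L] -
    S2[i + k + 1L, j - k] + S2[i - k, j - k]
  out[i, j] <- sums2 / n1^2 - (sums / n1^2)^2
  out
}

# candidate focus depths of an overlap region: per-pixel argmax of the
# local contrast across planes (each pixel "votes" for the plane where its
# neighbourhood is sharpest), histogram smoothed and searched for
# well-separated modes. Two genuinely superposed particles produce two
# modes of comparable strength (each contributes its own pixel share), so
# a second mode must gather at least `min_votes_frac` of the strongest
# mode's votes; single-depth regions show only low-vote fringe side-modes.
split_depth_candidates <- function(region, stack, min_sep = 4L,
                                   min_votes_frac = 0.5) {
  nr <- region$dims[1]; nc <- region$dims[2]
  rr <- range(region$px[, 1]); cr <- range(region$px[, 2])
  rr <- c(max(1L, rr[1] - 5L), min(nr, rr[2] + 5L))
  cr <- c(max(1L, cr[1] - 5L), min(nc, cr[2] + 5L))
  pr <- region$px[, 1] - rr[1] + 1L
  pc <- region$px[, 2] - cr[1] + 1L
  cnr <- rr[2] - rr[1] + 1L
  ii <- pr + cnr * (pc - 1L)
  V <- vapply(stack$planes, function(P) {
    box_variance(P[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE])[ii]
  }, numeric(length(ii)))
  am <- apply(V, 1, function(x) if (all(is.na(x))) NA_integer_ else which.max(x))
  am <- am[!is.na(am)]
  if (length(am) == 0L) return(integer(0))
  tb <- tabulate(am, length(stack$planes))
  sm <- as.numeric(stats::filter(tb, rep(1, 3)))
  sm[is.na(sm)] <- 0
  peaks <- profile_maxima(sm, min_sep = min_sep)
  if (length(peaks) == 0L) return(integer(0))
  peaks[sm[peaks] >= min_votes_frac * sm[peaks[1]] & sm[peaks] >= 5]
}

#' Detect and separate overlapping particles
#'
#' Overlapping particles merge into one region in the composite and betray
#' themselves by a high ratio of convex-hull area to filled pixel area.
#' Candidates with `hull/filled <= hull_ratio_threshold` pass through
#' unchanged. For flagged candidates the per-pixel sharpness-versus-depth
#' behaviour over the region is inspected (each pixel votes for the plane
#' where its neighbourhood contrast peaks): two well-separated vote modes
#' mean two particles at distinct depths, which are re-segmented at their
#' own focus planes and returned as two records; otherwise the candidate
#' is discarded (a logged outcome, not an error).
#'
#' @param region a segmented region (the overlap candidate).
#' @param stack the [reconstruct_stack()] it came from.
#' @param pitch_um pixel pitch (um/px).
#' @param hull_ratio_threshold hull/filled ratio above which a region is
#'   treated as a potential overlap (default 1.5).
#' @param seg_threshold threshold for re-segmentation at the two focus
#'   planes; defaults to the amplitude threshold of the original
#'   segmentation if supplied.
#' @param min_px minimum region size on re-segmentation.
#' @return list with `records` (data frame of 0, 1 or 2 measured
#'   particles, with `z_mm` and `overlap_flag` set) and `status`
#'   (`"kept"`, `"split"` or `"discarded"`).
#' @export
resolve_overlaps <- function(region, stack, pitch_um = 4.59,
                             hull_ratio_threshold = 1.5,
                             seg_threshold = NULL, min_px = 5L) {
  rec <- measure_region(region, pitch_um)
  ratio <- rec$hull_area_um2 / rec$filled_area_um2
  if (ratio <= hull_ratio_threshold) {
    rec$z_mm <- region_depth(region, stack)$z * 1e3
    rec$overlap_flag <- FALSE
    return(list(records = rec, status = "kept"))
  }
  dips <- split_depth_candidates(region, stack)
  if (length(dips) < 2L)
    return(list(records = rec[0, ], status = "discarded"))
  dips <- sort(dips[1:2])
  if (is.null(seg_threshold)) {
    dark <- region_depth_profile(region, stack)
    seg_threshold <- mean(dark) - 2 * stats::sd(dark)
  }
  nr <- region$dims[1]; nc <- region$dims[2]
  rr <- range(region$px[, 1]); cr <- range(region$px[, 2])
  rr <- c(max(1L, rr[1] - 2L), min(nr, rr[2] + 2L))
  cr <- c(max(1L, cr[1] - 2L), min(nc, cr[2] + 2L))
  cand_key <- region$px[, 1] + nr * as.numeric(region$px[, 2] - 1L)
  recs <- list()
  for (k in dips) {
    P <- stack$planes[[k]]
    sub <- matrix(FALSE, nr, nc)
    crop <- lowpass_2x2(P[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE])
    sub[rr[1]:rr[2], cr[1]:cr[2]] <- crop < seg_threshold
    lab <- label8(sub)
    regs <- regions_from_labels(lab, min_px)
    if (length(regs) == 0L) next
    ov <- vapply(regs, function(rg) {
      key <- rg$px[, 1] + nr * as.numeric(rg$px[, 2] - 1L)
      sum(key %in% cand_key)
    }, numeric(1))
    if (max(ov) < min_px) next
    best <- regs[[which.max(ov)]]
    r1 <- measure_region(best, pitch_um)
    r1$z_mm <- stack$z[k] * 1e3
    r1$overlap_flag <- TRUE
    recs[[length(recs) + 1L]] <- r1
  }
  if (length(recs) == 2L)
    list(records = do.call(rbind, recs), status = "split")
  else
    list(records = rec[0, ], status = "discarded")
}
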