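# Per-particle morphometry: chain re-connection, farthest-pair major axis,
# aspect ratio, orientation, convex hull, curvature (length
# underestimation) flag.

#' Re-connect diatom chains split into discrete cells
#'
#' Narrow cell linkages often segment above threshold, so a chain appears
#' as several discrete regions. Regions whose minimum boundary-to-boundary
#' separation is at most `max_gap_um` are merged transitively (union-find
#' semantics, so the merge order is irrelevant) and subsequently treated
#' as one particle. The gap is measured as the count of empty pixels
#' between boundary pixel centres (centre distance minus one pixel), so
#' cells separated by a single empty pixel merge at `max_gap >= 1` pixel
#' and `max_gap = 0` leaves any disjoint regions untouched.
#'
#' @param regions a `particle_regions` list from [segment_composite()].
#' @param max_gap_um maximum gap to bridge (um); default 30.
#' @param pitch_um pixel pitch (um/px).
#' @return a `particle_regions` list with merged regions; merged regions
#'   get `chain_flag = TRUE`.
#' @export
reconnect_chains <- function(regions, max_gap_um = 30, pitch_um = 4.59) {
  stopifnot(max_gap_um >= 0)
  n <- length(regions)
  if (n < 2L) return(regions)
  bnds <- lapply(regions, region_boundary)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    gap_px <- min_cross_dist(bnds[[i]], bnds[[j]]) - 1
    if (gap_px * pitch_um <= max_gap_um) {
      a <- find(i); b <- find(j)
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (g in unique(root)) {
    members <- which(root == g)
    if (length(members) == 1L) {
      r <- regions[[members]]
      r$chain_flag <- isTRUE(r$chain_flag)
      out[[length(out) + 1L]] <- r
    } else {
      px <- do.call(rbind, lapply(regions[members], `[[`, "px"))
      dims <- regions[[members[1]]]$dims
      m <- matrix(FALSE, dims[1], dims[2])
      m[px] <- TRUE
      filled <- EBImage::fillHull(m)
      fpx_i <- which(as.logical(filled))
      fpx <- cbind(row = (fpx_i - 1L) %% dims[1] + 1L,
                   col = (fpx_i - 1L) %/% dims[1] + 1L)
      out[[length(out) + 1L]] <-
        list(px = px, filled_px = fpx, dims = dims, chain_flag = TRUE)
    }
  }
  structure(out, class = "particle_regions")
}

# minimum pairwise euclidean distance between two pixel sets (px units)
min_cross_dist <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  sqrt(min(d2))
}

#' Measure morphometry and orientation of one region
#'
#' The major axis is the segment between the two mutually farthest
#' boundary pixels (the "extrema line"); the minor axis is the maximal
#' extent perpendicular to it; the aspect ratio is their quotient. The
#' filled area `A` (interior holes included) gives the equivalent
#' spherical diameter `D = sqrt(4 A / pi)`. The raw orientation is the
#' angle of the extrema line to the image horizontal, positive for a
#' positive slope with the origin at the bottom-left image corner, on
#' (-90, +90]; it still needs platform-pitch correction
#' ([correct_orientation()]).
#'
#' @param region one region from [segment_composite()] /
#'   [reconnect_chains()] (>= 5 px).
#' @param pitch_um pixel pitch (um/px).
#' @return one-row data frame: `x_um, y_um` (centroid, bottom-left
#'   origin), `area_px`, `filled_area_um2`, `equiv_diam_um`, `major_um`,
#'   `minor_um`, `aspect_ratio`, `theta_deg` (raw), `hull_area_um2`,
#'   `chain_flag`, `degenerate_flag`.
#' @export
measure_region <- function(region, pitch_um = 4.59) {
  px <- region$px
  stopifnot(nrow(px) >= 5L)
  nr <- region$dims[1]
  x <- px[, 2]          # px units; orientation uses y up = bottom-left origin
  y <- nr - px[, 1]
  pts <- cbind(x, y)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  # farthest pair over hull vertices; the direction is the circular mean
  # over all near-maximal pairs (within 1.5 px of the longest chord),
  # which suppresses single-pixel digitization jitter at the tips
  d2 <- outer(hp[, 1], hp[, 1], `-`)^2 + outer(hp[, 2], hp[, 2], `-`)^2
  dlen <- sqrt(max(d2))
  degenerate <- FALSE
  if (dlen < 1e-9) {               # single-pixel-cluster guard
    u <- c(1, 0); dlen <- 0
  } else {
    sel <- which(sqrt(d2) >= dlen - 1.5, arr.ind = TRUE)
    sel <- sel[sel[, 1] < sel[, 2], , drop = FALSE]
    angs <- atan2(hp[sel[, 2], 2] - hp[sel[, 1], 2],
                  hp[sel[, 2], 1] - hp[sel[, 1], 1])
    a2 <- atan2(mean(sin(2 * angs)), mean(cos(2 * angs))) / 2
    u <- c(cos(a2), sin(a2))
  }
  theta <- wrap_angle(rad2deg(atan2(u[2], u[1])))
  major_px <- dlen + 1             # pixel extent, not centre-to-centre
  nvec <- c(-u[2], u[1])
  tproj <- pts[, 1] * nvec[1] + pts[, 2] * nvec[2]
  minor_px <- diff(range(tproj)) + 1
  if (minor_px <= 1) { minor_px <- 1; degenerate <- TRUE }
  area_px <- nrow(px)
  filled_px <- nrow(region$filled_px)
  A <- filled_px * pitch_um^2
  hull_px <- hull_pixel_area(hp)
  data.frame(
    x_um = mean(x - 0.5) * pitch_um,
    y_um = mean(y + 0.5) * pitch_um,
    area_px = area_px,
    filled_area_um2 = A,
    equiv_diam_um = sqrt(4 * A / pi),
    major_um = major_px * pitch_um,
    minor_um = minor_px * pitch_um,
    aspect_ratio = major_px / minor_px,
    theta_deg = theta,
    hull_area_um2 = hull_px * pitch_um^2,
    chain_flag = isTRUE(region$chain_flag),
    degenerate_flag = degenerate)
}

# pixel-equivalent area of the convex hull: shoelace area of the vertex
# polygon plus a lattice (Pick-style) boundary correction, comparable to a
# filled pixel count
hull_pixel_area <- function(hp) {
  n <- nrow(hp)
  if (n < 3L) return(max(n, 1))
  xs <- hp[, 1]; ys <- hp[, 2]
  j <- c(2:n, 1)
  A <- abs(sum(xs * ys[j] - xs[j] * ys)) / 2
  P <- sum(sqrt((xs[j] - xs)^2 + (ys[j] - ys)^2))
  A + P / 2 + 1
}

#' Correct a measured orientation for platform pitch
#'
#' The profiling package tilts as it descends; the tilt-sensor pitch
#' reading is subtracted from the raw image-plane angle and the result is
#' wrapped back into (-90, +90].
#'
#' @param raw_theta raw orientation(s), degrees.
#' @param pitch platform pitch (deg); must satisfy `|pitch| < 45`.
#' @return corrected orientation(s) in (-90, +90].
#' @export
correct_orientation <- function(raw_theta, pitch) {
  if (any(abs(pitch) >= 45))
    stop("|pitch| must be < 45 degrees")
  wrap_angle(raw_theta - pitch)
}

#' Flag curved particles whose straight-line length is an underestimate
#'
#' The major-axis length of a curved chain (straight line between
#' extrema) underestimates its true arc length. The region is thinned to
#' its skeleton (Zhang-Suen) and the geodesic diameter along the skeleton
#' is compared with the extrema chord: when the skeleton path exceeds the
#' chord by more than `tol` (default 10%) the region is flagged. The
#' measured `major_um` is never altered - the flag only marks the
#' underestimate.
#'
#' @param region a region (>= 5 px).
#' @param tol relative excess of skeleton length over chord that triggers
#'   the flag (default 0.1).
#' @return list with `flag`, `skeleton_len_px`, `chord_px`.
#' @export
flag_curvature <- function(region, tol = 0.1) {
  px <- region$px
  m <- matrix(FALSE, region$dims[1], region$dims[2])
  m[px] <- TRUE
  sk <- thin_mask(m)
  sd <- skeleton_diameter(sk)
  # both lengths are centreline quantities: the geodesic along the
  # skeleton versus the straight chord between its own endpoints, so tip
  # erosion by thinning cancels out of the ratio
  list(flag = is.finite(sd$len) && sd$chord > 0 &&
         sd$len > (1 + tol) * sd$chord,
       skeleton_len_px = sd$len, chord_px = sd$chord)
}

# Zhang-Suen morphological thinning to a 1-px skeleton
thin_mask <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  M <- matrix(FALSE, nr + 2, nc + 2)
  M[2:(nr + 1), 2:(nc + 1)] <- m
  nbr <- function(M, dr, dc) {
    R <- nrow(M); C <- ncol(M)
    M[(1 + dr):(R - 2 + dr) + 1, (1 + dc):(C - 2 + dc) + 1]
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      P <- M[2:(nr + 1), 2:(nc + 1)]
      p2 <- nbr(M, -1, 0); p3 <- nbr(M, -1, 1); p4 <- nbr(M, 0, 1)
      p5 <- nbr(M, 1, 1);  p6 <- nbr(M, 1, 0);  p7 <- nbr(M, 1, -1)
      p8 <- nbr(M, 0, -1); p9 <- nbr(M, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- Reduce(`+`, lapply(1:8, function(i)
        (!seqs[[i]]) & seqs[[i + 1]]))
      if (phase == 1) {
        cond <- P & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- P & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        changed <- TRUE
        P[cond] <- FALSE
        M[2:(nr + 1), 2:(nc + 1)] <- P
      }
    }
    if (!changed) break
  }
  M[2:(nr + 1), 2:(nc + 1)]
}

# geodesic diameter along a skeleton (8-connected, diagonal weight sqrt(2));
# two-sweep Dijkstra, valid for the (near-tree) skeleton graphs produced
# by thinning
skeleton_diameter <- function(sk) {
  idx <- which(sk)
  n <- length(idx)
  if (n == 0L) return(list(len = NA_real_, chord = NA_real_))
  if (n == 1L) return(list(len = 0, chord = 0))
  nr <- nrow(sk)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  key <- rr + (nr + 2) * as.numeric(cc)
  lookup <- seq_len(n)
  names(lookup) <- as.character(key)
  adj <- vector("list", n)
  wts <- vector("list", n)
  for (k in seq_len(n)) {
    nb <- integer(0); w <- numeric(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      j <- lookup[as.character((rr[k] + dr) + (nr + 2) * as.numeric(cc[k] + dc))]
      if (!is.na(j)) { nb <- c(nb, j); w <- c(w, sqrt(dr^2 + dc^2)) }
    }
    adj[[k]] <- nb; wts[[k]] <- w
  }
  dijkstra <- function(s) {
    dist <- rep(Inf, n); dist[s] <- 0
    done <- rep(FALSE, n)
    for (it in seq_len(n)) {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      nb <- adj[[u]]
      nd <- dist[u] + wts[[u]]
      imp <- nd < dist[nb]
      dist[nb[imp]] <- nd[imp]
    }
    dist
  }
  d1 <- dijkstra(1L)
  d1[!is.finite(d1)] <- -1
  a <- which.max(d1)
  d2 <- dijkstra(a)
  d2[!is.finite(d2)] <- -1
  b <- which.max(d2)
  list(len = d2[b],
       chord = sqrt((rr[a] - rr[b])^2 + (cc[a] - cc[b])^2))
}
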