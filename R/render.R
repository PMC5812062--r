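# Synthetic hologram rendering: opaque amplitude masks propagated to the
# sensor with the angular-spectrum kernel, multiplicative superposition.

#' Rasterize a rotated ellipse
#'
#' Pixel-centre inclusion test for an ellipse with semi-axes `a`, `b`
#' centred at `(cx, cy)` (metres, origin at the bottom-left image corner)
#' and in-plane angle `angle_deg` to the horizontal.
#'
#' @param dims `c(nrow, ncol)` of the target image.
#' @param cx,cy centre (m).
#' @param a,b semi-major and semi-minor axes (m).
#' @param angle_deg in-plane angle (deg).
#' @param optics an [optical_config()] (pixel pitch).
#' @return logical matrix of the mask.
#' @export
ellipse_mask <- function(dims, cx, cy, a, b, angle_deg, optics) {
  p <- optics$pixel_pitch
  nr <- dims[1]; nc <- dims[2]
  # bounding box in pixels to keep the test local
  half <- max(a, b)
  c0 <- max(1L, floor((cx - half) / p)); c1 <- min(nc, ceiling((cx + half) / p) + 1L)
  r_y0 <- max(0, cy - half); r_y1 <- min(nr * p, cy + half)
  r0 <- max(1L, floor((nr * p - r_y1) / p)); r1 <- min(nr, ceiling((nr * p - r_y0) / p) + 1L)
  m <- matrix(FALSE, nr, nc)
  if (c0 > c1 || r0 > r1) return(m)
  cols <- c0:c1; rows <- r0:r1
  xs <- (cols - 0.5) * p
  ys <- (nr - rows + 0.5) * p
  th <- deg2rad(angle_deg)
  dx <- outer(rep(1, length(rows)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(cols)))
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  m[rows, cols] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

# mask of one scene particle (spheroid or chain) at its projected geometry
particle_mask <- function(p, dims, optics) {
  # projected major length of a 3D line of length L at (theta_p, theta_a)
  tp <- deg2rad(p$theta_p); ta <- deg2rad(p$theta_a)
  proj <- sqrt(sin(tp)^2 * cos(ta)^2 + cos(tp)^2)
  Lp <- max(p$major * proj, p$minor)   # projection never thinner than the cell width
  ang <- if (proj < 1e-9) 0 else p$theta_2d
  if (identical(p$shape, "chain") && p$cells > 1L) {
    k <- p$cells
    gap <- p$gap_px * optics$pixel_pitch
    cell <- (Lp - (k - 1) * gap) / k
    if (cell <= 0) cell <- Lp / k
    th <- deg2rad(ang)
    offs <- (seq_len(k) - (k + 1) / 2) * (cell + gap)
    m <- matrix(FALSE, dims[1], dims[2])
    for (o in offs) {
      m <- m | ellipse_mask(dims, p$x + o * cos(th), p$y + o * sin(th),
                            cell / 2, p$minor / 2, ang, optics)
    }
    m
  } else {
    ellipse_mask(dims, p$x, p$y, Lp / 2, p$minor / 2, ang, optics)
  }
}

#' Render an in-line hologram of a synthetic scene
#'
#' Each particle is an opaque amplitude mask at its depth plane. A unit
#' plane wave enters at the far window; at each occupied depth (processed
#' far to near) the field is propagated with the angular-spectrum kernel
#' and multiplied by the particle transmission (0 inside particles), then
#' propagated to the sensor. The recorded frame is the intensity
#' `|U|^2` plus optional additive Gaussian sensor noise and an optional
#' smooth background, normalized to \[0, 1\]. An empty noiseless scene
#' yields a uniform unit-intensity frame.
#'
#' @param scene a `holo_scene` from [make_scene()] (or a compatible data
#'   frame with columns `x, y, z, major, minor, theta_p, theta_a,
#'   theta_2d, shape, cells, gap_px`).
#' @param optics an [optical_config()].
#' @param noise_sd standard deviation of additive Gaussian sensor noise
#'   (intensity units).
#' @param background optional matrix (or function of `(nrow, ncol)`)
#'   added to the intensity before normalization, to exercise background
#'   subtraction.
#' @param seed seed for the noise draw.
#' @param timestamp,depth,pitch,cast acquisition metadata forwarded to
#'   [hologram()].
#' @return a `hologram` object: list with `intensity` (matrix in \[0,1\]),
#'   `optics`, and metadata fields `timestamp`, `depth`, `pitch`, `cast`.
#' @export
render_hologram <- function(scene, optics = attr(scene, "optics"),
                            noise_sd = 0, background = NULL, seed = NULL,
                            timestamp = 0, depth = 0, pitch = 0,
                            cast = "down") {
  if (is.null(optics)) optics <- optical_config()
  stopifnot(inherits(optics, "optical_config"), noise_sd >= 0)
  dims <- optics$sensor_px
  fov_min <- min(dims) * optics$pixel_pitch
  if (nrow(scene) > 0) {
    too_big <- scene$major >= fov_min
    if (any(too_big))
      stop("particle mask larger than sensor for particle id ",
           paste(scene$id[too_big], collapse = ", "))
  }
  field <- matrix(1 + 0i, dims[1], dims[2])
  if (nrow(scene) > 0) {
    ord <- order(-scene$z)                       # far window first
    zs <- scene$z[ord]
    cur_z <- zs[1]
    for (i in seq_along(ord)) {
      p <- scene[ord[i], , drop = FALSE]
      if (p$z < cur_z - 1e-12) {
        field <- propagate_field(field, cur_z - p$z, optics)
        cur_z <- p$z
      }
      field[particle_mask(as.list(p), dims, optics)] <- 0 + 0i
    }
    field <- propagate_field(field, cur_z, optics)
  }
  I <- Mod(field)^2
  if (!is.null(background)) {
    bg <- if (is.function(background)) background(dims[1], dims[2]) else background
    I <- I + bg
  }
  if (noise_sd > 0)
    I <- I + with_seed(seed, matrix(stats::rnorm(length(I), 0, noise_sd),
                                    dims[1], dims[2]))
  I <- pmin(pmax(I, 0), 1)   # clip: undisturbed beam = unit intensity
  hologram(I, optics, timestamp = timestamp, depth = depth,
           pitch = pitch, cast = cast)
}

#' Construct a hologram object
#'
#' @param intensity matrix of recorded intensity in \[0, 1\].
#' @param optics an [optical_config()]; dimensions must match.
#' @param timestamp acquisition time (s).
#' @param depth depth of the centre of the field of view (m, >= 0).
#' @param pitch platform pitch at acquisition (deg).
#' @param cast `"down"` or `"up"`.
#' @return an object of class `hologram`.
#' @export
hologram <- function(intensity, optics, timestamp = 0, depth = 0,
                     pitch = 0, cast = c("down", "up")) {
  cast <- match.arg(cast)
  stopifnot(inherits(optics, "optical_config"), depth >= 0,
            nrow(intensity) == optics$sensor_px[1],
            ncol(intensity) == optics$sensor_px[2])
  structure(list(intensity = intensity, optics = optics,
                 timestamp = timestamp, depth = depth, pitch = pitch,
                 cast = cast),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("hologram %d x %d px, depth %.2f m, pitch %.1f deg, %scast, t = %.3f s\n",
              nrow(x$intensity), ncol(x$intensity), x$depth, x$pitch,
              x$cast, x$timestamp))
  invisible(x)
}
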