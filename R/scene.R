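#' Orientation models for synthetic scenes
#'
#' Three ways to assign 3D orientations (polar angle `theta_p` from the
#' vertical image axis, azimuth `theta_a` in the horizontal plane measured
#' from the image x-axis) to generated particles:
#'
#' * `orientation_uniform3d()`: both angles drawn uniformly
#'   (`theta_p ~ U(0, 180)`, `theta_a ~ U(0, 180)`), the
#'   random-orientation null model whose 2D projection is biased towards
#'   steep apparent angles (note this is angle-uniform, not
#'   sphere-isotropic: an isotropic draw projects to an exactly uniform
#'   apparent angle by rotational symmetry);
#' * `orientation_jeffery(S)`: in-plane angles drawn from the Jeffery-orbit
#'   occupancy distribution for each particle's own aspect ratio
#'   (`theta_a = 0`, so the projected angle equals the drawn orbit angle);
#' * `orientation_fixed(theta_p, theta_a)`: a degenerate distribution, every
#'   particle identical.
#'
#' @param S shear rate for the Jeffery model (1/s); the occupancy
#'   distribution itself is independent of `S`.
#' @param theta_p polar angle in degrees, in (0, 180).
#' @param theta_a azimuth in degrees, in \[0, 180).
#' @return a list describing the model, for use in [scene_config()].
#' @name orientation_models
NULL

#' @rdname orientation_models
#' @export
orientation_uniform3d <- function() list(type = "uniform3D")

#' @rdname orientation_models
#' @export
orientation_jeffery <- function(S = 0.1) list(type = "jeffery", S = S)

#' @rdname orientation_models
#' @export
orientation_fixed <- function(theta_p, theta_a) {
  stopifnot(theta_p > 0, theta_p < 180, theta_a >= 0, theta_a < 180)
  list(type = "fixed", theta_p = theta_p, theta_a = theta_a)
}

#' Configuration of a synthetic particle scene
#'
#' Scenes emulate a sparse 3D field of opaque spheroidal (optionally
#' chain-forming) particles: the number of particles is Poisson with mean
#' `concentration * volume`, equivalent diameters follow a Junge power law
#' with exponent `-junge_gamma` on `size_range`, aspect ratios are uniform
#' on `aspect_range`, and orientations follow `orientation_model`.
#'
#' @param concentration particles per mL.
#' @param junge_gamma power-law (Junge) size-distribution exponent, > 0.
#' @param size_range equivalent-diameter range (m), `c(Dmin, Dmax)`.
#' @param orientation_model one of the [orientation_models].
#' @param aspect_range aspect-ratio range, uniform draw, min >= 1.
#' @param chain_fraction fraction of particles rendered as chains of
#'   discrete cells instead of single spheroids.
#' @param chain_cells range of the number of cells per chain.
#' @param chain_gap_px inter-cell gap in pixels (kept small so the chain
#'   re-connection step can rejoin the cells).
#' @param seed integer seed; scene generation is reproducible given the seed.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(concentration = 20,
                         junge_gamma = 1.8,
                         size_range = c(20e-6, 400e-6),
                         orientation_model = orientation_uniform3d(),
                         aspect_range = c(1, 8),
                         chain_fraction = 0,
                         chain_cells = c(3L, 8L),
                         chain_gap_px = 1,
                         seed = NULL) {
  stopifnot(concentration > 0, junge_gamma > 0,
            size_range[1] > 0, size_range[1] < size_range[2],
            aspect_range[1] >= 1, aspect_range[1] <= aspect_range[2],
            chain_fraction >= 0, chain_fraction <= 1, chain_gap_px >= 0)
  structure(list(concentration = concentration, junge_gamma = junge_gamma,
                 size_range = size_range,
                 orientation_model = orientation_model,
                 aspect_range = aspect_range,
                 chain_fraction = chain_fraction,
                 chain_cells = as.integer(chain_cells),
                 chain_gap_px = chain_gap_px, seed = seed),
            class = "scene_config")
}

#' Sample equivalent diameters from a Junge power law
#'
#' Inverse-CDF sampling from the density `n(D) proportional to D^-gamma`
#' truncated to `range`.
#'
#' @param n number of draws.
#' @param gamma power-law exponent (> 0).
#' @param range `c(Dmin, Dmax)`, any consistent length unit.
#' @return numeric vector of diameters in the units of `range`.
#' @export
sample_junge <- function(n, gamma, range) {
  stopifnot(n >= 0, gamma > 0, range[1] > 0, range[1] < range[2])
  if (n == 0) return(numeric(0))
  u <- stats::runif(n)
  if (abs(gamma - 1) < 1e-12) {
    exp(log(range[1]) + u * (log(range[2]) - log(range[1])))
  } else {
    a <- 1 - gamma
    (range[1]^a + u * (range[2]^a - range[1]^a))^(1 / a)
  }
}

#' Generate a synthetic particle scene
#'
#' Draws a Poisson number of particles (mean `concentration x volume`),
#' sizes from the configured Junge law, aspect ratios and orientations from
#' the configured models, and uniform positions such that every particle
#' lies fully inside the imaged volume. If the volume cannot accommodate
#' even the smallest particle, an explicit empty scene is returned.
#'
#' @param cfg a [scene_config()].
#' @param optics an [optical_config()]; defines the field of view and path.
#' @return a data frame of class `holo_scene`, one particle per row:
#'   `id, x, y, z` (m; `z` measured from the sensor-side window),
#'   `major, minor` (m), `theta_p, theta_a` (deg), `theta_2d` (deg,
#'   projected in-plane angle), `shape` ("spheroid" or "chain"),
#'   `cells`, `gap_px`.
#' @export
make_scene <- function(cfg, optics = optical_config()) {
  stopifnot(inherits(cfg, "scene_config"), inherits(optics, "optical_config"))
  with_seed(cfg$seed, {
    vol_ml <- hologram_volume_ml(optics)
    n <- stats::rpois(1L, cfg$concentration * vol_ml)
    fov <- optics$sensor_px * optics$pixel_pitch   # (rows->y, cols->x)
    zr <- c(optics$window_margin + optics$z_step,
            optics$path_length - optics$window_margin)
    empty <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        z = numeric(0), major = numeric(0), minor = numeric(0),
                        theta_p = numeric(0), theta_a = numeric(0),
                        theta_2d = numeric(0), shape = character(0),
                        cells = integer(0), gap_px = numeric(0))
    class(empty) <- c("holo_scene", "data.frame")
    attr(empty, "optics") <- optics
    if (n == 0) return(empty)

    D <- sample_junge(n, cfg$junge_gamma, cfg$size_range)
    r <- stats::runif(n, cfg$aspect_range[1], cfg$aspect_range[2])
    major <- D * sqrt(r)
    minor <- D / sqrt(r)

    # drop particles the field of view cannot hold (fully-inside constraint)
    fits <- major < min(fov[1], fov[2])
    if (!any(fits)) {
      warning("volume too small to place any particle; returning empty scene")
      return(empty)
    }
    D <- D[fits]; r <- r[fits]; major <- major[fits]; minor <- minor[fits]
    n <- sum(fits)

    om <- cfg$orientation_model
    if (om$type == "uniform3D") {
      # uniform in BOTH angles (the random-orientation null used for the
      # projection-bias argument): over-weights near-vertical directions
      # relative to an isotropic (sphere-uniform) draw, for which the
      # projected angle would be exactly uniform by symmetry
      theta_p <- stats::runif(n, 1e-6, 180 - 1e-6)
      theta_a <- stats::runif(n, 0, 180)
    } else if (om$type == "jeffery") {
      th <- sample_jeffery_angles(n, r = r)
      theta_p <- 90 - th      # in-plane: projected angle == orbit angle
      theta_a <- rep(0, n)
      theta_p[theta_p <= 0] <- theta_p[theta_p <= 0] + 180
      theta_p <- pmin(pmax(theta_p, 1e-6), 180 - 1e-6)
    } else if (om$type == "fixed") {
      theta_p <- rep(om$theta_p, n)
      theta_a <- rep(om$theta_a, n)
    } else stop("unknown orientation model: ", om$type)

    x <- stats::runif(n, major / 2, fov[2] - major / 2)
    y <- stats::runif(n, major / 2, fov[1] - major / 2)
    z <- stats::runif(n, zr[1], zr[2])

    is_chain <- stats::runif(n) < cfg$chain_fraction
    cells <- ifelse(is_chain,
                    sample(seq(cfg$chain_cells[1], cfg$chain_cells[2]),
                           n, replace = TRUE), 1L)

    out <- data.frame(id = seq_len(n), x = x, y = y, z = z,
                      major = major, minor = minor,
                      theta_p = theta_p, theta_a = theta_a,
                      theta_2d = project_to_2d(theta_p, theta_a),
                      shape = ifelse(is_chain, "chain", "spheroid"),
                      cells = as.integer(cells),
                      gap_px = ifelse(is_chain, cfg$chain_gap_px, 0))
    class(out) <- c("holo_scene", "data.frame")
    attr(out, "optics") <- optics
    out
  })
}

#' Project a 3D line orientation onto the image plane
#'
#' For a line at polar angle `theta_p` (degrees from the vertical image
#' axis) and azimuth `theta_a` (degrees from the image x-axis in the
#' horizontal plane), the projected in-plane angle is
#' `theta = atan(cot(theta_p) / cos(theta_a))`, wrapped to (-90, +90].
#' A line with `theta_a = 90` and `theta_p != 90` lies in the vertical
#' plane perpendicular to the image and projects to a point/vertical; this
#' degenerate case is signalled as an error of class
#' `holoshear_undefined_projection`.
#'
#' Projection is biased: under uniform 3D orientations the projected-angle
#' density increases towards +/-90 degrees, so 2D projections
#' under-represent truly horizontal particles.
#'
#' @param theta_p polar angle(s), degrees in (0, 180).
#' @param theta_a azimuth(s), degrees in \[0, 180).
#' @return projected angle(s) in degrees, in (-90, +90].
#' @examples
#' project_to_2d(45, 60)   # 63.43 deg
#' project_to_2d(30, 0)    # 60 deg (in-plane line at 90 - theta_p)
#' @export
project_to_2d <- function(theta_p, theta_a) {
  stopifnot(length(theta_p) == length(theta_a) ||
              length(theta_p) == 1L || length(theta_a) == 1L)
  n <- max(length(theta_p), length(theta_a))
  theta_p <- rep_len(theta_p, n); theta_a <- rep_len(theta_a, n)
  if (any(theta_p <= 0 | theta_p >= 180) || any(theta_a < 0 | theta_a >= 180))
    stop("theta_p must lie in (0, 180), theta_a in [0, 180)")
  bad <- abs(theta_a - 90) < 1e-12 & abs(theta_p - 90) >= 1e-12
  if (any(bad)) {
    cond <- structure(
      class = c("holoshear_undefined_projection", "error", "condition"),
      list(message = "projection undefined: theta_a = 90 with theta_p != 90 (line projects to a point)",
           call = sys.call(-1)))
    stop(cond)
  }
  co <- cos(deg2rad(theta_a))
  ct <- 1 / tan(deg2rad(theta_p))
  out <- numeric(n)
  horiz <- abs(theta_p - 90) < 1e-12
  out[horiz] <- 0
  out[!horiz] <- rad2deg(atan(ct[!horiz] / co[!horiz]))
  wrap_angle(out)
}
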