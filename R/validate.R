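# Ground-truth round-trip validation: render a known scene, run the full
# processing chain, match recovered particles back to the truth.

#' Build a sparse, non-overlapping test scene
#'
#' Places `n` elongated spheroids with in-plane orientations at uniform
#' random angles, depths uniform over the retained planes, and centres
#' rejection-sampled so that projected silhouettes cannot overlap
#' (pairwise centre separation of at least the sum of the semi-major axes
#' plus `margin`).
#'
#' @param n number of particles.
#' @param optics an [optical_config()].
#' @param major_range major-axis length range (m).
#' @param aspect_range aspect-ratio range.
#' @param margin extra pairwise clearance (m).
#' @param seed integer seed.
#' @return a `holo_scene` data frame (in-plane orientations:
#'   `theta_a = 0`, `theta_2d = 90 - theta_p`).
#' @export
make_test_scene <- function(n, optics = optical_config(),
                            major_range = c(250e-6, 450e-6),
                            aspect_range = c(3, 8),
                            margin = 150e-6, seed = NULL) {
  with_seed(seed, {
    fov <- optics$sensor_px * optics$pixel_pitch
    zr <- c(optics$window_margin + optics$z_step + 1e-3,
            optics$path_length - optics$window_margin - 1e-3)
    major <- stats::runif(n, major_range[1], major_range[2])
    r <- stats::runif(n, aspect_range[1], aspect_range[2])
    minor <- major / r
    th <- stats::runif(n, -89, 89)
    xs <- numeric(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      for (attempt in 1:500) {
        x <- stats::runif(1, major[i] / 2 + margin, fov[2] - major[i] / 2 - margin)
        y <- stats::runif(1, major[i] / 2 + margin, fov[1] - major[i] / 2 - margin)
        if (i == 1L) break
        sep <- sqrt((x - xs[1:(i - 1)])^2 + (y - ys[1:(i - 1)])^2)
        if (all(sep > (major[i] + major[1:(i - 1)]) / 2 + margin)) break
      }
      xs[i] <- x; ys[i] <- y
    }
    out <- data.frame(id = seq_len(n), x = xs, y = ys,
                      z = stats::runif(n, zr[1], zr[2]),
                      major = major, minor = minor,
                      theta_p = 90 - th, theta_a = 0, theta_2d = th,
                      shape = "spheroid", cells = 1L, gap_px = 0)
    class(out) <- c("holo_scene", "data.frame")
    attr(out, "optics") <- optics
    out
  })
}

#' Render-process round trip against ground truth
#'
#' Renders a [make_test_scene()] hologram, runs [process_hologram()], and
#' matches each recovered particle to the nearest true particle by
#' centroid. The returned table carries per-particle truth and
#' measurement for depth, orientation and aspect ratio: the basis of the
#' depth-localization and orientation-recovery accuracy claims.
#'
#' @param seed integer seed.
#' @param optics an [optical_config()]; smaller sensors keep the trial
#'   fast without changing the per-pixel physics.
#' @param n_particles particles per scene.
#' @param window_size consolidation window (px).
#' @param ... passed to [make_test_scene()].
#' @return data frame with one row per true particle: `true_z_mm,
#'   true_theta, true_r, meas_z_mm, meas_theta, meas_r, matched`
#'   (plus `n_found`, `n_true`, `n_discarded` as attributes).
#' @export
roundtrip_trial <- function(seed, optics = optical_config(sensor_px = c(256L, 256L)),
                            n_particles = 2L, window_size = 64L, ...) {
  scene <- make_test_scene(n_particles, optics, seed = seed, ...)
  h <- render_hologram(scene, optics)
  found <- process_hologram(h, window_size = window_size)
  pitch_um <- optics$pixel_pitch * 1e6
  out <- data.frame(true_z_mm = scene$z * 1e3, true_theta = scene$theta_2d,
                    true_r = scene$major / scene$minor,
                    meas_z_mm = NA_real_, meas_theta = NA_real_,
                    meas_r = NA_real_, matched = FALSE)
  if (nrow(found) > 0) {
    for (i in seq_len(nrow(scene))) {
      dx <- found$x_um - scene$x[i] * 1e6
      dy <- found$y_um - scene$y[i] * 1e6
      d <- sqrt(dx^2 + dy^2)
      j <- which.min(d)
      if (d[j] < scene$major[i] * 1e6 / 2) {
        out$meas_z_mm[i] <- found$z_mm[j]
        out$meas_theta[i] <- found$theta_deg[j]
        out$meas_r[i] <- found$aspect_ratio[j]
        out$matched[i] <- TRUE
      }
    }
  }
  attr(out, "n_found") <- nrow(found)
  attr(out, "n_true") <- nrow(scene)
  attr(out, "n_discarded") <- attr(found, "n_discarded")
  out
}

#' Angular difference modulo 180 degrees
#'
#' @param a,b angles in degrees.
#' @return absolute difference folded into \[0, 90\].
#' @export
angle_diff <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  pmin(d, 180 - d)
}
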