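# Plain-text/TIFF interchange: holograms with sidecar metadata, particle
# lists, velocity and density series, scene ground truth.

#' Write / read a hologram as 16-bit TIFF with sidecar metadata
#'
#' The intensity frame is stored as a 16-bit grayscale TIFF; acquisition
#' metadata (timestamp, depth, pitch, cast) goes to a plain-text sidecar
#' `<path>.meta` with `key: value` lines.
#'
#' @param h a `hologram` object.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_hologram <- function(h, path) {
  stopifnot(inherits(h, "hologram"))
  tiff::writeTIFF(pmin(pmax(h$intensity, 0), 1), path, bits.per.sample = 16L)
  meta <- c(sprintf("timestamp: %.6f", h$timestamp),
            sprintf("depth: %.6f", h$depth),
            sprintf("pitch: %.6f", h$pitch),
            sprintf("cast: %s", h$cast))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_hologram
#' @param optics an [optical_config()] matching the stored frame.
#' @export
read_hologram <- function(path, optics) {
  m <- tiff::readTIFF(path)
  meta_path <- paste0(path, ".meta")
  ts <- 0; depth <- 0; pitch <- 0; cast <- "down"
  if (file.exists(meta_path)) {
    kv <- strsplit(readLines(meta_path), ":\\s*")
    for (p in kv) {
      switch(p[1],
             timestamp = ts <- as.numeric(p[2]),
             depth = depth <- as.numeric(p[2]),
             pitch = pitch <- as.numeric(p[2]),
             cast = cast <- p[2])
    }
  }
  hologram(m, optics, timestamp = ts, depth = depth, pitch = pitch,
           cast = cast)
}

#' Write / read a particle list CSV
#'
#' One header row; columns exactly `id, hologram_id, depth_m, x_um, y_um,
#' z_mm, area_px, filled_area_um2, equiv_diam_um, major_um, minor_um,
#' aspect_ratio, theta_deg, hull_area_um2, chain_flag, overlap_flag,
#' curvature_flag`.
#'
#' @param particles particle data frame from [process_hologram()].
#' @param path CSV path.
#' @return `path` invisibly; `read_particles` returns the data frame.
#' @export
write_particles <- function(particles, path) {
  cols <- particle_columns()
  stopifnot(all(cols %in% names(particles)))
  utils::write.csv(particles[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  utils::read.csv(path)
}

#' Write / read scene ground truth CSV
#'
#' One particle per row: `id, x, y, z, major, minor, theta_p, theta_a`
#' (SI units / degrees), plus shape columns.
#'
#' @param scene a `holo_scene` from [make_scene()].
#' @param path CSV path.
#' @export
write_scene <- function(scene, path) {
  utils::write.csv(as.data.frame(scene), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("holo_scene", "data.frame")
  out
}

#' Write / read a velocity series CSV
#'
#' Columns `t_s, u_ms, v_ms, w_ms, pitch_deg, depth_m`.
#'
#' @param series data frame with the columns above.
#' @param path CSV path.
#' @export
write_velocity <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_velocity
#' @export
read_velocity <- function(path) utils::read.csv(path)

#' Write / read a density profile CSV (`depth_m, sigma_t`)
#'
#' @param density data frame with `depth_m`, `sigma_t`.
#' @param path CSV path.
#' @export
write_density <- function(density, path) {
  utils::write.csv(density, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) utils::read.csv(path)
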