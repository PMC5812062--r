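#' Process one hologram into a particle list
#'
#' Runs the full chain on a single frame: optional background subtraction,
#' angular-spectrum reconstruction at every retained plane, sub-window
#' focus consolidation, 2 x 2 low-pass smoothing, binary segmentation into
#' 8-connected regions of at least `min_px` pixels, chain re-connection,
#' overlap detection/separation, morphometry, best-focus depth assignment,
#' platform-pitch orientation correction and the curvature
#' (length-underestimate) flag.
#'
#' @param h a `hologram` object (see [hologram()], [render_hologram()]).
#' @param background optional background matrix from
#'   [ensemble_background()].
#' @param window_size consolidation sub-window side (px); must divide the
#'   sensor dimensions. Default 128.
#' @param seg_threshold segmentation threshold on the smoothed composite;
#'   default Otsu.
#' @param min_px minimum particle size in pixels (default 5).
#' @param max_gap_um chain re-connection gap (um).
#' @param hull_ratio_threshold overlap-candidate hull/filled ratio.
#' @param hologram_id identifier copied into the records.
#' @return data frame with one row per retained particle and columns
#'   `id, hologram_id, depth_m, x_um, y_um, z_mm, area_px,
#'   filled_area_um2, equiv_diam_um, major_um, minor_um, aspect_ratio,
#'   theta_deg, hull_area_um2, chain_flag, overlap_flag, curvature_flag`.
#'   `theta_deg` is pitch-corrected. Attribute `n_discarded` counts
#'   overlap candidates eliminated from the analysis.
#' @export
process_hologram <- function(h, background = NULL, window_size = 128L,
                             seg_threshold = NULL, min_px = 5L,
                             max_gap_um = 30, hull_ratio_threshold = 1.5,
                             hologram_id = 1L) {
  stopifnot(inherits(h, "hologram"))
  optics <- h$optics
  frame <- if (!is.null(background)) normalize_hologram(h, background)
           else h$intensity
  stack <- reconstruct_stack(frame, optics)
  comp <- consolidate(stack, window_size = window_size)
  img <- lowpass_2x2(comp$image)
  pitch_um <- optics$pixel_pitch * 1e6
  regions <- segment_composite(img, threshold = seg_threshold,
                               min_px = min_px)
  seg_thr <- attr(regions, "threshold")
  regions <- reconnect_chains(regions, max_gap_um = max_gap_um,
                              pitch_um = pitch_um)
  rows <- list()
  n_disc <- 0L
  for (rg in regions) {
    if (isTRUE(rg$chain_flag)) {
      # re-connected chains legitimately have a high hull/filled ratio
      # (the hull spans the inter-cell gaps); they bypass overlap triage
      res <- list(records = NULL, status = "kept")
    } else {
      res <- resolve_overlaps(rg, stack, pitch_um = pitch_um,
                              hull_ratio_threshold = hull_ratio_threshold,
                              seg_threshold = seg_thr, min_px = min_px)
    }
    if (res$status == "discarded") { n_disc <- n_disc + 1L; next }
    if (res$status == "kept") {
      # re-extract the outline from the particle's own best-focus plane
      ref <- refine_region(rg, stack, seg_thr, min_px = min_px)
      rec <- measure_region(ref$region, pitch_um)
      rec$z_mm <- region_depth(ref$region, stack)$z * 1e3
      rec$overlap_flag <- FALSE
      rec$curvature_flag <- flag_curvature(ref$region)$flag
    } else {
      rec <- res$records
      rec$curvature_flag <- FALSE
    }
    rows[[length(rows) + 1L]] <- rec
  }
  if (length(rows) == 0L) {
    out <- empty_particle_frame()
  } else {
    out <- do.call(rbind, rows)
    out$theta_deg <- correct_orientation(out$theta_deg, h$pitch)
    out$id <- seq_len(nrow(out))
    out$hologram_id <- hologram_id
    out$depth_m <- h$depth
    out <- out[, particle_columns()]
  }
  attr(out, "n_discarded") <- n_disc
  out
}

particle_columns <- function() {
  c("id", "hologram_id", "depth_m", "x_um", "y_um", "z_mm", "area_px",
    "filled_area_um2", "equiv_diam_um", "major_um", "minor_um",
    "aspect_ratio", "theta_deg", "hull_area_um2", "chain_flag",
    "overlap_flag", "curvature_flag")
}

empty_particle_frame <- function() {
  out <- data.frame(id = integer(0), hologram_id = integer(0),
                    depth_m = numeric(0), x_um = numeric(0),
                    y_um = numeric(0), z_mm = numeric(0),
                    area_px = integer(0), filled_area_um2 = numeric(0),
                    equiv_diam_um = numeric(0), major_um = numeric(0),
                    minor_um = numeric(0), aspect_ratio = numeric(0),
                    theta_deg = numeric(0), hull_area_um2 = numeric(0),
                    chain_flag = logical(0), overlap_flag = logical(0),
                    curvature_flag = logical(0))
  out
}
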