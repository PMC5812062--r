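# shared fixture builders: binary masks rendered as dark-on-bright images
# so they can run through the public segmentation interface

# image with value 0 inside the mask, 1 outside
mask_image <- function(mask) 1 - mask

# digitized ellipse mask (pixel-centre inclusion), angle in degrees,
# bottom-left origin
digit_ellipse <- function(nr, nc, cx, cy, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  xs <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  ys <- matrix(rep(nr - seq_len(nr) + 0.5, nc), nr, nc)
  u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
  v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# segment a binary mask into regions through the public interface
regions_of <- function(mask, min_px = 5L) {
  segment_composite(mask_image(mask), threshold = 0.5, min_px = min_px)
}

first_region <- function(mask, min_px = 5L) {
  regs <- regions_of(mask, min_px)
  stopifnot(length(regs) >= 1L)
  regs[[which.max(vapply(regs, function(r) nrow(r$px), numeric(1)))]]
}

# one-particle scene row in the layout make_scene() produces
scene_row <- function(x, y, z, major, minor, theta_p, theta_a = 0,
                      shape = "spheroid", cells = 1L, gap_px = 0) {
  data.frame(id = 1L, x = x, y = y, z = z, major = major, minor = minor,
             theta_p = theta_p, theta_a = theta_a,
             theta_2d = project_to_2d(theta_p, theta_a),
             shape = shape, cells = cells, gap_px = gap_px)
}

small_optics <- function(n = 256L) optical_config(sensor_px = c(n, n))
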