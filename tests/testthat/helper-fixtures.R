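# Fixture builders shared across the suite. All geometry is constructed in
# code at test time; nothing is read from disk.

# one ellipse mark row in the generator's ground-truth layout
mark_row <- function(type, cx, cy, major, minor = major, angle = 0) {
  data.frame(type = type, center_x_um = cx, center_y_um = cy,
             major_um = major, minor_um = minor, orientation_deg = angle,
             radius_um = NA_real_, stringsAsFactors = FALSE)
}

# render marks and run split + detection (+ central identification)
detect_fixture <- function(marks, image_px, scale = 1, identify = TRUE,
                           min_pixels = 4, ...) {
  img <- render_annotation(marks, image_px, scale, ...)
  tab <- detect_marks(color_split(img), min_pixels = min_pixels)
  if (identify) tab <- identify_central_vessels(tab, require_vein = FALSE)
  tab
}

# area of the lens-shaped intersection of two disks (classical closed form)
lens_area <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
}

# small-image specification used by study-level simulations: 512 px at
# 4 um/px with proportionally larger capillaries so every mark stays well
# above the minimum component size
small_sample_spec <- function(n_capillaries = 30, seed = 1) {
  sample_spec(image_px = 512, scale = 4,
              vein = list(center = NULL, diameter = 300),
              artery = list(center = NULL, diameter = 200),
              n_capillaries = n_capillaries,
              radial = list(dist = "uniform", min = 280, max = 850),
              diameter = list(median = 40, sigma_log = 0.35, min = 16, max = 120),
              seed = seed)
}

small_config <- function(...) study_config(scale = 4, target_px = 512, ...)
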