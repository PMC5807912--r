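# The five per-sample read-out parameters: total vessel count, virtually
# perfused area, perfused-area vessel density, radial ingrowth distance, and
# minor-axis vessel diameter — plus their histogram representations.

#' Total vessel count of a sample
#'
#' Number of capillary-class marks; the central artery and central vein are
#' excluded by definition.
#'
#' @param table A `vessel_table` with central vessels identified.
#' @return Integer count.
#' @export
total_vessel_count <- function(table) {
  stopifnot(inherits(table, "vessel_table"))
  sum(table$marks$type == "capillary")
}

#' Virtually perfused area of a sample
#'
#' Every vessel mark's actual painted shape is expanded by a fixed radius
#' (default 150 um, a conventional oxygen-diffusion distance) and the area of
#' the union of the expanded shapes is returned; overlapping regions are
#' counted once. The union is computed by thresholding a Euclidean distance
#' transform of the mark raster, i.e. an exact-metric morphological dilation,
#' on a canvas padded by the radius so the expansion is never clipped at the
#' image border.
#'
#' @param table A `vessel_table` carrying pixel sets (i.e. produced by
#'   [detect_marks()], not re-read from CSV).
#' @param radius Expansion radius in micrometers (default 150).
#' @param raster_scale Micrometers per pixel of the evaluation raster.
#'   Defaults to the table's native scale; a smaller value re-rasterizes the
#'   marks on a finer grid for higher-accuracy area estimates.
#' @param include_central Include the central artery and vein marks in the
#'   union (default `TRUE`; set `FALSE` to restrict the perfused area to the
#'   counted vessels).
#' @return Area in mm^2 (0 for an empty table).
#' @export
perfused_area <- function(table, radius = 150, raster_scale = NULL,
                          include_central = TRUE) {
  stopifnot(inherits(table, "vessel_table"))
  if (!is_scalar_pos(radius)) validation_error("radius must be a single positive number (um)")
  if (is.null(table$pixels) || is.null(table$dim))
    validation_error("table carries no pixel sets; perfused_area needs a table produced by detect_marks()")
  s <- table$scale
  rs <- raster_scale %||% s
  if (!is_scalar_pos(rs)) validation_error("raster_scale must be a single positive number (um/px)")
  keep <- if (include_central) seq_len(nrow(table$marks))
          else which(table$marks$type == "capillary")
  if (!length(keep)) return(0)
  h <- table$dim[1]; w <- table$dim[2]
  mask <- matrix(FALSE, h, w)
  mask[unlist(table$pixels[keep], use.names = FALSE)] <- TRUE
  if (!isTRUE(all.equal(rs, s))) {
    # nearest-neighbor re-rasterization onto the evaluation grid
    h2 <- max(1L, as.integer(ceiling(h * s / rs)))
    w2 <- max(1L, as.integer(ceiling(w * s / rs)))
    map_r <- pmin(h, pmax(1L, as.integer(round((seq_len(h2) - 1L) * rs / s)) + 1L))
    map_c <- pmin(w, pmax(1L, as.integer(round((seq_len(w2) - 1L) * rs / s)) + 1L))
    mask <- mask[map_r, map_c]
  }
  pad <- as.integer(ceiling(radius / rs)) + 2L
  # distmap: distance of non-zero pixels to the nearest zero pixel, so marks
  # are the zeros and the padding ring must be non-zero
  padded <- matrix(1, nrow(mask) + 2L * pad, ncol(mask) + 2L * pad)
  padded[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- !mask
  d <- EBImage::distmap(padded)
  sum(d <= radius / rs) * rs^2 / 1e6
}

#' Perfused-area vessel density
#'
#' @param count Total vessel count.
#' @param area Total perfused area in mm^2.
#' @return Density in vessels/mm^2. An empty sample (count 0, area 0) has
#'   density 0 by convention; area 0 with a positive count is impossible.
#' @export
vessel_density <- function(count, area) {
  if (!is_count(count)) validation_error("count must be a non-negative integer")
  if (!is.numeric(area) || length(area) != 1 || area < 0)
    validation_error("area must be a single non-negative number (mm^2)")
  if (area == 0) {
    if (count > 0)
      impossible_state_error("positive vessel count with zero perfused area")
    return(0)
  }
  count / area
}

#' Radial ingrowth distance of one mark
#'
#' Euclidean distance from the mark's centroid to the central vein's
#' centroid, in micrometers.
#'
#' @param mark,vein Single rows of a vessel table's `marks` data frame (or
#'   any list with `centroid_x_um`/`centroid_y_um`).
#' @return Distance in um.
#' @export
ingrowth_distance <- function(mark, vein) {
  if (is.null(vein)) missing_reference_error("central vein is absent")
  sqrt((mark$centroid_x_um - vein$centroid_x_um)^2 +
       (mark$centroid_y_um - vein$centroid_y_um)^2)
}

#' Ingrowth distances of all counted vessels
#'
#' @param table A `vessel_table` with the central vein identified.
#' @return Numeric vector of distances in um, one per capillary-class mark.
#' @export
ingrowth_distances <- function(table) {
  stopifnot(inherits(table, "vessel_table"))
  if (is.na(table$central_vein_id))
    missing_reference_error("central vein not identified; run identify_central_vessels() first")
  vein <- table$marks[table$marks$id == table$central_vein_id, ]
  caps <- table$marks[table$marks$type == "capillary", ]
  sqrt((caps$centroid_x_um - vein$centroid_x_um)^2 +
       (caps$centroid_y_um - vein$centroid_y_um)^2)
}

#' Vessel diameter of one mark
#'
#' The diameter is defined as the minor axis of the mark's moment-equivalent
#' ellipse (wall included): robust against oblique sectioning, which
#' elongates only the major axis, and against compression artifacts.
#'
#' @param mark A single row of a vessel table's `marks` data frame.
#' @return Diameter in um.
#' @export
vessel_diameter <- function(mark) mark$minor_axis_um

#' Diameters of all counted vessels
#'
#' @param table A `vessel_table`.
#' @return Numeric vector of minor-axis diameters in um, one per
#'   capillary-class mark.
#' @export
vessel_diameters <- function(table) {
  stopifnot(inherits(table, "vessel_table"))
  table$marks$minor_axis_um[table$marks$type == "capillary"]
}

#' Histogram specification
#'
#' @param bin_width Bin width in um.
#' @param range Two-element (min, max) range in um; values outside are
#'   dropped.
#' @param normalized If `TRUE`, heights are fractions of the total count
#'   (they sum to 1 for non-empty input).
#' @param smoothing_window Centered moving-average window in bins (odd, or 0
#'   for none), applied after normalization with zero padding at the edges.
#' @return A `histogram_spec` object.
#' @export
histogram_spec <- function(bin_width, range, normalized = FALSE,
                           smoothing_window = 0) {
  if (!is_scalar_pos(bin_width)) validation_error("bin_width must be positive")
  if (length(range) != 2 || range[2] <= range[1])
    validation_error("range must be (min, max) with max > min")
  if (!is_count(smoothing_window) || (smoothing_window > 0 && smoothing_window %% 2 == 0))
    validation_error("smoothing_window must be 0 or an odd integer")
  structure(list(bin_width = bin_width, range = as.numeric(range),
                 normalized = isTRUE(normalized),
                 smoothing_window = as.integer(smoothing_window)),
            class = "histogram_spec")
}

#' Histogram of diameters or ingrowth distances
#'
#' @param values Numeric vector (um).
#' @param spec A [histogram_spec()].
#' @return Data frame with `bin_center` and `height` columns.
#' @export
vessel_histogram <- function(values, spec) {
  stopifnot(inherits(spec, "histogram_spec"))
  lo <- spec$range[1]; hi <- spec$range[2]
  nbins <- as.integer(ceiling((hi - lo) / spec$bin_width - 1e-9))
  values <- values[!is.na(values) & values >= lo & values <= hi]
  bins <- pmin(nbins, floor((values - lo) / spec$bin_width) + 1L)
  heights <- as.numeric(tabulate(bins, nbins))
  if (spec$normalized && sum(heights) > 0) heights <- heights / sum(heights)
  if (spec$smoothing_window > 0) {
    w <- spec$smoothing_window
    half <- (w - 1L) / 2L
    padded <- c(numeric(half), heights, numeric(half))
    heights <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[half + seq_len(nbins)]
  }
  data.frame(bin_center = lo + (seq_len(nbins) - 0.5) * spec$bin_width,
             height = heights)
}

#' Compute the five read-out parameters of one sample
#'
#' @param table A `vessel_table` with central vessels identified (a missing
#'   central vein yields `NA` ingrowth results and a `no_central_vein` flag
#'   rather than an error).
#' @param perfusion_radius Expansion radius in um (default 150).
#' @param raster_scale Evaluation raster for the perfused area; defaults to
#'   the table's scale.
#' @param include_central Include central artery/vein in the perfused-area
#'   union (default `TRUE`).
#' @return A `sample_metrics` object.
#' @export
compute_sample_metrics <- function(table, perfusion_radius = 150,
                                   raster_scale = NULL, include_central = TRUE) {
  stopifnot(inherits(table, "vessel_table"))
  flags <- character(0)
  count <- total_vessel_count(table)
  if (nrow(table$marks) == 0) flags <- c(flags, "empty")
  area <- if (nrow(table$marks) > 0)
    perfused_area(table, radius = perfusion_radius, raster_scale = raster_scale,
                  include_central = include_central) else 0
  density <- vessel_density(count, area)
  if (is.na(table$central_vein_id)) {
    flags <- c(flags, "no_central_vein")
    dists <- rep(NA_real_, count)
    av_dist <- NA_real_
  } else {
    dists <- ingrowth_distances(table)
    av_dist <- if (!is.na(table$central_artery_id))
      ingrowth_distance(table$marks[table$marks$id == table$central_artery_id, ],
                        table$marks[table$marks$id == table$central_vein_id, ])
      else NA_real_
  }
  diams <- vessel_diameters(table)
  stopifnot(length(dists) == count, length(diams) == count)
  structure(list(sample_id = table$sample_id,
                 total_vessel_count = count,
                 total_perfused_area_mm2 = area,
                 vessel_density_per_mm2 = density,
                 ingrowth_distances_um = dists,
                 diameters_um = diams,
                 perfusion_radius_um = perfusion_radius,
                 artery_vein_distance_um = av_dist,
                 flags = flags),
            class = "sample_metrics")
}

#' @export
as.data.frame.sample_metrics <- function(x, ...) {
  data.frame(sample_id = x$sample_id,
             total_vessel_count = x$total_vessel_count,
             total_perfused_area_mm2 = x$total_perfused_area_mm2,
             vessel_density_per_mm2 = x$vessel_density_per_mm2,
             mean_ingrowth_um = if (length(x$ingrowth_distances_um)) mean(x$ingrowth_distances_um) else NA_real_,
             mean_diameter_um = if (length(x$diameters_um)) mean(x$diameters_um) else NA_real_,
             perfusion_radius_um = x$perfusion_radius_um,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' @export
print.sample_metrics <- function(x, ...) {
  cat(sprintf("sample '%s': %d vessels, perfused area %.4g mm^2, density %.4g vessels/mm^2\n",
              x$sample_id, x$total_vessel_count, x$total_perfused_area_mm2,
              x$vessel_density_per_mm2))
  if (length(x$ingrowth_distances_um) && !all(is.na(x$ingrowth_distances_um)))
    cat(sprintf("  ingrowth distance: mean %.4g um (range %.4g-%.4g)\n",
                mean(x$ingrowth_distances_um), min(x$ingrowth_distances_um),
                max(x$ingrowth_distances_um)))
  if (length(x$diameters_um))
    cat(sprintf("  diameter: median %.4g um (perfusion radius %g um)\n",
                stats::median(x$diameters_um), x$perfusion_radius_um))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
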