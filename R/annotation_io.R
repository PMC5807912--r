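# Reading, calibrating, resampling and color-splitting annotation images,
# plus tabular output writers.
#
# Coordinate convention used throughout the package: origin at the center of
# the top-left pixel, x rightward (columns), y downward (rows), units are
# micrometers after calibration. Pixel (row r, col c) has center
# ((c-1)*scale, (r-1)*scale).

#' Construct a calibrated annotation image
#'
#' @param pixels Integer array `h x w x 3` with 8-bit channel values (0-255).
#' @param scale Isotropic pixel size in micrometers per pixel.
#' @return An object of class `calibrated_image` with fields `pixels` and
#'   `scale`.
#' @export
calibrated_image <- function(pixels, scale) {
  if (!is_scalar_pos(scale)) validation_error("scale must be a single positive number (um/pixel)")
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    validation_error("pixels must be an h x w x 3 array")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    validation_error("pixel values must lie in 0..255 (8 bit per channel)")
  structure(list(pixels = pixels, scale = as.numeric(scale)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("calibrated annotation image: %d x %d px at %.4g um/px (%.3g x %.3g mm)\n",
              d[2], d[1], x$scale, d[2] * x$scale / 1000, d[1] * x$scale / 1000))
  invisible(x)
}

image_width <- function(image) dim(image$pixels)[2]
image_height <- function(image) dim(image$pixels)[1]

#' Read an annotation image with a physical calibration
#'
#' Decodes an 8-bit RGB(A) PNG or TIFF raster; an alpha channel, if present,
#' is discarded. Grayscale rasters are expanded to three identical channels.
#' Anisotropic calibrations are rejected: `scale` must be a single value.
#'
#' @param path Path to a PNG or TIFF file.
#' @param scale Pixel size in micrometers per pixel (e.g. 0.644 for a scan at
#'   644 nm per pixel).
#' @return A [calibrated_image].
#' @export
read_annotation_image <- function(path, scale) {
  if (length(scale) != 1) validation_error("anisotropic pixel calibrations are not supported; scale must be one value")
  if (!is_scalar_pos(scale)) validation_error("scale must be a single positive number (um/pixel)")
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    io_error(sprintf("cannot read annotation image: '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path),
           io_error(sprintf("unsupported image format '.%s' for '%s' (PNG or TIFF expected)", ext, path))),
    error = function(e) io_error(sprintf("failed to decode '%s': %s", path, conditionMessage(e))))
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  nch <- dim(raw)[3]
  if (nch == 1L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  if (nch == 2L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]  # gray + alpha
  if (nch >= 4L) raw <- raw[, , 1:3, drop = FALSE]            # drop alpha
  px <- array(as.integer(round(raw[, , 1:3] * 255)), dim = c(dim(raw)[1:2], 3L))
  calibrated_image(px, scale)
}

#' Write a calibrated image as PNG
#'
#' @param image A [calibrated_image].
#' @param path Destination `.png` path.
#' @return Invisibly, `path`.
#' @export
write_annotation_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  ok <- tryCatch({
    png::writePNG(image$pixels / 255, target = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) io_error(sprintf("cannot write image to '%s'", path))
  invisible(path)
}

#' Resample an annotation image to a square working size
#'
#' Nearest-neighbor resampling, so no colors outside the annotation palette
#' are created. The physical extent is preserved: the scale is multiplied by
#' `max(width, height) / target_px`. Non-square inputs keep their aspect
#' ratio and are padded to square with the background color.
#'
#' @param image A [calibrated_image].
#' @param target_px Edge length of the square output in pixels (default 2500,
#'   the working resolution of the analysis).
#' @param background Background RGB triplet used for padding (default white).
#' @return A [calibrated_image] of size `target_px x target_px`.
#' @export
resample_image <- function(image, target_px = 2500, background = c(255L, 255L, 255L)) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!is_count(target_px) || target_px < 1) validation_error("target_px must be a positive integer")
  h <- image_height(image); w <- image_width(image)
  if (h == target_px && w == target_px) return(image)
  ratio <- max(h, w) / target_px
  new_h <- max(1L, as.integer(round(h / ratio)))
  new_w <- max(1L, as.integer(round(w / ratio)))
  src_r <- pmin(h, floor((seq_len(new_h) - 0.5) * ratio) + 1L)
  src_c <- pmin(w, floor((seq_len(new_w) - 0.5) * ratio) + 1L)
  out <- array(rep(as.integer(background), each = target_px * target_px),
               dim = c(target_px, target_px, 3L))
  out[seq_len(new_h), seq_len(new_w), ] <- image$pixels[src_r, src_c, , drop = FALSE]
  calibrated_image(out, image$scale * ratio)
}

#' Define the three-color annotation convention
#'
#' A pixel belongs to a vessel class when each of its channels deviates from
#' the class's reference color by at most `tolerance`. Reference colors must
#' be pairwise separated by more than twice the tolerance in at least one
#' channel, which guarantees that no pixel can match two classes.
#'
#' @param artery,vein,capillary Reference RGB triplets (0-255). Defaults:
#'   pure red, pure blue, pure green.
#' @param tolerance Maximum per-channel deviation (default 40).
#' @return An object of class `color_convention`.
#' @export
color_convention <- function(artery = c(255, 0, 0), vein = c(0, 0, 255),
                             capillary = c(0, 255, 0), tolerance = 40) {
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance < 0)
    validation_error("tolerance must be a single non-negative number")
  refs <- list(artery = artery, vein = vein, capillary = capillary)
  for (nm in names(refs)) {
    v <- refs[[nm]]
    if (length(v) != 3 || any(v < 0) || any(v > 255))
      validation_error(sprintf("%s color must be an RGB triplet in 0..255", nm))
  }
  pairs <- combn(names(refs), 2)
  for (j in seq_len(ncol(pairs))) {
    a <- refs[[pairs[1, j]]]; b <- refs[[pairs[2, j]]]
    if (max(abs(a - b)) <= 2 * tolerance)
      validation_error(sprintf(
        "reference colors '%s' and '%s' are not separated beyond 2x tolerance; a pixel could match both classes",
        pairs[1, j], pairs[2, j]))
  }
  structure(list(artery = as.numeric(artery), vein = as.numeric(vein),
                 capillary = as.numeric(capillary), tolerance = as.numeric(tolerance)),
            class = "color_convention")
}

#' Split an annotation image into per-class binary masks
#'
#' @param image A [calibrated_image].
#' @param convention A [color_convention].
#' @return An object of class `channel_masks`: logical matrices `artery`,
#'   `vein`, `capillary` (same dimensions as the image) plus the carried-over
#'   `scale`. Masks are pairwise disjoint by construction.
#' @export
color_split <- function(image, convention = color_convention()) {
  stopifnot(inherits(image, "calibrated_image"), inherits(convention, "color_convention"))
  r <- image$pixels[, , 1]; g <- image$pixels[, , 2]; b <- image$pixels[, , 3]
  tol <- convention$tolerance
  # integer band comparisons (no double coercion of the full channel planes)
  match_class <- function(ref) {
    lo <- as.integer(ceiling(ref - tol)); hi <- as.integer(floor(ref + tol))
    r >= lo[1] & r <= hi[1] & g >= lo[2] & g <= hi[2] & b >= lo[3] & b <= hi[3]
  }
  structure(list(artery = match_class(convention$artery),
                 vein = match_class(convention$vein),
                 capillary = match_class(convention$capillary),
                 scale = image$scale),
            class = "channel_masks")
}

# ---- tabular output ----------------------------------------------------

vessel_table_columns <- c("id", "type", "centroid_x_um", "centroid_y_um",
                          "area_um2", "major_axis_um", "minor_axis_um",
                          "pixel_count")

#' Write a vessel table to CSV
#'
#' One row per detected mark with columns id, type, centroid_x_um,
#' centroid_y_um, area_um2, major_axis_um, minor_axis_um, pixel_count.
#' Full double precision is kept, so a written table re-reads losslessly.
#'
#' @param table A `vessel_table` (see [detect_marks()]).
#' @param path Destination CSV path.
#' @return Invisibly, `path`.
#' @export
write_vessel_table <- function(table, path) {
  stopifnot(inherits(table, "vessel_table"))
  df <- table$marks[, vessel_table_columns, drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot write vessel table to '%s'", path))
  invisible(path)
}

#' Read back a vessel table written by [write_vessel_table()]
#'
#' The result carries the tabular measurements only (no pixel sets), which is
#' sufficient for all downstream metrics except re-rasterizing the perfused
#' area.
#'
#' @param path CSV path.
#' @param scale Micrometers per pixel of the source image (stored on the
#'   returned table).
#' @return A `vessel_table`.
#' @export
read_vessel_table <- function(path, scale = NA_real_) {
  if (!file.exists(path)) io_error(sprintf("vessel table '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(vessel_table_columns, names(df))
  if (length(missing)) io_error(sprintf("'%s' lacks vessel-table columns: %s",
                                        path, paste(missing, collapse = ", ")))
  new_vessel_table(df[, vessel_table_columns, drop = FALSE], pixels = NULL,
                   dim = NULL, scale = scale)
}

#' Write per-sample metrics or a study summary to CSV
#'
#' For a `sample_metrics` object: one row with the five read-out parameters
#' (distributional parameters summarized by their per-sample mean). For a
#' `study_summary`: one row per group and metric with mean, SEM and n.
#'
#' @param metrics A `sample_metrics` or `study_summary` object.
#' @param path Destination CSV path.
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(metrics, path) UseMethod("write_metrics")

#' @export
write_metrics.sample_metrics <- function(metrics, path) {
  df <- as.data.frame(metrics)
  ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot write metrics to '%s'", path))
  invisible(path)
}

#' @export
write_metrics.study_summary <- function(metrics, path) {
  rows <- list()
  for (metric in names(metrics$metrics)) {
    m <- metrics$metrics[[metric]]
    for (g in names(m$groups)) {
      s <- m$groups[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, group = g, mean = s$mean, sem = s$sem, n = s$n,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot write study summary to '%s'", path))
  invisible(path)
}

#' Write a study summary as JSON
#'
#' Serializes per-group descriptives, ANOVA tables and Duncan post hoc pairs
#' for every metric.
#'
#' @param summary A `study_summary` from [run_study()].
#' @param path Destination `.json` path.
#' @return Invisibly, `path`.
#' @export
write_study_summary <- function(summary, path) {
  stopifnot(inherits(summary, "study_summary"))
  jsonlite::write_json(unclass_summary(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

unclass_summary <- function(summary) {
  out <- list(alpha = summary$alpha, metrics = list())
  for (metric in names(summary$metrics)) {
    m <- summary$metrics[[metric]]
    entry <- list(groups = m$groups)
    if (!is.null(m$anova))
      entry$anova <- list(F = m$anova$F, df_between = m$anova$df_between,
                          df_within = m$anova$df_within, p = m$anova$p)
    if (!is.null(m$posthoc))
      entry$posthoc <- lapply(seq_len(nrow(m$posthoc$pairs)), function(i) {
        p <- m$posthoc$pairs[i, ]
        list(group_a = p$group_a, group_b = p$group_b, diff = p$diff,
             significant = p$significant, p_value = p$p_value,
             star_level = p$star_level, stars = strrep("*", p$star_level))
      })
    out$metrics[[metric]] <- entry
  }
  out
}
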