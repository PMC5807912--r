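# Connected-component detection of painted vessel marks, moment-based shape
# measurement, and identification of the central artery/vein references.

new_vessel_table <- function(marks, pixels, dim, scale, sample_id = NA_character_,
                             central_artery_id = NA_integer_,
                             central_vein_id = NA_integer_) {
  structure(list(marks = marks, pixels = pixels, dim = dim, scale = scale,
                 sample_id = sample_id,
                 central_artery_id = central_artery_id,
                 central_vein_id = central_vein_id),
            class = "vessel_table")
}

#' @export
print.vessel_table <- function(x, ...) {
  tab <- table(factor(x$marks$type, levels = c("artery", "vein", "capillary")))
  cat(sprintf("vessel table '%s': %d marks (%d artery, %d vein, %d capillary)\n",
              x$sample_id, nrow(x$marks), tab["artery"], tab["vein"], tab["capillary"]))
  if (!is.na(x$central_vein_id)) cat(sprintf("  central vein: mark %d\n", x$central_vein_id))
  if (!is.na(x$central_artery_id)) cat(sprintf("  central artery: mark %d\n", x$central_artery_id))
  invisible(x)
}

#' Label 8-connected components of a binary mask
#'
#' Hand-painted strokes frequently touch only diagonally, so components are
#' joined across edges and corners (8-connectivity).
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same dimensions; 0 is background, components
#'   are numbered from 1.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  n <- length(idx)
  if (n == 0L) return(lab)
  id <- matrix(0L, h, w)
  id[idx] <- seq_len(n)
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  edge_list <- vector("list", 4L)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(shifts)) {
    dr <- shifts[[k]][1]; dc <- shifts[[k]][2]
    keep <- r + dr >= 1L & r + dr <= h & cc + dc <= w
    nb <- idx[keep] + dr + dc * h
    hit <- mask[nb]
    edge_list[[k]] <- cbind(id[idx[keep][hit]], id[nb[hit]])
  }
  edges <- do.call(rbind, edge_list)
  g <- igraph::make_graph(edges = as.vector(t(edges)), n = n, directed = FALSE)
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

# Moment measurement of every labeled component at once. Pixel-center second
# moments get the 1/12 per-pixel variance correction so that axes equal those
# of the moment-equivalent ellipse of the pixel squares (a single pixel has
# axes 4*sqrt(1/12) ~ 1.155 px rather than zero).
measure_components <- function(lab, scale) {
  n <- max(lab)
  empty <- data.frame(centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      area_um2 = numeric(0), major_axis_um = numeric(0),
                      minor_axis_um = numeric(0), pixel_count = integer(0))
  if (n == 0L) return(empty)
  h <- nrow(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  x <- (((idx - 1L) %/% h)) * scale   # (col-1)*scale
  y <- (((idx - 1L) %% h)) * scale    # (row-1)*scale
  cnt <- tabulate(l, nbins = n)
  sx <- rowsum(x, l)[, 1]; sy <- rowsum(y, l)[, 1]
  sxx <- rowsum(x * x, l)[, 1]; syy <- rowsum(y * y, l)[, 1]
  sxy <- rowsum(x * y, l)[, 1]
  mx <- sx / cnt; my <- sy / cnt
  pxvar <- scale^2 / 12
  vxx <- sxx / cnt - mx^2 + pxvar
  vyy <- syy / cnt - my^2 + pxvar
  vxy <- sxy / cnt - mx * my
  tr2 <- (vxx + vyy) / 2
  det <- sqrt(pmax(((vxx - vyy) / 2)^2 + vxy^2, 0))
  l1 <- tr2 + det
  l2 <- pmax(tr2 - det, 0)
  data.frame(centroid_x_um = mx, centroid_y_um = my,
             area_um2 = cnt * scale^2,
             major_axis_um = 4 * sqrt(l1), minor_axis_um = 4 * sqrt(l2),
             pixel_count = cnt)
}

#' Measure the shape of one pixel component
#'
#' Returns the pixel centroid, the pixel-count area, and the axes of the
#' moment-equivalent ellipse computed from the second central moments of the
#' pixel set, all in micrometers.
#'
#' @param component Either a logical matrix marking the component's pixels or
#'   a two-column matrix of (row, col) pixel indices.
#' @param scale Micrometers per pixel.
#' @return A list with `centroid` (x, y in um), `area` (um^2), `major_axis`
#'   and `minor_axis` (um), and `pixel_count`.
#' @export
measure_shape <- function(component, scale) {
  if (!is_scalar_pos(scale)) validation_error("scale must be a single positive number")
  if (is.logical(component) && is.matrix(component)) {
    if (!any(component)) validation_error("component is empty")
    lab <- matrix(0L, nrow(component), ncol(component))
    lab[component] <- 1L
  } else if (is.matrix(component) && ncol(component) == 2) {
    if (nrow(component) == 0) validation_error("component is empty")
    h <- max(component[, 1]); w <- max(component[, 2])
    lab <- matrix(0L, h, w)
    lab[cbind(component[, 1], component[, 2])] <- 1L
  } else {
    validation_error("component must be a logical matrix or a 2-column (row, col) index matrix")
  }
  m <- measure_components(lab, scale)
  list(centroid = c(x = m$centroid_x_um, y = m$centroid_y_um),
       area = m$area_um2, major_axis = m$major_axis_um,
       minor_axis = m$minor_axis_um, pixel_count = m$pixel_count)
}

#' Detect all vessel marks in per-class masks
#'
#' Every 8-connected component of each class mask becomes one vessel mark;
#' components smaller than `min_pixels` are discarded as stray annotation
#' pixels. Red and blue components are typed `artery`/`vein` candidates at
#' this stage; [identify_central_vessels()] resolves the single central pair.
#'
#' @param masks A `channel_masks` object from [color_split()].
#' @param min_pixels Minimum component size in pixels (default 4 at the
#'   2500 px working resolution; 0 keeps every painted pixel group).
#' @param sample_id Optional sample identifier stored on the table.
#' @return A `vessel_table`: measurement data frame `marks`, per-mark pixel
#'   index sets `pixels`, image `dim` and `scale`.
#' @export
detect_marks <- function(masks, min_pixels = 4, sample_id = NA_character_) {
  stopifnot(inherits(masks, "channel_masks"))
  if (!is_count(min_pixels)) validation_error("min_pixels must be a non-negative integer")
  scale <- masks$scale
  marks <- list(); pixels <- list()
  for (type in c("artery", "vein", "capillary")) {
    lab <- label_components(masks[[type]])
    m <- measure_components(lab, scale)
    if (nrow(m) == 0) next
    keep <- which(m$pixel_count >= max(min_pixels, 1L))
    if (!length(keep)) next
    comp_pixels <- split(which(lab > 0L), lab[lab > 0L])[as.character(keep)]
    m <- m[keep, , drop = FALSE]
    m$type <- type
    marks[[type]] <- m
    pixels[[type]] <- comp_pixels
  }
  if (length(marks)) {
    df <- do.call(rbind, marks)
    rownames(df) <- NULL
    df$id <- seq_len(nrow(df))
    df <- df[, vessel_table_columns]
    px <- unname(do.call(c, unname(pixels)))
  } else {
    df <- data.frame(id = integer(0), type = character(0),
                     centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                     area_um2 = numeric(0), major_axis_um = numeric(0),
                     minor_axis_um = numeric(0), pixel_count = integer(0))
    px <- list()
  }
  new_vessel_table(df, pixels = px, dim = dim(masks$artery), scale = scale,
                   sample_id = sample_id)
}

#' Identify the central artery and vein
#'
#' The largest blue component becomes the central vein and the largest red
#' component the central artery. Any additional red or blue components are
#' reclassified as capillaries with a warning (hand annotation occasionally
#' leaves stray strokes in the reserved colors).
#'
#' @param table A `vessel_table` from [detect_marks()].
#' @param require_vein If `TRUE` (default), a missing blue component raises a
#'   missing-reference error, since ingrowth distances cannot be computed
#'   without the central vein. The pipeline relaxes this to flag and continue.
#' @return The table with `central_artery_id`/`central_vein_id` set and
#'   surplus candidates re-typed.
#' @export
identify_central_vessels <- function(table, require_vein = TRUE) {
  stopifnot(inherits(table, "vessel_table"))
  marks <- table$marks
  for (type in c("vein", "artery")) {
    cand <- which(marks$type == type)
    if (!length(cand)) next
    main <- cand[which.max(marks$area_um2[cand])]
    extra <- setdiff(cand, main)
    if (length(extra)) {
      warning(sprintf("%d extra %s-colored component(s) reclassified as capillaries (largest kept as central %s)",
                      length(extra), type, type), call. = FALSE)
      marks$type[extra] <- "capillary"
    }
    if (type == "vein") table$central_vein_id <- marks$id[main]
    else table$central_artery_id <- marks$id[main]
  }
  if (require_vein && is.na(table$central_vein_id))
    missing_reference_error("no central vein (blue) mark present; ingrowth distances cannot be computed")
  table$marks <- marks
  table
}
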