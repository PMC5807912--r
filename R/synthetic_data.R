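# Seeded generator of color-coded annotation images with ground truth:
# one centric vein (blue) and artery (red), plus a population of elliptical
# capillary marks (green) with configurable radial, diameter and orientation
# distributions, rendered on a white background.

#' Specification of one synthetic annotation sample
#'
#' Defaults emulate a ~4 x 4 mm tissue cross section at the 2500 px working
#' resolution (1.6 um/px): a 400 um central vein with a 250 um artery beside
#' it, and capillaries with log-normal minor-axis diameters (median 15 um,
#' sigma_log 0.5, truncated to 5-300 um) placed uniformly in radius from the
#' vein center. The seed fully determines the output.
#'
#' @param image_px Square image edge length in pixels.
#' @param scale Micrometers per pixel.
#' @param vein,artery Lists with `center` (x, y in um; `NULL` centers the
#'   vein and offsets the artery beside it) and `diameter` (um).
#' @param n_capillaries Number of capillary marks.
#' @param radial List: `dist` (`"uniform"` or `"normal"`) plus `min`/`max`
#'   or `mean`/`sd`, the distance of capillary centers from the vein center
#'   in um.
#' @param diameter List: log-normal `median` and `sigma_log` plus truncation
#'   `min`/`max`, for the minor-axis diameter in um.
#' @param eccentricity_range Range of the minor/major axis ratio.
#' @param seed Integer seed.
#' @param min_separation_px Minimum boundary separation between distinct
#'   marks, in pixels (default 3, so every mark is a separate 8-connected
#'   component).
#' @param max_attempts Rejection-sampling attempts per capillary.
#' @param anti_alias Render with 4x4 subpixel coverage blending (only for
#'   exercising color-tolerance handling; default off for clean labels).
#' @param convention [color_convention()] used for rendering.
#' @return A `sample_spec` object.
#' @export
sample_spec <- function(image_px = 2500, scale = 1.6,
                        vein = list(center = NULL, diameter = 400),
                        artery = list(center = NULL, diameter = 250),
                        n_capillaries = 100,
                        radial = list(dist = "uniform", min = 350, max = 1800),
                        diameter = list(median = 15, sigma_log = 0.5, min = 5, max = 300),
                        eccentricity_range = c(0.5, 1),
                        seed = 1,
                        min_separation_px = 3,
                        max_attempts = 1000,
                        anti_alias = FALSE,
                        convention = color_convention()) {
  if (!is_count(image_px) || image_px < 1) validation_error("image_px must be a positive integer")
  if (!is_scalar_pos(scale)) validation_error("scale must be positive")
  if (!is_count(n_capillaries)) validation_error("n_capillaries must be a non-negative integer")
  extent <- (image_px - 1) * scale
  if (is.null(vein$center)) vein$center <- c(extent / 2, extent / 2)
  if (is.null(artery$center))
    artery$center <- vein$center + c(vein$diameter / 2 + artery$diameter / 2 + 125, 0)
  for (v in list(vein, artery)) {
    if (v$diameter <= 0) validation_error("central vessel diameters must be positive")
    if (any(v$center - v$diameter / 2 < 0) || any(v$center + v$diameter / 2 > extent))
      validation_error("central vessels must fit inside the image")
  }
  if (diameter$min <= 0 || diameter$max <= diameter$min)
    validation_error("diameter truncation must satisfy 0 < min < max")
  structure(list(image_px = as.integer(image_px), scale = scale, vein = vein,
                 artery = artery, n_capillaries = as.integer(n_capillaries),
                 radial = radial, diameter = diameter,
                 eccentricity_range = eccentricity_range,
                 seed = as.integer(seed),
                 min_separation_px = min_separation_px,
                 max_attempts = as.integer(max_attempts),
                 anti_alias = isTRUE(anti_alias),
                 convention = convention),
            class = "sample_spec")
}

#' Render filled ellipses as a tricolor annotation image
#'
#' Low-level rasterizer used by [generate_sample()] and handy for building
#' fixtures with exactly known geometry. A pixel belongs to an ellipse when
#' its center lies inside it; in anti-aliased mode, boundary pixels are
#' blended with the background by 4x4 subpixel coverage.
#'
#' @param marks Data frame with columns `type` (`artery`, `vein`,
#'   `capillary`), `center_x_um`, `center_y_um`, `major_um`, `minor_um`,
#'   `orientation_deg`.
#' @param image_px Square edge length in pixels.
#' @param scale Micrometers per pixel.
#' @param convention [color_convention()] supplying the class colors.
#' @param background Background RGB triplet (default white).
#' @param anti_alias Blend boundary pixels (default `FALSE`).
#' @return A [calibrated_image].
#' @export
render_annotation <- function(marks, image_px, scale,
                              convention = color_convention(),
                              background = c(255, 255, 255),
                              anti_alias = FALSE) {
  n <- image_px
  red <- matrix(as.numeric(background[1]), n, n)
  grn <- matrix(as.numeric(background[2]), n, n)
  blu <- matrix(as.numeric(background[3]), n, n)
  sub <- if (anti_alias) (seq_len(4) - 2.5) / 4 else 0
  for (i in seq_len(nrow(marks))) {
    color <- convention[[marks$type[i]]]
    a <- marks$major_um[i] / 2; b <- marks$minor_um[i] / 2
    th <- marks$orientation_deg[i] * pi / 180
    ct <- cos(th); st <- sin(th)
    cx <- marks$center_x_um[i]; cy <- marks$center_y_um[i]
    cols <- max(1L, floor((cx - a) / scale)):min(n, ceiling((cx + a) / scale) + 1L)
    rows <- max(1L, floor((cy - a) / scale)):min(n, ceiling((cy + a) / scale) + 1L)
    dx <- matrix((cols - 1) * scale - cx, length(rows), length(cols), byrow = TRUE)
    dy <- matrix((rows - 1) * scale - cy, length(rows), length(cols))
    cov <- matrix(0, length(rows), length(cols))
    for (ox in sub) for (oy in sub) {
      u <- (dx + ox * scale) * ct + (dy + oy * scale) * st
      v <- -(dx + ox * scale) * st + (dy + oy * scale) * ct
      cov <- cov + ((u / a)^2 + (v / b)^2 <= 1)
    }
    cov <- cov / length(sub)^2
    hit <- cov > 0
    if (!any(hit)) next
    lin <- outer(rows, (cols - 1L) * n, "+")[hit]
    cv <- cov[hit]
    red[lin] <- cv * color[1] + (1 - cv) * red[lin]
    grn[lin] <- cv * color[2] + (1 - cv) * grn[lin]
    blu[lin] <- cv * color[3] + (1 - cv) * blu[lin]
  }
  px <- array(0L, c(n, n, 3L))
  px[, , 1] <- as.integer(round(red))
  px[, , 2] <- as.integer(round(grn))
  px[, , 3] <- as.integer(round(blu))
  calibrated_image(px, scale)
}

draw_radius <- function(radial) {
  switch(radial$dist %||% "uniform",
         uniform = stats::runif(1, radial$min, radial$max),
         normal = abs(stats::rnorm(1, radial$mean, radial$sd)),
         validation_error(sprintf("unknown radial distribution '%s'", radial$dist)))
}

draw_diameter <- function(d) {
  repeat {
    x <- stats::rlnorm(1, meanlog = log(d$median), sdlog = d$sigma_log)
    if (x >= d$min && x <= d$max) return(x)
  }
}

#' Generate one synthetic annotation sample with ground truth
#'
#' Capillary placements are rejection-sampled so that all marks (including
#' the central pair) are separated by at least `min_separation_px` pixels of
#' background; identical seeds yield identical images.
#'
#' @param spec A [sample_spec()].
#' @return A `synthetic_sample`: `image` (a [calibrated_image]), `truth`
#'   (data frame: type, center, axes, orientation, placed radius) and the
#'   `spec`.
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "sample_spec"))
  extent <- (spec$image_px - 1) * spec$scale
  sep <- spec$min_separation_px * spec$scale
  vein_c <- spec$vein$center; art_c <- spec$artery$center
  vein_r <- spec$vein$diameter / 2; art_r <- spec$artery$diameter / 2
  truth <- with_seed(spec$seed, {
    rows <- list(
      data.frame(type = "vein", center_x_um = vein_c[1], center_y_um = vein_c[2],
                 major_um = spec$vein$diameter, minor_um = spec$vein$diameter,
                 orientation_deg = 0, radius_um = 0),
      data.frame(type = "artery", center_x_um = art_c[1], center_y_um = art_c[2],
                 major_um = spec$artery$diameter, minor_um = spec$artery$diameter,
                 orientation_deg = 0,
                 radius_um = sqrt(sum((art_c - vein_c)^2))))
    acc_x <- numeric(0); acc_y <- numeric(0); acc_a <- numeric(0)
    for (i in seq_len(spec$n_capillaries)) {
      placed <- FALSE
      for (att in seq_len(spec$max_attempts)) {
        r <- draw_radius(spec$radial)
        ang <- stats::runif(1, 0, 2 * pi)
        cx <- vein_c[1] + r * cos(ang); cy <- vein_c[2] + r * sin(ang)
        minor <- draw_diameter(spec$diameter)
        ratio <- stats::runif(1, spec$eccentricity_range[1], spec$eccentricity_range[2])
        major <- minor / ratio
        orient <- stats::runif(1, 0, 180)
        semi <- major / 2
        if (cx < semi + sep || cx > extent - semi - sep ||
            cy < semi + sep || cy > extent - semi - sep) next
        if (r < vein_r + semi + sep) next
        if (sqrt((cx - art_c[1])^2 + (cy - art_c[2])^2) < art_r + semi + sep) next
        if (length(acc_x) &&
            any(sqrt((acc_x - cx)^2 + (acc_y - cy)^2) < acc_a + semi + sep)) next
        acc_x <- c(acc_x, cx); acc_y <- c(acc_y, cy); acc_a <- c(acc_a, semi)
        rows[[length(rows) + 1L]] <- data.frame(
          type = "capillary", center_x_um = cx, center_y_um = cy,
          major_um = major, minor_um = minor, orientation_deg = orient,
          radius_um = r)
        placed <- TRUE
        break
      }
      if (!placed)
        packing_error(sprintf("could not place capillary %d within %d attempts",
                              i, spec$max_attempts), index = i)
    }
    do.call(rbind, rows)
  })
  image <- render_annotation(truth, spec$image_px, spec$scale,
                             convention = spec$convention,
                             anti_alias = spec$anti_alias)
  structure(list(image = image, truth = truth,
                 realized_count = sum(truth$type == "capillary"),
                 spec = spec),
            class = "synthetic_sample")
}

#' Generate a multi-group synthetic study
#'
#' Per-sample seeds are derived deterministically from the study seed.
#' Group effects are expressed as overrides of the base specification; an
#' `n_capillaries` override is interpreted as the group's mean count, with
#' per-sample counts drawn from a Poisson distribution (between-sample
#' variability, as in real histology).
#'
#' @param group_effects Named list (one entry per group) of override lists,
#'   e.g. `list(control = list(n_capillaries = 60), vegf = list(n_capillaries
#'   = 170))`. Overrides other than `n_capillaries` (e.g. `radial`) replace
#'   the base spec's fields directly.
#' @param n_per_group Samples per group.
#' @param seed Study seed.
#' @param base_spec Template [sample_spec()].
#' @return A `synthetic_study`: list of `samples`, each with `sample_id`,
#'   `group` and a fully resolved `spec` (generate images on demand with
#'   [generate_sample()]).
#' @export
generate_study <- function(group_effects, n_per_group, seed = 1,
                           base_spec = sample_spec()) {
  if (length(group_effects) < 2 || is.null(names(group_effects)))
    validation_error("need a named list with at least 2 groups")
  groups <- names(group_effects)
  total <- length(groups) * n_per_group
  plan <- with_seed(seed, {
    seeds <- sample.int(2^31 - 2, total)
    counts <- integer(total)
    i <- 0L
    for (g in groups) {
      lambda <- group_effects[[g]]$n_capillaries %||% base_spec$n_capillaries
      counts[i + seq_len(n_per_group)] <- stats::rpois(n_per_group, lambda)
      i <- i + n_per_group
    }
    list(seeds = seeds, counts = counts)
  })
  samples <- list()
  i <- 0L
  for (g in groups) {
    for (j in seq_len(n_per_group)) {
      i <- i + 1L
      spec <- base_spec
      for (field in setdiff(names(group_effects[[g]]), "n_capillaries"))
        spec[[field]] <- group_effects[[g]][[field]]
      spec$n_capillaries <- plan$counts[i]
      spec$seed <- plan$seeds[i]
      samples[[i]] <- list(sample_id = sprintf("%s_%02d", g, j), group = g,
                           spec = spec)
    }
  }
  structure(list(samples = samples, seed = seed), class = "synthetic_study")
}

#' Write a synthetic sample (PNG + ground-truth CSV) to disk
#'
#' @param sample A `synthetic_sample`.
#' @param dir Output directory (created if needed).
#' @param name Base file name (default `sample`).
#' @return Invisibly, the PNG path.
#' @export
write_sample <- function(sample, dir, name = "sample") {
  stopifnot(inherits(sample, "synthetic_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png_path <- file.path(dir, paste0(name, ".png"))
  write_annotation_image(sample$image, png_path)
  utils::write.csv(sample$truth, file.path(dir, paste0(name, "_truth.csv")),
                   row.names = FALSE)
  invisible(png_path)
}

#' Write a synthetic study (images, truth tables, manifest) to disk
#'
#' The manifest CSV (`filename`, `group`, `seed`) is directly consumable by
#' [run_study()].
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(study$samples, function(s) {
    sm <- generate_sample(s$spec)
    write_sample(sm, dir, s$sample_id)
    data.frame(filename = paste0(s$sample_id, ".png"), group = s$group,
               seed = s$spec$seed, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
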