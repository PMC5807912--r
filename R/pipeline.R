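# End-to-end orchestration: read -> resample -> color split -> detect ->
# identify central vessels -> per-sample metrics -> group statistics.

#' Study configuration
#'
#' All analysis parameters in one place, with the conventional defaults:
#' 2500 px working resolution, 150 um perfusion radius, per-channel color
#' tolerance 40, alpha = 0.05 with Duncan stars at p <= 0.05/0.01/0.001.
#'
#' @param scale Micrometers per pixel of the input scans.
#' @param target_px Square working resolution (default 2500); images already
#'   at this size are left untouched.
#' @param perfusion_radius Expansion radius in um (default 150).
#' @param tolerance Per-channel color tolerance (default 40).
#' @param alpha Significance level (default 0.05).
#' @param min_pixels Minimum mark size in pixels (default 4; 0 keeps all).
#' @param include_central_in_area Include the dilated central artery/vein in
#'   the perfused-area union (default `TRUE`).
#' @param raster_scale Optional finer raster (um/px) for the perfused-area
#'   union; default: the working scale.
#' @param compute Metric stages to run: subset of `"count"`, `"area"`,
#'   `"ingrowth"`, `"diameter"` (the count is always computed).
#' @param diameter_hist,ingrowth_hist [histogram_spec()]s for the study
#'   histograms (defaults: 10 um bins over 0-300 um; 250 um bins over
#'   0-5000 um).
#' @param smoothing_window Moving-average window (bins) for the smoothed
#'   diameter histogram variant (default 3).
#' @param convention Optional [color_convention()]; built from `tolerance`
#'   when missing.
#' @return A `study_config` object.
#' @export
study_config <- function(scale = 1.6, target_px = 2500, perfusion_radius = 150,
                         tolerance = 40, alpha = 0.05, min_pixels = 4,
                         include_central_in_area = TRUE, raster_scale = NULL,
                         compute = c("count", "area", "ingrowth", "diameter"),
                         diameter_hist = histogram_spec(10, c(0, 300)),
                         ingrowth_hist = histogram_spec(250, c(0, 5000)),
                         smoothing_window = 3,
                         convention = NULL) {
  if (!is_scalar_pos(perfusion_radius)) validation_error("perfusion_radius must be positive")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) validation_error("alpha must be in (0, 1)")
  structure(list(scale = scale, target_px = as.integer(target_px),
                 perfusion_radius = perfusion_radius, tolerance = tolerance,
                 alpha = alpha, min_pixels = min_pixels,
                 include_central_in_area = isTRUE(include_central_in_area),
                 raster_scale = raster_scale,
                 compute = match.arg(compute, several.ok = TRUE),
                 diameter_hist = diameter_hist, ingrowth_hist = ingrowth_hist,
                 smoothing_window = as.integer(smoothing_window),
                 convention = convention %||% color_convention(tolerance = tolerance)),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [study_config()]; unknown keys
#' are rejected. Histogram specs are given as nested maps with `bin_width`
#' and `range`.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("config '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    validation_error(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  for (h in c("diameter_hist", "ingrowth_hist"))
    if (!is.null(raw[[h]]))
      raw[[h]] <- do.call(histogram_spec, raw[[h]])
  do.call(study_config, raw)
}

#' Analyze one annotation sample
#'
#' Runs the full per-sample pipeline: read (if given a path), resample to the
#' working resolution, color split, component detection, central-vessel
#' identification, and the five read-out parameters. A sample without a blue
#' central vein is flagged `no_central_vein` and its distance-dependent
#' metrics are `NA`; the run continues.
#'
#' @param image A file path or a [calibrated_image].
#' @param config A [study_config()].
#' @param sample_id Identifier (defaults to the file name, or `"sample"`).
#' @param out_dir If given, the per-vessel table and per-sample metrics CSVs
#'   are written there.
#' @return A `sample_metrics` object; the underlying `vessel_table` is
#'   attached as attribute `"table"`.
#' @export
run_sample <- function(image, config = study_config(), sample_id = NULL,
                       out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.character(image)) {
    sample_id <- sample_id %||% tools::file_path_sans_ext(basename(image))
    image <- read_annotation_image(image, config$scale)
  }
  sample_id <- sample_id %||% "sample"
  stopifnot(inherits(image, "calibrated_image"))
  if (image_width(image) != config$target_px || image_height(image) != config$target_px)
    image <- resample_image(image, config$target_px)
  masks <- color_split(image, config$convention)
  table <- detect_marks(masks, min_pixels = config$min_pixels, sample_id = sample_id)
  table <- identify_central_vessels(table, require_vein = FALSE)
  if (any(c("area", "ingrowth", "diameter") %in% config$compute)) {
    metrics <- compute_sample_metrics(
      table, perfusion_radius = config$perfusion_radius,
      raster_scale = config$raster_scale,
      include_central = config$include_central_in_area)
  } else {
    # count-only fast path (used by large simulation studies)
    metrics <- structure(list(sample_id = sample_id,
                              total_vessel_count = total_vessel_count(table),
                              total_perfused_area_mm2 = NA_real_,
                              vessel_density_per_mm2 = NA_real_,
                              ingrowth_distances_um = numeric(0),
                              diameters_um = numeric(0),
                              perfusion_radius_um = config$perfusion_radius,
                              artery_vein_distance_um = NA_real_,
                              flags = "count_only"),
                         class = "sample_metrics")
  }
  if (!"area" %in% config$compute && !"count_only" %in% metrics$flags) {
    metrics$total_perfused_area_mm2 <- NA_real_
    metrics$vessel_density_per_mm2 <- NA_real_
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vessel_table(table, file.path(out_dir, paste0(sample_id, "_vessels.csv")))
    write_metrics(metrics, file.path(out_dir, paste0(sample_id, "_metrics.csv")))
  }
  attr(metrics, "table") <- table
  metrics
}

study_metric_columns <- c(total_vessel_count = "total_vessel_count",
                          total_perfused_area_mm2 = "total_perfused_area_mm2",
                          vessel_density_per_mm2 = "vessel_density_per_mm2",
                          mean_ingrowth_um = "mean_ingrowth_um",
                          mean_diameter_um = "mean_diameter_um")

#' Aggregate per-sample metrics into group statistics
#'
#' For each metric: per-group mean, SEM and n; one-way ANOVA and Duncan's
#' post hoc test across all groups with at least 2 usable samples. Samples
#' with a missing value for a metric are dropped from that metric only.
#'
#' @param per_sample Data frame with a `group` column plus the metric
#'   columns (as produced by [run_study()]; one row per sample).
#' @param alpha Significance level.
#' @return A `study_summary` object.
#' @export
summarize_study <- function(per_sample, alpha = 0.05) {
  stopifnot(is.data.frame(per_sample), "group" %in% names(per_sample))
  out <- list(alpha = alpha, per_sample = per_sample, metrics = list())
  for (metric in intersect(study_metric_columns, names(per_sample))) {
    vals <- split(per_sample[[metric]], per_sample$group)
    vals <- lapply(vals, function(v) v[!is.na(v)])
    vals <- vals[vapply(vals, length, 1L) > 0]
    if (!length(vals)) next
    entry <- list(groups = lapply(vals, group_summary))
    eligible <- vals[vapply(vals, length, 1L) >= 2]
    dropped <- setdiff(names(vals), names(eligible))
    if (length(dropped))
      warning(sprintf("metric %s: group(s) %s have < 2 samples and are excluded from ANOVA",
                      metric, paste(dropped, collapse = ", ")), call. = FALSE)
    if (length(eligible) >= 2) {
      entry$anova <- tryCatch(one_way_anova(eligible),
                              degenerate_variance_error = function(e) NULL)
      if (!is.null(entry$anova))
        entry$posthoc <- duncan_posthoc(eligible, alpha = alpha)
    }
    out$metrics[[metric]] <- entry
  }
  structure(out, class = "study_summary")
}

#' Run a complete study
#'
#' Accepts a `synthetic_study` (in-memory specifications), a manifest data
#' frame with `filename` and `group` columns, or the path to such a manifest
#' CSV (image paths resolved relative to it). Every sample is analyzed with
#' [run_sample()]; metrics are aggregated per group and compared by ANOVA +
#' Duncan. When `out_dir` is given, writes per-sample CSVs, a per-group
#' metric CSV, pooled per-group diameter and ingrowth histograms
#' (raw/normalized, plus the smoothed normalized diameter variant), and the
#' JSON study summary.
#'
#' @param study Study input (see above).
#' @param config A [study_config()].
#' @param out_dir Optional output directory.
#' @return A `study_summary`; per-sample rows are in `$per_sample`.
#' @export
run_study <- function(study, config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  samples <- list()
  if (inherits(study, "synthetic_study")) {
    for (s in study$samples) {
      img <- generate_sample(s$spec)$image
      samples[[length(samples) + 1L]] <-
        list(metrics = run_sample(img, config, sample_id = s$sample_id,
                                  out_dir = out_dir),
             group = s$group)
    }
  } else {
    if (is.character(study)) {
      base <- dirname(study)
      manifest <- utils::read.csv(study, stringsAsFactors = FALSE)
      manifest$filename <- file.path(base, manifest$filename)
    } else manifest <- study
    if (!all(c("filename", "group") %in% names(manifest)))
      validation_error("manifest needs 'filename' and 'group' columns")
    for (i in seq_len(nrow(manifest)))
      samples[[i]] <- list(metrics = run_sample(manifest$filename[i], config,
                                                out_dir = out_dir),
                           group = manifest$group[i])
  }
  per_sample <- do.call(rbind, lapply(samples, function(s) {
    df <- as.data.frame(s$metrics)
    df$group <- s$group
    df
  }))
  summary <- summarize_study(per_sample, alpha = config$alpha)
  summary$histograms <- study_histograms(samples, config)
  class(summary) <- "study_summary"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics(summary, file.path(out_dir, "group_metrics.csv"))
    utils::write.csv(per_sample, file.path(out_dir, "samples.csv"), row.names = FALSE)
    for (nm in names(summary$histograms))
      utils::write.csv(summary$histograms[[nm]],
                       file.path(out_dir, paste0("hist_", nm, ".csv")),
                       row.names = FALSE)
    write_study_summary(summary, file.path(out_dir, "summary.json"))
  }
  summary
}

study_histograms <- function(samples, config) {
  groups <- unique(vapply(samples, function(s) s$group, ""))
  pools <- list(diameter = lapply(samples, function(s) s$metrics$diameters_um),
                ingrowth = lapply(samples, function(s) s$metrics$ingrowth_distances_um))
  specs <- list(
    diameter = config$diameter_hist,
    diameter_normalized = histogram_spec(config$diameter_hist$bin_width,
                                         config$diameter_hist$range, normalized = TRUE),
    diameter_smoothed = histogram_spec(config$diameter_hist$bin_width,
                                       config$diameter_hist$range, normalized = TRUE,
                                       smoothing_window = config$smoothing_window),
    ingrowth = config$ingrowth_hist,
    ingrowth_normalized = histogram_spec(config$ingrowth_hist$bin_width,
                                         config$ingrowth_hist$range, normalized = TRUE))
  out <- list()
  grp_of <- vapply(samples, function(s) s$group, "")
  for (nm in names(specs)) {
    kind <- if (startsWith(nm, "diameter")) "diameter" else "ingrowth"
    tabs <- lapply(groups, function(g) {
      vals <- unlist(pools[[kind]][grp_of == g], use.names = FALSE)
      h <- vessel_histogram(vals, specs[[nm]])
      h$group <- g
      h
    })
    out[[nm]] <- do.call(rbind, tabs)
  }
  out
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("study summary: %d samples, %d groups (alpha = %g)\n",
              nrow(x$per_sample), length(unique(x$per_sample$group)), x$alpha))
  for (metric in names(x$metrics)) {
    m <- x$metrics[[metric]]
    cat(sprintf("- %s\n", metric))
    for (g in names(m$groups))
      cat(sprintf("    %s: %.4g +/- %.4g (SEM, n = %d)\n",
                  g, m$groups[[g]]$mean, m$groups[[g]]$sem, m$groups[[g]]$n))
    if (!is.null(m$anova))
      cat(sprintf("    ANOVA F(%d,%d) = %.4g, p = %.4g\n", m$anova$df_between,
                  m$anova$df_within, m$anova$F, m$anova$p))
    if (!is.null(m$posthoc)) {
      sig <- m$posthoc$pairs[m$posthoc$pairs$significant, , drop = FALSE]
      if (nrow(sig))
        for (i in seq_len(nrow(sig)))
          cat(sprintf("    %s vs %s %s (p = %.3g)\n", sig$group_a[i],
                      sig$group_b[i], strrep("*", sig$star_level[i]),
                      sig$p_value[i]))
    }
  }
  invisible(x)
}

#' Match detected marks to ground truth
#'
#' Greedy nearest-centroid one-to-one matching between a synthetic sample's
#' ground-truth capillaries and the detected capillary marks. Used to assess
#' the detection-completeness claim of the pipeline.
#'
#' @param truth Ground-truth data frame from [generate_sample()].
#' @param table A detected `vessel_table`.
#' @param tol_um Maximum centroid distance for a match (default 3 pixels at
#'   the table's scale).
#' @return A list with `n_truth`, `n_detected`, `n_matched`, and `accuracy`
#'   (matched / truth).
#' @export
detection_accuracy <- function(truth, table, tol_um = 3 * table$scale) {
  stopifnot(inherits(table, "vessel_table"))
  tru <- truth[truth$type == "capillary", ]
  det <- table$marks[table$marks$type == "capillary", ]
  n_t <- nrow(tru); n_d <- nrow(det)
  if (n_t == 0 || n_d == 0)
    return(list(n_truth = n_t, n_detected = n_d, n_matched = 0L,
                accuracy = if (n_t == 0) 1 else 0))
  d <- outer(tru$center_x_um, det$centroid_x_um, "-")^2 +
       outer(tru$center_y_um, det$centroid_y_um, "-")^2
  d <- sqrt(d)
  matched <- 0L
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] > tol_um) break
    i <- (m - 1) %% n_t + 1; j <- (m - 1) %/% n_t + 1
    matched <- matched + 1L
    d[i, ] <- Inf; d[, j] <- Inf
    if (matched == min(n_t, n_d)) break
  }
  list(n_truth = n_t, n_detected = n_d, n_matched = matched,
       accuracy = matched / n_t)
}
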