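# Image reading, calibration, resampling, color splitting and table output.

test_that("PNG round trip preserves pixels and calibration", {
  marks <- rbind(mark_row("vein", 60, 60, 40),
                 mark_row("artery", 130, 60, 30),
                 mark_row("capillary", 100, 140, 24, 12, 30))
  img <- render_annotation(marks, 200, 1)
  path <- withr::local_tempfile(fileext = ".png")
  write_annotation_image(img, path)
  back <- read_annotation_image(path, scale = 1)
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$scale, 1)

  # native-resolution calibration is stored as given
  back2 <- read_annotation_image(path, scale = 0.644)
  expect_equal(back2$scale, 0.644)
})

test_that("an all-background image reads with zero annotated pixels", {
  img <- calibrated_image(array(255L, c(50, 50, 3)), 1)
  path <- withr::local_tempfile(fileext = ".png")
  write_annotation_image(img, path)
  back <- read_annotation_image(path, 1)
  masks <- color_split(back)
  expect_false(any(masks$artery) || any(masks$vein) || any(masks$capillary))
})

test_that("read errors are classed and informative", {
  expect_error(read_annotation_image("does/not/exist.png", 1), class = "io_error")
  expect_error(read_annotation_image("x.png", 0), class = "validation_error")
  expect_error(read_annotation_image("x.png", c(0.5, 0.7)), class = "validation_error")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(read_annotation_image(bad, 1), class = "io_error")
})

test_that("alpha channels are discarded on read", {
  path <- withr::local_tempfile(fileext = ".png")
  rgba <- array(runif(20 * 20 * 4), c(20, 20, 4))
  png::writePNG(rgba, path)
  img <- read_annotation_image(path, 2)
  expect_equal(dim(img$pixels), c(20L, 20L, 3L))
})

test_that("resampling preserves physical extent and the color palette", {
  marks <- rbind(mark_row("vein", 150, 150, 80), mark_row("artery", 80, 220, 50))
  img <- render_annotation(marks, 500, 0.644)
  out <- resample_image(img, 250)
  expect_equal(dim(out$pixels)[1:2], c(250L, 250L))
  expect_equal(out$scale, 0.644 * 2)
  expect_equal(250 * out$scale, 500 * img$scale, tolerance = 1e-12)
  # nearest neighbor: no colors invented
  cols_of <- function(x) unique(as.vector(x$pixels[, , 1] * 65536L +
                                          x$pixels[, , 2] * 256L + x$pixels[, , 3]))
  expect_true(all(cols_of(out) %in% cols_of(img)))
})

test_that("resampling an image already at target size is the identity", {
  img <- render_annotation(mark_row("vein", 30, 30, 20), 64, 1)
  expect_identical(resample_image(img, 64), img)
})

test_that("non-square inputs keep aspect ratio and pad to square", {
  px <- array(255L, c(80, 120, 3))
  px[40, 60, ] <- c(0L, 0L, 255L)
  img <- calibrated_image(px, 1)
  out <- resample_image(img, 60)
  expect_equal(dim(out$pixels)[1:2], c(60L, 60L))
  expect_equal(out$scale, 2)  # ratio = 120/60
  # padded rows (beyond 80/2 = 40) are background
  expect_true(all(out$pixels[41:60, , ] == 255L))
})

test_that("color split separates the three classes into disjoint masks", {
  marks <- rbind(mark_row("artery", 50, 50, 30),
                 mark_row("vein", 130, 50, 36),
                 mark_row("capillary", 90, 140, 40, 20, 25))
  img <- render_annotation(marks, 180, 1)
  masks <- color_split(img)
  for (cls in c("artery", "vein", "capillary"))
    expect_equal(max(label_components(masks[[cls]])), 1)
  # pairwise disjoint, union within the non-background pixels
  expect_false(any(masks$artery & masks$vein))
  expect_false(any(masks$artery & masks$capillary))
  expect_false(any(masks$vein & masks$capillary))
  background <- img$pixels[, , 1] == 255L & img$pixels[, , 2] == 255L &
    img$pixels[, , 3] == 255L
  expect_false(any((masks$artery | masks$vein | masks$capillary) & background))
  # disk pixel count matches the analytic area within rasterization error
  expect_equal(sum(masks$artery), pi * 15^2, tolerance = 0.05)
})

test_that("anti-aliased edges survive a tolerant color split", {
  disk <- mark_row("artery", 150, 150, 200)
  hard <- sum(color_split(render_annotation(disk, 300, 1))$artery)
  soft <- sum(color_split(render_annotation(disk, 300, 1, anti_alias = TRUE),
                          color_convention(tolerance = 30))$artery)
  expect_lt(abs(soft - hard) / hard, 0.05)
})

test_that("reference colors closer than twice the tolerance are rejected", {
  expect_error(color_convention(artery = c(255, 0, 0), vein = c(200, 0, 0),
                                capillary = c(0, 255, 0), tolerance = 40),
               class = "validation_error")
  expect_silent(color_convention(tolerance = 40))
})

test_that("vessel tables round-trip through CSV losslessly", {
  tab <- detect_fixture(rbind(mark_row("vein", 60, 60, 40),
                              mark_row("artery", 140, 60, 30),
                              mark_row("capillary", 100, 150, 25, 13, 80)), 200)
  path <- withr::local_tempfile(fileext = ".csv")
  write_vessel_table(tab, path)
  back <- read_vessel_table(path, scale = 1)
  expect_equal(back$marks, tab$marks, tolerance = 1e-9)

  # empty table: header-only CSV
  empty <- detect_marks(color_split(render_annotation(mark_row("vein", 1, 1, 0.1),
                                                      20, 1)))
  write_vessel_table(empty, path)
  expect_equal(nrow(utils::read.csv(path)), 0)
  expect_equal(names(utils::read.csv(path)),
               c("id", "type", "centroid_x_um", "centroid_y_um", "area_um2",
                 "major_axis_um", "minor_axis_um", "pixel_count"))
})

test_that("sample metrics serialize as one row with the five parameters", {
  tab <- detect_fixture(rbind(mark_row("vein", 200, 200, 60),
                              mark_row("artery", 320, 200, 40),
                              mark_row("capillary", 200, 350, 20),
                              mark_row("capillary", 80, 180, 16)), 500, 2)
  m <- compute_sample_metrics(tab)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics(m, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 1)
  expect_true(all(c("total_vessel_count", "total_perfused_area_mm2",
                    "vessel_density_per_mm2", "mean_ingrowth_um",
                    "mean_diameter_um") %in% names(df)))
  expect_equal(df$total_vessel_count, 2)
})
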