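# The five read-out parameters and their histogram representations.

central_pair <- function(cx = 400, cy = 400)
  rbind(mark_row("vein", cx, cy, 60), mark_row("artery", cx + 120, cy, 40))

test_that("total vessel count excludes the central artery and vein", {
  tab <- detect_fixture(rbind(central_pair(),
                              mark_row("capillary", 200, 200, 20),
                              mark_row("capillary", 600, 300, 18)), 800, 2)
  expect_equal(total_vessel_count(tab), 2)
  only_central <- detect_fixture(central_pair(), 800, 2)
  expect_equal(total_vessel_count(only_central), 0)
})

test_that("perfused area matches the closed-form disk and annulus", {
  tab <- detect_fixture(mark_row("capillary", 300, 300, 100), 600, identify = FALSE)
  a <- perfused_area(tab, 150)
  expect_equal(a, pi * 200^2 / 1e6, tolerance = 0.01)
  annulus <- a - tab$marks$area_um2 / 1e6
  expect_equal(annulus, pi * (200^2 - 50^2) / 1e6, tolerance = 0.01)
})

test_that("disjoint marks add, overlapping marks union-count once", {
  two <- function(d) rbind(mark_row("capillary", 300, 300, 50),
                           mark_row("capillary", 300 + d, 300, 50))
  far <- perfused_area(detect_fixture(two(600), 1200, identify = FALSE), 150)
  expect_equal(far, 2 * pi * 175^2 / 1e6, tolerance = 0.01)
  near <- perfused_area(detect_fixture(two(100), 800, identify = FALSE), 150)
  oracle <- (2 * pi * 175^2 - lens_area(100, 175, 175)) / 1e6
  expect_equal(near, oracle, tolerance = 0.01)
  expect_lt(near, far)
})

test_that("perfused area is monotone in radius and bounded by its parts", {
  marks <- rbind(central_pair(300, 300), mark_row("capillary", 150, 450, 24),
                 mark_row("capillary", 460, 420, 18))
  tab <- detect_fixture(marks, 600, identify = FALSE)
  radii <- c(50, 100, 150, 250)
  areas <- vapply(radii, function(r) perfused_area(tab, r), 1.0)
  expect_true(all(diff(areas) > 0))
  # union <= sum of single-mark dilations, >= the largest single dilation
  singles <- vapply(seq_len(nrow(tab$marks)), function(i) {
    one <- tab; one$marks <- one$marks[i, , drop = FALSE]; one$pixels <- one$pixels[i]
    perfused_area(one, 150)
  }, 1.0)
  expect_lte(areas[3], sum(singles))
  expect_gte(areas[3], max(singles))
})

test_that("central marks can be excluded from the perfused-area union", {
  tab <- detect_fixture(rbind(central_pair(300, 300),
                              mark_row("capillary", 150, 120, 20)), 600, 2)
  with_central <- perfused_area(tab, 150, include_central = TRUE)
  without <- perfused_area(tab, 150, include_central = FALSE)
  expect_lt(without, with_central)
  expect_equal(without, pi * 160^2 / 1e6, tolerance = 0.01)
})

test_that("a finer evaluation raster refines the same area estimate", {
  tab <- detect_fixture(mark_row("capillary", 300, 300, 100), 300, 2,
                        identify = FALSE)
  coarse <- perfused_area(tab, 150)
  fine <- perfused_area(tab, 150, raster_scale = 1)
  expect_equal(fine, coarse, tolerance = 0.02)
  expect_equal(fine, pi * 200^2 / 1e6, tolerance = 0.01)
})

test_that("vessel density follows the count/area conventions", {
  expect_equal(vessel_density(100, 1.0), 100)
  expect_equal(vessel_density(0, 0), 0)
  expect_error(vessel_density(3, 0), class = "impossible_state_error")
})

test_that("ingrowth distance is the Euclidean centroid distance", {
  mark <- list(centroid_x_um = 300, centroid_y_um = 400)
  vein <- list(centroid_x_um = 0, centroid_y_um = 0)
  expect_equal(ingrowth_distance(mark, vein), 500)
  expect_equal(ingrowth_distance(vein, vein), 0)
  tab <- detect_fixture(mark_row("capillary", 50, 50, 20), 100, identify = FALSE)
  expect_error(ingrowth_distances(tab), class = "missing_reference_error")
})

test_that("diameter is the minor axis, equal to major for circles", {
  expect_equal(vessel_diameter(list(minor_axis_um = 12.5)), 12.5)
  tab <- detect_fixture(mark_row("capillary", 100, 100, 60), 200, identify = FALSE)
  expect_equal(tab$marks$minor_axis_um, tab$marks$major_axis_um, tolerance = 0.02)
  tab2 <- detect_fixture(mark_row("capillary", 150, 150, 200, 80, 55), 300,
                         identify = FALSE)
  expect_equal(vessel_diameters(tab2), 80, tolerance = 0.02)
})

test_that("histograms bin, normalize and smooth as specified", {
  h <- vessel_histogram(c(5, 15, 25), histogram_spec(10, c(0, 30)))
  expect_equal(h$height, c(1, 1, 1))
  expect_equal(h$bin_center, c(5, 15, 25))
  hn <- vessel_histogram(c(5, 15, 25), histogram_spec(10, c(0, 30), normalized = TRUE))
  expect_equal(hn$height, rep(1 / 3, 3))
  expect_equal(sum(hn$height), 1, tolerance = 1e-9)
  hs <- vessel_histogram(c(15, 15, 15),
                         histogram_spec(10, c(0, 30), smoothing_window = 3))
  expect_equal(hs$height, c(1, 1, 1))
  empty <- vessel_histogram(numeric(0), histogram_spec(10, c(0, 30), normalized = TRUE))
  expect_equal(empty$height, c(0, 0, 0))
  expect_error(histogram_spec(10, c(0, 30), smoothing_window = 2),
               class = "validation_error")
})

test_that("normalized histograms of random data sum to one", {
  set.seed(31)
  for (i in 1:10) {
    v <- rlnorm(sample(1:200, 1), log(15), 0.5)
    h <- vessel_histogram(v, histogram_spec(10, c(0, 300), normalized = TRUE))
    expect_equal(sum(h$height), 1, tolerance = 1e-9)
  }
})

test_that("sample metrics satisfy the structural invariants", {
  tab <- detect_fixture(rbind(central_pair(500, 500),
                              mark_row("capillary", 250, 250, 22, 14, 10),
                              mark_row("capillary", 700, 600, 18),
                              mark_row("capillary", 420, 760, 26, 12, 140)),
                        1000, 1.6)
  m <- compute_sample_metrics(tab)
  expect_equal(m$total_vessel_count, length(m$ingrowth_distances_um))
  expect_equal(m$total_vessel_count, length(m$diameters_um))
  expect_gt(m$total_perfused_area_mm2, 0)
  expect_equal(m$vessel_density_per_mm2 * m$total_perfused_area_mm2,
               m$total_vessel_count, tolerance = 1e-9)
  expect_equal(m$artery_vein_distance_um, 120, tolerance = 2)
})
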