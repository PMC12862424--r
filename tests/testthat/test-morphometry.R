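test_that("patch_area matches the analytic area of a planar point grid", {
  g <- expand.grid(x = (0:9) * 0.1, y = (0:9) * 0.1)
  p <- fake_patch(cbind(g$x, g$y, 0))
  a <- patch_area(p, 0.1)
  expect_equal(a, 1.0, tolerance = 0.1)   # one boundary-pixel ring at most
  # translation invariance
  p2 <- fake_patch(cbind(g$x + 12.3, g$y - 4.56, 7.89))
  expect_equal(patch_area(p2, 0.1), a)
})

test_that("patch_area is invariant under rigid rotation", {
  g <- expand.grid(x = (0:19) * 0.1, y = (0:9) * 0.1)
  pts <- cbind(g$x, g$y, 0)
  a0 <- patch_area(fake_patch(pts), 0.1)
  R <- rotation_matrix(c(1, 2, 0.5), 0.7)
  pr <- pts %*% t(R)
  ar <- patch_area(fake_patch(pr, plane_point = colMeans(pr),
                              plane_normal = R %*% c(0, 0, 1)), 0.1)
  expect_lt(abs(ar - a0) / a0, 0.01)
})

test_that("area scales quadratically and extents linearly with size", {
  g <- expand.grid(x = (0:19) * 0.1, y = (0:9) * 0.1)
  pts <- cbind(g$x, g$y, 0)
  p1 <- fake_patch(pts)
  p2 <- fake_patch(pts * 2)
  expect_equal(patch_area(p2, 0.2) / patch_area(p1, 0.1), 4,
               tolerance = 0.02)
  ax <- c(1, 0, 0)
  expect_equal(max_extent(p2, ax) / max_extent(p1, ax), 2)
})

test_that("max_extent projects onto the requested axis", {
  p <- fake_patch(rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 0)))
  expect_equal(max_extent(p, c(3, 4, 0) / 5), 5)
  line <- fake_patch(cbind(1:5, 0, 0))
  expect_equal(max_extent(line, c(0, 1, 0)), 0)
  expect_error(max_extent(line, c(1, 1, 0)), class = "fp_error_value")
})

test_that("center_thickness counts the sheet column along the normal", {
  mask <- array(FALSE, c(10, 10, 12))
  mask[, , 4:9] <- TRUE                  # 6 voxels thick
  plane <- list(point = c(0, 0, 0), normal = c(0, 0, 1))
  expect_equal(center_thickness(mask, rep(0.1, 3), plane), 0.6)
  one <- array(FALSE, c(5, 5, 5)); one[, , 3] <- TRUE
  expect_equal(center_thickness(one, rep(0.1, 3), plane), 0.1)
  # doubling the spacing doubles the thickness
  expect_equal(center_thickness(mask, rep(0.2, 3), plane), 1.2)
  expect_error(center_thickness(array(FALSE, c(3, 3, 3)), rep(1, 3), plane),
               class = "fp_error_value")
})

test_that("center thickness of the phantom sheet matches the design", {
  ph <- cached_phantom()
  tf <- extract_label_mask(ph$volume, "tfcc")
  th <- center_thickness(tf, ph$volume$spacing,
                         ph$truth$footprint_plane)
  expect_equal(th, ph$truth$tfc_center_thickness, tolerance = 0.26)
})

test_that("classify_shape applies the elongation/solidity rules", {
  band <- structure(list(elongation = 3.37, solidity = 0.95, area = 43.4,
                         dv_length = 13.4, ru_length = 3.98),
                    class = "shape_descriptors")
  expect_equal(as.character(classify_shape(band)), "ribbon")
  square <- structure(list(elongation = 1.0, solidity = 0.99, area = 25,
                           dv_length = 5, ru_length = 5),
                      class = "shape_descriptors")
  expect_equal(as.character(classify_shape(square)),
               "irregular_quadrilateral")
  # crescent points rasterized from the template, hull-area oracle
  tpl <- footprintr:::footprint_template("semilunar", 13.4, 3.98)
  g <- expand.grid(u = seq(-7, 7, 0.1), v = seq(-7, 7, 0.1))
  inside <- tpl$sdf(g$u, g$v) <= 0
  pts <- cbind(g$u[inside], g$v[inside], 0)
  p <- fake_patch(pts)
  desc <- shape_descriptors(p)
  hull <- grDevices::chull(pts[, 1:2])
  hull_area <- footprintr:::polygon_area(pts[hull, 1:2])
  expect_equal(desc$solidity, tpl$area / hull_area, tolerance = 0.02)
  expect_lt(desc$solidity, 0.8)
  expect_equal(as.character(classify_shape(desc)), "semilunar")
})

test_that("measure_patch bundles reproducible morphometry", {
  patch <- cached_deep_patch()
  m1 <- measure_patch(patch)
  m2 <- measure_patch(patch)
  expect_identical(unclass(m1), unclass(m2))
  expect_equal(m1$shape, "ribbon")
  # swapping the DV and RU axes exchanges the reported lengths
  swapped <- anatomical_frame(dv_axis = c(0, 1, 0), ru_axis = c(1, 0, 0),
                              pd_axis = c(0, 0, -1))
  ms <- measure_patch(patch, frame = swapped)
  expect_equal(ms$dv_length, m1$ru_length)
  expect_equal(ms$ru_length, m1$dv_length)
})

test_that("phantom DV/RU lengths are recovered within tolerance", {
  ph <- cached_phantom()
  m <- measure_patch(cached_deep_patch())
  s <- max(ph$volume$spacing)
  # tolerance: 5% plus the two half-voxel rings lost to centre sampling
  expect_lt(abs(m$dv_length - ph$truth$dv_length),
            0.05 * ph$truth$dv_length + 2 * s)
  expect_lt(abs(m$ru_length - ph$truth$ru_length),
            0.05 * ph$truth$ru_length + 2 * s)
})
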