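test_that("phantom generation is deterministic for a fixed spec", {
  spec <- phantom_spec(spacing = rep(0.3, 3), seed = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth, b$truth)
  spec2 <- phantom_spec(spacing = rep(0.3, 3), seed = 6)
  expect_false(identical(generate_phantom(spec2)$volume$voxels,
                         a$volume$voxels))
})

test_that("closed-form template areas agree with Monte-Carlo rasterization", {
  L <- 13.4; W <- 3.98
  ribbon <- footprintr:::footprint_template("ribbon", L, W)
  expect_equal(ribbon$area, (L - W) * W + pi * (W / 2)^2)
  mc <- mc_area_2d(function(x, y) ribbon$sdf(x, y) <= 0,
                   c(-7.5, 7.5), c(-2.5, 2.5))
  expect_equal(ribbon$area, mc, tolerance = 0.01)

  quad <- footprintr:::footprint_template("irregular_quadrilateral", 9, 6)
  mcq <- mc_area_2d(function(x, y) quad$sdf(x, y) <= 0,
                    c(-5, 5), c(-3.5, 3.5))
  expect_equal(quad$area, mcq, tolerance = 0.01)

  cres <- footprintr:::footprint_template("semilunar", L, W)
  mcc <- mc_area_2d(function(x, y) cres$sdf(x, y) <= 0,
                    c(-7, 7), c(-7, 7))
  expect_equal(cres$area, mcc, tolerance = 0.01)
  expect_equal(cres$dv, L)
  expect_equal(cres$ru, L / 2 + W / 2)
})

test_that("phantom truth carries the closed-form template values", {
  ph <- cached_phantom()
  expect_equal(ph$truth$deep_area,
               (13.4 - 3.98) * 3.98 + pi * (3.98 / 2)^2)
  expect_equal(ph$truth$shape, "ribbon")
  expect_gte(ph$truth$dv_length, ph$truth$ru_length)  # ribbon invariant
  expect_equal(ph$truth$superficial_area, 20.11)
  expect_equal(ph$truth$tfc_center_thickness, 0.6)
  expect_equal(ph$truth$footprint_plane$normal, c(0, 0, 1))
})

test_that("voxel-centre counts of the template converge to the truth area", {
  # at 0.1 mm the discretized template area is within 2% of closed form
  tpl <- footprintr:::footprint_template("ribbon", 13.4, 3.98)
  for (res in c(0.1, 0.05)) {
    g <- expand.grid(u = seq(-7, 7, by = res), v = seq(-2.5, 2.5, by = res))
    est <- sum(tpl$sdf(g$u, g$v) <= 0) * res^2
    expect_equal(est, tpl$area, tolerance = 0.02)
  }
})

test_that("phantom labels and structure separation are as designed", {
  ph <- cached_phantom()
  vox <- ph$volume$voxels
  expect_setequal(unique(as.vector(vox)), 0:3)
  # the sheet never touches bone interiors: every TFCC voxel is outside
  # the eroded bone masks
  bones <- vox == 1L | vox == 2L
  interior <- erode6_oracle(bones)
  expect_equal(sum(vox == 3L & interior), 0)
})

test_that("a footprint too large for the head raises a geometry error", {
  expect_error(phantom_spec(footprint_dv_length = 25,
                            footprint_ru_width = 6),
               class = "fp_error_geometry")
  expect_error(phantom_spec(ulna_head_radius = -1),
               class = "fp_error_usage")
})

test_that("disabling the superficial patch removes its contact", {
  ph <- cached_phantom("nosup", spacing = rep(0.3, 3),
                       superficial_patch_area = 0, seed = 2)
  expect_equal(ph$truth$superficial_area, 0)
  # all TFCC voxels adjacent to ulna must be close to the fovea centre,
  # not near the styloid apex
  vox <- ph$volume$voxels
  tf <- vox == 3L; ul <- vox == 2L
  inter <- tf & !erode6_oracle(!ul)   # TFCC voxels face-adjacent to ulna
  w <- which(inter, arr.ind = TRUE)
  pts <- voxel_to_world(ph$volume, w - 1)
  sty <- ph$truth$landmarks$styloid_apex
  fov <- ph$truth$landmarks$fovea
  d_f <- sqrt(rowSums(sweep(pts, 2, fov)^2))
  d_s <- sqrt(rowSums(sweep(pts, 2, sty)^2))
  expect_true(all(d_f < d_s))
})

test_that("paired-measurement simulator matches its variance design", {
  exact <- simulate_paired_measurements(10, 4, 0, 0, seed = 1)
  expect_equal(exact$method_a, exact$method_b)
  expect_equal(attr(simulate_paired_measurements(5, 9, 1, 1, seed = 1),
                    "theoretical_icc"), 0.9)
  expect_error(simulate_paired_measurements(1, 1, 1, 1),
               class = "fp_error_usage")
  expect_error(simulate_paired_measurements(5, -1, 1, 1),
               class = "fp_error_usage")
  # n = 500 at theoretical ICC 0.9: downstream estimate within 0.03
  tab <- simulate_paired_measurements(500, 9, 1, 1, seed = 7)
  est <- icc_two_way(tab$method_a, tab$method_b)$estimate
  expect_lt(abs(est - 0.9), 0.03)
})
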