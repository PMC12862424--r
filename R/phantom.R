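#' Specification of a synthetic wrist phantom
#'
#' Defines the geometry of a seeded synthetic distal-forearm phantom: an
#' ulna (spherical head truncated by a flat articular facet, plus a conical
#' styloid), a radius slab, and a constant-thickness fibrocartilage sheet
#' (TFCC) suspended above the facet. The sheet dips down to touch the facet
#' over one or two designed contact patches whose continuous geometry --
#' area, dorsal-volar (DV) and radial-ulnar (RU) extents, shape class -- is
#' known in closed form before voxelization.
#'
#' The deep insertion patch is one of three planar templates:
#' \describe{
#'   \item{ribbon}{a stadium (rectangle of length `L - W` capped by two
#'     half-discs of radius `W/2`); area `(L - W) W + pi (W/2)^2`.}
#'   \item{irregular_quadrilateral}{a fixed asymmetric convex quadrilateral
#'     with extents `L` x `W`; area by the shoelace formula.}
#'   \item{semilunar}{a crescent: a disc of radius `L/2` minus the same
#'     disc offset by `W` along RU; area in closed form from the
#'     lens-intersection formula.}
#' }
#' The optional superficial patch is a disc of the requested area placed on
#' the same facet next to the styloid base, at least 2 mm from the deep
#' patch.
#'
#' @param grid_shape Integer voxel triple, or `NULL` (default) to auto-size
#'   the grid to the geometry plus margins.
#' @param spacing Voxel spacing in mm (default isotropic 0.1 mm, the
#'   super-resolved working resolution of the pipeline).
#' @param ulna_head_radius Head sphere radius in mm (default 12; broadened
#'   so the flat facet can host both insertion patches).
#' @param styloid_height Cone height in mm (default 4).
#' @param tfc_thickness Sheet thickness in mm (default 0.6).
#' @param footprint_shape `"ribbon"`, `"irregular_quadrilateral"` or
#'   `"semilunar"`.
#' @param footprint_dv_length Designed DV extent of the deep patch, mm
#'   (default 13.40).
#' @param footprint_ru_width Designed RU width parameter, mm (default
#'   3.98); for the crescent it is the band thickness at mid-length.
#' @param superficial_patch_area Superficial disc area in mm^2 (default
#'   20.11; 0 disables the patch).
#' @param frame [anatomical_frame()]; the phantom is built with x = DV,
#'   y = RU, z = proximal-distal.
#' @param noise_level Standard deviation of Gaussian jitter applied to the
#'   signed-distance threshold at voxelization, in voxel units (default 0).
#' @param seed Integer RNG seed (default 1).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = NULL, spacing = c(0.1, 0.1, 0.1),
                         ulna_head_radius = 12, styloid_height = 4,
                         tfc_thickness = 0.6,
                         footprint_shape = c("ribbon",
                                             "irregular_quadrilateral",
                                             "semilunar"),
                         footprint_dv_length = 13.40,
                         footprint_ru_width = 3.98,
                         superficial_patch_area = 20.11,
                         frame = anatomical_frame(),
                         noise_level = 0, seed = 1L) {
  footprint_shape <- match.arg(footprint_shape)
  geo <- c(ulna_head_radius = ulna_head_radius,
           styloid_height = styloid_height, tfc_thickness = tfc_thickness,
           footprint_dv_length = footprint_dv_length,
           footprint_ru_width = footprint_ru_width)
  for (nm in names(geo))
    if (!is.numeric(geo[[nm]]) || !is.finite(geo[[nm]]) || geo[[nm]] <= 0)
      stop_fp(paste0("'", nm, "' must be a positive number"),
              "fp_error_usage", field = nm)
  if (superficial_patch_area < 0)
    stop_fp("'superficial_patch_area' must be >= 0", "fp_error_usage",
            field = "superficial_patch_area")
  if (footprint_ru_width >= footprint_dv_length)
    stop_fp("footprint_ru_width must be smaller than footprint_dv_length",
            "fp_error_usage", field = "footprint_ru_width")
  if (noise_level < 0)
    stop_fp("'noise_level' must be >= 0", "fp_error_usage",
            field = "noise_level")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_fp("'spacing' must be a positive mm triple", "fp_error_usage",
            field = "spacing")
  spec <- structure(list(
    grid_shape = grid_shape, spacing = spacing,
    ulna_head_radius = ulna_head_radius, styloid_height = styloid_height,
    tfc_thickness = tfc_thickness, footprint_shape = footprint_shape,
    footprint_dv_length = footprint_dv_length,
    footprint_ru_width = footprint_ru_width,
    superficial_patch_area = superficial_patch_area, frame = frame,
    noise_level = noise_level, seed = as.integer(seed)),
    class = "phantom_spec")
  layout <- phantom_layout(spec)   # validates that the footprint fits
  if (!is.null(grid_shape)) {
    grid_shape <- as.integer(grid_shape)
    if (length(grid_shape) != 3L || any(grid_shape < 1L))
      stop_fp("'grid_shape' must be a positive integer triple",
              "fp_error_usage", field = "grid_shape")
    if (any(grid_shape < layout$grid_shape))
      stop_fp(paste0("grid_shape too small for the footprint geometry; ",
                     "need at least ",
                     paste(layout$grid_shape, collapse = " x ")),
              "fp_error_geometry", field = "grid_shape")
    spec$grid_shape <- grid_shape
  } else {
    spec$grid_shape <- layout$grid_shape
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", x$footprint_shape, "deep footprint",
      sprintf("%.2f x %.2f mm,", x$footprint_dv_length,
              x$footprint_ru_width),
      sprintf("superficial %.2f mm^2\n", x$superficial_patch_area))
  cat("  grid", paste(x$grid_shape, collapse = " x "), "at",
      paste(format(x$spacing), collapse = " x "), "mm; noise",
      x$noise_level, "voxels; seed", x$seed, "\n")
  invisible(x)
}

# ---- planar footprint templates ------------------------------------------

# Each template exposes: sdf(u, v) vectorized signed distance (<= 0 inside),
# closed-form area, dv/ru extents, and the circumradius about the centre.
footprint_template <- function(shape, L, W) {
  if (shape == "ribbon") {
    a <- (L - W) / 2   # half-length of the straight segment
    r <- W / 2
    list(sdf = function(u, v) {
           du <- pmax(abs(u) - a, 0)
           sqrt(du^2 + v^2) - r
         },
         area = (L - W) * W + pi * r^2,
         dv = L, ru = W, circumradius = L / 2)
  } else if (shape == "irregular_quadrilateral") {
    vx <- c(-0.50, 0.10, 0.50, -0.15) * L
    vy <- c(-0.10, -0.50, 0.15, 0.50) * W
    # shoelace area (vertices are ordered counter-clockwise)
    area <- 0.5 * abs(sum(vx * vy[c(2:4, 1)] - vx[c(2:4, 1)] * vy))
    list(sdf = function(u, v) {
           d <- rep(-Inf, length(u))
           for (e in 1:4) {
             f <- if (e == 4) 1 else e + 1
             ex <- vx[f] - vx[e]; ey <- vy[f] - vy[e]
             len <- sqrt(ex^2 + ey^2)
             # outward normal of a CCW edge
             d <- pmax(d, ((u - vx[e]) * ey - (v - vy[e]) * ex) / len)
           }
           d
         },
         area = area, dv = L, ru = W, circumradius = max(sqrt(vx^2 + vy^2)))
  } else if (shape == "semilunar") {
    R1 <- L / 2; d <- W
    lens <- 2 * R1^2 * acos(d / (2 * R1)) -
      (d / 2) * sqrt(4 * R1^2 - d^2)
    list(sdf = function(u, v) {
           d1 <- sqrt(u^2 + v^2) - R1
           d2 <- R1 - sqrt(u^2 + (v - d)^2)   # carve the offset disc
           pmax(d1, d2)
         },
         area = pi * R1^2 - lens,
         dv = L, ru = R1 + d / 2, circumradius = R1)
  } else stop_fp("unknown footprint shape", "fp_error_usage")
}

# ---- geometric layout -----------------------------------------------------

# World-coordinate placement of every phantom element, plus the minimal
# grid. Constants: 1.0 mm sheet-to-facet gap, 2.0 mm deep/superficial
# separation, 0.8 mm facet margin, 2.0 mm thick radius slab.
phantom_layout <- function(spec) {
  R <- spec$ulna_head_radius
  tpl <- footprint_template(spec$footprint_shape, spec$footprint_dv_length,
                            spec$footprint_ru_width)
  r_s <- if (spec$superficial_patch_area > 0)
    sqrt(spec$superficial_patch_area / pi) else 0
  sup_off <- if (r_s > 0) tpl$ru / 2 + 2.0 + r_s else 0
  a_f <- max(tpl$circumradius, if (r_s > 0) sup_off + r_s else 0) + 0.8
  if (a_f > 0.85 * R)
    stop_fp(sprintf(paste0("footprint template (facet radius %.2f mm) ",
                           "exceeds the ulnar head surface (radius %.2f mm)"),
                    a_f, R), "fp_error_geometry")
  h <- sqrt(R^2 - a_f^2)
  gap <- 1.0
  t <- spec$tfc_thickness
  z_below <- 3.0
  Fz <- z_below + 0.03
  rho_dome <- if (h > z_below) sqrt(R^2 - (h - z_below)^2) else R
  s <- spec$spacing
  Fx <- rho_dome + 1.0
  y_r0 <- 0.3; rad_th <- 2.0
  Fy <- y_r0 + rad_th + 1.2 + rho_dome
  # styloid cone just beyond the facet rim; vertical offsets are kept
  # relative to Fz so the whole assembly can be placed with sub-voxel
  # jitter at generation time
  y_st_off <- a_f + 0.9
  r_c <- 1.3
  dz_surf <- if (y_st_off < 0.995 * R) -h + sqrt(R^2 - y_st_off^2) else -h
  base_dz <- dz_surf - 0.5
  apex_dz <- base_dz + spec$styloid_height
  a_sheet <- a_f + 0.8
  r_carve <- r_c * max(0, 1 + base_dz / spec$styloid_height) + 0.8
  x_max <- 2 * Fx + 1.0
  y_max <- max(Fy + y_st_off + r_c + 1.0, Fy + a_sheet + 1.0) + 1.0
  z_max <- max(Fz + gap + t + 1.2, Fz + apex_dz + 0.8) + 1.0
  grid_shape <- as.integer(ceiling(c(x_max / s[1], y_max / s[2],
                                     z_max / s[3])))
  list(template = tpl, r_s = r_s, sup_off = sup_off, a_f = a_f, h = h,
       gap = gap, t = t, Fx = Fx, Fy = Fy, Fz = Fz, y_st_off = y_st_off,
       r_c = r_c, base_dz = base_dz, apex_dz = apex_dz, a_sheet = a_sheet,
       r_carve = r_carve, y_r0 = y_r0, rad_th = rad_th,
       grid_shape = grid_shape)
}

#' Generate a synthetic wrist phantom with known footprint truth
#'
#' Voxelizes the analytic phantom geometry of a [phantom_spec()] onto its
#' grid and returns the label volume together with the continuous-geometry
#' ground truth. Voxels take a label when the structure's signed distance
#' (optionally jittered by seeded Gaussian noise of `noise_level` voxels)
#' is non-positive; bone always wins over the soft-tissue sheet, so the
#' sheet never invades bone interiors. Deterministic for a fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `volume` (a [label_volume()]) and `truth`
#'   (class `phantom_truth`: closed-form `deep_area`, `superficial_area`,
#'   `dv_length`, `ru_length`, `shape`, `tfc_center_thickness`,
#'   `footprint_plane` and `landmarks`).
#' @export
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_spec(spacing = c(0.2, 0.2, 0.2)))
#' ph$truth$deep_area
#' }
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ly <- phantom_layout(spec)
  d <- spec$grid_shape
  s <- spec$spacing
  n <- prod(d)

  # seeded sub-voxel placement jitter: emulates arbitrary positioning of
  # the anatomy relative to the voxel lattice, the dominant source of
  # discretisation variability across acquisitions
  rng <- with_private_seed(spec$seed, {
    list(jitter = stats::runif(3, 0, s),
         noise = if (spec$noise_level > 0)
           matrix(rnorm(3 * n, 0, spec$noise_level * mean(s)), ncol = 3))
  })
  Fx <- ly$Fx + rng$jitter[1]
  Fy <- ly$Fy + rng$jitter[2]
  Fz <- ly$Fz + rng$jitter[3]

  xs <- (seq_len(d[1]) - 1) * s[1]
  ys <- (seq_len(d[2]) - 1) * s[2]
  zs <- (seq_len(d[3]) - 1) * s[3]
  ii <- rep(xs, times = d[2] * d[3])
  jj <- rep(rep(ys, each = d[1]), times = d[3])
  kk <- rep(zs, each = d[1] * d[2])

  R <- spec$ulna_head_radius
  Cz <- Fz - ly$h
  u <- ii - Fx
  v <- jj - Fy
  rho2 <- u^2 + v^2

  sdf_dome <- pmax(sqrt(rho2 + (kk - Cz)^2) - R, kk - Fz)
  y_st <- Fy + ly$y_st_off
  base_z <- Fz + ly$base_dz
  apex_z <- Fz + ly$apex_dz
  rho_st <- sqrt(u^2 + (jj - y_st)^2)
  r_at <- ly$r_c * (1 - (kk - base_z) / spec$styloid_height)
  sdf_cone <- pmax(rho_st - r_at, base_z - kk, kk - apex_z)
  sdf_ulna <- pmin(sdf_dome, sdf_cone)

  x_max <- d[1] * s[1]
  sdf_rad <- pmax(1.0 - ii, ii - (x_max - 1.0), ly$y_r0 - jj,
                  jj - (ly$y_r0 + ly$rad_th), kk - Fz)

  in_deep <- ly$template$sdf(u, v) <= 0
  in_patch <- in_deep
  if (ly$r_s > 0)
    in_patch <- in_patch | (sqrt(u^2 + (v - ly$sup_off)^2) <= ly$r_s)
  zb <- ifelse(in_patch, Fz, Fz + ly$gap)
  sdf_tfcc <- pmax(zb - kk, kk - (zb + ly$t),
                   sqrt(rho2) - ly$a_sheet, ly$r_carve - rho_st)

  if (!is.null(rng$noise)) {
    sdf_rad <- sdf_rad + rng$noise[, 1]
    sdf_ulna <- sdf_ulna + rng$noise[, 2]
    sdf_tfcc <- sdf_tfcc + rng$noise[, 3]
  }

  vox <- integer(n)
  vox[sdf_rad <= 0] <- 1L
  vox[sdf_ulna <= 0] <- 2L
  vox[sdf_tfcc <= 0 & vox == 0L] <- 3L
  dim(vox) <- d

  volume <- label_volume(vox, spacing = s)
  truth <- structure(list(
    deep_area = ly$template$area,
    superficial_area = spec$superficial_patch_area,
    dv_length = ly$template$dv,
    ru_length = ly$template$ru,
    shape = spec$footprint_shape,
    tfc_center_thickness = ly$t,
    footprint_plane = list(point = c(Fx, Fy, Fz), normal = c(0, 0, 1)),
    landmarks = list(fovea = c(Fx, Fy, Fz),
                     styloid_apex = c(Fx, y_st, apex_z))),
    class = "phantom_truth")
  list(volume = volume, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth:", x$shape, "\n")
  cat(sprintf("  deep area %.2f mm^2, superficial %.2f mm^2\n",
              x$deep_area, x$superficial_area))
  cat(sprintf("  DV %.2f mm, RU %.2f mm, TFC thickness %.2f mm\n",
              x$dv_length, x$ru_length, x$tfc_center_thickness))
  invisible(x)
}

#' Write a phantom's truth record as JSON
#'
#' @param truth A `phantom_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate paired measurements with a known intraclass correlation
#'
#' Per specimen a shared latent level is drawn with variance
#' `true_between_variance`; each method observes it with independent
#' Gaussian error. The theoretical single-measure ICC,
#' `sigma2_between / (sigma2_between + sigma2_error)` with
#' `sigma2_error` the mean of the two error variances, is attached as an
#' attribute.
#'
#' @param n_specimens Number of specimens (>= 2).
#' @param true_between_variance,true_error_variance_a,true_error_variance_b
#'   Variance components (>= 0).
#' @param mean_level Grand mean of the measurements.
#' @param seed Integer RNG seed.
#' @return `data.frame` with columns `specimen`, `method_a`, `method_b`;
#'   attributes `theoretical_icc` and `seed`.
#' @export
#' @examples
#' tab <- simulate_paired_measurements(10, 9, 1, 1, seed = 1)
#' attr(tab, "theoretical_icc")  # 0.9
simulate_paired_measurements <- function(n_specimens, true_between_variance,
                                         true_error_variance_a,
                                         true_error_variance_b,
                                         mean_level = 40, seed = 1L) {
  if (n_specimens < 2)
    stop_fp("need at least 2 specimens", "fp_error_usage",
            field = "n_specimens")
  if (any(c(true_between_variance, true_error_variance_a,
            true_error_variance_b) < 0))
    stop_fp("variances must be >= 0", "fp_error_usage")
  tab <- with_private_seed(seed, {
    latent <- mean_level + rnorm(n_specimens, 0,
                                 sqrt(true_between_variance))
    data.frame(specimen = seq_len(n_specimens),
               method_a = latent + rnorm(n_specimens, 0,
                                         sqrt(true_error_variance_a)),
               method_b = latent + rnorm(n_specimens, 0,
                                         sqrt(true_error_variance_b)))
  })
  sig_e <- (true_error_variance_a + true_error_variance_b) / 2
  attr(tab, "theoretical_icc") <-
    if (true_between_variance + sig_e == 0) NA_real_
    else true_between_variance / (true_between_variance + sig_e)
  attr(tab, "seed") <- as.integer(seed)
  tab
}
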