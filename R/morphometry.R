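#' Planar area of a footprint patch
#'
#' Projects the patch's inlier points onto its fitted plane, rasterizes the
#' projection at `raster_resolution_mm`, applies a one-pixel morphological
#' closing to seal sampling gaps, and returns occupied pixels times pixel
#' area. Translation- and rotation-invariant up to raster discretisation.
#'
#' @param patch A `footprint_patch` (see [extract_footprint()]).
#' @param raster_resolution_mm Pixel size of the occupancy raster; default
#'   the smallest voxel spacing of the source volume.
#' @return Area in mm^2.
#' @export
patch_area <- function(patch, raster_resolution_mm = NULL) {
  uv <- project_to_plane(patch)
  res <- raster_resolution_mm
  if (is.null(res)) res <- min(patch$spacing)
  if (res <= 0)
    stop_fp("raster resolution must be > 0", "fp_error_value")
  raster_area(uv, res)
}

project_to_plane <- function(patch) {
  stopifnot(inherits(patch, "footprint_patch"))
  pts <- patch$world_points[patch$inlier_flags, , drop = FALSE]
  if (nrow(pts) < 3)
    stop_fp("patch has fewer than 3 inlier points", "fp_error_degenerate")
  nrm <- patch$plane$normal
  basis <- plane_basis(nrm)
  rel <- sweep(pts, 2, patch$plane$point)
  cbind(rel %*% basis$u, rel %*% basis$v)
}

plane_basis <- function(nrm) {
  e <- diag(3)[, which.min(abs(nrm))]
  u <- pracma_cross(nrm, e)
  u <- u / sqrt(sum(u^2))
  v <- pracma_cross(nrm, u)
  list(u = u, v = v)
}

raster_area <- function(uv, res) {
  iu <- floor(uv[, 1] / res)
  iv <- floor(uv[, 2] / res)
  iu <- iu - min(iu) + 3L   # 2-pixel pad for the closing
  iv <- iv - min(iv) + 3L
  nu <- max(iu) + 3L
  nv <- max(iv) + 3L
  occ <- matrix(FALSE, nu, nv)
  occ[cbind(iu, iv)] <- TRUE
  occ <- shift2d_reduce(occ, `|`)   # 3x3 dilation
  occ <- shift2d_reduce(occ, `&`)   # 3x3 erosion
  sum(occ) * res^2
}

# Apply op over the 3x3 neighbourhood via shifted copies (padded edges are
# FALSE, which is correct for both dilation and erosion after padding).
shift2d_reduce <- function(m, op) {
  n <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sh <- matrix(FALSE, n[1], n[2])
    xs <- max(1, 1 + dx):min(n[1], n[1] + dx)
    ys <- max(1, 1 + dy):min(n[2], n[2] + dy)
    sh[xs, ys] <- m[xs - dx, ys - dy]
    out <- op(out, sh)
  }
  out
}

#' Maximal extent of a patch along a direction
#'
#' Range (max minus min) of the inlier points' projections onto a unit
#' axis; this is how dorsal-volar and radial-ulnar maximal lengths are
#' measured.
#'
#' @param patch A `footprint_patch`.
#' @param axis Unit 3-vector in world coordinates.
#' @return Extent in mm.
#' @export
max_extent <- function(patch, axis) {
  stopifnot(inherits(patch, "footprint_patch"))
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9)
    stop_fp("axis must be a unit vector", "fp_error_value")
  pts <- patch$world_points[patch$inlier_flags, , drop = FALSE]
  if (nrow(pts) < 1)
    stop_fp("patch has no inlier points", "fp_error_degenerate")
  proj <- pts %*% axis
  max(proj) - min(proj)
}

#' Centre thickness of a sheet structure
#'
#' Extent of the sheet mask along the plane normal in the voxel column at
#' the sheet's in-plane centroid (the ray through voxel centres), plus one
#' voxel thickness along the normal. If the exact centroid column is empty
#' the nearest non-empty column within one voxel is used.
#'
#' @param sheet_mask Logical 3D array (e.g. the TFCC label mask).
#' @param spacing mm triple.
#' @param plane List with unit `normal` and `point` (e.g. a patch plane).
#' @return Thickness in mm.
#' @export
center_thickness <- function(sheet_mask, spacing, plane) {
  w <- which(sheet_mask)
  if (!length(w)) stop_fp("sheet mask is empty", "fp_error_value")
  d <- dim(sheet_mask)
  pts <- sweep(sweep(linear_to_ijk(w, d), 2, as.numeric(spacing), `*`),
               2, rep(0, 3), `+`)
  nrm <- plane$normal / sqrt(sum(plane$normal^2))
  basis <- plane_basis(nrm)
  uv <- cbind(pts %*% basis$u, pts %*% basis$v)
  ctr <- colMeans(uv)
  dist2 <- (uv[, 1] - ctr[1])^2 + (uv[, 2] - ctr[2])^2
  tol1 <- (0.51 * max(spacing))^2
  tol2 <- (1.1 * max(spacing))^2
  sel <- dist2 <= tol1
  if (!any(sel)) sel <- dist2 <= tol2
  if (!any(sel))
    stop_fp("no sheet voxels within one voxel of the in-plane centroid",
            "fp_error_degenerate")
  proj <- pts[sel, , drop = FALSE] %*% nrm
  vox_thick <- sum(abs(nrm) * spacing)
  (max(proj) - min(proj)) + vox_thick
}

#' Shape descriptors of a footprint patch
#'
#' In-plane elongation (maximal extent over the orthogonal extent, from
#' the convex-hull diameter) and solidity (raster area over convex-hull
#' area) of the projected patch, together with its area and DV/RU lengths.
#'
#' @param patch A `footprint_patch`.
#' @param frame An [anatomical_frame()] supplying the DV/RU axes.
#' @param raster_resolution_mm Passed to [patch_area()].
#' @return Object of class `shape_descriptors` with fields `elongation`,
#'   `solidity`, `area`, `dv_length`, `ru_length`.
#' @export
shape_descriptors <- function(patch, frame = anatomical_frame(),
                              raster_resolution_mm = NULL) {
  uv <- project_to_plane(patch)
  hull <- chull(uv)
  hp <- uv[hull, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3)
    stop_fp("projected patch is degenerate", "fp_error_degenerate")
  # diameter over hull vertices = maximal extent over all directions
  dmat <- as.matrix(dist(hp))
  idx <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  dir <- hp[idx[2], ] - hp[idx[1], ]
  diam <- sqrt(sum(dir^2))
  dir <- dir / diam
  perp <- c(-dir[2], dir[1])
  orth <- diff(range(uv %*% perp))
  area <- patch_area(patch, raster_resolution_mm)
  hull_area <- polygon_area(hp)
  structure(list(
    elongation = if (orth > 0) max(1, diam / orth) else Inf,
    solidity = min(1, area / hull_area),
    area = area,
    dv_length = max_extent(patch, frame$dv_axis),
    ru_length = max_extent(patch, frame$ru_axis)),
    class = "shape_descriptors")
}

polygon_area <- function(p) {
  i2 <- c(2:nrow(p), 1)
  0.5 * abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]))
}

#' @export
print.shape_descriptors <- function(x, ...) {
  cat(sprintf(paste0("shape_descriptors: area %.2f mm^2, DV %.2f mm, ",
                     "RU %.2f mm,\n  elongation %.2f, solidity %.3f\n"),
              x$area, x$dv_length, x$ru_length, x$elongation, x$solidity))
  invisible(x)
}

#' Three-way footprint shape classification
#'
#' Operationalizes the visual taxonomy (irregular quadrilateral / ribbon /
#' semilunar) with quantitative rules: crescent-like low-solidity patches
#' are semilunar; elongated high-solidity bands are ribbons; compact convex
#' patches are irregular quadrilaterals.
#'
#' @param descriptors A [shape_descriptors()] object.
#' @param elongation_threshold Ribbon cut-off on elongation (default 2.5).
#' @param solidity_threshold Semilunar cut-off on solidity (default 0.80).
#' @return Character scalar: `"semilunar"`, `"ribbon"` or
#'   `"irregular_quadrilateral"`, with the thresholds attached as
#'   attributes.
#' @export
classify_shape <- function(descriptors, elongation_threshold = 2.5,
                           solidity_threshold = 0.80) {
  stopifnot(inherits(descriptors, "shape_descriptors"))
  cls <- if (descriptors$solidity < solidity_threshold) "semilunar"
  else if (descriptors$elongation >= elongation_threshold) "ribbon"
  else "irregular_quadrilateral"
  structure(cls, elongation_threshold = elongation_threshold,
            solidity_threshold = solidity_threshold)
}

#' Full morphometry record of a footprint patch
#'
#' Bundles [patch_area()], DV/RU [max_extent()], [shape_descriptors()] and
#' [classify_shape()] into one record with provenance (configuration hash
#' and RANSAC seed).
#'
#' @param patch A `footprint_patch`.
#' @param frame An [anatomical_frame()].
#' @param cfg Optional [pipeline_config()] recorded for provenance.
#' @param raster_resolution_mm Passed to [patch_area()].
#' @param elongation_threshold,solidity_threshold Passed to
#'   [classify_shape()].
#' @return Object of class `footprint_morphometry`.
#' @export
measure_patch <- function(patch, frame = anatomical_frame(), cfg = NULL,
                          raster_resolution_mm = NULL,
                          elongation_threshold = 2.5,
                          solidity_threshold = 0.80) {
  desc <- shape_descriptors(patch, frame, raster_resolution_mm)
  shape <- classify_shape(desc, elongation_threshold, solidity_threshold)
  structure(list(
    region_tag = patch$region_tag,
    area = desc$area,
    dv_length = desc$dv_length,
    ru_length = desc$ru_length,
    elongation = desc$elongation,
    solidity = desc$solidity,
    shape = as.character(shape),
    n_inliers = sum(patch$inlier_flags),
    elongation_threshold = elongation_threshold,
    solidity_threshold = solidity_threshold,
    seed = patch$seed,
    config_hash = fnv1a_hash(if (is.null(cfg)) patch[c("source_labels",
                                                       "spacing")]
                             else unclass(cfg))),
    class = "footprint_morphometry")
}

#' @export
print.footprint_morphometry <- function(x, ...) {
  cat("footprint_morphometry (", x$region_tag, ")\n", sep = "")
  cat(sprintf("  area        %8.2f mm^2\n", x$area))
  cat(sprintf("  DV length   %8.2f mm\n", x$dv_length))
  cat(sprintf("  RU length   %8.2f mm\n", x$ru_length))
  cat(sprintf("  shape       %s (elongation %.2f, solidity %.3f)\n",
              x$shape, x$elongation, x$solidity))
  cat(sprintf("  provenance  seed %d, config %s\n", x$seed, x$config_hash))
  invisible(x)
}

#' @export
as.data.frame.footprint_morphometry <- function(x, ...) {
  data.frame(region = x$region_tag, area_mm2 = x$area,
             dv_length_mm = x$dv_length, ru_length_mm = x$ru_length,
             elongation = x$elongation, solidity = x$solidity,
             shape = x$shape, n_inliers = x$n_inliers,
             seed = x$seed, config_hash = x$config_hash,
             stringsAsFactors = FALSE)
}
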