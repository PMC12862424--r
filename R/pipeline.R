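#' Configuration of the footprint extraction pipeline
#'
#' @param smoothing_sigma Gaussian width for label smoothing, voxels
#'   (default 1; 0 disables smoothing).
#' @param sobel_threshold Boundary threshold as a fraction of the maximum
#'   Sobel gradient magnitude, in (0, 1\] (default 0.1).
#' @param dilation_radius_mm Physical radius of the overlap-detection
#'   dilation (default 0.3 mm).
#' @param component_connectivity 6, 18 or 26 (default 26).
#' @param ransac_iterations Number of RANSAC minimal samples (default 1000).
#' @param ransac_inlier_threshold_mm Plane inlier distance (default 0.15 mm).
#' @param min_component_voxels Components smaller than this are discarded
#'   (default 30).
#' @param seed Integer seed for the RANSAC sampler (default 1).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(smoothing_sigma = 1, sobel_threshold = 0.1,
                            dilation_radius_mm = 0.3,
                            component_connectivity = 26,
                            ransac_iterations = 1000,
                            ransac_inlier_threshold_mm = 0.15,
                            min_component_voxels = 30, seed = 1L) {
  if (smoothing_sigma < 0)
    stop_fp("smoothing_sigma must be >= 0", "fp_error_usage",
            field = "smoothing_sigma")
  if (sobel_threshold <= 0 || sobel_threshold > 1)
    stop_fp("sobel_threshold must lie in (0, 1]", "fp_error_usage",
            field = "sobel_threshold")
  if (dilation_radius_mm <= 0)
    stop_fp("dilation_radius_mm must be > 0", "fp_error_usage",
            field = "dilation_radius_mm")
  if (!component_connectivity %in% c(6L, 18L, 26L))
    stop_fp("component_connectivity must be 6, 18 or 26", "fp_error_usage",
            field = "component_connectivity")
  if (ransac_iterations < 1)
    stop_fp("ransac_iterations must be >= 1", "fp_error_usage",
            field = "ransac_iterations")
  if (ransac_inlier_threshold_mm <= 0)
    stop_fp("ransac_inlier_threshold_mm must be > 0", "fp_error_usage",
            field = "ransac_inlier_threshold_mm")
  structure(list(smoothing_sigma = smoothing_sigma,
                 sobel_threshold = sobel_threshold,
                 dilation_radius_mm = dilation_radius_mm,
                 component_connectivity = as.integer(component_connectivity),
                 ransac_iterations = as.integer(ransac_iterations),
                 ransac_inlier_threshold_mm = ransac_inlier_threshold_mm,
                 min_component_voxels = as.integer(min_component_voxels),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Gaussian one-hot label smoothing
#'
#' Smooths each label's indicator with a Gaussian of width `sigma` voxels
#' and reassigns every voxel to the label of largest smoothed indicator
#' (ties broken toward the lower label code). Never introduces labels
#' absent from the input; `sigma = 0` is the identity.
#'
#' @param volume A [label_volume()].
#' @param sigma Gaussian width in voxels, >= 0.
#' @return Smoothed [label_volume()].
#' @export
smooth_labels <- function(volume, sigma) {
  stopifnot(inherits(volume, "label_volume"))
  if (sigma < 0) stop_fp("sigma must be >= 0", "fp_error_value")
  if (sigma == 0) return(volume)
  labels <- sort(unique(as.vector(volume$voxels)))
  if (length(labels) == 1L) return(volume)
  d <- dim(volume$voxels)
  best_val <- rep(-Inf, prod(d))
  best_lab <- integer(prod(d))
  for (lab in labels) {
    onehot <- as.numeric(volume$voxels == lab)
    smoothed <- .cpp_gaussian_smooth3d(onehot, d, rep(sigma, 3))
    take <- smoothed > best_val   # strict: earlier (lower) label keeps ties
    best_val[take] <- smoothed[take]
    best_lab[take] <- lab
  }
  out <- volume
  out$voxels <- array(best_lab, d)
  out
}

#' Sobel boundary delineation of a binary mask
#'
#' Computes the 3D Sobel gradient magnitude of the mask indicator (scaled
#' per axis by 1/spacing), normalizes it to \[0, 1\] and keeps mask voxels
#' whose normalized magnitude reaches `threshold`. The result is the
#' surface shell of the mask; an empty mask yields an empty boundary.
#'
#' @param mask Logical 3D array.
#' @param spacing mm triple.
#' @param threshold Fraction of the maximum gradient magnitude (default 0.1).
#' @return Logical 3D array.
#' @export
boundary_voxels <- function(mask, spacing, threshold = 0.1) {
  d <- dim(mask)
  if (length(d) != 3L) stop_fp("mask must be 3D", "fp_error_value")
  if (!any(mask)) return(array(FALSE, d))
  g <- .cpp_sobel_magnitude3d(as.numeric(mask), d, as.numeric(spacing))
  m <- max(g)
  if (m == 0) return(array(FALSE, d))
  out <- (g / m >= threshold) & as.vector(mask)
  # isolated voxels have zero central gradient by symmetry but are pure
  # surface; flag them explicitly
  isolated <- as.vector(mask) &
    .cpp_count_neighbors6(as.vector(mask), d) == 0L
  array(out | isolated, d)
}

ellipsoid_offsets <- function(radius_mm, spacing) {
  r <- radius_mm / spacing
  rng <- lapply(r, function(ri) seq(-floor(ri), floor(ri)))
  g <- expand.grid(dx = rng[[1]], dy = rng[[2]], dz = rng[[3]])
  keep <- (g$dx / r[1])^2 + (g$dy / r[2])^2 + (g$dz / r[3])^2 <= 1 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' Morphological overlap between two structure boundaries
#'
#' Dilates both boundary masks by an ellipsoidal ball of the given physical
#' radius (converted to per-axis voxel radii, so anisotropic grids use
#' anisotropic structuring elements) and intersects them. Weakly attached
#' voxels (fewer than two face-connected neighbours) are then suppressed to
#' remove single-voxel bridges and speckle, and the result is restricted to
#' the union of the two boundary supports plus a one-voxel guard band. The
#' operation is symmetric in its two arguments.
#'
#' @param soft_boundary,bone_boundary Logical 3D arrays on the same grid.
#' @param dilation_radius_mm Physical dilation radius; must be at least the
#'   smallest voxel spacing (otherwise the dilation would be a no-op).
#' @param spacing mm triple.
#' @return Logical 3D array of candidate contact voxels.
#' @export
candidate_overlap <- function(soft_boundary, bone_boundary,
                              dilation_radius_mm, spacing) {
  d <- dim(soft_boundary)
  if (!identical(d, dim(bone_boundary)))
    stop_fp("boundary masks must share a grid", "fp_error_value")
  spacing <- as.numeric(spacing)
  if (dilation_radius_mm < min(spacing))
    stop_fp("dilation radius below the smallest voxel spacing is a no-op",
            "fp_error_value")
  offs <- ellipsoid_offsets(dilation_radius_mm, spacing)
  a <- .cpp_dilate_offsets(as.vector(soft_boundary), d, offs)
  b <- .cpp_dilate_offsets(as.vector(bone_boundary), d, offs)
  inter <- a & b
  if (!any(inter)) return(array(FALSE, d))
  counts <- .cpp_count_neighbors6(inter, d)
  inter <- inter & counts >= 2L
  one_ball <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  guard <- .cpp_dilate_offsets(as.vector(soft_boundary) |
                                 as.vector(bone_boundary), d, one_ball)
  array(inter & guard, d)
}

#' Largest connected component of a mask
#'
#' Components smaller than `min_size` are discarded first; among the rest
#' the one with the most voxels is returned (ties broken toward the
#' component containing the smallest linear voxel index). If no component
#' survives, an all-`FALSE` mask with attribute `empty = TRUE` is returned
#' rather than an error.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_size Minimum component voxel count (default 1).
#' @return Logical 3D array with attributes `size` and `n_components`.
#' @export
largest_component <- function(mask, connectivity = 26, min_size = 1) {
  d <- dim(mask)
  labs <- .cpp_label_components(as.vector(mask), d, as.integer(connectivity))
  sizes <- tabulate(labs)
  eligible <- which(sizes >= min_size)
  if (!length(eligible)) {
    out <- array(FALSE, d)
    attr(out, "empty") <- TRUE
    attr(out, "n_components") <- 0L
    return(out)
  }
  # components are numbered in raster-scan order of their seed voxel, so
  # which.max on sizes[eligible] already ties toward the smallest seed
  best <- eligible[which.max(sizes[eligible])]
  out <- array(labs == best, d)
  attr(out, "size") <- sizes[best]
  attr(out, "n_components") <- length(eligible)
  out
}

#' RANSAC plane fit
#'
#' Classical three-point RANSAC: `iterations` random minimal samples, each
#' defining a candidate plane; the candidate with the most points within
#' `threshold_mm` wins (ties broken by smaller mean absolute inlier
#' residual). The final plane is re-estimated from the inliers by total
#' least squares (centroid plus smallest-variance direction), with inlier
#' flags and the fit refreshed once more against the refined plane.
#' Deterministic for a fixed seed.
#'
#' @param points Numeric n x 3 matrix of world coordinates (n >= 3, not all
#'   collinear).
#' @param threshold_mm Inlier distance threshold.
#' @param iterations Number of random samples (default 1000).
#' @param seed Integer RNG seed.
#' @return List with `plane` (list of `point`, unit `normal`), logical
#'   `inliers`, and `threshold_mm`.
#' @export
ransac_plane <- function(points, threshold_mm, iterations = 1000,
                         seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3)
    stop_fp("plane fitting needs at least 3 points", "fp_error_degenerate")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr), nu = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12))
    stop_fp("points are collinear; no unique plane", "fp_error_degenerate")

  fit_ls <- function(pts) {
    c0 <- colMeans(pts)
    v <- svd(sweep(pts, 2, c0), nu = 0)$v[, 3]
    if (v[which.max(abs(v))] < 0) v <- -v
    list(point = c0, normal = v)
  }

  if (n == 3) {
    pl <- fit_ls(points)
    return(list(plane = pl, inliers = rep(TRUE, 3),
                threshold_mm = threshold_mm))
  }

  cand <- with_private_seed(seed, {
    normals <- matrix(0, iterations, 3)
    offs <- numeric(iterations)
    for (it in seq_len(iterations)) {
      idx <- sample.int(n, 3)
      p1 <- points[idx[1], ]
      nv <- pracma_cross(points[idx[2], ] - p1, points[idx[3], ] - p1)
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-12) next   # degenerate sample; leaves a zero normal
      nv <- nv / nn
      normals[it, ] <- nv
      offs[it] <- sum(nv * p1)
    }
    list(normals = normals, offs = offs)
  })
  valid <- rowSums(cand$normals^2) > 0.5
  counts <- integer(iterations)
  resid_sum <- numeric(iterations)
  chunk <- 250
  for (st in seq(1, iterations, by = chunk)) {
    en <- min(st + chunk - 1, iterations)
    sel <- st:en
    D <- abs(sweep(points %*% t(cand$normals[sel, , drop = FALSE]), 2,
                   cand$offs[sel], `-`))
    inl <- D <= threshold_mm
    counts[sel] <- colSums(inl)
    resid_sum[sel] <- colSums(D * inl)
  }
  counts[!valid] <- 0L
  if (max(counts) < 3)
    stop_fp("RANSAC found no plane with 3 inliers", "fp_error_degenerate")
  top <- which(counts == max(counts))
  if (length(top) > 1) top <- top[order(resid_sum[top] / counts[top])]
  best <- top[1]
  d0 <- abs(points %*% cand$normals[best, ] - cand$offs[best])
  flags <- as.vector(d0 <= threshold_mm)
  for (pass in 1:2) {
    pl <- fit_ls(points[flags, , drop = FALSE])
    d1 <- abs(sweep(points, 2, pl$point) %*% pl$normal)
    flags <- as.vector(d1 <= threshold_mm)
    if (sum(flags) < 3) {   # refinement degenerated; keep the raw sample
      flags <- as.vector(d0 <= threshold_mm)
      pl <- fit_ls(points[flags, , drop = FALSE])
      break
    }
  }
  list(plane = pl, inliers = flags, threshold_mm = threshold_mm)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Extract an insertion footprint patch from a label volume
#'
#' Runs the full extraction chain: Gaussian label smoothing, Sobel boundary
#' delineation of the soft-tissue and bone structures, dilation-based
#' overlap detection, selection of the connected candidate component
#' nearest the region seed, refinement to the true contact interface
#' (voxels face-adjacent to both structures), RANSAC plane fitting, and
#' retention of the largest connected inlier subset.
#'
#' @param volume A [label_volume()] containing both labels.
#' @param soft_label Soft-tissue label (default `"tfcc"`).
#' @param bone_label Bone label (default `"ulna"`).
#' @param cfg A [pipeline_config()].
#' @param region_seed Either a world point (numeric length 3), a landmark
#'   label present in the volume, or `NULL` to take the largest candidate
#'   component. Deep insertions are seeded at the fovea centre, superficial
#'   ones at the styloid apex.
#' @param region_tag `"deep"` or `"superficial"`; recorded on the patch.
#' @return Object of class `footprint_patch` with fields `voxel_indices`
#'   (0-based n x 3), `world_points`, `plane`, `inlier_flags`,
#'   `source_labels`, `region_tag`, `spacing`; per-stage voxel counts in
#'   attribute `stage_counts`.
#' @export
extract_footprint <- function(volume, soft_label = "tfcc",
                              bone_label = "ulna",
                              cfg = pipeline_config(), region_seed = NULL,
                              region_tag = c("deep", "superficial")) {
  stopifnot(inherits(volume, "label_volume"),
            inherits(cfg, "pipeline_config"))
  region_tag <- match.arg(region_tag)
  soft_code <- resolve_label(volume, soft_label)
  bone_code <- resolve_label(volume, bone_label)
  for (code in c(soft_code, bone_code))
    if (!any(volume$voxels == code))
      stop_fp(paste0("label ", code, " absent from volume"),
              "fp_error_precondition")
  d <- dim(volume$voxels)
  stages <- integer(0)

  sm <- smooth_labels(volume, cfg$smoothing_sigma)
  soft_mask <- sm$voxels == soft_code
  bone_mask <- sm$voxels == bone_code
  stages["smoothed_soft"] <- sum(soft_mask)
  stages["smoothed_bone"] <- sum(bone_mask)

  soft_b <- boundary_voxels(soft_mask, volume$spacing, cfg$sobel_threshold)
  bone_b <- boundary_voxels(bone_mask, volume$spacing, cfg$sobel_threshold)
  stages["soft_boundary"] <- sum(soft_b)
  stages["bone_boundary"] <- sum(bone_b)
  if (!any(soft_b) || !any(bone_b))
    stop_fp("boundary delineation produced an empty mask",
            "fp_error_extraction", stage = "boundary")

  overlap <- candidate_overlap(soft_b, bone_b, cfg$dilation_radius_mm,
                               volume$spacing)
  stages["overlap"] <- sum(overlap)
  if (!any(overlap))
    stop_fp("no soft-tissue/bone overlap detected", "fp_error_extraction",
            stage = "overlap")

  labs <- .cpp_label_components(as.vector(overlap), d,
                                cfg$component_connectivity)
  sizes <- tabulate(labs)
  eligible <- which(sizes >= cfg$min_component_voxels)
  if (!length(eligible))
    stop_fp("no overlap component reaches min_component_voxels",
            "fp_error_extraction", stage = "component")
  pick <- if (is.null(region_seed)) {
    eligible[which.max(sizes[eligible])]
  } else {
    seed_pt <- if (is.numeric(region_seed) && length(region_seed) == 3L) {
      as.numeric(region_seed)
    } else {
      code <- resolve_label(volume, region_seed)
      w <- which(volume$voxels == code)
      if (!length(w))
        stop_fp("landmark label absent from volume", "fp_error_precondition")
      colMeans(voxel_to_world(volume, linear_to_ijk(w, d)))
    }
    cent <- vapply(eligible, function(id) {
      colMeans(voxel_to_world(volume, linear_to_ijk(which(labs == id), d)))
    }, numeric(3))
    eligible[which.min(colSums((cent - seed_pt)^2))]
  }
  comp <- labs == pick
  stages["selected_component"] <- sum(comp)

  # The interface is defined on the input labels, not the smoothed ones:
  # one-hot smoothing can crawl one voxel around the triple junction at the
  # patch rim, which would add a one-voxel halo to the measured footprint.
  face <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
                 ncol = 3, byrow = TRUE)
  soft_orig <- as.vector(volume$voxels == soft_code)
  bone_orig <- as.vector(volume$voxels == bone_code)
  near_soft <- .cpp_dilate_offsets(soft_orig, d, face)
  near_bone <- .cpp_dilate_offsets(bone_orig, d, face)
  # a contact voxel belongs to one structure and touches the other; bare
  # background voxels wedged between the two would add a perimeter ring
  contact <- comp & ((soft_orig & near_bone) | (bone_orig & near_soft))
  stages["contact_interface"] <- sum(contact)
  if (sum(contact) < 3)
    stop_fp("contact-interface refinement left fewer than 3 voxels",
            "fp_error_extraction", stage = "contact_refinement")
  contact <- largest_component(array(contact, d),
                               cfg$component_connectivity)

  ijk <- linear_to_ijk(which(contact), d)
  pts <- voxel_to_world(volume, ijk)
  rp <- ransac_plane(pts, cfg$ransac_inlier_threshold_mm,
                     cfg$ransac_iterations, cfg$seed)
  stages["plane_inliers"] <- sum(rp$inliers)

  inl_mask <- array(FALSE, d)
  inl_mask[which(contact)[rp$inliers]] <- TRUE
  final <- largest_component(inl_mask, cfg$component_connectivity)
  flags <- as.vector(final)[which(contact)]
  stages["final_patch"] <- sum(flags)
  if (sum(flags) < 3)
    stop_fp("plane refinement left fewer than 3 connected inliers",
            "fp_error_extraction", stage = "plane")

  structure(list(voxel_indices = ijk, world_points = pts, plane = rp$plane,
                 inlier_flags = flags,
                 source_labels = c(soft = soft_code, bone = bone_code),
                 region_tag = region_tag, spacing = volume$spacing,
                 connectivity = cfg$component_connectivity,
                 inlier_threshold_mm = cfg$ransac_inlier_threshold_mm,
                 seed = cfg$seed),
            class = "footprint_patch", stage_counts = stages)
}

linear_to_ijk <- function(lin, d) {
  lin0 <- lin - 1
  cbind(lin0 %% d[1],
        (lin0 %/% d[1]) %% d[2],
        lin0 %/% (d[1] * d[2]))
}

#' @export
print.footprint_patch <- function(x, ...) {
  cat("footprint_patch (", x$region_tag, "): ", sum(x$inlier_flags),
      " inliers of ", nrow(x$world_points), " contact voxels\n", sep = "")
  cat(sprintf("  plane point (%s), normal (%s)\n",
              paste(format(x$plane$point, digits = 4), collapse = ", "),
              paste(format(x$plane$normal, digits = 4), collapse = ", ")))
  invisible(x)
}

#' @export
summary.footprint_patch <- function(object, ...) {
  res <- abs(sweep(object$world_points, 2, object$plane$point) %*%
               object$plane$normal)
  cat("footprint_patch summary\n")
  print(object)
  cat(sprintf("  inlier residuals: mean %.4f mm, max %.4f mm\n",
              mean(res[object$inlier_flags]), max(res[object$inlier_flags])))
  sc <- attr(object, "stage_counts")
  if (!is.null(sc)) {
    cat("  stage voxel counts:\n")
    for (nm in names(sc)) cat(sprintf("    %-20s %d\n", nm, sc[[nm]]))
  }
  invisible(object)
}
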