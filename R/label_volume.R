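#' Default label schema for wrist segmentation volumes
#'
#' Fixed codes for the four core structures; additional named landmark
#' labels are allowed with codes >= 10.
#'
#' @param extra Optional named integer vector of extra labels (codes >= 10),
#'   e.g. `c(fovea_landmark = 10L, styloid_landmark = 11L)`.
#' @return Named integer vector mapping structure names to label codes.
#' @export
#' @examples
#' default_label_schema()
default_label_schema <- function(extra = NULL) {
  schema <- c(background = 0L, radius = 1L, ulna = 2L, tfcc = 3L)
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))))
      stop_fp("extra labels must be named", "fp_error_schema")
    extra <- stats::setNames(as.integer(extra), names(extra))
    if (any(extra < 10L))
      stop_fp("extra label codes must be >= 10", "fp_error_schema")
    schema <- c(schema, stats::setNames(extra, names(extra)))
  }
  schema
}

#' Construct a multi-label 3D segmentation volume
#'
#' A `label_volume` couples an integer voxel grid with its physical
#' geometry: voxel spacing in mm, world origin, an axis-orientation tag and
#' a label schema. Voxel indexing is 0-based in world-coordinate formulas;
#' the world coordinate of voxel `(i, j, k)` is
#' `origin + c(i, j, k) * spacing` (voxel centres).
#'
#' @param voxels 3D array of non-negative integer label codes.
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin Numeric length-3 world position (mm) of voxel (0,0,0).
#' @param orientation Orientation tag; the package convention is `"LPS"`.
#' @param schema Named integer vector mapping structure names to codes
#'   (see [default_label_schema()]). Every voxel value must appear in it.
#' @return Object of class `label_volume`.
#' @export
#' @examples
#' v <- label_volume(array(0L, c(4, 4, 4)), spacing = c(0.1, 0.1, 1.1))
#' v
label_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         orientation = "LPS",
                         schema = default_label_schema()) {
  if (length(dim(voxels)) != 3L)
    stop_fp("voxels must be a 3D array", "fp_error_value")
  if (any(dim(voxels) < 1L))
    stop_fp("grid must have at least one voxel per axis", "fp_error_value")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_fp("spacing must be three positive mm values", "fp_error_value")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_fp("origin must be three finite mm values", "fp_error_value")
  if (is.double(voxels)) {
    if (any(voxels != round(voxels)))
      stop_fp("voxel data must be integer label codes", "fp_error_format")
    storage.mode(voxels) <- "integer"
  }
  if (any(voxels < 0L))
    stop_fp("label codes must be non-negative", "fp_error_format")
  present <- sort(unique(as.vector(voxels)))
  unknown <- setdiff(present, schema)
  if (length(unknown))
    stop_fp(paste0("voxel values not in label schema: ",
                   paste(unknown, collapse = ", ")), "fp_error_schema")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 orientation = orientation, schema = schema),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("label_volume:", paste(d, collapse = " x "), "voxels,",
      paste(format(x$spacing, digits = 4), collapse = " x "), "mm spacing,",
      x$orientation, "\n")
  counts <- table(factor(as.vector(x$voxels), levels = x$schema))
  for (nm in names(x$schema)) {
    n <- counts[[as.character(x$schema[[nm]])]]
    if (n > 0) cat(sprintf("  %-12s (%d): %d voxels\n", nm, x$schema[[nm]], n))
  }
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$voxels)

#' Binary mask of one label
#'
#' @param volume A [label_volume()].
#' @param label Label code or schema name.
#' @return Logical 3D array, `TRUE` exactly where voxels carry that label.
#' @export
extract_label_mask <- function(volume, label) {
  stopifnot(inherits(volume, "label_volume"))
  code <- resolve_label(volume, label)
  volume$voxels == code
}

resolve_label <- function(volume, label) {
  if (is.character(label)) {
    if (!label %in% names(volume$schema))
      stop_fp(paste0("label '", label, "' not in schema"), "fp_error_schema")
    return(volume$schema[[label]])
  }
  label <- as.integer(label)
  if (!label %in% volume$schema)
    stop_fp(paste0("label code ", label, " not in schema"), "fp_error_schema")
  label
}

#' World coordinates of voxel indices
#'
#' @param volume A [label_volume()].
#' @param ijk Integer matrix (n x 3) of 0-based voxel indices.
#' @return Numeric n x 3 matrix of world positions in mm (voxel centres).
#' @export
voxel_to_world <- function(volume, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk, 2, volume$spacing, `*`), 2, volume$origin, `+`)
}

#' Anatomical measurement frame
#'
#' Unit direction vectors (world mm) for the dorsal-volar, radial-ulnar and
#' proximal-distal measurement axes. Axes must be unit length and mutually
#' orthogonal to within 1e-9.
#'
#' @param dv_axis,ru_axis,pd_axis Numeric length-3 unit vectors.
#' @return Object of class `anatomical_frame`.
#' @export
#' @examples
#' anatomical_frame()  # identity frame: x = DV, y = RU, z = PD
anatomical_frame <- function(dv_axis = c(1, 0, 0), ru_axis = c(0, 1, 0),
                             pd_axis = c(0, 0, 1)) {
  ax <- list(dv_axis = as.numeric(dv_axis), ru_axis = as.numeric(ru_axis),
             pd_axis = as.numeric(pd_axis))
  for (nm in names(ax)) {
    if (length(ax[[nm]]) != 3L || abs(sqrt(sum(ax[[nm]]^2)) - 1) > 1e-9)
      stop_fp(paste(nm, "must be a unit 3-vector"), "fp_error_value")
  }
  pairs <- combn(names(ax), 2)
  for (p in seq_len(ncol(pairs))) {
    d <- abs(sum(ax[[pairs[1, p]]] * ax[[pairs[2, p]]]))
    if (d >= 1e-9)
      stop_fp("frame axes must be mutually orthogonal", "fp_error_value")
  }
  structure(ax, class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("anatomical_frame\n")
  for (nm in names(x))
    cat(sprintf("  %s: (%s)\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}
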