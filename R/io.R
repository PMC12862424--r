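#' Read a multi-label segmentation volume
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) via the RNifti library or NRRD
#' (`.nrrd`, raw or gzip encoding) files containing integer label data.
#' Spacing is taken from the file header. If a JSON sidecar
#' (`<path>.json`, as written by [write_volume()]) is present it supplies
#' origin, orientation and the label schema; otherwise defaults are used.
#'
#' @param path File path.
#' @param schema Optional label schema overriding sidecar/default.
#' @return A [label_volume()].
#' @export
read_volume <- function(path, schema = NULL) {
  if (!file.exists(path))
    stop_fp(paste0("file not found: ", path), "fp_error_input")
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) {
    parsed <- read_nrrd(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    vox <- array(as.vector(img), dim(img))   # plain array, no image class
    if (any(vox != round(vox)))
      stop_fp("NIfTI file does not contain integer label data",
              "fp_error_format")
    storage.mode(vox) <- "integer"
    parsed <- list(voxels = vox,
                   spacing = as.numeric(RNifti::pixdim(img))[1:3],
                   origin = NULL, orientation = NULL)
  } else {
    stop_fp("unsupported volume format (expected .nii, .nii.gz or .nrrd)",
            "fp_error_input")
  }
  side <- read_sidecar(path)
  # the sidecar stores spacing at full precision; NIfTI headers are float32
  if (!is.null(side$spacing)) parsed$spacing <- side$spacing
  if (is.null(schema)) schema <- side$schema
  if (is.null(schema)) {
    present <- unique(as.vector(parsed$voxels))
    extra <- sort(present[present >= 10L])
    schema <- default_label_schema(
      if (length(extra)) stats::setNames(extra, paste0("label_", extra)))
  }
  label_volume(parsed$voxels, spacing = parsed$spacing,
               origin = if (!is.null(parsed$origin)) parsed$origin
                        else if (!is.null(side$origin)) side$origin
                        else c(0, 0, 0),
               orientation = if (!is.null(side$orientation)) side$orientation
                             else "LPS",
               schema = schema)
}

#' Write a label volume with a JSON sidecar
#'
#' Writes `.nii`/`.nii.gz` (via RNifti) or `.nrrd` (raw little-endian
#' int32) plus a `<path>.json` sidecar carrying origin, orientation and the
#' label schema, so that [read_volume()] round-trips all metadata.
#'
#' @param volume A [label_volume()].
#' @param path Output path; format chosen by extension.
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, sidecar = TRUE) {
  stopifnot(inherits(volume, "label_volume"))
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) {
    write_nrrd(volume, path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(volume$voxels)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path, datatype = "int32")
  } else {
    stop_fp("unsupported volume format (expected .nii, .nii.gz or .nrrd)",
            "fp_error_input")
  }
  if (sidecar) {
    meta <- list(spacing = volume$spacing, origin = volume$origin,
                 orientation = volume$orientation,
                 schema = as.list(volume$schema))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) return(list())
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  out <- list()
  if (!is.null(meta$spacing)) out$spacing <- as.numeric(meta$spacing)
  if (!is.null(meta$origin)) out$origin <- as.numeric(meta$origin)
  if (!is.null(meta$orientation)) out$orientation <- meta$orientation
  if (!is.null(meta$schema))
    out$schema <- stats::setNames(as.integer(unlist(meta$schema)),
                                  names(meta$schema))
  out
}

# --- minimal NRRD0004 support (raw / gzip encodings, integer types) -------

nrrd_types <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8"        = list(what = "integer", size = 1, signed = TRUE),
  "uchar"       = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uint8"       = list(what = "integer", size = 1, signed = FALSE),
  "short"       = list(what = "integer", size = 2, signed = TRUE),
  "int16"       = list(what = "integer", size = 2, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
  "uint16"      = list(what = "integer", size = 2, signed = FALSE),
  "int"         = list(what = "integer", size = 4, signed = TRUE),
  "int32"       = list(what = "integer", size = 4, signed = TRUE))

read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10))
  split_at <- NA
  for (i in seq_along(nl)) {
    pos <- nl[i]
    if (pos < length(bytes) && bytes[pos + 1] == as.raw(10)) {
      split_at <- pos + 1; break
    }
    # tolerate \r\n line endings
    if (pos + 2 <= length(bytes) && bytes[pos + 1] == as.raw(13) &&
        bytes[pos + 2] == as.raw(10)) {
      split_at <- pos + 2; break
    }
  }
  if (is.na(split_at))
    stop_fp("malformed NRRD: no end of header", "fp_error_format")
  header <- strsplit(rawToChar(bytes[1:(split_at - 1)]), "\r?\n")[[1]]
  if (!grepl("^NRRD000", header[1]))
    stop_fp("not an NRRD file", "fp_error_format")
  fields <- list()
  for (line in header[-1]) {
    if (grepl("^#", line) || !nzchar(line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(kv[2])]] <- kv[3]
  }
  type <- fields[["type"]]
  if (is.null(type) || is.null(nrrd_types[[type]]))
    stop_fp(paste0("NRRD type '", type,
                   "' is not an integer label type"), "fp_error_format")
  ti <- nrrd_types[[type]]
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), " +")[[1]])
  if (length(sizes) != 3L)
    stop_fp("only 3-dimensional NRRD volumes are supported",
            "fp_error_format")
  enc <- fields[["encoding"]]
  data <- bytes[(split_at + 1):length(bytes)]
  if (identical(enc, "gzip")) {
    data <- memDecompress(data, type = "gzip")
  } else if (!identical(enc, "raw")) {
    stop_fp(paste0("unsupported NRRD encoding: ", enc), "fp_error_format")
  }
  endian <- if (!is.null(fields[["endian"]])) fields[["endian"]] else "little"
  vox <- readBin(data, what = ti$what, n = prod(sizes), size = ti$size,
                 signed = ti$signed, endian = endian)
  spacing <- nrrd_spacing(fields)
  origin <- nrrd_vector(fields[["space origin"]])
  list(voxels = array(as.integer(vox), dim = sizes), spacing = spacing,
       origin = origin, orientation = NULL)
}

nrrd_vector <- function(txt) {
  if (is.null(txt)) return(NULL)
  as.numeric(strsplit(gsub("[()]", "", trimws(txt)), ",")[[1]])
}

nrrd_spacing <- function(fields) {
  sd <- fields[["space directions"]]
  if (!is.null(sd)) {
    vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1]]
    mat <- t(vapply(vecs, function(v) nrrd_vector(v), numeric(3)))
    return(sqrt(rowSums(mat^2)))
  }
  sp <- fields[["spacings"]]
  if (!is.null(sp)) return(as.numeric(strsplit(trimws(sp), " +")[[1]]))
  c(1, 1, 1)
}

write_nrrd <- function(volume, path) {
  d <- dim(volume$voxels)
  s <- volume$spacing
  o <- volume$origin
  header <- c(
    "NRRD0004",
    "type: int",
    "dimension: 3",
    paste("sizes:", paste(d, collapse = " ")),
    "encoding: raw",
    "endian: little",
    "space: left-posterior-superior",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            s[1], s[2], s[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)", o[1], o[2], o[3]),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con,
            eos = NULL, useBytes = TRUE)
  writeBin(as.vector(volume$voxels), con, size = 4, endian = "little")
  invisible(path)
}

#' Export a footprint patch as an ASCII PLY point cloud
#'
#' Writes the patch's contact points (with a per-vertex inlier flag) for
#' inspection in external mesh viewers.
#'
#' @param patch A `footprint_patch`.
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_patch_ply <- function(patch, path) {
  stopifnot(inherits(patch, "footprint_patch"))
  pts <- patch$world_points
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(pts)),
           "property float x", "property float y", "property float z",
           "property uchar inlier", "end_header")
  body <- paste(format(pts[, 1], trim = TRUE), format(pts[, 2], trim = TRUE),
                format(pts[, 3], trim = TRUE),
                as.integer(patch$inlier_flags))
  writeLines(c(hdr, body), path)
  invisible(path)
}
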