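#' Resolution factor between two voxel spacings
#'
#' The factor by which the coarsest axis is refined, i.e. the maximum over
#' axes of `source/target` spacing ratios. Going from the anisotropic
#' acquisition spacing 0.1 x 0.1 x 1.1 mm to isotropic 0.1 mm gives 11.
#'
#' @param source_spacing,target_spacing Positive mm triples.
#' @return Positive scalar.
#' @export
#' @examples
#' upsampling_factor(c(0.1, 0.1, 1.1), c(0.1, 0.1, 0.1))  # 11
upsampling_factor <- function(source_spacing, target_spacing) {
  source_spacing <- as.numeric(source_spacing)
  target_spacing <- as.numeric(target_spacing)
  if (length(source_spacing) != 3L || length(target_spacing) != 3L ||
      any(source_spacing <= 0) || any(target_spacing <= 0) ||
      any(!is.finite(c(source_spacing, target_spacing))))
    stop_fp("spacings must be positive mm triples", "fp_error_value")
  max(source_spacing / target_spacing)
}

#' Nearest-neighbour label resampling
#'
#' Resamples a label volume to a new spacing. Labels are categorical, so
#' each output voxel takes the label of the input voxel whose centre is
#' nearest in world coordinates; no label absent from the input can appear.
#' The output grid covers the same world extent (sizes rounded to the
#' nearest voxel, at least 1 per axis) and keeps the input origin.
#'
#' @param volume A [label_volume()].
#' @param target_spacing Positive mm triple.
#' @return A [label_volume()] at the target spacing.
#' @export
resample_labels <- function(volume, target_spacing) {
  stopifnot(inherits(volume, "label_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop_fp("target spacing must be a positive mm triple", "fp_error_value")
  din <- dim(volume$voxels)
  s_in <- volume$spacing
  if (isTRUE(all.equal(s_in, target_spacing))) return(volume)
  d_out <- pmax(1L, as.integer(round(din * s_in / target_spacing)))
  idx <- lapply(1:3, function(a) {
    src <- round((seq_len(d_out[a]) - 1) * target_spacing[a] / s_in[a])
    pmin(pmax(as.integer(src), 0L), din[a] - 1L) + 1L
  })
  out <- volume$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(out) <- d_out
  label_volume(out, spacing = target_spacing, origin = volume$origin,
               orientation = volume$orientation, schema = volume$schema)
}
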