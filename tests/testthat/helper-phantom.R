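# Shared phantom fixtures, built once per test run. The validation grids
# use 0.15 mm isotropic spacing, which keeps each phantom around one
# million voxels while staying well inside the morphometric tolerances.

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key = "default", ...) {
  if (is.null(.phantom_cache[[key]])) {
    args <- list(...)
    if (!length(args)) args <- list(spacing = rep(0.15, 3), seed = 1L)
    .phantom_cache[[key]] <- generate_phantom(do.call(phantom_spec, args))
  }
  .phantom_cache[[key]]
}

cached_deep_patch <- function() {
  if (is.null(.phantom_cache$deep_patch)) {
    ph <- cached_phantom()
    .phantom_cache$deep_patch <- extract_footprint(
      ph$volume, cfg = pipeline_config(),
      region_seed = ph$truth$landmarks$fovea)
  }
  .phantom_cache$deep_patch
}

# per-class template geometries used in the recovery studies; the ribbon
# and crescent take the cadaveric mean deep-footprint dimensions, the
# quadrilateral a compact 9 x 6 mm block as reported for quadrilateral
# footprints in the comparative literature
recovery_classes <- function() {
  list(ribbon = list(footprint_shape = "ribbon",
                     footprint_dv_length = 13.40,
                     footprint_ru_width = 3.98),
       irregular_quadrilateral = list(
         footprint_shape = "irregular_quadrilateral",
         footprint_dv_length = 9.0, footprint_ru_width = 6.0),
       semilunar = list(footprint_shape = "semilunar",
                        footprint_dv_length = 13.40,
                        footprint_ru_width = 3.98))
}

recover_one <- function(class_args, seed, spacing = rep(0.15, 3)) {
  spec <- do.call(phantom_spec,
                  c(class_args, list(spacing = spacing,
                                     superficial_patch_area = 0,
                                     seed = seed)))
  ph <- generate_phantom(spec)
  patch <- extract_footprint(ph$volume, cfg = pipeline_config(),
                             region_seed = ph$truth$landmarks$fovea)
  m <- measure_patch(patch)
  list(measured = m, truth = ph$truth)
}
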