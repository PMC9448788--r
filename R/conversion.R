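## Conversion-time mandates: every intensity scale factor is applied to the
## voxel data before storage (ASL-BIDS defines no scaling metadata), and
## volumes exported out of order are restored to acquisition order together
## with their context rows.

#' Intensity scale factors for one series
#'
#' DICOM-style linear scaling `value * slope + intercept`. ASL and M0 series
#' frequently carry different factors (background suppression makes their
#' signal levels differ by orders of magnitude), so factors are applied per
#' series by the caller. Vendor dialects that store an inverse slope are the
#' caller's responsibility when constructing the factors.
#'
#' @param slope Multiplicative factor; must be non-zero.
#' @param intercept Additive offset.
#' @return A `scale_factors` object.
#' @export
scale_factors <- function(slope, intercept = 0) {
  stopifnot(is.numeric(slope), length(slope) == 1L,
            is.numeric(intercept), length(intercept) == 1L)
  if (!is.finite(slope) || slope == 0)
    asl_abort("zero_slope", "scale slope must be finite and non-zero")
  structure(list(slope = slope, intercept = intercept),
            class = "asl_scale_factors")
}

#' Apply intensity scaling to a raw series
#'
#' Every voxel `v` becomes `v * slope + intercept` in floating point. The
#' returned series is marked scaled (attribute `scaled`); an ASL-BIDS tree
#' must only ever contain scaled data.
#'
#' @param raw_series An [image_series()] of raw (finite) values.
#' @param factors A [scale_factors()] object.
#' @return The scaled [image_series()].
#' @export
apply_scaling <- function(raw_series, factors) {
  stopifnot(inherits(raw_series, "asl_image_series"),
            inherits(factors, "asl_scale_factors"))
  out <- image_series(raw_series$voxels * factors$slope + factors$intercept,
                      voxel_size_mm = raw_series$voxel_size_mm)
  attr(out, "scaled") <- TRUE
  out
}

#' Restore acquisition order of an exported series
#'
#' Scanners may export DICOM volumes in a different order than they were
#' acquired; ASL-BIDS stores acquisition order. `order_map[i]` gives the
#' acquisition index of the volume at export index `i` (1-based); volumes and
#' their context rows move jointly, so the type of each physical volume is
#' preserved.
#'
#' @param series An [image_series()] in export order.
#' @param context_export_order The [asl_context()] in the same export order.
#' @param order_map Integer permutation of `1:n_volumes` mapping export index
#'   to acquisition index.
#' @return List with the reordered `series` and `context`, now in acquisition
#'   order.
#' @export
sort_to_acquisition_order <- function(series, context_export_order, order_map) {
  stopifnot(inherits(series, "asl_image_series"))
  n <- series$n_volumes
  if (length(order_map) != n || length(context_export_order) != n)
    asl_abort("length_mismatch", sprintf(
      "order_map (%d) and context (%d) must both have length n_volumes (%d)",
      length(order_map), length(context_export_order), n))
  order_map <- as.integer(order_map)
  if (!identical(sort(order_map), seq_len(n)))
    asl_abort("not_a_permutation", "order_map is not a permutation of 1..n")
  d <- dim(series$voxels)
  vox <- series$voxels
  if (length(d) == 4L) {
    out <- vox
    out[, , , order_map] <- vox[, , , seq_len(n)]
  } else out <- vox
  ctx <- character(n)
  ctx[order_map] <- unclass(context_export_order)
  list(series = image_series(out, voxel_size_mm = series$voxel_size_mm),
       context = asl_context(ctx))
}
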