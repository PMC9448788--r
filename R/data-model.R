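#' @keywords internal
VOLUME_TYPES <- c("control", "label", "m0scan", "deltam", "cbf")

#' @keywords internal
REQUIREMENT_LEVELS <- c(REQUIRED = 3L, RECOMMENDED = 2L, OPTIONAL = 1L)

#' Ordered per-volume type labels (the aslcontext contents)
#'
#' One label per volume of the ASL series, in acquisition order (not scanner
#' export order). Legal tokens are the lowercase literals `control`, `label`,
#' `m0scan`, `deltam`, `cbf`; comparison is case-sensitive.
#'
#' @param volume_types Character vector of volume-type tokens.
#' @return An `asl_context` (a character vector with a class attribute).
#' @export
asl_context <- function(volume_types) {
  if (length(volume_types) == 0L)
    asl_abort("malformed_tsv", "aslcontext must contain at least one volume")
  if (!is.character(volume_types) || !all(volume_types %in% VOLUME_TYPES))
    asl_abort("malformed_tsv", sprintf(
      "unknown volume_type token(s): %s",
      paste(setdiff(unique(volume_types), VOLUME_TYPES), collapse = ", ")))
  structure(as.character(volume_types), class = "asl_context")
}

#' JSON sidecar metadata for one file role
#'
#' Holds the parsed key/value entries of a sidecar. Values of fields known to
#' the registry must conform to their declared value kind (a violation raises
#' a `type_mismatch` error naming the field); unknown keys pass through
#' untouched.
#'
#' @param role `"asl"`, `"m0scan"` or `"fieldmap"`.
#' @param entries Named list of values.
#' @param registry Field registry used for type checking.
#' @return An `asl_sidecar` object.
#' @export
sidecar_metadata <- function(role, entries = list(),
                             registry = build_field_registry()) {
  stopifnot(role %in% c("asl", "m0scan", "fieldmap"), is.list(entries))
  if (length(entries) && (is.null(names(entries)) || any(!nzchar(names(entries)))))
    asl_abort("malformed_json", "sidecar entries must all be named")
  for (nm in names(entries)) {
    spec <- registry_lookup(registry, role, nm)
    if (!is.null(spec) && !value_conforms(entries[[nm]], spec$kind))
      asl_abort("type_mismatch",
                sprintf("field '%s' does not conform to kind '%s'", nm, spec$kind),
                field = nm)
  }
  structure(list(role = role, entries = entries), class = "asl_sidecar")
}

# Convenience accessor: entry value or NULL.
sidecar_get <- function(sidecar, name) {
  if (is.null(sidecar)) return(NULL)
  sidecar$entries[[name]]
}

#' A fully scaled image series
#'
#' A 3D or 4D floating-point array with all conversion-time intensity scale
#' factors already applied: an ASL-BIDS image carries no latent slope or
#' intercept, so voxel values are used as stored.
#'
#' @param voxels 3D or 4D numeric array of finite values.
#' @param voxel_size_mm Numeric length-3 voxel size in mm.
#' @return An `asl_image_series` with fields `voxels`, `voxel_size_mm`,
#'   `n_volumes`.
#' @export
image_series <- function(voxels, voxel_size_mm = c(3, 3, 3)) {
  if (!is.numeric(voxels) || !(length(dim(voxels)) %in% c(3L, 4L)))
    asl_abort("invalid_series", "voxels must be a 3D or 4D numeric array")
  if (!all(is.finite(voxels)))
    asl_abort("invalid_series", "voxel values must all be finite")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    asl_abort("invalid_series", "voxel_size_mm must be 3 positive numbers")
  # NIfTI headers hold pixdim as float32; snap so write->read is the identity
  voxel_size_mm <- readBin(writeBin(as.numeric(voxel_size_mm), raw(), size = 4L),
                           "double", n = 3L, size = 4L)
  d <- dim(voxels)
  structure(
    list(voxels = voxels, voxel_size_mm = as.numeric(voxel_size_mm),
         n_volumes = if (length(d) == 4L) d[4L] else 1L),
    class = "asl_image_series"
  )
}

# The i-th volume of a series as a 3D array.
series_volume <- function(series, i) {
  d <- dim(series$voxels)
  if (length(d) == 3L) {
    if (i != 1L) asl_abort("invalid_series", "3D series has a single volume")
    return(series$voxels)
  }
  array(series$voxels[, , , i], dim = d[1:3])
}

#' One subject's perfusion contents
#'
#' Gathers everything under `sub-<label>/perf/` (and any linked PEPolar
#' fieldmap under `fmap/`): the ASL series and its sidecar, the acquisition
#' context, an optional separate m0scan, optional fieldmap entries, and the
#' labeling-plane screenshot flag.
#'
#' @param subject Subject label (without the `sub-` prefix).
#' @param asl_series,asl_sidecar,context The ASL time series, its sidecar and
#'   its `aslcontext`.
#' @param m0_series,m0_sidecar Optional separate m0scan image and sidecar
#'   (both or neither).
#' @param fieldmap_entries List of fieldmap entries, each a list with
#'   `series`, `sidecar` and `direction` (the `dir-` entity label).
#' @param labeling_screenshot_present Is a `*_asllabeling.jpg` present?
#' @param readme_present Does the dataset root carry a `README`?
#' @param extra_files Relative paths of unmodelled files in the tree.
#' @return An `asl_dataset`.
#' @export
asl_dataset <- function(subject, asl_series, asl_sidecar, context,
                        m0_series = NULL, m0_sidecar = NULL,
                        fieldmap_entries = list(),
                        labeling_screenshot_present = FALSE,
                        readme_present = FALSE,
                        extra_files = character()) {
  stopifnot(is.character(subject), length(subject) == 1L, nzchar(subject),
            inherits(asl_series, "asl_image_series"),
            inherits(asl_sidecar, "asl_sidecar"),
            inherits(context, "asl_context"))
  if (!is.null(m0_series) && is.null(m0_sidecar))
    asl_abort("invalid_dataset", "m0_series present without m0_sidecar")
  for (fe in fieldmap_entries)
    stopifnot(inherits(fe$series, "asl_image_series"),
              inherits(fe$sidecar, "asl_sidecar"))
  structure(
    list(subject = subject, asl_series = asl_series,
         asl_sidecar = asl_sidecar, context = context,
         m0_series = m0_series, m0_sidecar = m0_sidecar,
         fieldmap_entries = fieldmap_entries,
         labeling_screenshot_present = isTRUE(labeling_screenshot_present),
         readme_present = isTRUE(readme_present),
         extra_files = extra_files),
    class = "asl_dataset"
  )
}

# Relative paths of the dataset's own files (as written by write_asl_dataset),
# used for IntendedFor resolution and issue attribution.
dataset_paths <- function(dataset) {
  sub <- paste0("sub-", dataset$subject)
  p <- list(
    asl_image = sprintf("%s/perf/%s_asl.nii.gz", sub, sub),
    asl_sidecar = sprintf("%s/perf/%s_asl.json", sub, sub),
    context = sprintf("%s/perf/%s_aslcontext.tsv", sub, sub)
  )
  if (!is.null(dataset$m0_series)) {
    p$m0_image <- sprintf("%s/perf/%s_m0scan.nii.gz", sub, sub)
    p$m0_sidecar <- sprintf("%s/perf/%s_m0scan.json", sub, sub)
  }
  if (length(dataset$fieldmap_entries)) {
    p$fmap_images <- vapply(dataset$fieldmap_entries, function(fe)
      sprintf("%s/fmap/%s_dir-%s_m0scan.nii.gz", sub, sub, fe$direction),
      character(1))
    p$fmap_sidecars <- sub("\\.nii\\.gz$", ".json", p$fmap_images)
  }
  if (dataset$labeling_screenshot_present)
    p$screenshot <- sprintf("%s/perf/%s_asllabeling.jpg", sub, sub)
  p
}

#' @export
print.asl_dataset <- function(x, ...) {
  cat(sprintf("<asl_dataset> sub-%s: %d volumes [%s]\n", x$subject,
              x$asl_series$n_volumes,
              paste(table(unclass(x$context))[unique(unclass(x$context))],
                    unique(unclass(x$context)), collapse = ", ")))
  cat(sprintf("  M0Type: %s; separate m0scan: %s; fieldmaps: %d; screenshot: %s\n",
              sidecar_get(x$asl_sidecar, "M0Type") %||% "<missing>",
              !is.null(x$m0_series), length(x$fieldmap_entries),
              x$labeling_screenshot_present))
  invisible(x)
}
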