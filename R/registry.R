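#' ASL-BIDS metadata field registry
#'
#' The registry is the machine-readable schema behind validation: one
#' [field_spec()] per sidecar field, carrying its value kind, units,
#' requirement level on the REQUIRED > RECOMMENDED > OPTIONAL ladder, and an
#' applicability condition evaluated against the ASL sidecar (e.g.
#' `SliceTiming` is REQUIRED only for 2D readouts, `LabelingDuration` only for
#' (P)CASL labeling). Requirement levels are ranked by necessity for CBF
#' quantification: REQUIRED fields are those without which a cerebral blood
#' flow map cannot be computed from the sidecar alone.
#'
#' Fields defined by BIDS for the `perf` datatype but not needed for
#' quantification are carried as OPTIONAL so that real sidecars pass through
#' unharmed.
#'
#' @section Value kinds:
#' `number`, `boolean`, `string`, `number_array`, `string_array`, and
#' `number_or_array` (a scalar or an array; permitted for exactly
#' `PostLabelingDelay`, `LabelingDuration` and `FlipAngle`, the fields that
#' multi-delay and Look-Locker/QUASAR-style series may vectorise).
#' All time-valued fields are in seconds, the BIDS convention.
#'
#' @param name Field name as it appears in the JSON sidecar.
#' @param role File role the spec applies to: `"asl"`, `"m0scan"` or
#'   `"fieldmap"`.
#' @param kind Value kind (see section above).
#' @param requirement `"REQUIRED"`, `"RECOMMENDED"` or `"OPTIONAL"`.
#' @param units Unit string, `""` for unitless fields.
#' @param condition Applicability condition over sidecar values as an R
#'   expression string, or `NA` when the field always applies. A condition
#'   that cannot be evaluated (its operand is missing) makes the field not
#'   applicable.
#' @param allowed_values Optional character vector enumerating legal values.
#' @param plausible_range Optional `c(min, max)`; values outside it raise a
#'   WARNING (not an ERROR) during validation.
#' @return `field_spec()` returns an object of class `asl_field_spec`;
#'   `build_field_registry()` returns an `asl_field_registry`, an ordered list
#'   of field specs.
#' @export
field_spec <- function(name, role, kind, requirement, units = "",
                       condition = NA_character_, allowed_values = NULL,
                       plausible_range = NULL) {
  stopifnot(
    is.character(name), length(name) == 1L, nzchar(name),
    role %in% c("asl", "m0scan", "fieldmap"),
    kind %in% c("number", "boolean", "string", "number_array",
                "string_array", "number_or_array"),
    requirement %in% c("REQUIRED", "RECOMMENDED", "OPTIONAL")
  )
  if (!is.null(allowed_values) && length(allowed_values) == 0L)
    asl_abort("invalid_field_spec", "allowed_values, when given, must be non-empty")
  structure(
    list(name = name, role = role, kind = kind, requirement = requirement,
         units = units, condition = condition,
         allowed_values = allowed_values, plausible_range = plausible_range),
    class = "asl_field_spec"
  )
}

#' @rdname field_spec
#' @export
build_field_registry <- function() {
  sp <- field_spec
  specs <- list(
    ## --- role = asl: unconditionally REQUIRED for quantification ----------
    sp("ArterialSpinLabelingType", "asl", "string", "REQUIRED",
       allowed_values = c("CASL", "PCASL", "PASL")),
    sp("PostLabelingDelay", "asl", "number_or_array", "REQUIRED", "s",
       plausible_range = c(0, 10)),
    sp("BackgroundSuppression", "asl", "boolean", "REQUIRED"),
    sp("M0Type", "asl", "string", "REQUIRED",
       allowed_values = c("Separate", "Included", "Estimate", "Absent")),
    sp("TotalAcquiredPairs", "asl", "number", "REQUIRED",
       plausible_range = c(1, 1000)),
    sp("MagneticFieldStrength", "asl", "number", "REQUIRED", "T",
       plausible_range = c(0.1, 14)),
    sp("MRAcquisitionType", "asl", "string", "REQUIRED",
       allowed_values = c("2D", "3D")),
    sp("EchoTime", "asl", "number", "REQUIRED", "s",
       plausible_range = c(0, 10)),
    sp("FlipAngle", "asl", "number_or_array", "REQUIRED", "degrees",
       plausible_range = c(1e-9, 180)),
    sp("RepetitionTimePreparation", "asl", "number", "REQUIRED", "s",
       plausible_range = c(0, 50)),
    ## --- role = asl: conditionally REQUIRED -------------------------------
    sp("SliceTiming", "asl", "number_array", "REQUIRED", "s",
       condition = 'MRAcquisitionType == "2D"',
       plausible_range = c(0, 10)),
    sp("LabelingDuration", "asl", "number_or_array", "REQUIRED", "s",
       condition = 'ArterialSpinLabelingType %in% c("CASL", "PCASL")',
       plausible_range = c(0, 10)),
    sp("BolusCutOffFlag", "asl", "boolean", "REQUIRED",
       condition = 'ArterialSpinLabelingType == "PASL"'),
    sp("BolusCutOffDelayTime", "asl", "number_or_array", "REQUIRED", "s",
       condition = 'ArterialSpinLabelingType == "PASL" && isTRUE(BolusCutOffFlag)',
       plausible_range = c(0, 10)),
    sp("BolusCutOffTechnique", "asl", "string", "REQUIRED",
       condition = 'ArterialSpinLabelingType == "PASL" && isTRUE(BolusCutOffFlag)'),
    sp("M0Estimate", "asl", "number", "REQUIRED",
       condition = 'M0Type == "Estimate"'),
    ## --- role = asl: RECOMMENDED ------------------------------------------
    sp("AcquisitionVoxelSize", "asl", "number_array", "RECOMMENDED", "mm"),
    sp("BackgroundSuppressionNumberPulses", "asl", "number", "RECOMMENDED",
       condition = "isTRUE(BackgroundSuppression)",
       plausible_range = c(0, 20)),
    sp("BackgroundSuppressionPulseTime", "asl", "number_array", "RECOMMENDED", "s",
       condition = "isTRUE(BackgroundSuppression)",
       plausible_range = c(0, 10)),
    ## --- role = asl: OPTIONAL ---------------------------------------------
    sp("LabelingLocationDescription", "asl", "string", "OPTIONAL"),
    sp("LookLocker", "asl", "boolean", "OPTIONAL"),
    sp("LabelingEfficiency", "asl", "number", "OPTIONAL",
       plausible_range = c(1e-9, 1)),
    sp("VascularCrushing", "asl", "boolean", "OPTIONAL"),
    sp("VascularCrushingVENC", "asl", "number_or_array", "OPTIONAL", "cm/s"),
    sp("PCASLType", "asl", "string", "OPTIONAL",
       condition = 'ArterialSpinLabelingType == "PCASL"',
       allowed_values = c("balanced", "unbalanced")),
    sp("CASLType", "asl", "string", "OPTIONAL",
       condition = 'ArterialSpinLabelingType == "CASL"',
       allowed_values = c("single-coil", "double-coil")),
    sp("LabelingSlabThickness", "asl", "number", "OPTIONAL", "mm"),
    sp("LabelingPulseAverageGradient", "asl", "number", "OPTIONAL", "mT/m"),
    sp("LabelingPulseMaximumGradient", "asl", "number", "OPTIONAL", "mT/m"),
    sp("LabelingPulseAverageB1", "asl", "number", "OPTIONAL", "uT"),
    sp("LabelingPulseDuration", "asl", "number", "OPTIONAL", "s"),
    sp("LabelingPulseFlipAngle", "asl", "number", "OPTIONAL", "degrees"),
    sp("LabelingPulseInterval", "asl", "number", "OPTIONAL", "s"),
    sp("AcquisitionDuration", "asl", "number", "OPTIONAL", "s"),
    sp("PhaseEncodingDirection", "asl", "string", "OPTIONAL",
       allowed_values = c("i", "j", "k", "i-", "j-", "k-")),
    sp("Manufacturer", "asl", "string", "OPTIONAL"),
    sp("ManufacturersModelName", "asl", "string", "OPTIONAL"),
    sp("PulseSequenceType", "asl", "string", "OPTIONAL"),
    sp("PulseSequenceDetails", "asl", "string", "OPTIONAL"),
    ## --- role = m0scan -----------------------------------------------------
    sp("EchoTime", "m0scan", "number", "REQUIRED", "s",
       plausible_range = c(0, 10)),
    sp("FlipAngle", "m0scan", "number", "REQUIRED", "degrees",
       plausible_range = c(1e-9, 180)),
    sp("RepetitionTimePreparation", "m0scan", "number", "REQUIRED", "s",
       plausible_range = c(0, 50)),
    sp("IntendedFor", "m0scan", "string", "REQUIRED"),
    sp("AcquisitionVoxelSize", "m0scan", "number_array", "RECOMMENDED", "mm"),
    sp("PhaseEncodingDirection", "m0scan", "string", "OPTIONAL",
       allowed_values = c("i", "j", "k", "i-", "j-", "k-")),
    sp("MagneticFieldStrength", "m0scan", "number", "OPTIONAL", "T",
       plausible_range = c(0.1, 14)),
    sp("MRAcquisitionType", "m0scan", "string", "OPTIONAL",
       allowed_values = c("2D", "3D")),
    sp("Manufacturer", "m0scan", "string", "OPTIONAL"),
    ## --- role = fieldmap (PEPolar m0scan in fmap/) --------------------------
    sp("PhaseEncodingDirection", "fieldmap", "string", "REQUIRED",
       allowed_values = c("i", "j", "k", "i-", "j-", "k-")),
    sp("IntendedFor", "fieldmap", "string", "REQUIRED"),
    sp("EchoTime", "fieldmap", "number", "OPTIONAL", "s",
       plausible_range = c(0, 10)),
    sp("RepetitionTimePreparation", "fieldmap", "number", "OPTIONAL", "s",
       plausible_range = c(0, 50)),
    sp("TotalReadoutTime", "fieldmap", "number", "OPTIONAL", "s")
  )
  nm <- vapply(specs, function(s) paste(s$role, s$name), character(1))
  if (anyDuplicated(nm))
    asl_abort("invalid_field_spec", "duplicate (role, name) in registry")
  structure(specs, class = "asl_field_registry")
}

# Pure predicate: does `spec` apply to a sidecar with the given values?
# Conditions whose operands are absent evaluate to FALSE (not applicable).
field_applies <- function(spec, values) {
  if (is.na(spec$condition)) return(TRUE)
  env <- list2env(values, parent = baseenv())
  isTRUE(tryCatch(eval(parse(text = spec$condition), envir = env),
                  error = function(e) FALSE))
}

#' Fields applicable to a file role given the ASL sidecar values
#'
#' Filters the registry by role and evaluates each conditional-applicability
#' predicate against `values` (normally the ASL sidecar entries, which carry
#' the discriminating fields such as `MRAcquisitionType` and
#' `ArterialSpinLabelingType`). The result preserves registry order, so the
#' field set is deterministic for given inputs.
#'
#' @param role `"asl"`, `"m0scan"` or `"fieldmap"`.
#' @param values Named list of sidecar values used to evaluate conditions.
#' @param registry A registry from [build_field_registry()].
#' @return List of `asl_field_spec` objects.
#' @export
applicable_fields <- function(role, values = list(),
                              registry = build_field_registry()) {
  if (!role %in% c("asl", "m0scan", "fieldmap"))
    asl_abort("invalid_field_spec", sprintf("unknown role '%s'", role))
  keep <- vapply(registry, function(s) {
    s$role == role && field_applies(s, values)
  }, logical(1))
  unclass(registry)[keep]
}

# Registry lookup by (role, name); NULL when absent.
registry_lookup <- function(registry, role, name) {
  for (s in registry) if (s$role == role && s$name == name) return(s)
  NULL
}

#' Export the registry as a JSON document
#'
#' Serialises every field spec (name, role, kind, units, requirement,
#' condition string, allowed values, plausible range) for documentation
#' generation or external tooling.
#'
#' @param registry A registry from [build_field_registry()].
#' @param path Optional file to write to; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
registry_json <- function(registry = build_field_registry(), path = NULL) {
  doc <- lapply(registry, function(s) {
    list(name = s$name, role = s$role, kind = s$kind, units = s$units,
         requirement = s$requirement,
         condition = if (is.na(s$condition)) NULL else s$condition,
         allowed_values = s$allowed_values,
         plausible_range = s$plausible_range)
  })
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                           digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @export
print.asl_field_registry <- function(x, ...) {
  cat(sprintf("<asl_field_registry> %d field specs\n", length(x)))
  for (role in c("asl", "m0scan", "fieldmap")) {
    n <- sum(vapply(x, function(s) s$role == role, logical(1)))
    cat(sprintf("  role %-8s %d fields\n", role, n))
  }
  invisible(x)
}

# Does `value` conform to the registry value kind?
value_conforms <- function(value, kind) {
  is_num <- function(v) is.numeric(v) && !anyNA(v)
  switch(kind,
    number = is_num(value) && length(value) == 1L,
    boolean = is.logical(value) && length(value) == 1L && !is.na(value),
    string = is.character(value) && length(value) == 1L && !is.na(value),
    number_array = is_num(value) && length(value) >= 1L,
    string_array = is.character(value) && !anyNA(value) && length(value) >= 1L,
    number_or_array = is_num(value) && length(value) >= 1L,
    FALSE
  )
}
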