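## Rule engine. Each rule returns a data frame of issues; validate_asl()
## composes all rules, deduplicates and orders them deterministically.
##
## Rule catalogue (stable identifiers, published in the package docs):
##   ASL101  missing REQUIRED field (under applicability)          ERROR
##   ASL102  missing RECOMMENDED field                             WARNING
##   ASL103  value violates declared kind or allowed enumeration   ERROR
##   ASL104  value outside plausible range (ms-suspicion etc.)     WARNING
##   ASL201  context row count != number of volumes                ERROR
##   ASL202  control and label row counts differ                   ERROR
##   ASL203  observed pair count != TotalAcquiredPairs             WARNING
##   ASL204  deltam/cbf volumes mixed with control/label           ERROR
##   ASL301  M0Type=Separate without matching separate m0scan      ERROR
##   ASL302  M0Type=Included without in-series m0scan              ERROR
##   ASL303  M0Type=Estimate without positive M0Estimate           ERROR
##   ASL304  M0Type=Estimate but dataset has no README             WARNING
##   ASL305  M0Type=Absent but M0 information present              ERROR
##   ASL401  SliceTiming length != slice count                     ERROR
##   ASL402  PostLabelingDelay array length != number of volumes   ERROR
##   ASL501  forbidden intensity-scaling field present             ERROR
##   ASL601  fieldmap IntendedFor missing or dangling              ERROR
##   ASL602  PhaseEncodingDirection missing on fmap or target      ERROR
##   ASL603  phase-encoding polarities are not exact opposites     ERROR

SCALING_DENY_LIST <- c(
  "ScaleSlope", "ScaleIntercept", "RescaleSlope", "RescaleIntercept",
  "RescaleType", "M0ScaleFactor", "ASLScaleFactor", "PhilipsRescaleSlope",
  "PhilipsRescaleIntercept", "PhilipsScaleSlope", "SclSlope", "SclInter"
)

issue_row <- function(rule_id, severity, path, field, message) {
  data.frame(rule_id = rule_id, severity = severity, path = path,
             field = if (is.null(field)) NA_character_ else field,
             message = message, stringsAsFactors = FALSE)
}

no_issues <- function() {
  data.frame(rule_id = character(), severity = character(),
             path = character(), field = character(), message = character(),
             stringsAsFactors = FALSE)
}

bind_issues <- function(...) {
  do.call(rbind, Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))) %||%
    no_issues()
}

validation_report <- function(issues) {
  if (nrow(issues)) {
    issues <- issues[!duplicated(issues[c("rule_id", "path", "field", "message")]), ]
    issues <- issues[order(issues$rule_id, issues$path, issues$field,
                           method = "radix"), ]
    rownames(issues) <- NULL
  }
  structure(list(issues = issues,
                 valid = !any(issues$severity == "ERROR")),
            class = "asl_validation_report")
}

#' @export
print.asl_validation_report <- function(x, ...) {
  cat(sprintf("<asl_validation_report> %s: %d error(s), %d warning(s)\n",
              if (x$valid) "VALID" else "INVALID",
              sum(x$issues$severity == "ERROR"),
              sum(x$issues$severity == "WARNING")))
  if (nrow(x$issues))
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s %s%s: %s\n", x$issues$rule_id[i],
                  x$issues$severity[i], x$issues$path[i],
                  ifelse(is.na(x$issues$field[i]), "",
                         paste0(" (", x$issues$field[i], ")")),
                  x$issues$message[i]))
  invisible(x)
}

#' Serialise a validation report as JSON
#'
#' @param report An `asl_validation_report`.
#' @return JSON string with fields `valid` and `issues` (list of issue
#'   objects with `rule_id`, `severity`, `path`, `field`, `message`).
#' @export
report_json <- function(report) {
  issues <- lapply(seq_len(nrow(report$issues)), function(i) {
    r <- report$issues[i, ]
    list(rule_id = r$rule_id, severity = r$severity, path = r$path,
         field = if (is.na(r$field)) NULL else r$field, message = r$message)
  })
  jsonlite::toJSON(list(valid = report$valid, issues = issues),
                   auto_unbox = TRUE, null = "null", pretty = TRUE)
}

## Individual rules ----------------------------------------------------------

# Registry presence ladder for one sidecar: missing REQUIRED -> ASL101,
# missing RECOMMENDED -> ASL102, missing OPTIONAL -> silent.
rule_presence <- function(sidecar, cond_values, path, registry) {
  out <- no_issues()
  for (spec in applicable_fields(sidecar$role, cond_values, registry)) {
    if (!is.null(sidecar$entries[[spec$name]])) next
    if (spec$requirement == "REQUIRED")
      out <- bind_issues(out, issue_row("ASL101", "ERROR", path, spec$name,
        sprintf("REQUIRED field '%s' is missing", spec$name)))
    else if (spec$requirement == "RECOMMENDED")
      out <- bind_issues(out, issue_row("ASL102", "WARNING", path, spec$name,
        sprintf("RECOMMENDED field '%s' is missing", spec$name)))
  }
  out
}

# Value kind + enumeration conformity (ASL103) and plausible range (ASL104).
rule_values <- function(sidecar, path, registry) {
  out <- no_issues()
  for (nm in names(sidecar$entries)) {
    spec <- registry_lookup(registry, sidecar$role, nm)
    if (is.null(spec)) next
    v <- sidecar$entries[[nm]]
    if (!value_conforms(v, spec$kind)) {
      out <- bind_issues(out, issue_row("ASL103", "ERROR", path, nm,
        sprintf("'%s' must be of kind %s", nm, spec$kind)))
      next
    }
    if (!is.null(spec$allowed_values) && !all(v %in% spec$allowed_values))
      out <- bind_issues(out, issue_row("ASL103", "ERROR", path, nm,
        sprintf("'%s' must be one of {%s}", nm,
                paste(spec$allowed_values, collapse = ", "))))
    if (!is.null(spec$plausible_range) && is.numeric(v) &&
        any(v < spec$plausible_range[1] | v > spec$plausible_range[2]))
      out <- bind_issues(out, issue_row("ASL104", "WARNING", path, nm,
        sprintf("'%s' outside plausible range [%g, %g]%s", nm,
                spec$plausible_range[1], spec$plausible_range[2],
                if (spec$units == "s" && any(v > 10))
                  " (value > 10 s: milliseconds suspected; BIDS times are in seconds)"
                else "")))
  }
  out
}

#' Context/series consistency rule
#'
#' ERROR when the context row count differs from the number of image volumes
#' (ASL201) or when control and label rows are unbalanced (ASL202); WARNING
#' when the observed control-label pair count differs from
#' `TotalAcquiredPairs` (ASL203) - averaged exports legitimately lose
#' repetitions, so this is not an error.
#'
#' @param asl_series The ASL [image_series()].
#' @param context The [asl_context()].
#' @param total_acquired_pairs The sidecar `TotalAcquiredPairs` value, if any.
#' @param path Path used for issue attribution.
#' @return A data frame of issues.
#' @export
check_context_volume_match <- function(asl_series, context,
                                       total_acquired_pairs = NULL,
                                       path = "") {
  out <- no_issues()
  ctx <- unclass(context)
  if (length(ctx) != asl_series$n_volumes)
    out <- bind_issues(out, issue_row("ASL201", "ERROR", path, NULL,
      sprintf("aslcontext has %d rows but the series has %d volumes",
              length(ctx), asl_series$n_volumes)))
  n_control <- sum(ctx == "control"); n_label <- sum(ctx == "label")
  if (n_control != n_label)
    out <- bind_issues(out, issue_row("ASL202", "ERROR", path, NULL,
      sprintf("%d control vs %d label rows; pairs must balance",
              n_control, n_label)))
  if ((n_control > 0 || n_label > 0) && !is.null(total_acquired_pairs)) {
    observed <- min(n_control, n_label)
    if (is.numeric(total_acquired_pairs) && length(total_acquired_pairs) == 1L &&
        observed != total_acquired_pairs)
      out <- bind_issues(out, issue_row("ASL203", "WARNING", path,
        "TotalAcquiredPairs",
        sprintf("observed %d control-label pairs but TotalAcquiredPairs=%g",
                observed, total_acquired_pairs)))
  }
  out
}

rule_context_mixing <- function(context, path) {
  ctx <- unclass(context)
  if (any(ctx %in% c("deltam", "cbf")) && any(ctx %in% c("control", "label")))
    return(issue_row("ASL204", "ERROR", path, NULL,
      "deltam/cbf volumes must not be mixed with control/label volumes"))
  no_issues()
}

#' M0 consistency rule
#'
#' Checks that the dataset's M0 information matches the declared `M0Type`:
#' `Separate` needs a separate m0scan image+sidecar and no in-series m0scan
#' rows (ASL301); `Included` needs at least one in-series m0scan row and no
#' separate file (ASL302); `Estimate` needs a positive scalar `M0Estimate`
#' (ASL303) and warns when the dataset has no README documenting the
#' estimate's origin (ASL304); `Absent` forbids any m0scan file, m0scan row
#' or `M0Estimate` (ASL305).
#'
#' @param dataset An [asl_dataset()].
#' @return A data frame of issues (empty when `M0Type` is missing; the
#'   presence rule reports that case).
#' @export
check_m0_consistency <- function(dataset) {
  m0type <- sidecar_get(dataset$asl_sidecar, "M0Type")
  if (is.null(m0type) ||
      !m0type %in% c("Separate", "Included", "Estimate", "Absent"))
    return(no_issues())
  path <- dataset_paths(dataset)$asl_sidecar
  ctx <- unclass(dataset$context)
  has_file <- !is.null(dataset$m0_series)
  has_rows <- any(ctx == "m0scan")
  est <- sidecar_get(dataset$asl_sidecar, "M0Estimate")
  out <- no_issues()
  if (m0type == "Separate") {
    if (!has_file)
      out <- bind_issues(out, issue_row("ASL301", "ERROR", path, "M0Type",
        "M0Type=Separate but no separate m0scan image+sidecar exists in perf/"))
    if (has_rows)
      out <- bind_issues(out, issue_row("ASL301", "ERROR", path, "M0Type",
        "M0Type=Separate but the aslcontext contains m0scan rows"))
  } else if (m0type == "Included") {
    if (!has_rows)
      out <- bind_issues(out, issue_row("ASL302", "ERROR", path, "M0Type",
        "M0Type=Included but the aslcontext contains no m0scan row"))
    if (has_file)
      out <- bind_issues(out, issue_row("ASL302", "ERROR", path, "M0Type",
        "M0Type=Included but a separate m0scan file exists"))
  } else if (m0type == "Estimate") {
    if (!(is.numeric(est) && length(est) == 1L && is.finite(est) && est > 0))
      out <- bind_issues(out, issue_row("ASL303", "ERROR", path, "M0Estimate",
        "M0Type=Estimate requires a positive scalar M0Estimate"))
    if (!dataset$readme_present)
      out <- bind_issues(out, issue_row("ASL304", "WARNING", path, "M0Estimate",
        "M0Type=Estimate: document the estimate's origin in the dataset README"))
  } else if (m0type == "Absent") {
    if (has_file || has_rows || !is.null(est))
      out <- bind_issues(out, issue_row("ASL305", "ERROR", path, "M0Type",
        "M0Type=Absent but M0 information is present"))
  }
  out
}

#' Conditional-requirement rule for the ASL sidecar
#'
#' Evaluates the conditionally REQUIRED fields (`SliceTiming` for 2D,
#' `LabelingDuration` for (P)CASL, `BolusCutOffFlag`/`DelayTime`/`Technique`
#' for PASL, `M0Estimate` for M0Type=Estimate, `MagneticFieldStrength` needed
#' for default constants) plus the structural length checks: `SliceTiming`
#' must have one entry per slice (ASL401) and an array-valued
#' `PostLabelingDelay` one entry per volume (ASL402). Plausibility warnings
#' (ASL104) fire for values outside their documented ranges, notably
#' time-in-seconds fields above 10 s, a typical symptom of millisecond input.
#'
#' @param asl_sidecar The ASL [sidecar_metadata()].
#' @param n_slices Slice count (3rd spatial dimension), when known.
#' @param n_volumes Volume count, when known.
#' @param path Path used for issue attribution.
#' @param registry Field registry.
#' @return A data frame of issues.
#' @export
check_conditional_requirements <- function(asl_sidecar, n_slices = NULL,
                                           n_volumes = NULL, path = "",
                                           registry = build_field_registry()) {
  out <- bind_issues(
    rule_presence(asl_sidecar, asl_sidecar$entries, path, registry),
    rule_values(asl_sidecar, path, registry)
  )
  # keep only conditional/structural matters here: unconditional presence is
  # still reported (MagneticFieldStrength etc. are needed for defaults)
  st <- sidecar_get(asl_sidecar, "SliceTiming")
  if (!is.null(st) && !is.null(n_slices) && length(st) != n_slices)
    out <- bind_issues(out, issue_row("ASL401", "ERROR", path, "SliceTiming",
      sprintf("SliceTiming has %d entries but the image has %d slices",
              length(st), n_slices)))
  pld <- sidecar_get(asl_sidecar, "PostLabelingDelay")
  if (!is.null(pld) && length(pld) > 1L && !is.null(n_volumes) &&
      length(pld) != n_volumes)
    out <- bind_issues(out, issue_row("ASL402", "ERROR", path,
      "PostLabelingDelay",
      sprintf("PostLabelingDelay array has %d entries but the series has %d volumes",
              length(pld), n_volumes)))
  ll <- sidecar_get(asl_sidecar, "LookLocker")
  if (isTRUE(ll) && is.null(sidecar_get(asl_sidecar, "FlipAngle")))
    out <- bind_issues(out, issue_row("ASL101", "ERROR", path, "FlipAngle",
      "LookLocker=true requires FlipAngle"))
  out
}

#' Forbidden-scaling-field rule
#'
#' ASL-BIDS defines no metadata for intensity scaling: every slope and
#' intercept must already be applied to the image data at conversion. Any
#' sidecar key from the scaling deny-list (`ScaleSlope`, `RescaleSlope`,
#' `RescaleIntercept`, `M0ScaleFactor`, vendor dialects, ...) is therefore an
#' ERROR (ASL501) on that file.
#'
#' @param sidecars Named list mapping relative path to [sidecar_metadata()].
#' @return A data frame of issues.
#' @export
check_scaling_fields_absent <- function(sidecars) {
  out <- no_issues()
  for (path in names(sidecars)) {
    hits <- intersect(names(sidecars[[path]]$entries), SCALING_DENY_LIST)
    for (h in hits)
      out <- bind_issues(out, issue_row("ASL501", "ERROR", path, h,
        sprintf("scaling field '%s' is forbidden; apply all scale factors to the data at conversion", h)))
  }
  out
}

# Polarity opposition: same axis letter, exactly one trailing "-".
pepolar_opposite <- function(a, b) {
  axis <- function(x) sub("-$", "", x)
  neg <- function(x) grepl("-$", x)
  identical(axis(a), axis(b)) && xor(neg(a), neg(b))
}

#' PEPolar fieldmap linkage rule
#'
#' For every reversed phase-encoding m0scan stored under `fmap/`: its
#' `IntendedFor` must resolve to an existing file of the dataset (ASL601),
#' `PhaseEncodingDirection` must be present on both the fieldmap and the
#' intended file (ASL602), and the two directions must be exact polarity
#' opposites - same axis letter, opposite sign (ASL603).
#'
#' @param dataset An [asl_dataset()].
#' @return A data frame of issues.
#' @export
check_pepolar_fieldmap <- function(dataset) {
  out <- no_issues()
  if (!length(dataset$fieldmap_entries)) return(out)
  p <- dataset_paths(dataset)
  own_files <- c(p$asl_image, p$m0_image, dataset$extra_files)
  sub_prefix <- paste0("sub-", dataset$subject, "/")
  for (i in seq_along(dataset$fieldmap_entries)) {
    fe <- dataset$fieldmap_entries[[i]]
    fpath <- p$fmap_sidecars[i]
    intended <- sidecar_get(fe$sidecar, "IntendedFor")
    target_sidecar <- NULL
    if (is.null(intended)) {
      out <- bind_issues(out, issue_row("ASL601", "ERROR", fpath, "IntendedFor",
        "fieldmap m0scan must link its target via IntendedFor"))
    } else {
      # IntendedFor is relative to the subject directory
      resolved <- paste0(sub_prefix, intended)
      if (!resolved %in% own_files) {
        out <- bind_issues(out, issue_row("ASL601", "ERROR", fpath, "IntendedFor",
          sprintf("IntendedFor '%s' does not resolve to a file of this dataset",
                  intended)))
      } else if (identical(resolved, p$asl_image)) {
        target_sidecar <- list(sidecar = dataset$asl_sidecar,
                               path = p$asl_sidecar)
      } else if (!is.null(p$m0_image) && identical(resolved, p$m0_image)) {
        target_sidecar <- list(sidecar = dataset$m0_sidecar,
                               path = p$m0_sidecar)
      }
    }
    ped_f <- sidecar_get(fe$sidecar, "PhaseEncodingDirection")
    if (is.null(ped_f))
      out <- bind_issues(out, issue_row("ASL602", "ERROR", fpath,
        "PhaseEncodingDirection",
        "fieldmap m0scan must state its PhaseEncodingDirection"))
    if (!is.null(target_sidecar)) {
      ped_t <- sidecar_get(target_sidecar$sidecar, "PhaseEncodingDirection")
      if (is.null(ped_t))
        out <- bind_issues(out, issue_row("ASL602", "ERROR",
          target_sidecar$path, "PhaseEncodingDirection",
          "the file targeted by a PEPolar fieldmap must state its PhaseEncodingDirection"))
      else if (!is.null(ped_f) && !pepolar_opposite(ped_f, ped_t))
        out <- bind_issues(out, issue_row("ASL603", "ERROR", fpath,
          "PhaseEncodingDirection",
          sprintf("'%s' and '%s' are not opposite polarities of the same axis",
                  ped_f, ped_t)))
    }
  }
  out
}

## The composed validator ----------------------------------------------------

#' Validate an ASL dataset
#'
#' Runs the full rule catalogue: registry presence under conditional
#' applicability (REQUIRED -> ERROR, RECOMMENDED -> WARNING, OPTIONAL ->
#' silent), value kind/enumeration conformity, context/series consistency, M0
#' declaration consistency, structural length checks, the forbidden-scaling
#' deny-list, and PEPolar fieldmap linkage. Problems are reported as issues,
#' never raised as errors; the report is deterministic (issues ordered by
#' rule id, then path) and the function is stateless, so repeated validation
#' of an unchanged dataset yields an identical report.
#'
#' @param dataset An [asl_dataset()].
#' @param strict When `TRUE`, missing RECOMMENDED fields are promoted from
#'   WARNING to ERROR.
#' @param registry Field registry.
#' @return An `asl_validation_report` with fields `issues` (data frame) and
#'   `valid` (`TRUE` iff no ERROR issue).
#' @export
validate_asl <- function(dataset, strict = FALSE,
                         registry = build_field_registry()) {
  stopifnot(inherits(dataset, "asl_dataset"))
  p <- dataset_paths(dataset)
  asl_vals <- dataset$asl_sidecar$entries
  d <- dim(dataset$asl_series$voxels)
  n_slices <- d[3L]

  sidecars <- stats::setNames(list(dataset$asl_sidecar), p$asl_sidecar)
  if (!is.null(dataset$m0_sidecar))
    sidecars[[p$m0_sidecar]] <- dataset$m0_sidecar
  for (i in seq_along(dataset$fieldmap_entries))
    sidecars[[p$fmap_sidecars[i]]] <- dataset$fieldmap_entries[[i]]$sidecar

  issues <- bind_issues(
    check_conditional_requirements(dataset$asl_sidecar, n_slices = n_slices,
                                   n_volumes = dataset$asl_series$n_volumes,
                                   path = p$asl_sidecar, registry = registry),
    if (!is.null(dataset$m0_sidecar)) bind_issues(
      rule_presence(dataset$m0_sidecar, dataset$m0_sidecar$entries,
                    p$m0_sidecar, registry),
      rule_values(dataset$m0_sidecar, p$m0_sidecar, registry)),
    {
      fm <- no_issues()
      for (i in seq_along(dataset$fieldmap_entries)) {
        sc <- dataset$fieldmap_entries[[i]]$sidecar
        fm <- bind_issues(fm,
          rule_presence(sc, sc$entries, p$fmap_sidecars[i], registry),
          rule_values(sc, p$fmap_sidecars[i], registry))
      }
      fm
    },
    check_context_volume_match(dataset$asl_series, dataset$context,
                               sidecar_get(dataset$asl_sidecar, "TotalAcquiredPairs"),
                               path = p$context),
    rule_context_mixing(dataset$context, p$context),
    check_m0_consistency(dataset),
    check_scaling_fields_absent(sidecars),
    check_pepolar_fieldmap(dataset)
  )
  if (strict && nrow(issues)) {
    promote <- issues$rule_id == "ASL102"
    issues$severity[promote] <- "ERROR"
  }
  validation_report(issues)
}
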