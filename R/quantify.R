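## Single-delay CBF quantification from sidecar metadata alone, using the
## standard single-compartment closed forms:
##   (P)CASL: CBF = 6000*lambda*dM*exp(PLD/T1b) /
##                  (2*alpha*T1b*M0*(1 - exp(-tau/T1b)))
##   PASL (QUIPSS-II): CBF = 6000*lambda*dM*exp(TI/T1b) / (2*alpha*TI1*M0)
## in mL/100g/min, with per-slice effective PLD for 2D readouts and
## field-strength-dependent default constants.

ASL_CONSTANTS <- list(
  `3` = list(t1_blood_s = 1.650, t1_tissue_s = 1.330),
  `1.5` = list(t1_blood_s = 1.350, t1_tissue_s = 1.100)
)

#' Quantification constants
#'
#' Default constants keyed by `MagneticFieldStrength`: blood T1 1.650 s at
#' 3 T and 1.350 s at 1.5 T, tissue T1 (used only for the M0
#' saturation-recovery correction) 1.330 s at 3 T and 1.100 s at 1.5 T,
#' brain-blood partition coefficient 0.9 mL/g, and labeling efficiency 0.85
#' for (P)CASL or 0.98 for PASL. A sidecar `LabelingEfficiency` overrides the
#' default alpha. Unknown field strengths raise an error rather than
#' interpolating silently.
#'
#' @param field_strength_t `MagneticFieldStrength` in tesla (3 or 1.5).
#' @param labeling_type `"PCASL"`, `"CASL"` or `"PASL"`.
#' @param labeling_efficiency Optional override for alpha in (0, 1].
#' @return An `asl_quant_params` list with `lambda_ml_per_g`, `t1_blood_s`,
#'   `t1_tissue_s`, `alpha`.
#' @export
quantification_params <- function(field_strength_t, labeling_type = "PCASL",
                                  labeling_efficiency = NULL) {
  key <- as.character(field_strength_t)
  if (!key %in% names(ASL_CONSTANTS))
    asl_abort("unsupported_scheme", sprintf(
      "no default constants for MagneticFieldStrength=%s T (known: %s)",
      key, paste(names(ASL_CONSTANTS), collapse = ", ")))
  if (!labeling_type %in% c("PCASL", "CASL", "PASL"))
    asl_abort("unsupported_scheme",
              sprintf("unknown labeling type '%s'", labeling_type))
  alpha <- labeling_efficiency %||%
    if (labeling_type == "PASL") 0.98 else 0.85
  if (!(is.numeric(alpha) && alpha > 0 && alpha <= 1))
    asl_abort("unsupported_scheme", "labeling efficiency must lie in (0, 1]")
  structure(list(lambda_ml_per_g = 0.9,
                 t1_blood_s = ASL_CONSTANTS[[key]]$t1_blood_s,
                 t1_tissue_s = ASL_CONSTANTS[[key]]$t1_tissue_s,
                 alpha = alpha),
            class = "asl_quant_params")
}

#' Mean perfusion-weighted difference image
#'
#' Forms control-label pairs in acquisition order (k-th control with k-th
#' label), computes the voxelwise difference of each pair, and returns the
#' mean over pairs. In-series m0scan volumes are excluded from pairing. For a
#' `deltam` series the mean of the deltam volumes is returned directly.
#'
#' @param series The ASL [image_series()].
#' @param context The matching [asl_context()].
#' @return 3D array: the mean control-minus-label difference.
#' @export
subtract_pairs <- function(series, context) {
  stacks <- pair_difference_stack(series, context)
  out <- stacks$deltam[[1]]
  if (length(stacks$deltam) > 1L)
    for (i in 2:length(stacks$deltam)) out <- out + stacks$deltam[[i]]
  out / length(stacks$deltam)
}

# Per-pair difference volumes plus the per-pair index into the series,
# used to group pairs by post-labeling delay for multi-PLD series.
pair_difference_stack <- function(series, context) {
  ctx <- unclass(context)
  if (length(ctx) != series$n_volumes)
    asl_abort("unpairable_context",
              "context length does not match the number of volumes")
  dm_idx <- which(ctx == "deltam")
  if (length(dm_idx)) {
    return(list(deltam = lapply(dm_idx, function(i) series_volume(series, i)),
                volume_index = dm_idx))
  }
  c_idx <- which(ctx == "control"); l_idx <- which(ctx == "label")
  if (length(c_idx) == 0L || length(c_idx) != length(l_idx))
    asl_abort("unpairable_context", sprintf(
      "cannot pair %d control with %d label volumes",
      length(c_idx), length(l_idx)))
  list(deltam = lapply(seq_along(c_idx), function(k)
         series_volume(series, c_idx[k]) - series_volume(series, l_idx[k])),
       volume_index = c_idx)
}

#' Resolve the calibration M0
#'
#' Dispatches on the declared `M0Type`. For `Separate` and `Included` the
#' m0scan volumes are averaged and divided by the saturation-recovery factor
#' `1 - exp(-RepetitionTimePreparation / T1_tissue)` to compensate incomplete
#' T1 relaxation. For `Estimate` the scalar `M0Estimate` is used uncorrected
#' (it is taken to be a calibrated blood M0). For `Absent` an error is raised
#' unless `control_fallback = TRUE`, in which case the mean control signal
#' stands in for M0 (a documented opt-in approximation; a message is
#' emitted).
#'
#' @param dataset A validated [asl_dataset()].
#' @param params [quantification_params()].
#' @param control_fallback Opt-in fallback for `M0Type=Absent`.
#' @return A 3D array, or a scalar for `M0Type=Estimate`.
#' @export
resolve_m0 <- function(dataset, params, control_fallback = FALSE) {
  m0type <- sidecar_get(dataset$asl_sidecar, "M0Type")
  if (is.null(m0type)) asl_abort("m0_unavailable", "M0Type is missing")
  sat_corrected_mean <- function(vols, tr_prep) {
    if (is.null(tr_prep))
      asl_abort("m0_unavailable",
                "RepetitionTimePreparation needed for M0 saturation correction")
    m <- vols[[1]]
    if (length(vols) > 1L) for (i in 2:length(vols)) m <- m + vols[[i]]
    m <- m / length(vols)
    m / (1 - exp(-tr_prep / params$t1_tissue_s))
  }
  if (m0type == "Separate") {
    if (is.null(dataset$m0_series))
      asl_abort("m0_unavailable", "M0Type=Separate but no m0scan image")
    vols <- lapply(seq_len(dataset$m0_series$n_volumes),
                   function(i) series_volume(dataset$m0_series, i))
    return(sat_corrected_mean(vols,
      sidecar_get(dataset$m0_sidecar, "RepetitionTimePreparation")))
  }
  if (m0type == "Included") {
    idx <- which(unclass(dataset$context) == "m0scan")
    if (!length(idx))
      asl_abort("m0_unavailable", "M0Type=Included but no m0scan row in context")
    vols <- lapply(idx, function(i) series_volume(dataset$asl_series, i))
    return(sat_corrected_mean(vols,
      sidecar_get(dataset$asl_sidecar, "RepetitionTimePreparation")))
  }
  if (m0type == "Estimate") {
    est <- sidecar_get(dataset$asl_sidecar, "M0Estimate")
    if (!(is.numeric(est) && length(est) == 1L && est > 0))
      asl_abort("m0_unavailable", "M0Type=Estimate without a valid M0Estimate")
    return(est)
  }
  if (m0type == "Absent") {
    if (!control_fallback)
      asl_abort("m0_unavailable",
                "M0Type=Absent: no calibration image (set control_fallback=TRUE to approximate M0 by the mean control signal)")
    message("aslbids: M0 absent; approximating M0 by the mean control signal")
    idx <- which(unclass(dataset$context) == "control")
    if (!length(idx)) asl_abort("m0_unavailable", "no control volumes either")
    vols <- lapply(idx, function(i) series_volume(dataset$asl_series, i))
    m <- vols[[1]]
    if (length(vols) > 1L) for (i in 2:length(vols)) m <- m + vols[[i]]
    return(m / length(vols))
  }
  asl_abort("m0_unavailable", sprintf("unknown M0Type '%s'", m0type))
}

#' Per-slice effective post-labeling delay
#'
#' For 2D multi-slice readouts each slice is acquired at a different time
#' after labeling, so the effective PLD of slice z is
#' `PostLabelingDelay + SliceTiming[z]`. For 3D readouts the whole volume is
#' excited at once and the PLD is constant across slices.
#'
#' @param asl_sidecar The ASL [sidecar_metadata()].
#' @param n_slices Number of slices (3rd spatial dimension).
#' @param pld The nominal PLD in seconds; defaults to the sidecar's scalar
#'   `PostLabelingDelay`.
#' @return Numeric vector of length `n_slices`.
#' @export
effective_pld <- function(asl_sidecar, n_slices, pld = NULL) {
  if (is.null(pld)) {
    pld <- sidecar_get(asl_sidecar, "PostLabelingDelay")
    if (is.null(pld) || length(pld) != 1L)
      asl_abort("missing_slice_timing",
                "pass `pld` explicitly for array-valued PostLabelingDelay")
  }
  acq <- sidecar_get(asl_sidecar, "MRAcquisitionType")
  if (identical(acq, "2D")) {
    st <- sidecar_get(asl_sidecar, "SliceTiming")
    if (is.null(st))
      asl_abort("missing_slice_timing",
                "2D acquisition requires SliceTiming for the effective PLD")
    if (length(st) != n_slices)
      asl_abort("missing_slice_timing", sprintf(
        "SliceTiming has %d entries for %d slices", length(st), n_slices))
    return(pld + st)
  }
  rep(pld, n_slices)
}

#' Quantify CBF from a difference image and an M0
#'
#' Applies the single-delay closed form (see the package vignette) with
#' per-slice effective PLD. The voxel mask keeps voxels whose M0 exceeds a
#' configurable fraction (default 10%) of the M0 robust maximum (99th
#' percentile); for a scalar M0 the mask is all-true. Values outside the mask
#' are set to `NA` explicitly rather than propagating silently.
#'
#' @param deltam 3D mean difference image from [subtract_pairs()].
#' @param m0 3D M0 map or scalar from [resolve_m0()].
#' @param asl_sidecar The ASL [sidecar_metadata()] supplying
#'   `ArterialSpinLabelingType`, `LabelingDuration` or
#'   `BolusCutOffDelayTime`, `MRAcquisitionType` and `SliceTiming`.
#' @param params [quantification_params()]; defaults are derived from the
#'   sidecar's `MagneticFieldStrength` and labeling type.
#' @param pld Nominal PLD in seconds; defaults to the sidecar scalar.
#' @param mask_fraction M0 mask threshold as a fraction of the robust max.
#' @return An `asl_cbf_map`: list with `values` (3D array, mL/100g/min) and
#'   `mask` (3D logical).
#' @export
quantify_cbf <- function(deltam, m0, asl_sidecar, params = NULL, pld = NULL,
                         mask_fraction = 0.1) {
  ltype <- sidecar_get(asl_sidecar, "ArterialSpinLabelingType")
  if (is.null(ltype) || !ltype %in% c("PCASL", "CASL", "PASL"))
    asl_abort("unsupported_scheme", "unknown or missing ArterialSpinLabelingType")
  if (isTRUE(sidecar_get(asl_sidecar, "LookLocker")))
    asl_abort("unsupported_scheme", "Look-Locker series are not quantified")
  if (is.null(params))
    params <- quantification_params(
      sidecar_get(asl_sidecar, "MagneticFieldStrength") %||%
        asl_abort("unsupported_scheme", "MagneticFieldStrength needed for defaults"),
      ltype, sidecar_get(asl_sidecar, "LabelingEfficiency"))
  d <- dim(deltam)
  pld_slice <- effective_pld(asl_sidecar, d[3L], pld)
  t1b <- params$t1_blood_s

  # per-slice scale applied to dM/M0
  if (ltype %in% c("PCASL", "CASL")) {
    tau <- sidecar_get(asl_sidecar, "LabelingDuration")
    if (is.null(tau))
      asl_abort("unsupported_scheme", "(P)CASL requires LabelingDuration")
    if (length(tau) != 1L) tau <- tau[1L]
    scale_z <- 6000 * params$lambda_ml_per_g * exp(pld_slice / t1b) /
      (2 * params$alpha * t1b * (1 - exp(-tau / t1b)))
  } else {
    if (!isTRUE(sidecar_get(asl_sidecar, "BolusCutOffFlag")))
      asl_abort("unsupported_scheme",
                "PASL without bolus cutoff (QUIPSS-II) cannot be quantified with the single-delay form")
    ti1 <- sidecar_get(asl_sidecar, "BolusCutOffDelayTime")
    if (is.null(ti1)) asl_abort("unsupported_scheme",
                                "PASL requires BolusCutOffDelayTime")
    ti1 <- ti1[1L]
    scale_z <- 6000 * params$lambda_ml_per_g * exp(pld_slice / t1b) /
      (2 * params$alpha * ti1)
  }

  ratio <- if (length(m0) == 1L) deltam / m0 else {
    if (!identical(dim(m0), d))
      asl_abort("m0_unavailable", "M0 map dimensions do not match the difference image")
    deltam / m0
  }
  values <- ratio * rep(scale_z, each = d[1L] * d[2L])
  mask <- if (length(m0) == 1L) array(TRUE, dim = d) else {
    thr <- mask_fraction * stats::quantile(m0, 0.99, names = FALSE)
    m0 > thr
  }
  values[!mask] <- NA_real_
  values[mask & !is.finite(values)] <- NA_real_
  structure(list(values = values, mask = mask), class = "asl_cbf_map")
}

#' Quantify a whole dataset
#'
#' The end-to-end demonstration that REQUIRED metadata suffice: validates the
#' dataset (zero ERROR required unless `force`), resolves M0, groups
#' control-label pairs by their post-labeling delay (multi-delay series give
#' one CBF map per delay; no kinetic-model fitting), and quantifies each
#' group. Provenance records every constant and sidecar field used.
#'
#' @param dataset An [asl_dataset()].
#' @param params Optional [quantification_params()] override.
#' @param force Quantify even when validation reports errors.
#' @param control_fallback Passed to [resolve_m0()].
#' @return An `asl_quant_result`: list with `cbf` (named list of
#'   `asl_cbf_map`, one per distinct PLD, names `pld-<seconds>`), `plds_s`,
#'   and `provenance`.
#' @export
quantify_dataset <- function(dataset, params = NULL, force = FALSE,
                             control_fallback = FALSE) {
  report <- validate_asl(dataset)
  if (!report$valid && !force)
    asl_abort("validation_failed",
              "dataset has validation errors; fix them or use force = TRUE",
              report = report)
  sc <- dataset$asl_sidecar
  ltype <- sidecar_get(sc, "ArterialSpinLabelingType")
  if (is.null(params))
    params <- quantification_params(sidecar_get(sc, "MagneticFieldStrength"),
                                    ltype, sidecar_get(sc, "LabelingEfficiency"))
  m0 <- resolve_m0(dataset, params, control_fallback = control_fallback)
  stacks <- pair_difference_stack(dataset$asl_series, dataset$context)
  pld <- sidecar_get(sc, "PostLabelingDelay")
  pair_pld <- if (length(pld) == 1L) rep(pld, length(stacks$deltam))
              else pld[stacks$volume_index]
  cbf <- list()
  for (p in unique(pair_pld)) {
    grp <- which(pair_pld == p)
    dm <- stacks$deltam[[grp[1L]]]
    if (length(grp) > 1L) for (i in grp[-1L]) dm <- dm + stacks$deltam[[i]]
    dm <- dm / length(grp)
    cbf[[sprintf("pld-%g", p)]] <-
      quantify_cbf(dm, m0, sc, params = params, pld = p)
  }
  structure(list(
    cbf = cbf, plds_s = unique(pair_pld),
    provenance = list(
      labeling_type = ltype,
      lambda_ml_per_g = params$lambda_ml_per_g,
      t1_blood_s = params$t1_blood_s,
      t1_tissue_s = params$t1_tissue_s,
      alpha = params$alpha,
      magnetic_field_strength_t = sidecar_get(sc, "MagneticFieldStrength"),
      labeling_duration_s = sidecar_get(sc, "LabelingDuration"),
      bolus_cutoff_delay_s = sidecar_get(sc, "BolusCutOffDelayTime"),
      post_labeling_delay_s = pld,
      slice_timing_s = sidecar_get(sc, "SliceTiming"),
      m0_type = sidecar_get(sc, "M0Type"),
      n_pairs = length(stacks$deltam)
    )), class = "asl_quant_result")
}

#' Write quantification output as a derivatives tree
#'
#' Writes one `_cbf.nii.gz` per post-labeling delay under
#' `derivatives/aslbids/sub-<label>/perf/` plus a JSON provenance sidecar
#' recording every constant and field used.
#'
#' @param result An `asl_quant_result` from [quantify_dataset()].
#' @param root Dataset root (derivatives are placed beside the raw data).
#' @param subject Subject label.
#' @return Character vector of written relative paths (invisibly).
#' @export
write_cbf_derivatives <- function(result, root, subject) {
  sub <- paste0("sub-", subject)
  outdir <- file.path(root, "derivatives", "aslbids", sub, "perf")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (nm in names(result$cbf)) {
    map <- result$cbf[[nm]]
    vals <- map$values
    vals[is.na(vals)] <- 0
    rel <- file.path("derivatives", "aslbids", sub, "perf",
                     sprintf("%s_%s_cbf.nii.gz", sub, nm))
    write_nifti_series(image_series(vals), file.path(root, rel))
    written <- c(written, rel)
  }
  prov <- file.path("derivatives", "aslbids", sub, "perf",
                    sprintf("%s_cbf.json", sub))
  writeLines(jsonlite::toJSON(result$provenance, auto_unbox = TRUE,
                              digits = NA, null = "null", pretty = TRUE),
             file.path(root, prov))
  invisible(c(written, prov))
}
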