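## Synthetic ASL-BIDS generator. Builds valid-by-construction datasets with
## known ground-truth perfusion by inverting the quantifier's closed forms,
## emulating the five public example configurations (GE/Philips/Siemens
## single- and multi-delay PCASL/PASL, 2D and 3D readouts, separate or
## in-series M0, PEPolar fieldmap). No MR physics beyond the signal model is
## emulated: the generator exists to exercise format and quantification
## logic, not realism.

BS_SUPPRESSION_FACTOR <- 0.1  # static-signal attenuation when background suppression is on

#' Synthetic acquisition plan
#'
#' The configuration consumed by [synthesize_dataset()]. Invariants: (P)CASL
#' plans carry a labeling duration, PASL plans a bolus cutoff delay, 2D plans
#' a slice-timing vector of one nonnegative entry per slice, and
#' `deltam_only` plans a single delay.
#'
#' @param name Plan name (used as the dataset name).
#' @param labeling_type `"PCASL"` or `"PASL"`.
#' @param plds_s Post-labeling delays in seconds (one or more).
#' @param labeling_duration_s Labeling duration tau (s), (P)CASL only.
#' @param bolus_cutoff_delay_s QUIPSS-II bolus cutoff TI1 (s), PASL only.
#' @param readout `"2D"` or `"3D"`.
#' @param slice_timing_s Per-slice acquisition offsets (s), 2D only.
#' @param n_pairs Number of control-label pairs (`TotalAcquiredPairs`).
#' @param m0_mode `"Separate"`, `"Included"`, `"Estimate"` or `"Absent"`.
#' @param background_suppression,n_bs_pulses Background suppression flag and
#'   pulse count.
#' @param pepolar_fieldmap Add a reversed phase-encoding m0scan in `fmap/`?
#' @param deltam_only Store precomputed difference volumes instead of
#'   control/label pairs (GE-style averaged export)?
#' @param labeling_screenshot Write a `*_asllabeling.jpg` screenshot?
#' @param grid Image grid `c(nx, ny, nz)`.
#' @param voxel_size_mm Voxel size (mm).
#' @param field_strength_t `MagneticFieldStrength` (tesla).
#' @param echo_time_s,flip_angle_deg,tr_prep_s,tr_prep_m0_s Readout timing
#'   metadata (seconds / degrees).
#' @param noise_sd Standard deviation of additive zero-mean Gaussian noise.
#' @param seed RNG seed for the noise.
#' @return An `asl_acquisition_plan`.
#' @export
acquisition_plan <- function(name, labeling_type, plds_s,
                             labeling_duration_s = NULL,
                             bolus_cutoff_delay_s = NULL,
                             readout = "3D", slice_timing_s = NULL,
                             n_pairs = 10L, m0_mode = "Separate",
                             background_suppression = TRUE, n_bs_pulses = 2L,
                             pepolar_fieldmap = FALSE, deltam_only = FALSE,
                             labeling_screenshot = FALSE,
                             grid = c(16L, 16L, 5L),
                             voxel_size_mm = c(3.5, 3.5, 5),
                             field_strength_t = 3,
                             echo_time_s = 0.012, flip_angle_deg = 90,
                             tr_prep_s = 4.5, tr_prep_m0_s = 4.5,
                             noise_sd = 0, seed = 101L) {
  bad <- function(msg) asl_abort("invalid_plan", sprintf("plan '%s': %s", name, msg))
  if (!labeling_type %in% c("PCASL", "PASL")) bad("labeling_type must be PCASL or PASL")
  if (!is.numeric(plds_s) || length(plds_s) < 1L || any(plds_s < 0))
    bad("plds_s must be nonnegative")
  if (labeling_type == "PCASL" && is.null(labeling_duration_s))
    bad("PCASL needs labeling_duration_s")
  if (labeling_type == "PASL" && is.null(bolus_cutoff_delay_s))
    bad("PASL needs bolus_cutoff_delay_s")
  if (!readout %in% c("2D", "3D")) bad("readout must be 2D or 3D")
  if (readout == "2D") {
    if (is.null(slice_timing_s) || length(slice_timing_s) != grid[3L])
      bad("2D plans need slice_timing_s of length nz")
    if (any(slice_timing_s < 0) || anyDuplicated(slice_timing_s))
      bad("slice_timing_s must be nonnegative and distinct")
  }
  if (!m0_mode %in% c("Separate", "Included", "Estimate", "Absent"))
    bad("unknown m0_mode")
  if (deltam_only && length(plds_s) != 1L)
    bad("deltam_only plans must have a single delay")
  if (n_pairs < 1L) bad("n_pairs must be >= 1")
  if (length(plds_s) > 1L && n_pairs %% length(plds_s) != 0L)
    bad("n_pairs must be a multiple of the number of delays")
  structure(as.list(environment())[c(
    "name", "labeling_type", "plds_s", "labeling_duration_s",
    "bolus_cutoff_delay_s", "readout", "slice_timing_s", "n_pairs",
    "m0_mode", "background_suppression", "n_bs_pulses", "pepolar_fieldmap",
    "deltam_only", "labeling_screenshot", "grid", "voxel_size_mm",
    "field_strength_t", "echo_time_s", "flip_angle_deg", "tr_prep_s",
    "tr_prep_m0_s", "noise_sd", "seed")],
    class = "asl_acquisition_plan")
}

#' Plans emulating the five public example configurations
#'
#' Returns the acquisition plan matching one of the five freely accessible
#' example datasets: `asl001` (GE 3 T, single-delay PCASL, segmented 3D
#' spiral, four background-suppression pulses, averaged `deltam` plus
#' in-series `m0scan`), `asl002` (Philips 3 T, single-delay PCASL, 2D-EPI,
#' two pulses, separate `m0scan`), `asl003` (Siemens 3 T, multi-delay PASL,
#' segmented 3D GRASE, two pulses, separate `m0scan`), `asl004` (Siemens
#' 3 T, custom multi-delay PCASL, 2D-EPI, two pulses, in-series `m0scan`
#' plus a reversed phase-encoding `m0scan` in `fmap/`), `asl005` (Siemens
#' 3 T, single-delay PCASL, segmented 3D GRASE, four pulses, in-series
#' `m0scan`). Sequence timings not fixed by the configurations (delays,
#' durations) use consensus-typical product defaults.
#'
#' @param name One of `"asl001"` ... `"asl005"`.
#' @param grid Image grid.
#' @param noise_sd Additive noise SD (default 0: noiseless phantom).
#' @param seed RNG seed; defaults to a per-example constant.
#' @return An [acquisition_plan()].
#' @export
example_plan <- function(name, grid = c(16L, 16L, 5L), noise_sd = 0,
                         seed = NULL) {
  st2d <- function(nz) 0.04 * (seq_len(nz) - 1)
  plans <- list(
    asl001 = function() acquisition_plan(
      "asl001", "PCASL", plds_s = 1.525, labeling_duration_s = 1.45,
      readout = "3D", n_pairs = 3L, m0_mode = "Included",
      n_bs_pulses = 4L, deltam_only = TRUE, grid = grid,
      voxel_size_mm = c(3.75, 3.75, 4), noise_sd = noise_sd,
      seed = seed %||% 101L),
    asl002 = function() acquisition_plan(
      "asl002", "PCASL", plds_s = 1.8, labeling_duration_s = 1.65,
      readout = "2D", slice_timing_s = st2d(grid[3L]), n_pairs = 10L,
      m0_mode = "Separate", n_bs_pulses = 2L, labeling_screenshot = TRUE,
      grid = grid, voxel_size_mm = c(3, 3, 6), noise_sd = noise_sd,
      seed = seed %||% 102L),
    asl003 = function() acquisition_plan(
      "asl003", "PASL", plds_s = c(1.0, 1.5, 2.0, 2.5),
      bolus_cutoff_delay_s = 0.7, readout = "3D", n_pairs = 8L,
      m0_mode = "Separate", n_bs_pulses = 2L, grid = grid,
      voxel_size_mm = c(3.4, 3.4, 4), noise_sd = noise_sd,
      seed = seed %||% 103L),
    asl004 = function() acquisition_plan(
      "asl004", "PCASL", plds_s = c(1.0, 1.5, 2.0, 2.5),
      labeling_duration_s = 1.4, readout = "2D",
      slice_timing_s = st2d(grid[3L]), n_pairs = 8L, m0_mode = "Included",
      n_bs_pulses = 2L, pepolar_fieldmap = TRUE, grid = grid,
      voxel_size_mm = c(3.4, 3.4, 4), noise_sd = noise_sd,
      seed = seed %||% 104L),
    asl005 = function() acquisition_plan(
      "asl005", "PCASL", plds_s = 2.0, labeling_duration_s = 1.8,
      readout = "3D", n_pairs = 10L, m0_mode = "Included",
      n_bs_pulses = 4L, grid = grid, voxel_size_mm = c(3.4, 3.4, 4),
      noise_sd = noise_sd, seed = seed %||% 105L)
  )
  if (!name %in% names(plans))
    asl_abort("unknown_example", sprintf(
      "unknown example '%s' (known: %s)", name,
      paste(names(plans), collapse = ", ")))
  plans[[name]]()
}

#' Two-compartment ground-truth phantom
#'
#' A conventional-physiology test phantom: an inner "gray matter" block at
#' CBF 60, an outer "white matter" shell at CBF 20 (mL/100g/min), and zero
#' background; equilibrium magnetization 1000 (GM) / 900 (WM) arbitrary
#' signal units inside the brain. With `flat_m0 = TRUE` the whole brain gets
#' M0 1000, which a scalar `M0Estimate` can represent exactly.
#'
#' @param grid `c(nx, ny, nz)`.
#' @param flat_m0 Use a spatially constant in-brain M0.
#' @param field_strength_t Field strength for the embedded constants.
#' @param labeling_type Labeling scheme for the embedded alpha.
#' @return An `asl_ground_truth`: `cbf_true`, `m0_true`, `alpha`,
#'   `t1_blood_s`, `lambda_ml_per_g`.
#' @export
default_ground_truth <- function(grid = c(16L, 16L, 5L), flat_m0 = FALSE,
                                 field_strength_t = 3,
                                 labeling_type = "PCASL") {
  nx <- grid[1L]; ny <- grid[2L]; nz <- grid[3L]
  if (nx < 8L || ny < 8L)
    asl_abort("invalid_plan", "phantom grid must be at least 8x8 in plane")
  mx <- max(1L, round(nx / 8)); my <- max(1L, round(ny / 8))
  gx <- max(mx + 1L, round(nx / 4)); gy <- max(my + 1L, round(ny / 4))
  brain <- array(FALSE, dim = grid)
  brain[(mx + 1):(nx - mx), (my + 1):(ny - my), ] <- TRUE
  gm <- array(FALSE, dim = grid)
  zi <- if (nz >= 3L) 2:(nz - 1L) else seq_len(nz)
  gm[(gx + 1):(nx - gx), (gy + 1):(ny - gy), zi] <- TRUE
  cbf <- array(0, dim = grid)
  cbf[brain] <- 20; cbf[gm] <- 60
  m0 <- array(0, dim = grid)
  m0[brain] <- if (flat_m0) 1000 else 900
  if (!flat_m0) m0[gm] <- 1000
  params <- quantification_params(field_strength_t, labeling_type)
  structure(list(cbf_true = cbf, m0_true = m0, alpha = params$alpha,
                 t1_blood_s = params$t1_blood_s,
                 lambda_ml_per_g = params$lambda_ml_per_g),
            class = "asl_ground_truth")
}

# Per-slice CBF->(dM/M0) scale of the single-delay closed forms; identical
# algebra to quantify_cbf so the forward model is its exact inverse.
forward_scale <- function(plan, params, pld) {
  nz <- plan$grid[3L]
  pld_slice <- if (plan$readout == "2D") pld + plan$slice_timing_s else rep(pld, nz)
  t1b <- params$t1_blood_s
  if (plan$labeling_type == "PCASL")
    6000 * params$lambda_ml_per_g * exp(pld_slice / t1b) /
      (2 * params$alpha * t1b * (1 - exp(-plan$labeling_duration_s / t1b)))
  else
    6000 * params$lambda_ml_per_g * exp(pld_slice / t1b) /
      (2 * params$alpha * plan$bolus_cutoff_delay_s)
}

#' Synthesize a dataset with known ground truth
#'
#' Builds the forward signal model: the stored m0scan is the ground-truth M0
#' attenuated by the saturation-recovery factor for its
#' `RepetitionTimePreparation` (which [resolve_m0()] undoes); the control
#' signal is the static baseline attenuated by background suppression; the
#' label signal is control minus the difference signal obtained by inverting
#' the single-delay quantification form at each delay (per-slice effective
#' delay for 2D readouts). Volumes are stored in acquisition order with
#' in-series m0scan rows first, `TotalAcquiredPairs` matches the pair count,
#' and sidecars are populated so that [validate_asl()] reports zero errors.
#' Additive zero-mean Gaussian noise (`plan$noise_sd`, `plan$seed`) makes
#' replicates; the same plan and seed give identical output.
#'
#' @param plan An [acquisition_plan()].
#' @param ground_truth Optional [default_ground_truth()] override (its grid
#'   must match the plan's).
#' @return List with `dataset` (an [asl_dataset()]) and `truth`.
#' @export
synthesize_dataset <- function(plan, ground_truth = NULL) {
  stopifnot(inherits(plan, "asl_acquisition_plan"))
  params <- quantification_params(plan$field_strength_t, plan$labeling_type)
  truth <- ground_truth %||%
    default_ground_truth(plan$grid, flat_m0 = plan$m0_mode == "Estimate",
                         field_strength_t = plan$field_strength_t,
                         labeling_type = plan$labeling_type)
  if (!identical(dim(truth$cbf_true), as.integer(plan$grid)) &&
      !identical(dim(truth$cbf_true), plan$grid))
    asl_abort("invalid_plan", "ground truth grid does not match the plan grid")
  grid <- dim(truth$cbf_true)
  nvox <- prod(grid)

  m0_resolved <- if (plan$m0_mode == "Estimate") 1000 else truth$m0_true
  bs_factor <- if (plan$background_suppression) BS_SUPPRESSION_FACTOR else 1
  control_vol <- bs_factor * truth$m0_true
  n_plds <- length(plan$plds_s)
  pair_pld <- plan$plds_s[((seq_len(plan$n_pairs) - 1L) %% n_plds) + 1L]
  deltam_for <- function(pld) {
    sc <- forward_scale(plan, params, pld)
    truth$cbf_true * m0_resolved / rep(sc, each = grid[1L] * grid[2L])
  }

  volumes <- list(); ctx <- character()
  add <- function(vol, type) {
    volumes[[length(volumes) + 1L]] <<- vol
    ctx <<- c(ctx, type)
  }
  m0_stored <- truth$m0_true *
    (1 - exp(-(if (plan$m0_mode == "Included") plan$tr_prep_s else plan$tr_prep_m0_s) /
               params$t1_tissue_s))
  if (plan$m0_mode == "Included") add(m0_stored, "m0scan")
  if (plan$deltam_only) {
    add(deltam_for(plan$plds_s[1L]), "deltam")
  } else {
    for (k in seq_len(plan$n_pairs)) {
      dm <- deltam_for(pair_pld[k])
      add(control_vol, "control")
      add(control_vol - dm, "label")
    }
  }
  n_vol <- length(volumes)
  vox <- array(0, dim = c(grid, n_vol))
  for (i in seq_len(n_vol)) vox[, , , i] <- volumes[[i]]
  if (plan$noise_sd > 0)
    vox <- with_seed(plan$seed,
                     vox + array(stats::rnorm(nvox * n_vol, sd = plan$noise_sd),
                                 dim = c(grid, n_vol)))

  ped_main <- if (plan$pepolar_fieldmap || plan$readout == "2D") "j-" else NULL
  single_pld <- n_plds == 1L
  pld_entry <- if (single_pld) plan$plds_s else {
    per_vol <- numeric(n_vol)
    asl_rows <- which(ctx != "m0scan")
    per_vol[asl_rows] <- rep(pair_pld, each = if (plan$deltam_only) 1L else 2L)
    per_vol
  }
  bs_times <- round(seq(0.4, by = 0.4, length.out = plan$n_bs_pulses), 6)

  asl_entries <- list(
    ArterialSpinLabelingType = plan$labeling_type,
    PostLabelingDelay = pld_entry,
    BackgroundSuppression = plan$background_suppression,
    M0Type = plan$m0_mode,
    TotalAcquiredPairs = plan$n_pairs,
    MagneticFieldStrength = plan$field_strength_t,
    MRAcquisitionType = plan$readout,
    EchoTime = plan$echo_time_s,
    FlipAngle = plan$flip_angle_deg,
    RepetitionTimePreparation = plan$tr_prep_s,
    AcquisitionVoxelSize = plan$voxel_size_mm
  )
  if (plan$labeling_type == "PCASL") {
    asl_entries$LabelingDuration <- plan$labeling_duration_s
  } else {
    asl_entries$BolusCutOffFlag <- TRUE
    asl_entries$BolusCutOffDelayTime <- plan$bolus_cutoff_delay_s
    asl_entries$BolusCutOffTechnique <- "Q2TIPS"
  }
  if (plan$readout == "2D") asl_entries$SliceTiming <- plan$slice_timing_s
  if (plan$background_suppression) {
    asl_entries$BackgroundSuppressionNumberPulses <- plan$n_bs_pulses
    asl_entries$BackgroundSuppressionPulseTime <- bs_times
  }
  if (plan$m0_mode == "Estimate") asl_entries$M0Estimate <- 1000
  if (!is.null(ped_main)) asl_entries$PhaseEncodingDirection <- ped_main
  if (plan$labeling_screenshot)
    asl_entries$LabelingLocationDescription <-
      "Labeling plane 90 mm below ACPC, perpendicular to the carotid arteries"

  m0_series <- m0_sidecar <- NULL
  if (plan$m0_mode == "Separate") {
    m0_series <- image_series(m0_stored, voxel_size_mm = plan$voxel_size_mm)
    m0_entries <- list(
      EchoTime = plan$echo_time_s,
      FlipAngle = plan$flip_angle_deg,
      RepetitionTimePreparation = plan$tr_prep_m0_s,
      IntendedFor = "perf/sub-01_asl.nii.gz",
      AcquisitionVoxelSize = plan$voxel_size_mm)
    if (!is.null(ped_main)) m0_entries$PhaseEncodingDirection <- ped_main
    m0_sidecar <- sidecar_metadata("m0scan", m0_entries)
  }

  fieldmap_entries <- list()
  if (plan$pepolar_fieldmap) {
    target <- if (plan$m0_mode == "Separate") "perf/sub-01_m0scan.nii.gz"
              else "perf/sub-01_asl.nii.gz"
    fieldmap_entries <- list(list(
      series = image_series(m0_stored, voxel_size_mm = plan$voxel_size_mm),
      sidecar = sidecar_metadata("fieldmap", list(
        PhaseEncodingDirection = "j",
        IntendedFor = target,
        EchoTime = plan$echo_time_s)),
      direction = "PA"))
  }

  dataset <- asl_dataset(
    subject = "01",
    asl_series = image_series(vox, voxel_size_mm = plan$voxel_size_mm),
    asl_sidecar = sidecar_metadata("asl", asl_entries),
    context = asl_context(ctx),
    m0_series = m0_series, m0_sidecar = m0_sidecar,
    fieldmap_entries = fieldmap_entries,
    labeling_screenshot_present = plan$labeling_screenshot,
    readme_present = TRUE)
  list(dataset = dataset, truth = truth)
}

#' A random valid plan (for property sweeps)
#'
#' Draws labeling scheme, readout, delays, M0 mode and pair count from the
#' space the toolkit supports; the result always synthesizes to a dataset
#' with zero validation errors.
#'
#' @param seed RNG seed driving the draw (also becomes the plan's noise seed).
#' @return An [acquisition_plan()].
#' @export
random_plan <- function(seed) {
  with_seed(seed, {
    labeling <- sample(c("PCASL", "PASL"), 1L)
    readout <- sample(c("2D", "3D"), 1L)
    n_plds <- sample(1:3, 1L)
    plds <- round(sort(stats::runif(n_plds, 1.0, 2.5)), 3)
    n_pairs <- n_plds * sample(1:3, 1L)
    m0_mode <- sample(c("Separate", "Included", "Estimate", "Absent"), 1L,
                      prob = c(0.4, 0.4, 0.1, 0.1))
    nz <- 5L
    acquisition_plan(
      name = sprintf("random%04d", seed %% 10000L),
      labeling_type = labeling, plds_s = plds,
      labeling_duration_s = if (labeling == "PCASL") round(stats::runif(1, 1.2, 1.8), 3),
      bolus_cutoff_delay_s = if (labeling == "PASL") 0.7,
      readout = readout,
      slice_timing_s = if (readout == "2D") 0.04 * (seq_len(nz) - 1),
      n_pairs = n_pairs, m0_mode = m0_mode,
      background_suppression = sample(c(TRUE, FALSE), 1L),
      n_bs_pulses = sample(2:4, 1L),
      pepolar_fieldmap = m0_mode %in% c("Separate", "Included") &&
        stats::runif(1) < 0.3,
      noise_sd = sample(c(0, 0.01), 1L),
      seed = seed)
  })
}

#' Inject a single catalogued defect
#'
#' Returns a deep copy of the dataset with exactly one defect, for testing
#' that the validator pinpoints it. Catalogue (violation id -> rule ids the
#' validator must raise, see [violation_catalogue()]):
#' `delete-field:<name>` (optionally `delete-field:<role>:<name>`) removes a
#' sidecar field; `truncate-context` drops the last context row;
#' `wrong-m0type` flips `M0Type` to contradict the stored M0;
#' `scaling-key` adds a forbidden `RescaleSlope`; `break-pepolar` makes the
#' fieldmap polarity equal to its target's; `shuffle-context` relabels one
#' `label` row as `control` (a pure permutation of balanced rows is
#' undetectable without ground truth, so the catalogued context defect is a
#' relabeling that the control/label balance rule catches).
#'
#' @param dataset An [asl_dataset()].
#' @param violation_id A catalogue identifier.
#' @return The mutated [asl_dataset()].
#' @export
mutate_dataset <- function(dataset, violation_id) {
  stopifnot(inherits(dataset, "asl_dataset"))
  d <- dataset  # lists copy on modify
  drop_entry <- function(sidecar, name) {
    sidecar$entries[[name]] <- NULL
    sidecar
  }
  if (grepl("^delete-field:", violation_id)) {
    parts <- strsplit(violation_id, ":", fixed = TRUE)[[1]][-1]
    role <- if (length(parts) == 2L) parts[1L] else NA
    name <- parts[length(parts)]
    if ((is.na(role) || role == "asl") &&
        !is.null(sidecar_get(d$asl_sidecar, name))) {
      d$asl_sidecar <- drop_entry(d$asl_sidecar, name)
    } else if ((is.na(role) || role == "m0scan") &&
               !is.null(sidecar_get(d$m0_sidecar, name))) {
      d$m0_sidecar <- drop_entry(d$m0_sidecar, name)
    } else if ((is.na(role) || role == "fieldmap") &&
               length(d$fieldmap_entries) &&
               !is.null(sidecar_get(d$fieldmap_entries[[1L]]$sidecar, name))) {
      d$fieldmap_entries[[1L]]$sidecar <-
        drop_entry(d$fieldmap_entries[[1L]]$sidecar, name)
    } else {
      asl_abort("unknown_violation",
                sprintf("field '%s' not present; nothing to delete", name))
    }
    return(d)
  }
  switch(violation_id,
    "truncate-context" = {
      ctx <- unclass(d$context)
      d$context <- asl_context(ctx[-length(ctx)])
      d
    },
    "wrong-m0type" = {
      cur <- sidecar_get(d$asl_sidecar, "M0Type")
      d$asl_sidecar$entries$M0Type <-
        if (identical(cur, "Separate")) "Included" else "Separate"
      d
    },
    "scaling-key" = {
      d$asl_sidecar$entries$RescaleSlope <- 1.6
      d
    },
    "break-pepolar" = {
      if (!length(d$fieldmap_entries))
        asl_abort("unknown_violation", "dataset has no fieldmap entry to break")
      fe <- d$fieldmap_entries[[1L]]
      ped <- sidecar_get(fe$sidecar, "PhaseEncodingDirection")
      flipped <- if (grepl("-$", ped)) ped else paste0(ped, "-")
      d$fieldmap_entries[[1L]]$sidecar$entries$PhaseEncodingDirection <- flipped
      d
    },
    "shuffle-context" = {
      ctx <- unclass(d$context)
      i <- which(ctx == "label")[1L]
      if (is.na(i))
        asl_abort("unknown_violation", "no label row to relabel")
      ctx[i] <- "control"
      d$context <- asl_context(ctx)
      d
    },
    asl_abort("unknown_violation", sprintf("unknown violation '%s'", violation_id))
  )
}

#' Published violation -> rule mapping
#'
#' For each catalogued mutation: the rule ids of which at least one must be
#' raised (`expected`), and the full set of rule ids the defect may
#' legitimately imply (`allowed`) - a truncated context, for instance, can
#' also unbalance control/label rows.
#'
#' @return Data frame with columns `violation_id`, `expected`, `allowed`
#'   (comma-separated rule ids).
#' @export
violation_catalogue <- function() {
  data.frame(
    violation_id = c("delete-field:<name>", "truncate-context", "wrong-m0type",
                     "scaling-key", "break-pepolar", "shuffle-context"),
    expected = c("ASL101", "ASL201", "ASL301,ASL302,ASL305",
                 "ASL501", "ASL603", "ASL202"),
    allowed = c("ASL101", "ASL201,ASL202,ASL203", "ASL301,ASL302,ASL305",
                "ASL501", "ASL603", "ASL202,ASL203"),
    stringsAsFactors = FALSE
  )
}
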