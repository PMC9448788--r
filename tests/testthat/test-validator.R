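test_that("all five example fixtures validate with zero errors", {
  for (nm in example_names) {
    report <- validate_asl(fixture(nm)$dataset)
    expect_true(report$valid, info = nm)
    expect_equal(n_errors(report), 0L, info = nm)
  }
})

test_that("a deleted REQUIRED field yields exactly one error naming it", {
  d <- fixture("asl005")$dataset
  mutated <- mutate_dataset(d, "delete-field:M0Type")
  report <- validate_asl(mutated)
  errs <- report$issues[report$issues$severity == "ERROR", ]
  expect_equal(nrow(errs), 1L)
  expect_equal(errs$field, "M0Type")
  expect_equal(errs$rule_id, "ASL101")
})

test_that("missing RECOMMENDED fields warn without invalidating", {
  d <- mutate_dataset(fixture("asl002")$dataset,
                      "delete-field:AcquisitionVoxelSize")
  report <- validate_asl(d)
  expect_true(report$valid)
  warn <- report$issues[report$issues$severity == "WARNING", ]
  expect_true("AcquisitionVoxelSize" %in% warn$field)
  # strict mode promotes the omission to an error
  expect_false(validate_asl(d, strict = TRUE)$valid)
})

test_that("severity never exceeds the ladder: no ERROR for non-REQUIRED omissions", {
  d <- fixture("asl002")$dataset
  for (spec in applicable_fields("asl", d$asl_sidecar$entries)) {
    if (spec$requirement == "REQUIRED") next
    if (is.null(d$asl_sidecar$entries[[spec$name]])) next
    m <- mutate_dataset(d, paste0("delete-field:asl:", spec$name))
    report <- validate_asl(m)
    expect_equal(n_errors(report), 0L, info = spec$name)
  }
})

test_that("context/volume consistency rules fire as specified", {
  mk <- function(nvol, ctx, pairs = NULL)
    check_context_volume_match(
      image_series(array(1, dim = c(2, 2, 2, nvol))),
      asl_context(ctx), total_acquired_pairs = pairs)

  ok <- mk(10, rep(c("control", "label"), 5), pairs = 5)
  expect_equal(nrow(ok), 0L)

  short <- mk(10, rep(c("control", "label"), 4))
  expect_true("ASL201" %in% short$rule_id)

  unbal <- mk(3, c("control", "control", "label"))
  expect_true("ASL202" %in% unbal$rule_id)
  expect_equal(unbal$severity[unbal$rule_id == "ASL202"], "ERROR")

  few <- mk(10, rep(c("control", "label"), 5), pairs = 40)
  expect_equal(few$rule_id, "ASL203")
  expect_equal(few$severity, "WARNING")
})

test_that("deltam volumes must not mix with control/label", {
  d <- fixture("asl001")$dataset  # deltam + m0scan series
  expect_true(validate_asl(d)$valid)
  ctx <- unclass(d$context)
  d$context <- asl_context(c(ctx, "control"))
  report <- validate_asl(d)
  expect_true("ASL204" %in% error_rules(report))
})

test_that("M0 declaration must match the stored M0 information", {
  # Separate with a separate file: clean
  d2 <- fixture("asl002")$dataset
  expect_equal(nrow(check_m0_consistency(d2)), 0L)

  # Included claimed but no m0scan rows
  d5 <- fixture("asl005")$dataset
  ctx <- unclass(d5$context)
  keep <- ctx != "m0scan"
  broken <- d5
  broken$context <- asl_context(ctx[keep])
  broken$asl_series <- image_series(
    d5$asl_series$voxels[, , , keep, drop = FALSE],
    voxel_size_mm = d5$asl_series$voxel_size_mm)
  expect_true("ASL302" %in% check_m0_consistency(broken)$rule_id)

  # Estimate requires a positive scalar and recommends a README
  est <- d2
  est$m0_series <- NULL; est$m0_sidecar <- NULL
  est$asl_sidecar$entries$M0Type <- "Estimate"
  est$asl_sidecar$entries$M0Estimate <- 1200
  out <- check_m0_consistency(est)
  expect_false("ASL303" %in% out$rule_id)
  est$readme_present <- FALSE
  expect_true("ASL304" %in% check_m0_consistency(est)$rule_id)
  est$asl_sidecar$entries$M0Estimate <- -5
  expect_true("ASL303" %in% check_m0_consistency(est)$rule_id)

  # Absent forbids any M0 information
  absent <- d2
  absent$asl_sidecar$entries$M0Type <- "Absent"
  expect_true("ASL305" %in% check_m0_consistency(absent)$rule_id)
})

test_that("conditional requirements and structural lengths are enforced", {
  reg <- build_field_registry()
  base <- list(ArterialSpinLabelingType = "PCASL", PostLabelingDelay = 1.8,
               LabelingDuration = 1.8, BackgroundSuppression = FALSE,
               M0Type = "Absent", TotalAcquiredPairs = 5,
               MagneticFieldStrength = 3, EchoTime = 0.012, FlipAngle = 90,
               RepetitionTimePreparation = 4.2)

  # 2D without SliceTiming
  sc <- sidecar_metadata("asl", c(base, list(MRAcquisitionType = "2D")))
  out <- check_conditional_requirements(sc, n_slices = 5, n_volumes = 10)
  expect_true(any(out$rule_id == "ASL101" & out$field == "SliceTiming" &
                    out$severity == "ERROR"))

  # SliceTiming length must equal the slice count
  sc <- sidecar_metadata("asl", c(base, list(MRAcquisitionType = "2D",
                                             SliceTiming = c(0, 0.04, 0.08))))
  out <- check_conditional_requirements(sc, n_slices = 5, n_volumes = 10)
  expect_true("ASL401" %in% out$rule_id)

  # PCASL without LabelingDuration
  sc <- sidecar_metadata("asl", c(base[names(base) != "LabelingDuration"],
                                  list(MRAcquisitionType = "3D")))
  out <- check_conditional_requirements(sc, n_slices = 5, n_volumes = 10)
  expect_true(any(out$field == "LabelingDuration" & out$severity == "ERROR"))

  # PASL ladder: flag, then delay/technique when the flag is true
  pasl <- base[!names(base) %in% c("LabelingDuration")]
  pasl$ArterialSpinLabelingType <- "PASL"
  sc <- sidecar_metadata("asl", c(pasl, list(MRAcquisitionType = "3D")))
  out <- check_conditional_requirements(sc, 5, 10)
  expect_true(any(out$field == "BolusCutOffFlag" & out$severity == "ERROR"))
  sc <- sidecar_metadata("asl", c(pasl, list(MRAcquisitionType = "3D",
                                             BolusCutOffFlag = TRUE)))
  out <- check_conditional_requirements(sc, 5, 10)
  expect_true(any(out$field == "BolusCutOffDelayTime" & out$severity == "ERROR"))
  sc <- sidecar_metadata("asl", c(pasl, list(
    MRAcquisitionType = "3D", BolusCutOffFlag = TRUE,
    BolusCutOffDelayTime = 0.7, BolusCutOffTechnique = "Q2TIPS")))
  out <- check_conditional_requirements(sc, 5, 10)
  expect_equal(sum(out$severity == "ERROR"), 0L)

  # array PLD must have one entry per volume
  arr <- base
  arr$PostLabelingDelay <- c(1, 1.5, 2)
  sc <- sidecar_metadata("asl", c(arr, list(MRAcquisitionType = "3D")))
  out <- check_conditional_requirements(sc, 5, 10)
  expect_true("ASL402" %in% out$rule_id)

  # MagneticFieldStrength is REQUIRED (selects default constants)
  sc <- sidecar_metadata("asl", c(base[names(base) != "MagneticFieldStrength"],
                                  list(MRAcquisitionType = "3D")))
  out <- check_conditional_requirements(sc, 5, 10)
  expect_true(any(out$field == "MagneticFieldStrength" & out$severity == "ERROR"))
})

test_that("implausible values warn (milliseconds suspicion)", {
  sc <- sidecar_metadata("asl", list(PostLabelingDelay = 1800))
  out <- check_conditional_requirements(sc, 5, 10)
  hit <- out[out$field == "PostLabelingDelay" & out$rule_id == "ASL104", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$severity, "WARNING")
  expect_match(hit$message, "milliseconds")

  sc <- sidecar_metadata("asl", list(FlipAngle = 270))
  out <- check_conditional_requirements(sc, 5, 10)
  expect_true(any(out$field == "FlipAngle" & out$rule_id == "ASL104"))
})

test_that("scaling metadata is forbidden anywhere, attributed per file", {
  clean <- sidecar_metadata("asl", list(EchoTime = 0.012))
  expect_equal(nrow(check_scaling_fields_absent(list(a = clean))), 0L)

  dirty <- sidecar_metadata("asl", list(RescaleSlope = 1.6))
  out <- check_scaling_fields_absent(
    list("perf/sub-01_asl.json" = clean, "perf/sub-01_m0scan.json" = dirty))
  expect_equal(nrow(out), 1L)
  expect_equal(out$path, "perf/sub-01_m0scan.json")
  expect_equal(out$rule_id, "ASL501")
  expect_equal(out$severity, "ERROR")

  d <- mutate_dataset(fixture("asl002")$dataset, "scaling-key")
  expect_true("ASL501" %in% error_rules(validate_asl(d)))
})

test_that("PEPolar linkage demands a resolvable target and opposite polarity", {
  d <- fixture("asl004")$dataset
  expect_equal(nrow(check_pepolar_fieldmap(d)), 0L)

  # same polarity on both sides
  broken <- mutate_dataset(d, "break-pepolar")
  out <- check_pepolar_fieldmap(broken)
  expect_true("ASL603" %in% out$rule_id)

  # different axis is not a polar opposite either
  axis <- d
  axis$fieldmap_entries[[1]]$sidecar$entries$PhaseEncodingDirection <- "i"
  expect_true("ASL603" %in% check_pepolar_fieldmap(axis)$rule_id)

  # dangling IntendedFor
  dangling <- d
  dangling$fieldmap_entries[[1]]$sidecar$entries$IntendedFor <-
    "perf/sub-01_nonexistent.nii.gz"
  expect_true("ASL601" %in% check_pepolar_fieldmap(dangling)$rule_id)

  # PhaseEncodingDirection missing on the target side
  noped <- d
  noped$asl_sidecar$entries$PhaseEncodingDirection <- NULL
  expect_true("ASL602" %in% check_pepolar_fieldmap(noped)$rule_id)
})

test_that("validation is deterministic and stateless", {
  d <- fixture("asl004")$dataset
  r1 <- validate_asl(d)
  r2 <- validate_asl(d)
  expect_identical(r1, r2)
  m <- mutate_dataset(d, "truncate-context")
  expect_identical(validate_asl(m)$issues, validate_asl(m)$issues)
  # issues come out ordered by rule id then path
  iss <- validate_asl(m)$issues
  expect_false(is.unsorted(iss$rule_id))
})

test_that("reports serialise to JSON with a stable schema", {
  report <- validate_asl(mutate_dataset(fixture("asl005")$dataset,
                                        "delete-field:M0Type"))
  doc <- jsonlite::fromJSON(report_json(report), simplifyVector = FALSE)
  expect_named(doc, c("valid", "issues"))
  expect_false(doc$valid)
  expect_named(doc$issues[[1]],
               c("rule_id", "severity", "path", "field", "message"))
  expect_equal(doc$issues[[1]]$field, "M0Type")
})
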