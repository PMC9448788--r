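test_that("example plans match the published configurations", {
  p1 <- example_plan("asl001")
  expect_equal(p1$n_bs_pulses, 4L)
  expect_equal(p1$readout, "3D")
  expect_true(p1$deltam_only)
  expect_equal(p1$labeling_type, "PCASL")
  expect_equal(length(p1$plds_s), 1L)

  p2 <- example_plan("asl002")
  expect_equal(p2$readout, "2D")
  expect_equal(p2$m0_mode, "Separate")
  expect_equal(p2$n_bs_pulses, 2L)
  expect_equal(length(p2$plds_s), 1L)

  p3 <- example_plan("asl003")
  expect_equal(p3$labeling_type, "PASL")
  expect_gt(length(p3$plds_s), 1L)
  expect_equal(p3$m0_mode, "Separate")
  expect_equal(p3$readout, "3D")

  p4 <- example_plan("asl004")
  expect_true(p4$pepolar_fieldmap)
  expect_gt(length(p4$plds_s), 1L)
  expect_equal(p4$m0_mode, "Included")

  p5 <- example_plan("asl005")
  expect_equal(p5$n_bs_pulses, 4L)
  expect_equal(p5$m0_mode, "Included")
  expect_equal(p5$readout, "3D")

  expect_error(example_plan("asl999"), class = "aslbids_unknown_example")
})

test_that("plan invariants are enforced", {
  expect_error(acquisition_plan("x", "PCASL", 1.8),
               class = "aslbids_invalid_plan")  # no labeling duration
  expect_error(acquisition_plan("x", "PASL", 1.8),
               class = "aslbids_invalid_plan")  # no bolus cutoff
  expect_error(
    acquisition_plan("x", "PCASL", 1.8, labeling_duration_s = 1.8,
                     readout = "2D"),
    class = "aslbids_invalid_plan")  # 2D without slice timing
  expect_error(
    acquisition_plan("x", "PCASL", c(1, 2), labeling_duration_s = 1.8,
                     deltam_only = TRUE),
    class = "aslbids_invalid_plan")  # deltam_only must be single-delay
})

test_that("synthesis respects the plan's pair structure", {
  plan <- example_plan("asl005")
  syn <- synthesize_dataset(plan)
  ctx <- unclass(syn$dataset$context)
  expect_equal(sum(ctx == "control"), plan$n_pairs)
  expect_equal(sum(ctx == "label"), plan$n_pairs)
  expect_equal(syn$dataset$asl_sidecar$entries$TotalAcquiredPairs, plan$n_pairs)
  # in-series m0scan rows come first (acquisition order)
  expect_equal(ctx[1], "m0scan")
  expect_equal(syn$dataset$asl_series$n_volumes, length(ctx))
})

test_that("synthesis is deterministic: same plan and seed, identical tree bytes", {
  plan <- example_plan("asl002", noise_sd = 0.05)
  r1 <- withr::local_tempdir(); r2 <- withr::local_tempdir()
  write_asl_dataset(synthesize_dataset(plan)$dataset, r1)
  write_asl_dataset(synthesize_dataset(plan)$dataset, r2)
  f1 <- list.files(r1, recursive = TRUE)
  f2 <- list.files(r2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readBin(file.path(r1, f), "raw", file.size(file.path(r1, f))),
                     readBin(file.path(r2, f), "raw", file.size(file.path(r2, f))),
                     info = f)
  # a different seed changes the noisy images
  plan2 <- example_plan("asl002", noise_sd = 0.05, seed = 999L)
  d2 <- synthesize_dataset(plan2)$dataset
  expect_false(identical(d2$asl_series$voxels,
                         synthesize_dataset(plan)$dataset$asl_series$voxels))
})

test_that("validity by construction holds over the example and random plan sweep", {
  for (nm in example_names)
    expect_equal(n_errors(validate_asl(fixture(nm)$dataset)), 0L, info = nm)
  for (seed in 1:20) {
    syn <- synthesize_dataset(random_plan(seed))
    report <- validate_asl(syn$dataset)
    expect_equal(n_errors(report), 0L, info = paste("random seed", seed))
  }
})

test_that("every catalogued mutation is detected with its published rule", {
  catalogue <- violation_catalogue()
  expect_setequal(catalogue$violation_id,
                  c("delete-field:<name>", "truncate-context", "wrong-m0type",
                    "scaling-key", "break-pepolar", "shuffle-context"))
  getrow <- function(id) catalogue[catalogue$violation_id == id, ]
  split_ids <- function(x) strsplit(x, ",")[[1]]

  cases <- list(
    list(fix = "asl002", id = "truncate-context"),
    list(fix = "asl002", id = "wrong-m0type"),
    list(fix = "asl002", id = "scaling-key"),
    list(fix = "asl002", id = "shuffle-context"),
    list(fix = "asl004", id = "break-pepolar"),
    list(fix = "asl005", id = "wrong-m0type"),
    list(fix = "asl001", id = "truncate-context")
  )
  for (case in cases) {
    d <- mutate_dataset(fixture(case$fix)$dataset, case$id)
    rules <- error_rules(validate_asl(d))
    row <- getrow(case$id)
    expect_true(any(rules %in% split_ids(row$expected)),
                info = paste(case$fix, case$id))
    # defect isolation: no error beyond what the defect implies
    expect_true(all(rules %in% split_ids(row$allowed)),
                info = paste(case$fix, case$id))
  }

  # delete-field follows the generic mapping
  d <- mutate_dataset(fixture("asl003")$dataset, "delete-field:BolusCutOffFlag")
  expect_equal(error_rules(validate_asl(d)), "ASL101")

  expect_error(mutate_dataset(fixture("asl002")$dataset, "no-such-violation"),
               class = "aslbids_unknown_violation")
  expect_error(mutate_dataset(fixture("asl002")$dataset, "break-pepolar"),
               class = "aslbids_unknown_violation")
})

test_that("the full REQUIRED mutation matrix is detected and restorable", {
  reg <- build_field_registry()
  total <- 0L
  for (nm in example_names) {
    d <- fixture(nm)$dataset
    expect_equal(n_errors(validate_asl(d)), 0L, info = nm)
    roles <- list(asl = d$asl_sidecar,
                  m0scan = d$m0_sidecar,
                  fieldmap = if (length(d$fieldmap_entries))
                    d$fieldmap_entries[[1]]$sidecar)
    for (role in names(roles)) {
      sc <- roles[[role]]
      if (is.null(sc)) next
      for (spec in applicable_fields(role, d$asl_sidecar$entries, reg)) {
        if (spec$requirement != "REQUIRED") next
        if (is.null(sc$entries[[spec$name]])) next
        mutated <- mutate_dataset(d, paste0("delete-field:", role, ":", spec$name))
        report <- validate_asl(mutated)
        errs <- report$issues[report$issues$severity == "ERROR", ]
        expect_gte(nrow(errs), 1L)
        expect_true(spec$name %in% errs$field,
                    info = paste(nm, role, spec$name))
        total <- total + 1L
      }
    }
    # restoration returns to zero errors (the fixture itself is untouched)
    expect_equal(n_errors(validate_asl(d)), 0L, info = nm)
  }
  expect_gte(total, 50L)
})

test_that("the ground-truth phantom has the advertised structure", {
  gt <- default_ground_truth(c(16L, 16L, 5L))
  expect_setequal(unique(as.vector(gt$cbf_true)), c(0, 20, 60))
  expect_true(all(gt$m0_true[gt$cbf_true > 0] > 0))
  expect_true(all(gt$cbf_true >= 0))
  expect_equal(gt$lambda_ml_per_g, 0.9)
  expect_equal(gt$t1_blood_s, 1.650)
})
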