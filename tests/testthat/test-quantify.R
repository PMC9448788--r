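test_that("pairwise subtraction averages control minus label, skipping m0scan", {
  arr <- array(0, dim = c(2, 2, 2, 4))
  arr[, , , 1] <- 10; arr[, , , 2] <- 9; arr[, , , 3] <- 10; arr[, , , 4] <- 9
  dm <- subtract_pairs(image_series(arr),
                       asl_context(rep(c("control", "label"), 2)))
  expect_equal(as.vector(dm), rep(1, 8))

  # m0scan row excluded from pairing
  arr3 <- array(0, dim = c(2, 2, 2, 3))
  arr3[, , , 1] <- 500; arr3[, , , 2] <- 10; arr3[, , , 3] <- 9
  dm <- subtract_pairs(image_series(arr3),
                       asl_context(c("m0scan", "control", "label")))
  expect_equal(as.vector(dm), rep(1, 8))

  # deltam series: mean of deltam volumes
  arr2 <- array(0, dim = c(2, 2, 2, 2))
  arr2[, , , 1] <- 2; arr2[, , , 2] <- 4
  dm <- subtract_pairs(image_series(arr2), asl_context(c("deltam", "deltam")))
  expect_equal(as.vector(dm), rep(3, 8))

  expect_error(
    subtract_pairs(image_series(arr3),
                   asl_context(c("control", "control", "label"))),
    class = "aslbids_unpairable_context")
})

test_that("M0 resolution applies the saturation-recovery correction", {
  params <- quantification_params(3, "PCASL")
  base <- fixture("asl002")$dataset

  # long TRprep: correction factor approaches 1
  long <- base
  long$m0_sidecar$entries$RepetitionTimePreparation <- 1000
  raw_mean <- base$m0_series$voxels
  expect_equal(resolve_m0(long, params), raw_mean, tolerance = 1e-12)

  # TRprep equal to tissue T1: divide by 1 - exp(-1) = 0.6321206
  at_t1 <- base
  at_t1$m0_sidecar$entries$RepetitionTimePreparation <- params$t1_tissue_s
  expect_equal(resolve_m0(at_t1, params),
               raw_mean / 0.6321205588285577, tolerance = 1e-9)

  # Estimate: scalar used uncorrected
  est <- base
  est$m0_series <- NULL; est$m0_sidecar <- NULL
  est$asl_sidecar$entries$M0Type <- "Estimate"
  est$asl_sidecar$entries$M0Estimate <- 1200
  expect_equal(resolve_m0(est, params), 1200)

  # Absent: error unless the documented fallback is opted into
  absent <- est
  absent$asl_sidecar$entries$M0Type <- "Absent"
  absent$asl_sidecar$entries$M0Estimate <- NULL
  expect_error(resolve_m0(absent, params), class = "aslbids_m0_unavailable")
  expect_message(m0 <- resolve_m0(absent, params, control_fallback = TRUE),
                 "mean control")
  expect_equal(dim(m0), dim(absent$asl_series$voxels)[1:3])
})

test_that("effective delay adds slice timing for 2D and is flat for 3D", {
  sc2d <- sidecar_metadata("asl", list(MRAcquisitionType = "2D",
                                       PostLabelingDelay = 1.8,
                                       SliceTiming = c(0, 0.04, 0.08)))
  expect_equal(effective_pld(sc2d, 3), c(1.80, 1.84, 1.88))

  sc3d <- sidecar_metadata("asl", list(MRAcquisitionType = "3D",
                                       PostLabelingDelay = 2.0))
  expect_equal(effective_pld(sc3d, 5), rep(2.0, 5))

  bare <- sidecar_metadata("asl", list(MRAcquisitionType = "2D",
                                       PostLabelingDelay = 1.8))
  expect_error(effective_pld(bare, 3), class = "aslbids_missing_slice_timing")
})

test_that("the closed form reproduces an independently computed value", {
  # hand evaluation of the single-delay PCASL form with dM/M0 = 0.01,
  # lambda = 0.9, T1b = 1.65 s, alpha = 0.85, PLD = tau = 1.8 s
  sc <- sidecar_metadata("asl", list(
    ArterialSpinLabelingType = "PCASL", MRAcquisitionType = "3D",
    PostLabelingDelay = 1.8, LabelingDuration = 1.8,
    MagneticFieldStrength = 3))
  dm <- array(0.01, dim = c(2, 2, 2)); m0 <- array(1, dim = c(2, 2, 2))
  cbf <- quantify_cbf(dm, m0, sc)
  expect_equal(as.vector(cbf$values), rep(86.29992012955985, 8),
               tolerance = 1e-10)

  # PASL QUIPSS-II form: dM/M0 = 0.01, TI = 2.0, TI1 = 0.7, alpha = 0.98
  sc_pasl <- sidecar_metadata("asl", list(
    ArterialSpinLabelingType = "PASL", MRAcquisitionType = "3D",
    PostLabelingDelay = 2.0, BolusCutOffFlag = TRUE,
    BolusCutOffDelayTime = 0.7, MagneticFieldStrength = 3))
  cbf <- quantify_cbf(dm, m0, sc_pasl)
  expect_equal(as.vector(cbf$values), rep(132.26873568259194, 8),
               tolerance = 1e-10)

  # zero difference signal quantifies to exactly zero
  cbf0 <- quantify_cbf(array(0, dim = c(2, 2, 2)), m0, sc)
  expect_true(all(cbf0$values == 0))

  # unsupported schemes are refused
  nofl <- sidecar_metadata("asl", list(
    ArterialSpinLabelingType = "PASL", MRAcquisitionType = "3D",
    PostLabelingDelay = 2.0, BolusCutOffFlag = FALSE,
    MagneticFieldStrength = 3))
  expect_error(quantify_cbf(dm, m0, nofl), class = "aslbids_unsupported_scheme")
  ll <- sidecar_metadata("asl", list(
    ArterialSpinLabelingType = "PCASL", MRAcquisitionType = "3D",
    PostLabelingDelay = 1.8, LabelingDuration = 1.8, LookLocker = TRUE,
    MagneticFieldStrength = 3))
  expect_error(quantify_cbf(dm, m0, ll), class = "aslbids_unsupported_scheme")
  expect_error(quantification_params(7, "PCASL"),
               class = "aslbids_unsupported_scheme")
})

test_that("noise-free synthesis quantifies back to the exact ground truth", {
  for (nm in example_names) {
    syn <- fixture(nm)
    result <- quantify_dataset(syn$dataset)
    truth <- syn$truth$cbf_true
    m <- truth > 0
    for (key in names(result$cbf)) {
      est <- result$cbf[[key]]$values
      expect_true(all(is.finite(est[m])), info = paste(nm, key))
      expect_lt(max(abs(est[m] - truth[m]) / truth[m]), 1e-6)
    }
  }
})

test_that("CBF is invariant under joint positive rescaling of ASL and M0", {
  syn <- fixture("asl005")
  d <- syn$dataset
  base <- quantify_dataset(d)$cbf[[1]]$values
  for (c_scale in c(0.25, 3, 1750)) {
    scaled <- d
    scaled$asl_series <- apply_scaling(d$asl_series, scale_factors(c_scale))
    est <- quantify_dataset(scaled)$cbf[[1]]$values
    expect_equal(est, base, tolerance = 1e-12, info = paste("c =", c_scale))
  }
})

test_that("CBF rises with the difference signal and falls with M0", {
  sc <- sidecar_metadata("asl", list(
    ArterialSpinLabelingType = "PCASL", MRAcquisitionType = "3D",
    PostLabelingDelay = 1.8, LabelingDuration = 1.8,
    MagneticFieldStrength = 3))
  m0 <- array(1000, dim = c(2, 2, 2))
  dms <- seq(1, 10, by = 1)
  vals <- vapply(dms, function(dm)
    quantify_cbf(array(dm, dim = c(2, 2, 2)), m0, sc)$values[1], numeric(1))
  expect_true(all(diff(vals) > 0))
  m0s <- seq(500, 2000, by = 250)
  vals <- vapply(m0s, function(m)
    quantify_cbf(array(5, dim = c(2, 2, 2)), array(m, dim = c(2, 2, 2)),
                 sc)$values[1], numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("noisy recovery: masked-mean CBF within 5% over seeded replicates", {
  # noise calibrated to a difference-signal SNR of about 5 in gray matter,
  # 40 pairs; 25 replicates of the single-delay 3D configuration
  gt <- default_ground_truth(c(16L, 16L, 5L))
  params <- quantification_params(3, "PCASL")
  gm_dm <- 60 * 1000 /
    (6000 * 0.9 * exp(2.0 / 1.65) / (2 * 0.85 * 1.65 * (1 - exp(-1.8 / 1.65))))
  noise_sd <- gm_dm / 5
  truth_mean <- mean(gt$cbf_true[gt$cbf_true > 0])
  rel_err <- vapply(1:25, function(rep_seed) {
    plan <- example_plan("asl005", noise_sd = noise_sd, seed = 3000L + rep_seed)
    plan$n_pairs <- 40L
    syn <- synthesize_dataset(plan)
    est <- quantify_dataset(syn$dataset)$cbf[[1]]$values
    m <- syn$truth$cbf_true > 0
    abs(mean(est[m]) - truth_mean) / truth_mean
  }, numeric(1))
  expect_lt(mean(rel_err), 0.05)
  expect_lt(max(rel_err), 0.10)
})

test_that("quantification refuses invalid datasets unless forced", {
  d <- mutate_dataset(fixture("asl005")$dataset, "delete-field:M0Type")
  expect_error(quantify_dataset(d), class = "aslbids_validation_failed")
  # provenance records the constants actually used
  res <- quantify_dataset(fixture("asl003")$dataset)
  expect_equal(res$provenance$alpha, 0.98)
  expect_equal(res$provenance$t1_blood_s, 1.650)
  expect_equal(res$provenance$labeling_type, "PASL")
  expect_equal(length(res$cbf), length(example_plan("asl003")$plds_s))
})
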