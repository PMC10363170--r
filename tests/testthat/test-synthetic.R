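test_that("lesion generation is deterministic and plants guaranteed hits", {
  cfg <- small_config(seed = 8)
  a <- generate_lesions(cfg)
  b <- generate_lesions(cfg)
  expect_identical(lapply(a$volumes, `[[`, "data"),
                   lapply(b$volumes, `[[`, "data"))
  expect_identical(a$overlap_fraction, b$overlap_fraction)
  # seeded hits cover the critical region completely
  expect_equal(unname(a$overlap_fraction[seq_len(cfg$n_seeded_hits)]),
               rep(1, cfg$n_seeded_hits))
  expect_true(all(a$abnormal_truth[seq_len(cfg$n_seeded_hits)]))
  # abnormality flag is exactly the overlap rule
  expect_equal(unname(a$abnormal_truth),
               unname(a$overlap_fraction >= cfg$overlap_threshold))
  # different seeds give different masks
  c_ <- generate_lesions(small_config(seed = 9))
  expect_false(identical(lapply(a$volumes, `[[`, "data"),
                         lapply(c_$volumes, `[[`, "data")))
})

test_that("lesions are unilateral and zero-radius lesions are empty", {
  cfg <- small_config(seed = 8)
  les <- generate_lesions(cfg)
  aff <- les$volumes[[1]]$affine
  nx <- cfg$grid_shape[1]
  xw <- (0:(nx - 1)) * cfg$voxel_size_mm + aff[1, 4]
  for (id in names(les$volumes)) {
    m <- les$volumes[[id]]$data
    by_x <- apply(m, 1, sum)
    if (les$side[[id]] == "right") {
      expect_equal(sum(by_x[xw <= 0]), 0)
    } else {
      expect_equal(sum(by_x[xw >= 0]), 0)
    }
  }
  empty <- generate_lesions(small_config(
    seed = 3, lesion_radius_range_mm = c(0, 0), n_seeded_hits = 0L))
  expect_equal(sum(vapply(empty$volumes, function(v) sum(v$data),
                          numeric(1))), 0)
  expect_equal(unname(empty$overlap_fraction), rep(0, 14))
  expect_error(synthetic_cohort_config(
    critical_region = list(center = c(99L, 0L, 0L), radius_mm = 5)),
    "outside the grid")
})

test_that("noise-free behaviour recovers latent TDEs exactly", {
  cfg <- small_config(seed = 4, trial_noise_sd = 0)
  les <- generate_lesions(cfg)
  beh <- generate_behaviour(cfg, les)
  prof <- behavioural_profiles(beh$trials)
  ord <- match(prof$participant_id, beh$latent$participant_id)
  expect_equal(prof$tde_mean, beh$latent$latent_tde[ord], tolerance = 1e-10)
  expect_equal(prof$svba_upright_oriented, beh$latent$latent_upright[ord],
               tolerance = 1e-10)
  # both tilt directions carry the same latent TDE
  expect_equal(prof$tde_dir1, prof$tde_dir2, tolerance = 1e-10)
})

test_that("calibrated subgroup draws respect the cohort's own cut-off", {
  for (seed in 1:5) {
    cfg <- small_config(seed = seed)
    les <- generate_lesions(cfg)
    beh <- generate_behaviour(cfg, les)
    lat <- beh$latent
    ctrl <- lat$latent_tde[lat$group == "control"]
    cutoff <- mean(ctrl) - cfg$cutoff_k * stats::sd(ctrl)
    pat <- lat[lat$group == "stroke", ]
    expect_true(all(pat$latent_tde[pat$abnormal_truth] <
                      cutoff - cfg$cutoff_margin + 1e-9))
    expect_true(all(pat$latent_tde[!pat$abnormal_truth] >
                      cutoff + cfg$cutoff_margin - 1e-9))
  }
})

test_that("overlap threshold 0 makes every patient abnormal-distributed", {
  cfg <- small_config(seed = 6, overlap_threshold = 0)
  les <- generate_lesions(cfg)
  expect_true(all(les$abnormal_truth))
  beh <- generate_behaviour(cfg, les)
  expect_true(all(beh$latent$latent_tde[beh$latent$group == "stroke"] < 5))
})

test_that("unconditioned draws land on the configured group means", {
  # law of large numbers on the configured distributions
  cfg <- synthetic_cohort_config(
    grid_shape = c(8L, 8L, 8L), voxel_size_mm = 20,
    critical_region = list(center = c(6L, 4L, 4L), radius_mm = 30),
    lesion_radius_range_mm = c(10, 40),
    n_controls = 400L, n_patients = 400L, n_seeded_hits = 0L,
    overlap_threshold = 1, calibrate_to_cutoff = FALSE, seed = 12)
  les <- generate_lesions(cfg)
  beh <- generate_behaviour(cfg, les)
  lat <- beh$latent
  patients <- lat$latent_tde[lat$group == "stroke" & !lat$abnormal_truth]
  expect_equal(mean(patients), 19.2, tolerance = 1.5)
  expect_equal(stats::sd(patients), 14.8, tolerance = 1.5)
  expect_equal(mean(lat$latent_tde[lat$group == "control"]), 25.7,
               tolerance = 1.7)
})

test_that("covariates stay on scale and couple to TDE via slopes", {
  cfg <- small_config(seed = 7)
  les <- generate_lesions(cfg)
  beh <- generate_behaviour(cfg, les)
  cov <- generate_covariates(cfg, beh$latent)
  expect_true(all(cov$pass_dynamic <= 21 & cov$pass_dynamic >= 0))
  expect_true(all(cov$sias_motor <= 31 & cov$sias_motor >= 0))
  expect_true(all(cov$sias_sensory <= 12 & cov$sias_sensory >= 0))
  expect_equal(nrow(cov), cfg$n_patients)

  # a strong configured slope shows up as a positive correlation
  cfg2 <- synthetic_cohort_config(
    grid_shape = c(8L, 8L, 8L), voxel_size_mm = 20,
    critical_region = list(center = c(6L, 4L, 4L), radius_mm = 30),
    lesion_radius_range_mm = c(10, 40),
    n_controls = 5L, n_patients = 150L, n_seeded_hits = 0L,
    covariate_effects = c(pass_dynamic = 0.2), seed = 13)
  les2 <- generate_lesions(cfg2)
  beh2 <- generate_behaviour(cfg2, les2)
  cov2 <- generate_covariates(cfg2, beh2$latent)
  lat2 <- beh2$latent[beh2$latent$group == "stroke", ]
  expect_gt(pearson(lat2$latent_tde, cov2$pass_dynamic)$r, 0.3)
  # zero slopes: correlation near zero at large n
  cov0 <- generate_covariates(
    synthetic_cohort_config(
      grid_shape = c(8L, 8L, 8L), voxel_size_mm = 20,
      critical_region = list(center = c(6L, 4L, 4L), radius_mm = 30),
      lesion_radius_range_mm = c(10, 40),
      n_controls = 5L, n_patients = 150L, n_seeded_hits = 0L, seed = 13),
    beh2$latent)
  expect_lt(abs(pearson(lat2$latent_tde, cov0$pass_dynamic)$r), 0.2)
})

test_that("written cohorts round-trip through the analysis input formats", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(small_config(seed = 2))
  write_cohort(coh, dir, gzip = TRUE)
  masks <- list.files(file.path(dir, "masks"), full.names = TRUE)
  expect_length(masks, 14L)
  vol <- load_mask(masks[1])
  id <- vol$participant_id
  expect_identical(vol$data, coh$lesions[[id]]$data + 0)
  beh <- read_behaviour(file.path(dir, "behaviour.csv"))
  expect_identical(attr(beh, "format"), "long")
  prof <- behavioural_profiles(beh)
  expect_equal(nrow(prof), 24L)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  truth <- coh$ground_truth
  expect_setequal(gt$abnormal_ids,
                  truth$participant_id[which(truth$abnormal_truth)])
})
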