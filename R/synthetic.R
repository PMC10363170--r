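# Synthetic lesion-cohort generator: unilateral spherical lesion masks plus
# trial-level SVBA behaviour and clinical covariates, with the statistical
# structure the analysis assumes, so the whole pipeline is testable without
# patient data.

#' Synthetic cohort configuration
#'
#' Defaults encode the reference cohort: 20 controls and 37 stroke patients;
#' control mean TDE 25.7 +/- 17.1 deg, normal-TDE patients 19.2 +/- 14.8
#' deg, abnormal-TDE patients -4.1 +/- 1.8 deg; about 59% right-sided
#' lesions (22/37). Abnormality is a deterministic function of lesion
#' overlap with a designated critical region (fraction >=
#' `overlap_threshold`); `n_seeded_hits` patients receive a lesion sphere
#' centred on that region so the abnormal subgroup is reliably planted.
#'
#' @param grid_shape 3 integers (voxels per axis).
#' @param voxel_size_mm isotropic voxel size in mm (default 5, giving a
#'   160 mm field of view on the default grid).
#' @param n_controls,n_patients group sizes.
#' @param lesion_radius_range_mm min/max lesion sphere radius in mm.
#' @param lesions_per_patient number of spheres unioned per patient.
#' @param hemisphere_split fraction of right-sided lesions.
#' @param critical_region list: `center` (0-based voxel i,j,k) and
#'   `radius_mm`; defaults to a right temporo-parietal locus.
#' @param overlap_threshold critical-region damage fraction at or above
#'   which a patient's latent TDE is drawn from the abnormal distribution.
#' @param n_seeded_hits patients whose first lesion is centred on the
#'   critical region with radius >= the region radius (guaranteed hits).
#' @param tde_control,tde_normal_patient,tde_abnormal `c(mean, sd)` in
#'   degrees for the three latent TDE distributions.
#' @param calibrate_to_cutoff condition patient subgroup draws on the
#'   cohort's own control-referenced cut-off (see [generate_behaviour()]).
#' @param cutoff_k cut-off multiplier mirrored from the classifier.
#' @param cutoff_margin truncation margin (degrees) around the cut-off.
#' @param trial_noise_sd per-trial adjustment noise SD (degrees).
#' @param upright_bias_sd between-subject SD of the latent upright SVBA
#'   error (degrees).
#' @param covariate_effects named slopes coupling covariates to latent TDE
#'   (degrees^-1 scale units); all zero by default, emulating null
#'   brain-behaviour correlations.
#' @param n_trials trials per posture.
#' @param seed integer RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_cohort_config <- function(
    grid_shape = c(32L, 32L, 32L), voxel_size_mm = 5,
    n_controls = 20L, n_patients = 37L,
    lesion_radius_range_mm = c(10, 30), lesions_per_patient = 2L,
    hemisphere_split = 22 / 37,
    critical_region = list(center = c(24L, 18L, 18L), radius_mm = 12),
    overlap_threshold = 0.5, n_seeded_hits = 5L,
    tde_control = c(25.7, 17.1), tde_normal_patient = c(19.2, 14.8),
    tde_abnormal = c(-4.1, 1.8), calibrate_to_cutoff = TRUE,
    cutoff_k = 1.5, cutoff_margin = 1.0,
    trial_noise_sd = 2.0, upright_bias_sd = 4.0,
    covariate_effects = c(sias_motor = 0, sias_sensory = 0,
                          line_bisection_mm = 0, pass_dynamic = 0,
                          cop_max_ipsi_cm = 0, cop_max_contra_cm = 0),
    n_trials = 10L, seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm,
              n_controls = as.integer(n_controls),
              n_patients = as.integer(n_patients),
              lesion_radius_range_mm = lesion_radius_range_mm,
              lesions_per_patient = as.integer(lesions_per_patient),
              hemisphere_split = hemisphere_split,
              critical_region = critical_region,
              overlap_threshold = overlap_threshold,
              n_seeded_hits = as.integer(n_seeded_hits),
              tde_control = tde_control,
              tde_normal_patient = tde_normal_patient,
              tde_abnormal = tde_abnormal,
              calibrate_to_cutoff = isTRUE(calibrate_to_cutoff),
              cutoff_k = cutoff_k, cutoff_margin = cutoff_margin,
              trial_noise_sd = trial_noise_sd,
              upright_bias_sd = upright_bias_sd,
              covariate_effects = covariate_effects,
              n_trials = as.integer(n_trials),
              seed = as.integer(seed))
  stopifnot(length(cfg$grid_shape) == 3L, all(cfg$grid_shape > 0L),
            cfg$voxel_size_mm > 0,
            cfg$lesion_radius_range_mm[1L] >= 0,
            diff(cfg$lesion_radius_range_mm) >= 0,
            cfg$hemisphere_split >= 0, cfg$hemisphere_split <= 1,
            cfg$overlap_threshold >= 0, cfg$overlap_threshold <= 1,
            cfg$tde_control[2L] >= 0, cfg$tde_normal_patient[2L] >= 0,
            cfg$tde_abnormal[2L] >= 0, cfg$trial_noise_sd >= 0,
            cfg$upright_bias_sd >= 0, cfg$n_trials >= 1L)
  if (any(cfg$critical_region$center < 0) ||
      any(cfg$critical_region$center >= cfg$grid_shape))
    stop("critical region centre lies outside the grid", call. = FALSE)
  if (cfg$lesion_radius_range_mm[2L] >=
      min(cfg$grid_shape) * cfg$voxel_size_mm)
    stop("lesion radii must be smaller than the grid extent", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

synthetic_affine <- function(cfg) {
  s <- cfg$voxel_size_mm
  origin <- -(cfg$grid_shape / 2) * s
  rbind(cbind(diag(c(s, s, s)), origin), c(0, 0, 0, 1))
}

sphere_mask <- function(cfg, center_world, radius_mm, side) {
  shape <- cfg$grid_shape
  aff <- synthetic_affine(cfg)
  ax <- lapply(1:3, function(d) (0:(shape[d] - 1L)) * cfg$voxel_size_mm +
                 aff[d, 4L])
  dx2 <- (ax[[1L]] - center_world[1L])^2
  dy2 <- (ax[[2L]] - center_world[2L])^2
  dz2 <- (ax[[3L]] - center_world[3L])^2
  m <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius_mm^2
  # confine to one hemisphere (x > 0 world = right); clip at the midline
  if (!is.null(side)) {
    xw <- ax[[1L]]
    keep <- if (side == "right") xw > 0 else xw < 0
    m[!keep, , ] <- FALSE
  }
  m + 0
}

region_mask <- function(cfg) {
  center_world <- voxel_to_world(cfg$critical_region$center,
                                 synthetic_affine(cfg))
  sphere_mask(cfg, center_world, cfg$critical_region$radius_mm, side = NULL)
}

#' Generate synthetic lesion volumes
#'
#' Per patient, the union of `lesions_per_patient` random spheres confined
#' to one hemisphere (side drawn by `hemisphere_split`; sphere centres
#' uniform within the hemisphere, radii uniform in
#' `lesion_radius_range_mm`). The first `n_seeded_hits` patients get their
#' first sphere centred on the critical region with a radius at least the
#' region radius. Deterministic given `cfg$seed` (R's default Mersenne
#' Twister stream).
#'
#' @param cfg a [synthetic_cohort_config()].
#' @return list: `volumes` (list of [lesion_volume()]), `overlap_fraction`
#'   (named, exact fraction of critical-region voxels damaged), `side`
#'   (named lesion sides), `region` (critical-region binary array),
#'   `abnormal_truth` (named logical, overlap >= threshold).
#' @export
generate_lesions <- function(cfg) {
  set.seed(cfg$seed)
  aff <- synthetic_affine(cfg)
  region <- region_mask(cfg)
  region_n <- sum(region)
  extent <- cfg$grid_shape * cfg$voxel_size_mm
  xmax <- extent[1L] / 2
  ids <- sprintf("s%02d", seq_len(cfg$n_patients))
  sides <- ifelse(stats::runif(cfg$n_patients) < cfg$hemisphere_split,
                  "right", "left")
  if (cfg$n_seeded_hits > 0L)
    sides[seq_len(min(cfg$n_seeded_hits, cfg$n_patients))] <- "right"
  region_center <- voxel_to_world(cfg$critical_region$center, aff)
  volumes <- vector("list", cfg$n_patients)
  overlap <- numeric(cfg$n_patients)
  for (p in seq_len(cfg$n_patients)) {
    mask <- array(0, dim = cfg$grid_shape)
    for (l in seq_len(cfg$lesions_per_patient)) {
      r <- stats::runif(1, cfg$lesion_radius_range_mm[1L],
                        cfg$lesion_radius_range_mm[2L])
      cx <- if (sides[p] == "right") stats::runif(1, 0, xmax)
            else stats::runif(1, -xmax, 0)
      cy <- stats::runif(1, -extent[2L] / 2, extent[2L] / 2)
      cz <- stats::runif(1, -extent[3L] / 2, extent[3L] / 2)
      center <- c(cx, cy, cz)
      if (p <= cfg$n_seeded_hits && l == 1L) {
        # planted hit: sphere congruent with the critical region, so the
        # induced damage does not smear beyond the planted locus
        center <- region_center
        r <- cfg$critical_region$radius_mm
      }
      mask <- pmax(mask, sphere_mask(cfg, center, r, sides[p]))
    }
    volumes[[p]] <- lesion_volume(mask, aff, ids[p], "synthetic")
    overlap[p] <- if (region_n > 0) sum(mask * region) / region_n else 0
  }
  names(volumes) <- names(overlap) <- ids
  names(sides) <- ids
  list(volumes = volumes, overlap_fraction = overlap, side = sides,
       region = region,
       abnormal_truth = stats::setNames(overlap >= cfg$overlap_threshold,
                                        ids))
}

#' Generate trial-level SVBA behaviour for a synthetic cohort
#'
#' Each participant gets a latent mean TDE drawn from the control
#' distribution (controls), the abnormal distribution (patients whose
#' critical-region overlap is at or above `overlap_threshold`) or the
#' normal-patient distribution (other patients), plus a latent upright SVBA
#' error ~ Normal(0, `upright_bias_sd`^2).
#'
#' With `calibrate_to_cutoff = TRUE` (default) the patient subgroup draws
#' are conditioned on the cohort's own control-referenced cut-off
#' (`mean - cutoff_k * sd` of the control latents): abnormal latents are
#' truncated below `cutoff - cutoff_margin`, normal-patient latents above
#' `cutoff + cutoff_margin`. The reference subgroup statistics are
#' statistics of cut-off-defined groups, so this conditioning is what makes
#' a generated abnormal subgroup actually abnormal under the pipeline's
#' classifier — giving unambiguous ground truth for recovery checks. The
#' margin (default 1 degree, > 2 SD of the trial-noise error on a recovered
#' mean TDE at defaults) keeps trial noise from flipping boundary cases.
#' Set `calibrate_to_cutoff = FALSE` for unconditioned draws (e.g. strict
#' null-calibration worlds). Per-posture latent means are
#' arranged in the raw (rightward-positive) sign convention so that the
#' behavioural module recovers the latent TDE in expectation (exactly when
#' `trial_noise_sd = 0`); per-trial values add Normal(0, `trial_noise_sd`^2)
#' noise. Controls use posture directions left/right; patients ipsi/contra
#' by their lesion side.
#'
#' @param cfg a [synthetic_cohort_config()].
#' @param lesions a [generate_lesions()] result (ignored for controls).
#' @return list: `trials` (long data.frame: participant_id, group,
#'   lesion_side, posture, trial, adjustment), `latent` (data.frame of
#'   per-participant latent upright error and TDE plus truth flags).
#' @export
generate_behaviour <- function(cfg, lesions) {
  set.seed(cfg$seed + 1000L)
  over <- lesions$overlap_fraction
  stopifnot(all(over >= 0 & over <= 1))
  ids_c <- sprintf("c%02d", seq_len(cfg$n_controls))
  ids_p <- names(lesions$volumes)
  draw <- function(par, n) stats::rnorm(n, par[1L], par[2L])
  # inverse-CDF truncated-normal draws (below / above a bound)
  rtrunc <- function(par, n, bound, below) {
    pb <- stats::pnorm(bound, par[1L], par[2L])
    u <- stats::runif(n)
    q <- if (below) u * max(pb, 1e-12)
         else min(pb, 1 - 1e-12) + u * (1 - min(pb, 1 - 1e-12))
    stats::qnorm(q, par[1L], par[2L])
  }
  lat_c <- draw(cfg$tde_control, cfg$n_controls)
  abn <- lesions$abnormal_truth
  if (isTRUE(cfg$calibrate_to_cutoff)) {
    cutoff <- mean(lat_c) - cfg$cutoff_k * stats::sd(lat_c)
    lat_abn <- rtrunc(cfg$tde_abnormal, cfg$n_patients,
                      cutoff - cfg$cutoff_margin, below = TRUE)
    lat_nor <- rtrunc(cfg$tde_normal_patient, cfg$n_patients,
                      cutoff + cfg$cutoff_margin, below = FALSE)
  } else {
    lat_abn <- draw(cfg$tde_abnormal, cfg$n_patients)
    lat_nor <- draw(cfg$tde_normal_patient, cfg$n_patients)
  }
  lat_p <- ifelse(abn, lat_abn, lat_nor)
  latent <- data.frame(
    participant_id = c(ids_c, ids_p),
    group = rep(c("control", "stroke"), c(cfg$n_controls, cfg$n_patients)),
    lesion_side = c(rep("none", cfg$n_controls), unname(lesions$side)),
    latent_tde = c(lat_c, lat_p),
    latent_upright = stats::rnorm(cfg$n_controls + cfg$n_patients, 0,
                                  cfg$upright_bias_sd),
    abnormal_truth = c(rep(NA, cfg$n_controls), unname(abn)),
    stringsAsFactors = FALSE)

  rows <- vector("list", nrow(latent))
  for (i in seq_len(nrow(latent))) {
    u <- latent$latent_upright[i]
    tde <- latent$latent_tde[i]
    side <- latent$lesion_side[i]
    # oriented means: dir1 = u - tde (sign-reversed direction), dir2 = u + tde
    d1 <- u - tde; d2 <- u + tde
    # map oriented (upright, dir1, dir2) back to raw posture means
    if (side == "left") {
      post <- c(upright = -u, left10 = -d1, right10 = -d2)
    } else if (side == "right") {
      post <- c(upright = u, right10 = d1, left10 = d2)
    } else {
      post <- c(upright = u, left10 = d1, right10 = d2)
    }
    for (p in names(post)) {
      adj <- post[[p]] + stats::rnorm(cfg$n_trials, 0, cfg$trial_noise_sd)
      adj <- pmin(pmax(adj, -89.9), 90)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = latent$participant_id[i],
        group = latent$group[i], lesion_side = side, posture = p,
        trial = seq_len(cfg$n_trials), adjustment = adj,
        stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(trials = trials, latent = latent)
}

# Table-1-scale covariate generators: mean, sd, bounds per scale.
COVARIATE_SCALES <- list(
  sias_motor = c(mean = 19.9, sd = 7.7, lo = 0, hi = 31),
  sias_sensory = c(mean = 7.7, sd = 4.1, lo = 0, hi = 12),
  line_bisection_mm = c(mean = 2.2, sd = 6.5, lo = -Inf, hi = Inf),
  pass_dynamic = c(mean = 19.0, sd = 3.3, lo = 0, hi = 21),
  cop_static_cm = c(mean = 4.7, sd = 10.2, lo = -Inf, hi = Inf),
  cop_max_ipsi_cm = c(mean = 70.8, sd = 22.8, lo = 0, hi = Inf),
  cop_max_contra_cm = c(mean = 73.4, sd = 21.8, lo = 0, hi = Inf))

#' Generate clinical covariates for synthetic patients
#'
#' SIAS motor/sensory, line bisection, dynamic PASS and COP measures are
#' drawn Normal on their published group scales, each linearly coupled to
#' the patient's latent TDE by its configured slope (default 0, emulating
#' the null correlation findings) and clipped to the scale bounds.
#'
#' @param cfg a [synthetic_cohort_config()].
#' @param latent the `latent` data.frame from [generate_behaviour()].
#' @return data.frame: participant_id plus one column per covariate
#'   (patients only).
#' @export
generate_covariates <- function(cfg, latent) {
  set.seed(cfg$seed + 2000L)
  pat <- latent[latent$group == "stroke", , drop = FALSE]
  centred_tde <- pat$latent_tde - mean(pat$latent_tde)
  out <- data.frame(participant_id = pat$participant_id,
                    stringsAsFactors = FALSE)
  for (nm in names(COVARIATE_SCALES)) {
    sc <- COVARIATE_SCALES[[nm]]
    slope <- if (nm %in% names(cfg$covariate_effects))
      cfg$covariate_effects[[nm]] else 0
    vals <- sc[["mean"]] + slope * centred_tde +
      stats::rnorm(nrow(pat), 0, sc[["sd"]])
    out[[nm]] <- pmin(pmax(vals, sc[["lo"]]), sc[["hi"]])
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Runs [generate_lesions()], [generate_behaviour()] and
#' [generate_covariates()] under one config and returns everything the
#' pipeline consumes, plus the ground truth.
#'
#' @param cfg a [synthetic_cohort_config()].
#' @return list of class `synthetic_cohort`: `config`, `lesions` (volumes),
#'   `overlap_fraction`, `region` (critical-region array), `trials`
#'   (long behavioural table with covariates merged), `covariates`,
#'   `ground_truth` (per-patient abnormal flag + latent values).
#' @export
generate_cohort <- function(cfg = synthetic_cohort_config()) {
  les <- generate_lesions(cfg)
  beh <- generate_behaviour(cfg, les)
  cov <- generate_covariates(cfg, beh$latent)
  trials <- merge(beh$trials, cov, by = "participant_id", all.x = TRUE,
                  sort = FALSE)
  trials <- trials[order(match(trials$participant_id,
                               unique(beh$trials$participant_id)),
                         match(trials$posture, POSTURES), trials$trial), ]
  rownames(trials) <- NULL
  attr(trials, "format") <- "long"
  structure(list(config = cfg, lesions = les$volumes,
                 overlap_fraction = les$overlap_fraction,
                 region = les$region, trials = trials, covariates = cov,
                 ground_truth = beh$latent),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  abn <- x$ground_truth$abnormal_truth
  cat(sprintf(paste0("synthetic_cohort: %d controls + %d patients, grid %s",
                     " (%g mm voxels)\n  planted abnormal patients: %d\n"),
              x$config$n_controls, x$config$n_patients,
              paste(x$config$grid_shape, collapse = "x"),
              x$config$voxel_size_mm, sum(abn, na.rm = TRUE)))
  invisible(x)
}

#' Write a synthetic cohort to disk in the analysis input formats
#'
#' NIfTI lesion masks (one per patient), a long-format behavioural CSV, a
#' covariate CSV and a ground-truth JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` masks instead of `.nii`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask_dir <- file.path(dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  for (v in cohort$lesions)
    save_mask(v, file.path(mask_dir, paste0(v$participant_id, ext)))
  utils::write.csv(cohort$trials, file.path(dir, "behaviour.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(abnormal_ids = gt$participant_id[which(gt$abnormal_truth)],
         overlap_fraction = as.list(cohort$overlap_fraction),
         critical_region = cohort$config$critical_region,
         seed = cohort$config$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
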