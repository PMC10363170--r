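# End-to-end orchestration: behaviour -> classification -> subtraction maps
# -> Bayesian lesion-deficit inference -> brain-behaviour correlations, on
# real inputs (behaviour table + mask directory) or a simulated cohort.

#' Analysis configuration
#'
#' Exactly one of (`behaviour_path` + `mask_dir`) or `simulate = TRUE` must
#' be active. Threshold defaults mirror the reference analysis: abnormality
#' cut-off 1.5 control SDs, at-least-3-patients voxel coverage, 40%
#' subtraction display threshold, JZS prior scale 0.707.
#'
#' @param behaviour_path behavioural CSV/TSV (see [read_behaviour()]).
#' @param mask_dir directory of per-patient NIfTI lesion masks named
#'   `<participant_id>.nii[.gz]`.
#' @param simulate generate the inputs with [generate_cohort()] instead.
#' @param synthetic_config a [synthetic_cohort_config()] used when
#'   `simulate = TRUE`; its seed is overridden by `seed`.
#' @param cutoff_k abnormality cut-off multiplier (control SD units).
#' @param min_lesioned voxel coverage filter.
#' @param display_threshold_pct strict display threshold for the
#'   subtraction map.
#' @param rscale JZS Cauchy prior scale.
#' @param correlation_prior_scale stretched-beta width for correlation BFs.
#' @param run_association run the correlation stage (needs covariates).
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param seed integer seed (simulation only).
#' @param verbose log stage progress to stderr.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(behaviour_path = NULL, mask_dir = NULL,
                            simulate = FALSE,
                            synthetic_config = synthetic_cohort_config(),
                            cutoff_k = 1.5, min_lesioned = 3L,
                            display_threshold_pct = 40, rscale = 0.707,
                            correlation_prior_scale = 0.707,
                            run_association = TRUE, out_dir = NULL,
                            seed = 1L, verbose = FALSE) {
  real <- !is.null(behaviour_path) || !is.null(mask_dir)
  if (simulate && real)
    stop("config must activate exactly one of real inputs or simulate",
         call. = FALSE)
  if (!simulate && (is.null(behaviour_path) || is.null(mask_dir)))
    stop("real-input mode needs both behaviour_path and mask_dir",
         call. = FALSE)
  stopifnot(cutoff_k >= 0, min_lesioned >= 1, rscale > 0,
            correlation_prior_scale > 0)
  structure(list(behaviour_path = behaviour_path, mask_dir = mask_dir,
                 simulate = simulate, synthetic_config = synthetic_config,
                 cutoff_k = cutoff_k, min_lesioned = as.integer(min_lesioned),
                 display_threshold_pct = display_threshold_pct,
                 rscale = rscale,
                 correlation_prior_scale = correlation_prior_scale,
                 run_association = run_association, out_dir = out_dir,
                 seed = as.integer(seed), verbose = verbose),
            class = "analysis_config")
}

log_stage <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[tiltmap] ", sprintf(...))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage [%s]: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Validate analysis inputs without aborting
#'
#' Checks the behavioural table schema, lesion-mask grid consistency, and
#' id matching between table and masks; returns a report rather than
#' stopping.
#'
#' @param config an [analysis_config()] in real-input mode.
#' @return list with `problems` (character vector, empty when clean) and
#'   `n_masks`, `n_participants`.
#' @export
validate_inputs <- function(config) {
  problems <- character(0)
  beh <- NULL
  if (is.null(config$behaviour_path) || !file.exists(config$behaviour_path)) {
    problems <- c(problems, "behaviour table missing")
  } else {
    beh <- tryCatch(read_behaviour(config$behaviour_path),
                    error = function(e) {
                      problems <<- c(problems,
                                     paste("schema:", conditionMessage(e)))
                      NULL
                    })
  }
  table_ids <- character(0)
  if (!is.null(beh)) {
    table_ids <- unique(beh$participant_id)
    if (identical(attr(beh, "format"), "long")) {
      for (id in table_ids) {
        have <- unique(beh$posture[beh$participant_id == id])
        miss <- setdiff(POSTURES, have)
        if (length(miss))
          problems <- c(problems, sprintf(
            "schema: participant %s missing posture(s) %s", id,
            paste(miss, collapse = ", ")))
      }
    }
  }
  mask_files <- character(0)
  if (is.null(config$mask_dir) || !dir.exists(config$mask_dir)) {
    problems <- c(problems, "mask directory missing")
  } else {
    mask_files <- list.files(config$mask_dir, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE)
    shapes <- lapply(mask_files, function(f)
      tryCatch(dim(read_nifti(f)$data), error = function(e) {
        problems <<- c(problems, sprintf("mask %s unreadable: %s",
                                         basename(f), conditionMessage(e)))
        NULL
      }))
    shapes <- Filter(Negate(is.null), shapes)
    if (length(shapes) > 1L &&
        !all(vapply(shapes, identical, logical(1), shapes[[1L]])))
      problems <- c(problems, "mask grids are inconsistent")
    mask_ids <- sub("\\.nii(\\.gz)?$", "", basename(mask_files))
    stroke_ids <- if (!is.null(beh))
      unique(beh$participant_id[beh$group == "stroke"]) else character(0)
    for (id in setdiff(mask_ids, table_ids))
      problems <- c(problems, sprintf("unmatched id: mask %s has no behaviour row", id))
    for (id in setdiff(stroke_ids, mask_ids))
      problems <- c(problems, sprintf("unmatched id: patient %s has no mask", id))
  }
  list(problems = problems, n_masks = length(mask_files),
       n_participants = length(table_ids))
}

collect_inputs <- function(config) {
  if (config$simulate) {
    cfg <- config$synthetic_config
    cfg$seed <- config$seed
    cohort <- generate_cohort(cfg)
    list(behaviour = cohort$trials, volumes = cohort$lesions,
         cohort = cohort)
  } else {
    behaviour <- read_behaviour(config$behaviour_path)
    files <- list.files(config$mask_dir, pattern = "\\.nii(\\.gz)?$",
                        full.names = TRUE)
    if (length(files) == 0L)
      stop("no NIfTI masks found in ", config$mask_dir, call. = FALSE)
    volumes <- lapply(files, load_mask)
    names(volumes) <- vapply(volumes, `[[`, character(1), "participant_id")
    list(behaviour = behaviour, volumes = volumes, cohort = NULL)
  }
}

#' Run the full lesion-behaviour analysis
#'
#' Executes the pipeline end-to-end: behavioural profiles and group tests;
#' abnormality classification against the control TDE distribution; lesion
#' overlap, subtraction and thresholded subtraction maps with peak report;
#' voxel-wise JZS Bayes-factor lesion-deficit inference; and (optionally)
#' the brain-behaviour correlation battery. Outputs are deterministic given
#' config + seed. When `out_dir` is set, maps (NIfTI), tables (TSV) and a
#' JSON summary are written after all stages succeed, so a failed run
#' leaves no partial bundle.
#'
#' @param config an [analysis_config()].
#' @return object of class `tde_analysis`: `profiles`, `group_tests`,
#'   `cutoff`, `abnormal_ids`, `maps` (overlap/subtraction/thresholded
#'   stat_maps), `peak`, `bldi` ([bf_map()] result), `correlations`
#'   (data.frame or NULL), `summary` (the JSON-ready list), `config`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  inputs <- with_stage("input", collect_inputs(config))

  log_stage(config, "behavioural profiles")
  profiles <- with_stage("behavioural",
                         behavioural_profiles(inputs$behaviour))
  tests <- with_stage("behavioural", group_tests(profiles))

  log_stage(config, "classification")
  profiles <- with_stage("classification",
                         label_profiles(profiles, k = config$cutoff_k))
  cutoff <- attr(profiles, "cutoff")
  abnormal_ids <- profiles$participant_id[profiles$label == "abnormal"]
  normal_ids <- profiles$participant_id[profiles$label == "normal"]

  log_stage(config, "lesion matrix (%d masks)", length(inputs$volumes))
  maps <- peak <- bldi <- NULL
  vm <- with_stage("lesion_io", build_voxel_matrix(inputs$volumes))
  subtraction <- with_stage("subtraction", {
    if (length(abnormal_ids) == 0L || length(normal_ids) == 0L) {
      NULL  # subtraction undefined without both classified groups
    } else {
      abn_pct <- group_overlap_pct(vm, abnormal_ids)
      nor_pct <- group_overlap_pct(vm, normal_ids)
      sub <- subtraction_map(abn_pct, nor_pct)
      thr <- threshold_map(sub, config$display_threshold_pct)
      list(abnormal_overlap = abn_pct, normal_overlap = nor_pct,
           subtraction = sub,
           subtraction_thresholded = thr,
           peak = peak_voxel(sub))
    }
  })

  log_stage(config, "Bayesian lesion-deficit inference")
  bldi <- with_stage("bldi", {
    stroke <- profiles[profiles$group == "stroke", , drop = FALSE]
    scores <- stats::setNames(stroke$tde_mean, stroke$participant_id)
    vm_stroke <- build_voxel_matrix(
      inputs$volumes[names(inputs$volumes) %in% stroke$participant_id])
    bf_map(vm_stroke, scores, rscale = config$rscale,
           min_lesioned = config$min_lesioned)
  })

  correlations <- NULL
  if (isTRUE(config$run_association)) {
    log_stage(config, "brain-behaviour correlations")
    correlations <- with_stage("association",
      association_battery(profiles,
                          prior_scale = config$correlation_prior_scale))
  }

  summary_list <- with_stage("report", build_summary(
    config, tests, cutoff, abnormal_ids, subtraction, bldi, correlations))

  result <- structure(list(profiles = profiles, group_tests = tests,
                           cutoff = cutoff, abnormal_ids = abnormal_ids,
                           maps = subtraction,
                           peak = if (!is.null(subtraction)) subtraction$peak,
                           bldi = bldi, correlations = correlations,
                           summary = summary_list, config = config,
                           ground_truth =
                             if (!is.null(inputs$cohort))
                               inputs$cohort$ground_truth),
                      class = "tde_analysis")
  if (!is.null(config$out_dir))
    with_stage("report", write_bundle(result, config$out_dir))
  result
}

gt_to_list <- function(gt) {
  list(t = gt$statistic, df = gt$df, p = gt$p_two_tailed,
       d = gt$effect_size_d, kind = gt$test_kind)
}

build_summary <- function(config, tests, cutoff, abnormal_ids, subtraction,
                          bldi, correlations) {
  cat_counts <- as.list(table(bldi$table$category))
  out <- list(
    group_tests = lapply(tests[c("upright_control", "upright_stroke",
                                 "tilt_direction_control",
                                 "tilt_direction_stroke",
                                 "tde_between_groups")], gt_to_list),
    group_summary = tests$summary,
    cutoff = cutoff,
    abnormal_ids = as.list(sort(abnormal_ids)),
    n_abnormal = length(abnormal_ids),
    bldi = list(n_tested = bldi$n_tested, rscale = bldi$rscale,
                category_counts = cat_counts),
    parameters = list(cutoff_k = config$cutoff_k,
                      min_lesioned = config$min_lesioned,
                      display_threshold_pct = config$display_threshold_pct,
                      rscale = config$rscale,
                      correlation_prior_scale =
                        config$correlation_prior_scale,
                      seed = config$seed,
                      simulate = config$simulate))
  if (!is.null(subtraction))
    out$peak <- list(world_xyz = subtraction$peak$world_xyz,
                     value = subtraction$peak$value,
                     voxel_index = subtraction$peak$voxel_index)
  if (!is.null(correlations))
    out$correlations <- correlations
  out
}

write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prof <- result$profiles
  utils::write.table(prof, file.path(out_dir, "profiles.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(result$maps)) {
    save_stat_map(result$maps$abnormal_overlap,
                  file.path(out_dir, "overlap_abnormal.nii"))
    save_stat_map(result$maps$normal_overlap,
                  file.path(out_dir, "overlap_normal.nii"))
    save_stat_map(result$maps$subtraction,
                  file.path(out_dir, "subtraction.nii"))
    save_stat_map(result$maps$subtraction_thresholded,
                  file.path(out_dir, "subtraction_thresholded.nii"))
    jsonlite::write_json(
      list(world_xyz = result$peak$world_xyz, value = result$peak$value,
           voxel_index = result$peak$voxel_index),
      file.path(out_dir, "peak.json"), auto_unbox = TRUE, digits = NA)
  }
  save_stat_map(result$bldi$bf, file.path(out_dir, "bf10.nii"))
  save_stat_map(result$bldi$category, file.path(out_dir, "bf_category.nii"))
  utils::write.table(result$bldi$table, file.path(out_dir, "bldi.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$correlations))
    utils::write.table(result$correlations,
                       file.path(out_dir, "correlations.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

#' Brain-behaviour correlation battery
#'
#' The standard rows: mean TDE against the dynamic PASS score and the line
#' bisection deviation; per-direction TDE against the matching COP
#' lateral-shift amplitude; plus partial correlations (covariates: SIAS
#' motor, SIAS sensory, line bisection) for the PASS and COP rows.
#' Complete cases only (listwise deletion per row); rows without the needed
#' covariates are skipped.
#'
#' @param profiles a labelled profile data.frame with covariate columns.
#' @param prior_scale stretched-beta width for the correlation BFs.
#' @return data.frame: pair, n, r, p, bf10, covariates (`""` for simple
#'   correlations), or NULL when no covariate columns are present.
#' @export
association_battery <- function(profiles, prior_scale = 0.707) {
  stroke <- profiles[profiles$group == "stroke", , drop = FALSE]
  has <- function(cols) all(cols %in% names(stroke))
  rows <- list()
  add_row <- function(pair, x, y, covariates = NULL, covnames = "") {
    ok <- stats::complete.cases(cbind(x, y, covariates))
    if (sum(ok) < max(4, NCOL(covariates) + 3)) return()
    res <- if (is.null(covariates))
      pearson(x[ok], y[ok], bf = TRUE, prior_scale = prior_scale)
    else
      partial_correlation(x[ok], y[ok], covariates[ok, , drop = FALSE],
                          bf = TRUE, prior_scale = prior_scale)
    rows[[length(rows) + 1L]] <<- data.frame(
      pair = pair, n = sum(ok), r = res$r, p = res$p_two_tailed,
      bf10 = res$bf10, covariates = covnames, stringsAsFactors = FALSE)
  }
  cop_shift <- function(maxcol) {
    if (!has(c("cop_static_cm", maxcol))) return(NULL)
    cop_lateral_shift(stroke$cop_static_cm, stroke[[maxcol]])
  }
  if (has("pass_dynamic"))
    add_row("tde_mean~pass_dynamic", stroke$tde_mean, stroke$pass_dynamic)
  if (has("line_bisection_mm"))
    add_row("tde_mean~line_bisection", stroke$tde_mean,
            stroke$line_bisection_mm)
  ipsi <- cop_shift("cop_max_ipsi_cm")
  if (!is.null(ipsi))
    add_row("tde_dir1~cop_shift_ipsi", stroke$tde_dir1, ipsi)
  contra <- cop_shift("cop_max_contra_cm")
  if (!is.null(contra))
    add_row("tde_dir2~cop_shift_contra", stroke$tde_dir2, contra)
  if (has(c("sias_motor", "sias_sensory", "line_bisection_mm"))) {
    Z <- as.matrix(stroke[, c("sias_motor", "sias_sensory",
                              "line_bisection_mm")])
    covnames <- "sias_motor+sias_sensory+line_bisection"
    if (has("pass_dynamic"))
      add_row("tde_mean~pass_dynamic", stroke$tde_mean, stroke$pass_dynamic,
              Z, covnames)
    if (!is.null(ipsi))
      add_row("tde_dir1~cop_shift_ipsi", stroke$tde_dir1, ipsi, Z, covnames)
    if (!is.null(contra))
      add_row("tde_dir2~cop_shift_contra", stroke$tde_dir2, contra, Z,
              covnames)
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.tde_analysis <- function(x, ...) {
  s <- x$group_tests$summary
  cat("Tilt-dependent SVBA lesion analysis\n")
  cat(sprintf("  controls: n = %d, TDE %.1f +/- %.1f deg\n", s$n[1L],
              s$tde_mean[1L], s$tde_sd[1L]))
  cat(sprintf("  stroke:   n = %d, TDE %.1f +/- %.1f deg\n", s$n[2L],
              s$tde_mean[2L], s$tde_sd[2L]))
  gt <- x$group_tests$tde_between_groups
  cat(sprintf("  group difference: t(%g) = %.2f, p = %.3f, d = %.2f\n",
              gt$df, gt$statistic, gt$p_two_tailed, gt$effect_size_d))
  cat(sprintf("  abnormality cut-off %.2f deg -> %d abnormal patient(s): %s\n",
              x$cutoff, length(x$abnormal_ids),
              paste(sort(x$abnormal_ids), collapse = ", ")))
  if (!is.null(x$peak))
    cat(sprintf("  subtraction peak %.0f%% at world (%.0f, %.0f, %.0f)\n",
                x$peak$value, x$peak$world_xyz[1L], x$peak$world_xyz[2L],
                x$peak$world_xyz[3L]))
  cat(sprintf("  BLDI: %d voxels tested, %d with BF10 >= 3\n",
              x$bldi$n_tested,
              sum(x$bldi$table$category == "substantial_H1")))
  invisible(x)
}

#' @export
summary.tde_analysis <- function(object, ...) {
  out <- object$summary
  class(out) <- "summary.tde_analysis"
  out
}

#' @export
print.summary.tde_analysis <- function(x, ...) {
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
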