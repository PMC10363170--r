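POSTURES <- c("upright", "left10", "right10")
COVARIATE_COLS <- c("sias_motor", "sias_sensory", "line_bisection_mm",
                    "pass_dynamic", "cop_static_cm", "cop_max_ipsi_cm",
                    "cop_max_contra_cm")

#' Read a behavioural table
#'
#' Accepts the two documented schemas, in CSV or TSV (sniffed from the
#' header line):
#' \describe{
#'   \item{long}{one row per trial: `participant_id, group, lesion_side,
#'     posture, adjustment` (+ optional covariate columns, constant within a
#'     participant). `posture` is one of `upright`, `left10`, `right10`.}
#'   \item{wide}{one row per participant: `participant_id, group,
#'     lesion_side, svba_upright, svba_left, svba_right` (+ covariates),
#'     holding raw (rightward-positive) trial-mean errors.}
#' }
#'
#' @param path path to a delimited text file (UTF-8, decimal point).
#' @return a data.frame in the schema found, with a `"format"` attribute
#'   (`"long"` or `"wide"`).
#' @export
read_behaviour <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  long_cols <- c("participant_id", "group", "lesion_side", "posture",
                 "adjustment")
  wide_cols <- c("participant_id", "group", "lesion_side", "svba_upright",
                 "svba_left", "svba_right")
  if (all(long_cols %in% names(df))) {
    attr(df, "format") <- "long"
  } else if (all(wide_cols %in% names(df))) {
    attr(df, "format") <- "wide"
  } else {
    stop("unrecognised behavioural schema; need columns ",
         paste(long_cols, collapse = ", "), " (long) or ",
         paste(wide_cols, collapse = ", "), " (wide)", call. = FALSE)
  }
  df
}

per_participant_covariates <- function(df) {
  cov_cols <- intersect(COVARIATE_COLS, names(df))
  if (length(cov_cols) == 0L) return(NULL)
  first <- !duplicated(df$participant_id)
  out <- df[first, c("participant_id", cov_cols), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build per-participant behavioural profiles
#'
#' Collapses a behavioural table (long or wide, see [read_behaviour()]) into
#' one row per participant holding the raw per-posture mean SVBA errors, the
#' oriented errors after the lesion-side sign convention, and the
#' tilt-dependent errors. Direction 1 is the leftward tilt for controls and
#' the ipsilesional tilt for stroke patients (the `left10` posture for
#' left-sided lesions, `right10` for right-sided); direction 2 is the
#' opposite tilt.
#'
#' @param behaviour a data.frame from [read_behaviour()] (or of the same
#'   shape; the `"format"` attribute is re-detected when absent).
#' @param expected_trials per-posture trial count below which a warning is
#'   issued (long format only).
#' @return data.frame with columns `participant_id, group, lesion_side,
#'   svba_upright, svba_left, svba_right` (raw), `svba_upright_oriented,
#'   svba_dir1, svba_dir2` (oriented), `tde_dir1, tde_dir2, tde_mean`, any
#'   covariate columns present, and `label` (filled by
#'   [label_profiles()], `"unlabelled"` here).
#' @export
behavioural_profiles <- function(behaviour, expected_trials = 10L) {
  fmt <- attr(behaviour, "format")
  if (is.null(fmt))
    fmt <- if ("posture" %in% names(behaviour)) "long" else "wide"
  if (fmt == "long") {
    bad <- setdiff(unique(behaviour$posture), POSTURES)
    if (length(bad))
      stop("unknown posture label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    ids <- unique(behaviour$participant_id)
    rows <- lapply(ids, function(id) {
      sub <- behaviour[behaviour$participant_id == id, , drop = FALSE]
      miss <- setdiff(POSTURES, sub$posture)
      if (length(miss))
        stop(sprintf("participant %s lacks posture(s): %s", id,
                     paste(miss, collapse = ", ")), call. = FALSE)
      means <- vapply(POSTURES, function(p)
        mean_svba_error(sub$adjustment[sub$posture == p], expected_trials),
        numeric(1))
      data.frame(participant_id = id, group = sub$group[1L],
                 lesion_side = sub$lesion_side[1L],
                 svba_upright = means[["upright"]],
                 svba_left = means[["left10"]],
                 svba_right = means[["right10"]],
                 stringsAsFactors = FALSE)
    })
    wide <- do.call(rbind, rows)
    covs <- per_participant_covariates(behaviour)
    if (!is.null(covs)) wide <- merge(wide, covs, by = "participant_id",
                                      sort = FALSE)
  } else {
    wide <- behaviour
  }

  n <- nrow(wide)
  ori_up <- ori_d1 <- ori_d2 <- numeric(n)
  for (i in seq_len(n)) {
    grp <- wide$group[i]
    side <- wide$lesion_side[i]
    if (grp == "control" && side != "none")
      stop("controls must have lesion_side = 'none' (participant ",
           wide$participant_id[i], ")", call. = FALSE)
    raw <- c(wide$svba_upright[i], wide$svba_left[i], wide$svba_right[i])
    ori <- apply_sign_convention(raw, grp, side)
    # direction 1 = leftward (controls) / ipsilesional (patients)
    if (grp == "control" || side == "left") {
      ori_d1[i] <- ori[2L]; ori_d2[i] <- ori[3L]
    } else {
      ori_d1[i] <- ori[3L]; ori_d2[i] <- ori[2L]
    }
    ori_up[i] <- ori[1L]
  }
  tde <- mapply(function(u, d1, d2) compute_tde(u, d1, d2),
                ori_up, ori_d1, ori_d2)
  wide$svba_upright_oriented <- ori_up
  wide$svba_dir1 <- ori_d1
  wide$svba_dir2 <- ori_d2
  wide$tde_dir1 <- tde[1L, ]
  wide$tde_dir2 <- tde[2L, ]
  wide$tde_mean <- (wide$tde_dir1 + wide$tde_dir2) / 2
  wide$label <- "unlabelled"
  rownames(wide) <- NULL
  wide
}

#' Label stroke patients by the control-referenced TDE cut-off
#'
#' Computes the abnormality cut-off from the control rows of a profile table
#' (unrounded control statistics) and labels every stroke row `"abnormal"` or
#' `"normal"`; controls stay `"unlabelled"`.
#'
#' @param profiles a profile data.frame from [behavioural_profiles()].
#' @param k cut-off multiplier in control-SD units (default 1.5).
#' @return `profiles` with the `label` column filled; attributes
#'   `control_mean`, `control_sd`, `cutoff` record the reference values.
#' @export
label_profiles <- function(profiles, k = 1.5) {
  ctrl <- profiles$tde_mean[profiles$group == "control"]
  if (length(ctrl) < 2)
    stop("need >= 2 control participants to define the cut-off",
         call. = FALSE)
  m <- mean(ctrl); s <- stats::sd(ctrl)
  stroke <- profiles$group == "stroke"
  profiles$label[stroke] <-
    classify_abnormal(profiles$tde_mean[stroke], m, s, k)
  attr(profiles, "control_mean") <- m
  attr(profiles, "control_sd") <- s
  attr(profiles, "cutoff") <- abnormality_cutoff(m, s, k)
  profiles
}

#' Group-level behavioural tests on a profile table
#'
#' Reproduces the standard battery: one-sample t of the upright SVBA error
#' against zero in each group, a paired t between tilt directions in each
#' group, and the pooled two-sample t comparing mean TDE between groups.
#'
#' @param profiles a profile data.frame from [behavioural_profiles()].
#' @return named list of `group_test` objects plus group summary statistics.
#' @export
group_tests <- function(profiles) {
  ctrl <- profiles[profiles$group == "control", , drop = FALSE]
  strk <- profiles[profiles$group == "stroke", , drop = FALSE]
  out <- list(
    upright_control = one_sample_t(ctrl$svba_upright_oriented),
    upright_stroke = one_sample_t(strk$svba_upright_oriented),
    tilt_direction_control = paired_t(ctrl$tde_dir1, ctrl$tde_dir2),
    tilt_direction_stroke = paired_t(strk$tde_dir1, strk$tde_dir2),
    tde_between_groups = two_sample_pooled_t(ctrl$tde_mean, strk$tde_mean)
  )
  out$summary <- data.frame(
    group = c("control", "stroke"),
    n = c(nrow(ctrl), nrow(strk)),
    tde_mean = c(mean(ctrl$tde_mean), mean(strk$tde_mean)),
    tde_sd = c(stats::sd(ctrl$tde_mean), stats::sd(strk$tde_mean))
  )
  out
}
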