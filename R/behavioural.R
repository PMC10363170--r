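#' Mean SVBA error across trials of one posture
#'
#' The subjective visual body axis (SVBA) error of a trial is the signed
#' angular deviation (degrees) of the adjusted visual line from the true body
#' axis. The per-posture score is the arithmetic mean over trials; the
#' reference protocol uses ten trials per posture, but any number >= 1 is
#' accepted (a warning is issued below ten).
#'
#' @param adjustments numeric vector of per-trial signed angles in degrees,
#'   each in (-90, 90].
#' @param expected_trials trial count below which a warning is issued.
#' @return mean error in degrees.
#' @export
mean_svba_error <- function(adjustments, expected_trials = 10L) {
  if (length(adjustments) == 0L)
    stop("no trials supplied: cannot compute a mean SVBA error", call. = FALSE)
  if (!is.numeric(adjustments) || any(!is.finite(adjustments)))
    stop("SVBA adjustments must be finite numeric angles", call. = FALSE)
  if (any(adjustments <= -90 | adjustments > 90))
    stop("SVBA adjustments must lie in (-90, 90] degrees", call. = FALSE)
  if (length(adjustments) < expected_trials)
    warning(sprintf("only %d trials (expected %d)", length(adjustments),
                    expected_trials), call. = FALSE)
  mean(adjustments)
}

#' Orient SVBA errors by lesion side
#'
#' Raw SVBA errors are signed rightward-positive. For stroke patients the
#' signs are transformed so that positive means an ipsilesional bias: patients
#' with a left-sided lesion have all error signs flipped, right-sided lesions
#' (and controls) are left unchanged.
#'
#' @param errors numeric vector of raw SVBA errors (degrees, rightward
#'   positive), typically the upright/left-tilt/right-tilt triple.
#' @param group `"control"` or `"stroke"`.
#' @param lesion_side `"left"`, `"right"`, or `"none"` (controls only).
#' @return oriented errors (degrees; for patients positive = ipsilesional).
#' @export
apply_sign_convention <- function(errors, group, lesion_side = "none") {
  group <- match.arg(group, c("control", "stroke"))
  lesion_side <- match.arg(lesion_side, c("left", "right", "none"))
  if (group == "control") {
    if (lesion_side != "none")
      stop("controls must have lesion_side = 'none'", call. = FALSE)
    return(errors)
  }
  if (lesion_side == "none")
    stop("stroke patients require a lesion side for the sign convention",
         call. = FALSE)
  if (lesion_side == "left") -errors else errors
}

#' Tilt-dependent errors from per-posture SVBA errors
#'
#' TDE quantifies the shift of the SVBA induced by 10 degree whole-body roll
#' tilt, relative to the upright SVBA. Direction 1 is the leftward tilt for
#' controls and the ipsilesional tilt for patients; its sign is reversed so
#' that positive TDE corresponds to an SVBA shift in the direction of body
#' tilt:
#' \deqn{TDE_1 = -(SVBA_1 - SVBA_{upright}), \quad TDE_2 = SVBA_2 - SVBA_{upright}}
#' Both outputs are invariant under adding a common constant to all three
#' inputs.
#'
#' @param svba_upright,svba_dir1,svba_dir2 per-posture mean SVBA errors
#'   (degrees, oriented; see [apply_sign_convention()]).
#' @return named numeric vector `c(tde_dir1, tde_dir2)` in degrees.
#' @export
compute_tde <- function(svba_upright, svba_dir1, svba_dir2) {
  v <- c(svba_upright, svba_dir1, svba_dir2)
  if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)))
    stop("all three SVBA values must be finite scalars", call. = FALSE)
  c(tde_dir1 = -(svba_dir1 - svba_upright),
    tde_dir2 = svba_dir2 - svba_upright)
}

#' Classify abnormally reduced TDE against a control reference
#'
#' The cut-off is `k` standard deviations below the control-group mean TDE
#' (default 1.5 SD, a conservative convention in neuropsychological studies).
#' A patient is abnormal iff their mean TDE falls strictly below the cut-off;
#' ties classify as normal.
#'
#' @param tde_means numeric vector of per-patient mean TDEs (degrees).
#' @param control_mean,control_sd control-group mean and SD of TDE (degrees);
#'   `control_sd` must be positive.
#' @param k cut-off multiplier (SD units below the control mean).
#' @return character vector of labels, `"abnormal"` or `"normal"`.
#' @export
classify_abnormal <- function(tde_means, control_mean, control_sd, k = 1.5) {
  if (!is.finite(control_sd) || control_sd <= 0)
    stop("control_sd must be positive", call. = FALSE)
  cutoff <- control_mean - k * control_sd
  ifelse(tde_means < cutoff, "abnormal", "normal")
}

#' @rdname classify_abnormal
#' @export
abnormality_cutoff <- function(control_mean, control_sd, k = 1.5) {
  if (!is.finite(control_sd) || control_sd <= 0)
    stop("control_sd must be positive", call. = FALSE)
  control_mean - k * control_sd
}

group_test_result <- function(statistic, df, p, d = NA_real_, kind) {
  structure(list(statistic = statistic, df = df, p_two_tailed = p,
                 effect_size_d = d, test_kind = kind),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s t-test: t(%g) = %.3f, p = %.4f%s\n",
              gsub("_", " ", x$test_kind), x$df, x$statistic, x$p_two_tailed,
              if (is.finite(x$effect_size_d))
                sprintf(", d = %.3f", x$effect_size_d) else ""))
  invisible(x)
}

#' One-sample t-test (two-tailed), from data or summary statistics
#'
#' @param x numeric vector of observations; omit when supplying summaries.
#' @param n,mean,sd summary statistics, used when `x` is `NULL`.
#' @param mu0 null-hypothesis mean.
#' @return a `group_test` object: statistic, df, two-tailed p, Cohen's d.
#' @export
one_sample_t <- function(x = NULL, n = NULL, mean = NULL, sd = NULL, mu0 = 0) {
  if (!is.null(x)) {
    n <- length(x); mean <- base::mean(x); sd <- stats::sd(x)
  }
  if (is.null(n) || is.null(mean) || is.null(sd))
    stop("supply either x or all of (n, mean, sd)", call. = FALSE)
  if (n < 2) stop("one-sample t requires n >= 2", call. = FALSE)
  if (!is.finite(sd) || sd <= 0)
    stop("sample standard deviation must be positive", call. = FALSE)
  tstat <- (mean - mu0) / (sd / sqrt(n))
  df <- n - 1
  group_test_result(tstat, df, 2 * stats::pt(-abs(tstat), df),
                    (mean - mu0) / sd, "one_sample")
}

#' Pooled-variance two-sample t-test (two-tailed), from data or summaries
#'
#' Student's t with the pooled variance estimate, df = n1 + n2 - 2, matching
#' group comparisons whose reported df equals n1 + n2 - 2. Cohen's d uses the
#' pooled SD.
#'
#' @param x,y numeric vectors; omit when supplying summaries.
#' @param n1,mean1,sd1,n2,mean2,sd2 per-group summary statistics.
#' @return a `group_test` object.
#' @export
two_sample_pooled_t <- function(x = NULL, y = NULL,
                                n1 = NULL, mean1 = NULL, sd1 = NULL,
                                n2 = NULL, mean2 = NULL, sd2 = NULL) {
  if (!is.null(x) && !is.null(y)) {
    n1 <- length(x); mean1 <- mean(x); sd1 <- stats::sd(x)
    n2 <- length(y); mean2 <- mean(y); sd2 <- stats::sd(y)
  }
  if (any(vapply(list(n1, mean1, sd1, n2, mean2, sd2), is.null, logical(1))))
    stop("supply either (x, y) or all six summary statistics", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 <= 0 && sd2 <= 0) stop("pooled variance is zero", call. = FALSE)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  tstat <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  group_test_result(tstat, df, 2 * stats::pt(-abs(tstat), df),
                    (mean1 - mean2) / sp, "two_sample_pooled")
}

#' Paired t-test (two-tailed)
#'
#' One-sample t-test on the element-wise differences against zero; Cohen's d
#' is mean(diff)/sd(diff).
#'
#' @param a,b paired numeric vectors of equal length >= 2.
#' @return a `group_test` object.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(a) < 2) stop("paired t requires n >= 2", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences: t undefined", call. = FALSE)
  res <- one_sample_t(d)
  res$test_kind <- "paired"
  res
}

#' Lateral centre-of-pressure shift
#'
#' Difference between the maximum COP position reached during a lateral trunk
#' tilt and the static sitting COP position, in cm, signed so that positive
#' means a shift toward the tilt side.
#'
#' @param static_cop_cm COP position during quiet upright sitting (cm).
#' @param max_tilt_cop_cm most deviated COP position during the tilt (cm).
#' @return shift amplitude in cm.
#' @export
cop_lateral_shift <- function(static_cop_cm, max_tilt_cop_cm) {
  if (!all(is.finite(c(static_cop_cm, max_tilt_cop_cm))))
    stop("COP positions must be finite", call. = FALSE)
  max_tilt_cop_cm - static_cop_cm
}
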