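## Assay analytics: standard curves, activity calls against negative
## controls, specific activity in U/mg, temperature/pH optima and
## residual-activity time courses. One enzyme unit (U) is 1 umol of
## product (reducing sugar or p-nitrophenol) released per minute;
## specific activity is U per mg protein.

#' Fit a linear standard curve
#'
#' Ordinary least squares of absorbance on concentration (with
#' intercept). Refuses curves with a nonpositive slope.
#'
#' @param concentrations analyte concentrations (>= 3 distinct values).
#' @param absorbances matching absorbances.
#' @return list of class `standardCurve`: `slope`, `intercept`, `r2`.
#' @examples
#' fitStandardCurve(0:4, 2 * (0:4))  # slope 2, intercept 0, r2 1
#' @export
fitStandardCurve <- function(concentrations, absorbances) {
  if (length(concentrations) < 3L ||
      length(concentrations) != length(absorbances))
    stop("need >= 3 matched points", call. = FALSE)
  if (length(unique(concentrations)) < 2L)
    stop("concentrations have zero variance", call. = FALSE)
  fit <- lm(absorbances ~ concentrations)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("standard curve rejected: slope must be positive", call. = FALSE)
  res <- absorbances - stats::fitted(fit)
  tss <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r2 = r2), class = "standardCurve")
}

#' @export
print.standardCurve <- function(x, ...) {
  cat(sprintf("standard curve: A = %.4f + %.4f x conc (r2 = %.4f)\n",
              x$intercept, x$slope, x$r2))
  invisible(x)
}

#' Call enzymatic activity against the negative control
#'
#' Positive iff the sample mean strictly exceeds
#' `1.5 x (control mean + control SD)` -- i.e. the product exceeds the
#' negative control plus one standard deviation by at least 50%. The SD
#' is the sample standard deviation (n - 1), so at least two control
#' wells are required; duplicates suffice. The alternative reading of
#' the rule, `control mean + 1.5 x control SD`, is available as
#' `rule = "sd-scaled"`. The call is invariant to rescaling all wells
#' by a positive constant.
#'
#' @param sample_wells sample absorbances (>= 1).
#' @param control_wells negative-control absorbances (>= 2).
#' @param rule `"scaled-sum"` (default) or `"sd-scaled"`.
#' @return list: `positive`, `sample_mean`, `control_mean`,
#'   `control_sd`, `threshold`, `rule`.
#' @export
callActivity <- function(sample_wells, control_wells,
                         rule = c("scaled-sum", "sd-scaled")) {
  rule <- match.arg(rule)
  if (length(sample_wells) < 1L)
    stop("need at least one sample well", call. = FALSE)
  if (length(control_wells) < 2L)
    stop("need >= 2 control wells (SD undefined otherwise)", call. = FALSE)
  cm <- mean(control_wells)
  cs <- sd(control_wells)
  thr <- if (rule == "scaled-sum") 1.5 * (cm + cs) else cm + 1.5 * cs
  sm <- mean(sample_wells)
  list(positive = sm > thr, sample_mean = sm, control_mean = cm,
       control_sd = cs, threshold = thr, rule = rule)
}

#' Specific activity from an absorbance change
#'
#' Inverts the standard curve to product concentration, converts to
#' umol via the reaction volume, to U (umol/min) via the reaction time,
#' and to U/mg via the protein mass:
#' `U/mg = ((deltaA - intercept) / slope x volume_ml) / minutes / mg`.
#' Blank the absorbance (subtract the substrate-only blank) before
#' calling unless the curve's intercept already absorbs it.
#'
#' @param delta_absorbance measured absorbance (blanked as appropriate).
#' @param curve a `standardCurve` (absorbance per umol/ml).
#' @param reaction_minutes reaction time (> 0).
#' @param reaction_volume_ml reaction volume in ml (> 0).
#' @param protein_mg protein mass in mg (> 0).
#' @return specific activity in U/mg.
#' @export
specificActivity <- function(delta_absorbance, curve, reaction_minutes,
                             reaction_volume_ml, protein_mg) {
  stopifnot(inherits(curve, "standardCurve"))
  assertScalarNumeric(reaction_minutes, "reaction_minutes")
  assertScalarNumeric(reaction_volume_ml, "reaction_volume_ml")
  if (reaction_minutes <= 0 || reaction_volume_ml <= 0)
    stop("time and volume must be positive", call. = FALSE)
  if (!is.numeric(protein_mg) || length(protein_mg) != 1L ||
      protein_mg <= 0)
    stop("'protein_mg' must be positive", call. = FALSE)
  conc <- (delta_absorbance - curve$intercept) / curve$slope  # umol/ml
  umol <- conc * reaction_volume_ml
  (umol / reaction_minutes) / protein_mg
}

#' Optimum condition and relative-activity curve
#'
#' The optimum is the argmax of activity over conditions (temperature
#' grid or pH grid); ties report the lower condition value with a flag.
#' Relative activity is 100 x activity / max, so the optimum reads
#' 100%.
#'
#' @param conditions numeric grid (>= 3 values, e.g. 30-70 degC in 5-deg
#'   steps, or pH 3-10).
#' @param activities matching activities, not all zero.
#' @return list: `optimum`, `tie`, `relative` (data.frame `condition`,
#'   `relative_pct`).
#' @export
profileOptimum <- function(conditions, activities) {
  if (length(conditions) < 3L || length(conditions) != length(activities))
    stop("need >= 3 matched conditions", call. = FALSE)
  if (all(activities <= 0))
    stop("all activities are zero", call. = FALSE)
  mx <- max(activities)
  at <- conditions[activities == mx]
  list(optimum = min(at), tie = length(at) > 1L,
       relative = data.frame(condition = conditions,
                             relative_pct = 100 * activities / mx))
}

#' Residual activity over a time course
#'
#' `residual(t) = 100 x activity(t) / baseline`; also flags whether the
#' sequence is nonincreasing within a tolerance (monotone decay, the
#' expected thermal-inactivation shape).
#'
#' @param times timepoints (nonempty).
#' @param activities activities at `times`.
#' @param baseline untreated (time-zero) activity (> 0).
#' @param tol nonmonotonicity tolerance in percentage points (default 1).
#' @return data.frame `time`, `residual_pct`, with attribute
#'   `monotone_decay`.
#' @export
residualActivity <- function(times, activities, baseline, tol = 1) {
  if (!length(times) || length(times) != length(activities))
    stop("empty or mismatched time course", call. = FALSE)
  if (!is.numeric(baseline) || length(baseline) != 1L || baseline <= 0)
    stop("'baseline' must be > 0", call. = FALSE)
  o <- order(times)
  res <- 100 * activities[o] / baseline
  out <- data.frame(time = times[o], residual_pct = res)
  attr(out, "monotone_decay") <- all(diff(res) <= tol)
  out
}
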