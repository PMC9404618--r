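#' Decision thresholds: ROPE, MCID, and large-effect margins
#'
#' Assembles the thresholds used to turn posterior draws into clinically
#' interpretable probabilities:
#'
#' * the region of practical equivalence (ROPE) on the OR scale, derived from a
#'   standardized mean difference of `cohens_d` via the logistic-distribution
#'   conversion factor `pi/sqrt(3)` (log(OR) half-width `cohens_d * pi/sqrt(3)`,
#'   0.18 for d = 0.1, i.e. OR 0.83 to 1.19);
#' * the minimal clinically important difference (MCID): an absolute risk
#'   reduction of `mcid_abs` over a `baseline` event rate, converted to an OR
#'   with [or_from_risks()] (0.84 for 4 points over 40%), plus a day margin for
#'   the bounded day-count endpoints;
#' * the "large effect" margin: `large_multiplier` times the published MCID
#'   log-OR magnitude of 0.175, i.e. OR bounds exp(-0.2625)/exp(+0.2625) =
#'   0.77/1.30 at the default multiplier 1.5.
#'
#' Unrounded values are stored; rounding (ORs to 2 decimals) is applied only by
#' the report renderer. The printed MCID magnitude 0.175 is used for the large
#' margin, rather than the exact `-log(0.84375) = 0.1699`, because the
#' published 0.77/1.30 bounds follow from the printed value; both conventions
#' are retained deliberately (exact for computation, printed for margins).
#'
#' @param cohens_d Cohen's d defining the ROPE half-width; non-negative.
#' @param mcid_abs MCID as an absolute risk reduction (fraction), in (0, baseline).
#' @param baseline Baseline event probability.
#' @param large_multiplier Multiplier on the MCID log-OR defining a large effect.
#' @param mcid_days MCID margin for day-count endpoints, in days.
#' @param mcid_logor_printed Published MCID log-OR magnitude used for the large
#'   margin (default 0.175).
#' @return An object of class `threshold_set` with fields `rope_or`,
#'   `large_or`, `mcid_or`, `mcid_abs_diff`, `mcid_days`, `equivalence_days_1`,
#'   `cohens_d_rope`.
#' @examples
#' build_thresholds()
#' @export
build_thresholds <- function(cohens_d = 0.1, mcid_abs = 0.04, baseline = 0.40,
                             large_multiplier = 1.5, mcid_days = 3,
                             mcid_logor_printed = 0.175) {
  check_number(cohens_d, "cohens_d", lower = 0)
  check_number(baseline, "baseline", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(mcid_abs, "mcid_abs", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  if (mcid_abs >= baseline) stop_invalid("mcid_abs", "must be below the baseline rate")
  check_number(large_multiplier, "large_multiplier", lower = 1)
  check_number(mcid_days, "mcid_days", lower = 0, strict_lower = TRUE)
  check_number(mcid_logor_printed, "mcid_logor_printed", lower = 0, strict_lower = TRUE)

  rope_half <- cohens_d * pi / sqrt(3)
  large_half <- large_multiplier * mcid_logor_printed
  ts <- structure(list(
    rope_or = c(lower = exp(-rope_half), upper = exp(rope_half)),
    large_or = c(lower = exp(-large_half), upper = exp(large_half)),
    mcid_or = or_from_risks(baseline, baseline - mcid_abs),
    mcid_abs_diff = mcid_abs,
    mcid_days = mcid_days,
    equivalence_days_1 = 1,
    cohens_d_rope = cohens_d
  ), class = "threshold_set")
  validate_thresholds(ts)
  ts
}

validate_thresholds <- function(ts) {
  if (!inherits(ts, "threshold_set")) stop_invalid("thresholds", "must be a threshold_set")
  r <- ts$rope_or; l <- ts$large_or
  if (!(r[["lower"]] <= 1 && 1 <= r[["upper"]])) {
    stop_invalid("rope_or", "must bracket the null OR of 1")
  }
  if (ts$cohens_d_rope > 0 && !(l[["lower"]] < r[["lower"]] && l[["upper"]] > r[["upper"]])) {
    stop_invalid("large_or", "large-effect margin must lie outside the ROPE")
  }
  invisible(ts)
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>\n")
  cat(sprintf("  ROPE (OR):        %.2f - %.2f  (Cohen's d %.2g)\n",
              x$rope_or[["lower"]], x$rope_or[["upper"]], x$cohens_d_rope))
  cat(sprintf("  large effect OR:  < %.2f or > %.2f\n",
              x$large_or[["lower"]], x$large_or[["upper"]]))
  cat(sprintf("  MCID:             OR < %.2f (= %g-point absolute reduction); %g days\n",
              x$mcid_or, 100 * x$mcid_abs_diff, x$mcid_days))
  invisible(x)
}
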