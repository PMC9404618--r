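# Posterior metric layer: every quantity the reporting surface needs --
# highest density intervals, probability of direction, ROPE mass, MCID and
# large-effect probabilities, and covariate-marginalized risk differences.

#' Highest density interval of a posterior sample
#'
#' The shortest contiguous interval over the sorted draws containing
#' `ceiling(mass * N)` draws; ties are broken by the earliest (lowest) start.
#'
#' @param draws Numeric sample, at least 100 draws.
#' @param mass Interval mass in (0, 1); default 0.95.
#' @return Length-2 numeric `c(lower, upper)`.
#' @examples
#' hdi(rnorm(1000))
#' @export
hdi <- function(draws, mass = 0.95) {
  if (!is.numeric(draws) || length(draws) < 100) {
    stop_invalid("draws", "need at least 100 draws")
  }
  check_number(mass, "mass", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)  # earliest start on ties
  c(lower = x[i], upper = x[i + k - 1])
}

#' Probability of direction
#'
#' The fraction of draws sharing the sign of the sample median (on the
#' log(OR) or difference scale); lies in `[0.5, 1]` up to ties at zero. When
#' the median is exactly zero the direction is undefined and 0.5 is returned.
#'
#' @param draws Numeric sample, at least 100 draws.
#' @return A probability.
#' @export
prob_direction <- function(draws) {
  if (!is.numeric(draws) || length(draws) < 100) {
    stop_invalid("draws", "need at least 100 draws")
  }
  med <- stats::median(draws)
  if (med > 0) mean(draws > 0) else if (med < 0) mean(draws < 0) else 0.5
}

#' Fraction of the posterior inside the region of practical equivalence
#'
#' @param draws Sample of the treatment effect on the log(OR) scale.
#' @param thresholds A [build_thresholds()] object; its `rope_or` bounds are
#'   applied strictly (draws exactly on a bound do not count as inside).
#' @return The fraction of all draws with OR strictly inside the ROPE.
#' @export
rope_fraction <- function(draws, thresholds) {
  validate_thresholds(thresholds)
  if (!is.numeric(draws) || !length(draws)) stop_invalid("draws", "must be numeric")
  lo <- log(thresholds$rope_or[["lower"]])
  hi <- log(thresholds$rope_or[["upper"]])
  mean(draws > lo & draws < hi)
}

# collapse the observed adjuster rows to unique 0/1 patterns with weights;
# keeps g-computation O(#patterns) instead of O(n) per draw
covariate_patterns <- function(data, covariates) {
  if (!length(covariates)) {
    return(list(X = matrix(0, 1, 0), w = 1))
  }
  X <- as.matrix(data[covariates])
  storage.mode(X) <- "double"
  key <- apply(X, 1, paste, collapse = ",")
  tab <- table(key)
  pats <- do.call(rbind, lapply(strsplit(names(tab), ","), as.numeric))
  colnames(pats) <- covariates
  list(X = pats, w = as.numeric(tab) / nrow(X))
}

#' Marginal absolute risk difference by g-computation
#'
#' For each posterior draw, averages the inverse-logit predictions over the
#' observed adjuster distribution with the treatment indicator set to 1 and to
#' 0 (site random effects excluded, i.e. predictions for a typical site), and
#' returns the posterior sample of differences in event probability
#' (accelerated minus standard).
#'
#' @param draws A `posterior_draws` object from [fit_binary_model()].
#' @param data The dataset the model was fitted to (or any dataset carrying
#'   the same adjuster columns to standardize over).
#' @return Numeric vector, one risk difference per posterior draw.
#' @export
marginal_risk_difference <- function(draws, data) {
  if (!inherits(draws, "posterior_draws")) stop_invalid("draws", "must be posterior_draws")
  covs <- draws$meta$covariates
  if (length(setdiff(covs, names(data)))) {
    stop_invalid("data", "adjuster columns do not match the fitted model")
  }
  b0 <- draws_of(draws, "b_intercept")
  th <- draws_of(draws, "theta")
  pat <- covariate_patterns(data, covs)
  lin <- if (length(covs)) {
    B <- vapply(paste0("b_", covs), function(p) draws_of(draws, p),
                numeric(length(b0)))                       # draws x K
    tcrossprod(B, pat$X)                                   # draws x patterns
  } else {
    matrix(0, length(b0), 1)
  }
  eta0 <- lin + b0
  drop(stats::plogis(eta0 + th) %*% pat$w - stats::plogis(eta0) %*% pat$w)
}

#' Summarize a binary-endpoint posterior into the reporting metrics
#'
#' Assembles the full metric bundle for one endpoint-prior combination: the
#' posterior median OR and its 95% HDI, probability of benefit `P(OR < 1)`,
#' probability of direction, %ROPE, probability the effect is not large,
#' probability the OR beats the MCID threshold, the probability of an
#' absolute risk reduction beyond the MCID, and the covariate-marginalized
#' absolute difference (median and 95% HDI, percentage points). The median OR
#' is the posterior median of the conditional coefficient `exp(theta)`; the
#' absolute difference is marginal over the observed adjuster distribution.
#'
#' As a secondary reading of "significance by practical equivalence" the
#' summary also carries an HDI+ROPE decision (`rope_decision`): "equivalent"
#' if the 95% HDI of the OR lies entirely inside the ROPE, "different" if
#' entirely outside, else "undecided". The %ROPE field is the reported
#' quantity; the decision rule is labelled separately.
#'
#' @param draws A `posterior_draws` from [fit_binary_model()].
#' @param data The dataset the model was fitted to.
#' @param thresholds A [build_thresholds()] object.
#' @param force Summarize even if the convergence gates failed
#'   (default `FALSE`, which errors on a non-converged fit).
#' @return An object of class `effect_summary`.
#' @export
summarize_effect <- function(draws, data, thresholds = build_thresholds(),
                             force = FALSE) {
  if (!inherits(draws, "posterior_draws")) stop_invalid("draws", "must be posterior_draws")
  validate_thresholds(thresholds)
  if (!draws$diagnostics$converged && !force) {
    stop("fit did not meet the convergence gates (", draws$diagnostics$message,
         "); pass force = TRUE to summarize anyway", call. = FALSE)
  }
  th <- draws_of(draws, "theta")
  or <- exp(th)
  rd <- marginal_risk_difference(draws, data)
  hdi_or <- hdi(or, 0.95)
  rope <- thresholds$rope_or
  large <- thresholds$large_or
  decision <- if (hdi_or[["lower"]] > rope[["lower"]] && hdi_or[["upper"]] < rope[["upper"]]) {
    "equivalent"
  } else if (hdi_or[["upper"]] < rope[["lower"]] || hdi_or[["lower"]] > rope[["upper"]]) {
    "different"
  } else "undecided"
  structure(list(
    prior = draws$meta$prior %||% NA_character_,
    outcome = draws$meta$outcome %||% NA_character_,
    median_or = stats::median(or),
    hdi95_or = hdi_or,
    p_benefit = mean(or < 1),
    prob_direction = prob_direction(th),
    pct_in_rope = rope_fraction(th, thresholds),
    p_not_large = mean(or > large[["lower"]] & or < large[["upper"]]),
    p_or_below_mcid = mean(or < thresholds$mcid_or),
    p_absdiff_beyond_mcid = mean(rd < -thresholds$mcid_abs_diff),
    absdiff_median = 100 * stats::median(rd),
    absdiff_hdi95 = 100 * hdi(rd, 0.95),
    converged = draws$diagnostics$converged,
    rope_decision = decision,
    n = draws$meta$n %||% NA_integer_
  ), class = "effect_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("<effect_summary> %s / %s prior (n = %s)%s\n",
              x$outcome, x$prior, x$n,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  cat(sprintf("  OR %.2f (95%% HDI %.2f-%.2f); P(benefit) %.2f; PD %.2f\n",
              x$median_or, x$hdi95_or[["lower"]], x$hdi95_or[["upper"]],
              x$p_benefit, x$prob_direction))
  cat(sprintf("  %%ROPE %.2f; P(not large) %.2f; P(OR < MCID) %.2f; P(diff < -MCID) %.2f\n",
              x$pct_in_rope, x$p_not_large, x$p_or_below_mcid, x$p_absdiff_beyond_mcid))
  cat(sprintf("  abs. difference %.2f%% (95%% HDI %.2f%% to %.2f%%)\n",
              x$absdiff_median, x$absdiff_hdi95[["lower"]], x$absdiff_hdi95[["upper"]]))
  invisible(x)
}

#' Between-arm difference in expected days from a ZOIB fit
#'
#' For each posterior draw, computes the expected endpoint value under each
#' arm assignment by plugging the arm-specific boundary probabilities and the
#' covariate-averaged beta mean into the mixture mean `zoi*coi + (1-zoi)*mu`
#' (g-computation over the observed adjuster rows, site random effects
#' excluded), rescales to days, and summarizes the accelerated-minus-standard
#' difference.
#'
#' @param draws A `posterior_draws` from [fit_zoib()].
#' @param data The dataset the model was fitted to.
#' @param spec The [zoib_model_spec()] used for the fit.
#' @param thresholds A [build_thresholds()]; supplies the 1-day equivalence
#'   window and the day MCID.
#' @param force Summarize even if the convergence gates failed.
#' @return An object of class `day_difference_summary` with the median
#'   difference, 95% HDI, `p_more_days` (accelerated arm has more days),
#'   `p_within_1day`, `p_within_mcid`, and `p_at_least_mcid_benefit`.
#' @export
day_difference <- function(draws, data, spec, thresholds = build_thresholds(),
                           force = FALSE) {
  if (!inherits(draws, "posterior_draws") || draws$model != "zoib") {
    stop_invalid("draws", "must be posterior_draws from fit_zoib()")
  }
  if (!inherits(spec, "zoib_model_spec")) stop_invalid("spec", "must be a zoib_model_spec")
  validate_thresholds(thresholds)
  if (!draws$diagnostics$converged && !force) {
    stop("fit did not meet the convergence gates (", draws$diagnostics$message,
         "); pass force = TRUE to summarize anyway", call. = FALSE)
  }
  covs <- draws$meta$covariates
  if (length(setdiff(covs, names(data)))) {
    stop_invalid("data", "adjuster columns do not match the fitted model")
  }
  g0 <- draws_of(draws, "zoi_intercept"); g1 <- draws_of(draws, "zoi_arm")
  h0 <- draws_of(draws, "coi_intercept"); h1 <- draws_of(draws, "coi_arm")
  c0 <- draws_of(draws, "mu_intercept"); ct <- draws_of(draws, "mu_arm")
  pat <- covariate_patterns(data, covs)
  lin <- if (length(covs)) {
    B <- vapply(paste0("mu_", covs), function(p) draws_of(draws, p),
                numeric(length(c0)))
    tcrossprod(B, pat$X)
  } else {
    matrix(0, length(c0), 1)
  }
  expected_days <- function(a) {
    zoi <- stats::plogis(g0 + g1 * a)
    coi <- stats::plogis(h0 + h1 * a)
    mu_bar <- drop(stats::plogis(lin + c0 + ct * a) %*% pat$w)
    draws$meta$scale_max * (zoi * coi + (1 - zoi) * mu_bar)
  }
  diff <- expected_days(1) - expected_days(0)
  structure(list(
    outcome = draws$meta$outcome,
    median_diff = stats::median(diff),
    hdi95 = hdi(diff, 0.95),
    p_more_days = mean(diff > 0),
    p_within_1day = mean(abs(diff) < thresholds$equivalence_days_1),
    p_within_mcid = mean(abs(diff) < thresholds$mcid_days),
    p_at_least_mcid_benefit = mean(diff >= thresholds$mcid_days),
    converged = draws$diagnostics$converged,
    n = draws$meta$n %||% NA_integer_
  ), class = "day_difference_summary")
}

#' @export
print.day_difference_summary <- function(x, ...) {
  cat(sprintf("<day_difference_summary> %s (n = %s)%s\n",
              x$outcome, x$n, if (!x$converged) "  [NOT CONVERGED]" else ""))
  cat(sprintf("  median difference %.2f days (95%% HDI %.2f to %.2f)\n",
              x$median_diff, x$hdi95[["lower"]], x$hdi95[["upper"]]))
  cat(sprintf("  P(more days) %.3f; P(within 1 day) %.3f; P(within MCID) %.3f; P(>= MCID benefit) %.3f\n",
              x$p_more_days, x$p_within_1day, x$p_within_mcid, x$p_at_least_mcid_benefit))
  invisible(x)
}
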