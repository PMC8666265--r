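## Monte Carlo performance metrics.
##
## Estimates from matched positive- and negative-effect simulation arms are
## folded into five summary metrics: directional bias (average error pooled
## over the two signed arms), magnitude bias (sign-folded average error,
## isolating systematic over/under-statement), root mean squared error,
## Type I error under the null, and the correct-rejection rate after a
## per-cell SE calibration that pins the Type I error at the nominal level.

check_nonempty <- function(x, what) {
  if (length(x) == 0 || all(is.na(x))) stop_arg(what, " must be non-empty")
  x[!is.na(x)]
}

#' Directional bias
#'
#' `(mean(pos - alpha_pos) + mean(neg - alpha_neg)) / 2`: the average
#' estimation error pooled over matched positive- and negative-effect
#' simulation arms.
#'
#' @param pos,neg estimate vectors from the positive/negative arms (NA,
#'   e.g. non-converged fits, dropped).
#' @param truth length-2 numeric `c(alpha_pos, alpha_neg)`.
#' @return Scalar bias on the estimates' scale.
#' @export
directional_bias <- function(pos, neg, truth) {
  pos <- check_nonempty(pos, "pos estimates")
  neg <- check_nonempty(neg, "neg estimates")
  (mean(pos - truth[1]) + mean(neg - truth[2])) / 2
}

#' Magnitude bias
#'
#' `(mean(pos - alpha_pos) - mean(neg - alpha_neg)) / 2`: the bias folded by
#' effect sign, so a positive value means the model exaggerates effect
#' magnitude in both directions (e.g. estimates +0.4 / -0.4 for a true
#' ±0.3 give +0.1) and a negative value means it attenuates.
#'
#' @inheritParams directional_bias
#' @return Scalar bias on the estimates' scale.
#' @export
magnitude_bias <- function(pos, neg, truth) {
  pos <- check_nonempty(pos, "pos estimates")
  neg <- check_nonempty(neg, "neg estimates")
  (mean(pos - truth[1]) - mean(neg - truth[2])) / 2
}

#' Root mean squared error
#'
#' `sqrt(mean((estimates - truth)^2))`.
#'
#' @param estimates estimate vector (NA dropped).
#' @param truth scalar true value.
#' @return Scalar RMSE.
#' @export
rmse <- function(estimates, truth) {
  estimates <- check_nonempty(estimates, "estimates")
  sqrt(mean((estimates - truth)^2))
}

#' Convert an effect on a model's native scale into national annual excess deaths
#'
#' Standardizes effects so linear and log-scale models are comparable: a
#' linear (per-100,000 rate) effect maps to `effect * population / 1e5`
#' national deaths per year; a log-scale effect (log rate ratio) maps to
#' `(exp(effect) - 1) * baseline_deaths`, with the baseline taken as the
#' panel's mean annual national death count.
#'
#' @param effect effect on the model's native scale.
#' @param link model link (`"linear"` treats the effect as a rate
#'   difference; `"log_linear"`, `"poisson"`, `"negbin"` as a log rate
#'   ratio).
#' @param panel_context list with `total_population` and
#'   `annual_baseline_deaths`; a `state_panel` may be given instead, from
#'   which both are computed.
#' @return National annual excess deaths (signed).
#' @export
standardize_to_deaths <- function(effect, link, panel_context) {
  if (inherits(panel_context, "state_panel") || is.data.frame(panel_context)) {
    panel_context <- list(
      total_population = sum(tapply(panel_context$population,
                                    panel_context$state, function(p) p[1])),
      annual_baseline_deaths = sum(panel_context$deaths) /
        length(unique(panel_context$year))
    )
  }
  if (is.null(panel_context$total_population) ||
      is.null(panel_context$annual_baseline_deaths)) {
    stop_arg("panel_context needs total_population and annual_baseline_deaths")
  }
  link <- match.arg(link, MODEL_LINKS)
  if (link == "linear") {
    effect * panel_context$total_population / 1e5
  } else {
    (exp(effect) - 1) * panel_context$annual_baseline_deaths
  }
}

#' Type I error rate
#'
#' Fraction of null-condition p-values below the significance level, among
#' converged fits.
#'
#' @param p_values p-values from null-effect simulations (NA dropped).
#' @param level significance level (default 0.05).
#' @param null_condition set to `FALSE` by callers passing non-null results
#'   by mistake; kept as an explicit guard.
#' @return Proportion in `[0, 1]`.
#' @export
type1_rate <- function(p_values, level = 0.05, null_condition = TRUE) {
  if (!isTRUE(null_condition)) {
    stop_arg("type1_rate is only defined for null-effect conditions")
  }
  p <- check_nonempty(p_values, "p_values")
  mean(p < level)
}

#' SE correction factor from null-condition test statistics
#'
#' Ratio of the empirical `1 - level` quantile (inverse-ECDF quantile) of
#' `|t|` under the null to the nominal two-sided critical value. Dividing
#' test statistics by this factor (equivalently, inflating SEs by it)
#' makes the empirical Type I error on the calibration sample exactly
#' `level` (up to the integer-count granularity of the sample).
#'
#' @param null_t test statistics from null-effect simulations of the same
#'   model/SE/condition cell (NA dropped).
#' @param level significance level (default 0.05).
#' @return Scalar correction factor.
#' @export
se_correction_factor <- function(null_t, level = 0.05) {
  t <- check_nonempty(null_t, "null test statistics")
  if (length(t) < 100) {
    warning("fewer than 100 null statistics; correction factor is noisy")
  }
  q <- stats::quantile(abs(t), probs = 1 - level, type = 1, names = FALSE)
  q / stats::qnorm(1 - level / 2)
}

#' Calibrated correct-rejection rate
#'
#' Fraction of converged effect-condition fits that are both statistically
#' significant after SE calibration (`|t| / factor` exceeding the nominal
#' two-sided critical value) and signed like the true effect. The
#' conventional 80% adequacy benchmark is reported as a flag.
#'
#' @param estimates effect-condition estimates (for the sign check).
#' @param t_stats matching test statistics.
#' @param factor SE correction factor from the matching null cell
#'   ([se_correction_factor()]).
#' @param truth_sign sign of the true effect (+1 or -1).
#' @param level significance level (default 0.05).
#' @return List with `rate` and `meets_benchmark` (rate >= 0.8).
#' @export
correct_rejection_rate <- function(estimates, t_stats, factor, truth_sign,
                                   level = 0.05) {
  if (!is.finite(factor) || factor <= 0) {
    stop_arg("correction factor must be positive")
  }
  keep <- !is.na(estimates) & !is.na(t_stats)
  estimates <- check_nonempty(estimates[keep], "estimates")
  t_stats <- t_stats[keep]
  crit <- stats::qnorm(1 - level / 2)
  hit <- (abs(t_stats) / factor > crit) &
    (base::sign(estimates) == base::sign(truth_sign))
  list(rate = mean(hit), meets_benchmark = mean(hit) >= 0.8)
}

#' Assemble one metrics row for a (model, SE method, condition) cell
#'
#' Combines the individual metric functions into the row emitted by the
#' experiment runner: native-scale and death-standardized directional and
#' magnitude bias (with percent versions dividing by the condition's
#' expected national excess deaths), RMSE per signed arm, Type I error from
#' the matching null cell, and the calibrated correct-rejection rate.
#'
#' @param pos,neg estimate vectors for the two signed arms.
#' @param t_pos,t_neg matching test statistics.
#' @param truth `c(alpha_pos, alpha_neg)` on the native scale.
#' @param null_p,null_t p-values and test statistics from the matching null
#'   cell.
#' @param link model link (for death standardization).
#' @param panel_context see [standardize_to_deaths()].
#' @param expected_excess expected national annual excess deaths for this
#'   condition (positive arm), the percent-standardization denominator.
#' @param level significance level.
#' @return One-row data.frame.
#' @export
condition_metrics <- function(pos, neg, t_pos, t_neg, truth, null_p, null_t,
                              link, panel_context, expected_excess,
                              level = 0.05) {
  db <- directional_bias(pos, neg, truth)
  mb <- magnitude_bias(pos, neg, truth)
  db_deaths <- standardize_to_deaths(truth[1] + db, link, panel_context) -
    standardize_to_deaths(truth[1], link, panel_context)
  mb_deaths <- standardize_to_deaths(truth[1] + mb, link, panel_context) -
    standardize_to_deaths(truth[1], link, panel_context)
  fac <- se_correction_factor(null_t, level)
  cr_pos <- correct_rejection_rate(pos, t_pos, fac, +1, level)
  cr_neg <- correct_rejection_rate(neg, t_neg, fac, -1, level)
  data.frame(
    directional_bias = db,
    magnitude_bias = mb,
    directional_bias_deaths = db_deaths,
    magnitude_bias_deaths = mb_deaths,
    pct_directional_bias = 100 * db_deaths / abs(expected_excess),
    pct_magnitude_bias = 100 * mb_deaths / abs(expected_excess),
    rmse_pos = rmse(pos, truth[1]),
    rmse_neg = rmse(neg, truth[2]),
    type1_rate = type1_rate(null_p, level),
    se_correction_factor = fac,
    correct_rejection_rate = (cr_pos$rate + cr_neg$rate) / 2,
    meets_power_benchmark = (cr_pos$rate + cr_neg$rate) / 2 >= 0.8
  )
}
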