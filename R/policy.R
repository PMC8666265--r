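## Policy assignment, exposure coding, and effect injection.
##
## Hypothetical ("placebo") policies are assigned to a random subset of
## states with a random enactment month/year; exposure A_it in [0,1] encodes
## the fraction of each year the policy was effective (instantaneous step) or
## a 3-year linear phase-in; known effects are injected into a no-policy
## baseline on either the additive rate scale or the multiplicative scale.

#' Randomly assign a hypothetical policy to k states
#'
#' Chooses `k` distinct treated states uniformly at random; for each, an
#' enactment year uniform on the window that leaves at least three full years
#' of data before and after (2002--2013 for a 1999--2016 panel) and an
#' enactment month uniform on 1..12 (policy starts the first day of the
#' month).
#'
#' @param panel a `state_panel` defining states and years.
#' @param k number of treated states, `1 <= k < n_states`.
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return A `policy_assignment`: list with `treated` (data.frame `state`,
#'   `year`, `month`) and `k`.
#' @export
assign_policy <- function(panel, k, seed) {
  states <- panel_states(panel)
  years <- panel_years(panel)
  n <- length(states)
  if (!(k >= 1 && k < n)) {
    stop_arg("k must satisfy 1 <= k < n_states (= ", n,
             "); k = n leaves no comparison group")
  }
  window <- (min(years) + 3):(max(years) - 3)
  if (length(window) < 1) {
    stop_arg("panel too short: no enactment year leaves 3 years on both sides")
  }
  with_seed(seed, {
    treated <- sample(states, k)
    out <- data.frame(
      state = treated,
      year = sample(window, k, replace = TRUE),
      month = sample(1:12, k, replace = TRUE),
      stringsAsFactors = FALSE
    )
    structure(list(treated = out, k = as.integer(k)),
              class = "policy_assignment")
  })
}

#' Code policy exposure for a panel
#'
#' Builds the exposure series A_it and its first difference (change coding)
#' from an assignment. Under `instantaneous` coding the enactment-year value
#' is the fraction of the year the policy was in effect, `(13 - month)/12`,
#' and 1 thereafter. Under `linear_3yr` the policy's effectiveness ramps
#' linearly by month, reaching 1 exactly 36 months after enactment; the
#' annual value is the mean of the 12 monthly values.
#'
#' @param assignment a [assign_policy()] result.
#' @param panel the panel the assignment refers to.
#' @param phase_in `"instantaneous"` or `"linear_3yr"`.
#' @return An `exposure_series`: data.frame with columns `state`, `year`,
#'   `A`, `A_change` (`NA` in the first panel year), ordered like the panel;
#'   attribute `phase_in`.
#' @export
code_exposure <- function(assignment, panel,
                          phase_in = c("instantaneous", "linear_3yr")) {
  phase_in <- match.arg(phase_in)
  states <- panel_states(panel)
  years <- panel_years(panel)
  tr <- assignment$treated
  if (any(!(tr$state %in% states))) {
    stop_arg("assignment includes states not in the panel")
  }
  if (any(tr$year < min(years) | tr$year > max(years))) {
    stop_arg("enactment year outside panel years")
  }
  grid <- expand.grid(year = years, state = states,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("state", "year")]
  grid$A <- 0
  for (r in seq_len(nrow(tr))) {
    s <- tr$state[r]; e_year <- tr$year[r]; e_month <- tr$month[r]
    idx <- grid$state == s
    yrs <- grid$year[idx]
    if (phase_in == "instantaneous") {
      A <- ifelse(yrs < e_year, 0,
                  ifelse(yrs > e_year, 1, (13 - e_month) / 12))
    } else {
      ## months since enactment at the start of calendar month mo of year y
      A <- vapply(yrs, function(y) {
        j <- 12 * (y - e_year) + (1:12 - e_month)
        mean(pmin(pmax(j, 0) / 36, 1) * (j >= 0))
      }, numeric(1))
    }
    grid$A[idx] <- A
  }
  ord <- order(grid$state, grid$year)
  grid <- grid[ord, ]
  rownames(grid) <- NULL
  grid$A_change <- stats::ave(grid$A, grid$state, FUN = function(a) {
    c(NA_real_, diff(a))
  })
  structure(grid, phase_in = phase_in, class = c("exposure_series", "data.frame"))
}

#' Specify a policy effect size
#'
#' Canonical effect sizes on the multiplicative scale: null (0), small
#' (±5%), medium (±15%), large (±25%). The additive per-100,000 analogue
#' `alpha_linear` is panel-dependent and is filled in by
#' [calibrate_alpha_linear()].
#'
#' @param size_class one of `"null"`, `"small"`, `"medium"`, `"large"`.
#' @param sign `"+"` or `"-"` (ignored for null).
#' @param alpha_linear optional pre-calibrated additive effect per 100,000.
#' @return An `effect_spec` list with `size_class`, `sign`, `s` (signed
#'   multiplicative effect), `m = 1 + s`, `alpha_linear`.
#' @export
effect_spec <- function(size_class = c("null", "small", "medium", "large"),
                        sign = c("+", "-"), alpha_linear = NULL) {
  size_class <- match.arg(size_class)
  sign <- match.arg(sign)
  base <- c(null = 0, small = 0.05, medium = 0.15, large = 0.25)[[size_class]]
  s <- if (sign == "-") -base else base
  if (size_class == "null") {
    s <- 0
    alpha_linear <- 0
  }
  if (!is.null(alpha_linear) && size_class != "null" &&
      base::sign(alpha_linear) != base::sign(s)) {
    stop_arg("alpha_linear must have the same sign as the multiplicative effect")
  }
  structure(list(size_class = size_class, sign = sign, s = s, m = 1 + s,
                 alpha_linear = alpha_linear),
            class = "effect_spec")
}

#' Calibrate the additive effect to match a multiplicative effect
#'
#' Finds the additive per-100,000 rate effect whose implied national excess
#' deaths equal those of the multiplicative effect `m = 1 + s` on the same
#' panel. For one assignment with exposure A, excess deaths are
#' `sum(A * s * Y0 * pop) / 1e5` under the multiplicative effect and
#' `alpha * sum(A * pop) / 1e5` under the additive one, so the matched value
#' is the exposure- and population-weighted mean baseline rate times `s`.
#' The value is averaged empirically over `n_assign` random assignments.
#'
#' @param panel baseline `state_panel` (its `crude_rate` is Y0).
#' @param s signed multiplicative effect (nonzero).
#' @param k number of treated states in the calibration assignments.
#' @param phase_in exposure coding used for calibration.
#' @param n_assign number of random assignments averaged over.
#' @param seed integer seed for the assignment draws.
#' @return Signed additive effect per 100,000 (scalar).
#' @export
calibrate_alpha_linear <- function(panel, s, k = 15, phase_in = "instantaneous",
                                   n_assign = 200, seed = 1L) {
  if (!is.numeric(s) || length(s) != 1 || s == 0) {
    stop_arg("s must be a nonzero scalar (the null effect needs no calibration)")
  }
  ratios <- vapply(seq_len(n_assign), function(j) {
    asg <- assign_policy(panel, k, seed = hash_seed(seed, "calibrate", j))
    ex <- code_exposure(asg, panel, phase_in)
    stopifnot(all(ex$state == panel$state), all(ex$year == panel$year))
    w <- ex$A * panel$population
    sum(w * panel$crude_rate) / sum(w)
  }, numeric(1))
  s * mean(ratios)
}

#' Inject a known policy effect into a baseline panel
#'
#' Produces the observed panel `Y_obs = A * Y1 + (1 - A) * Y0` where the
#' treated potential outcome is `Y1 = Y0 + alpha_linear` (additive rate
#' scale) or `Y1 = Y0 * (1 + s)` (multiplicative scale); with fractional
#' exposure the injected effect is scaled linearly in A. Untreated cells and
#' null effects leave the baseline untouched. Deaths are re-derived from the
#' modified rate (rounded to the nearest integer, floored at 0) so count
#' models keep integer outcomes; the modified rate itself is kept as
#' `crude_rate`. Additive effects that would drive a rate below zero are
#' clamped to zero, with the number of clamped cells recorded and warned.
#'
#' @param baseline baseline `state_panel` (Y0).
#' @param exposure an [code_exposure()] series aligned with the baseline.
#' @param effect an [effect_spec()]; for `scale = "additive_rate"` its
#'   `alpha_linear` must be set (see [calibrate_alpha_linear()]).
#' @param scale `"additive_rate"` or `"multiplicative"`.
#' @return A `simulated_panel`: list with `baseline`, `observed`,
#'   `exposure`, `effect`, `scale`, `truth` (the true coefficient on the
#'   analysis model's native scale: `alpha_linear` for the additive scale,
#'   `log(1+s)` for the multiplicative), `expected_excess_deaths` (signed
#'   national annual excess-death magnitude used as the standardization
#'   denominator), `n_clamped`.
#' @export
inject_effect <- function(baseline, exposure, effect,
                          scale = c("additive_rate", "multiplicative")) {
  scale <- match.arg(scale)
  if (!all(exposure$state == baseline$state) ||
      !all(exposure$year == baseline$year)) {
    stop_arg("exposure series is not aligned with the baseline panel")
  }
  A <- exposure$A
  y0 <- baseline$crude_rate
  observed <- baseline
  n_clamped <- 0L
  null_effect <- effect$size_class == "null" || effect$s == 0

  if (!null_effect) {
    if (scale == "additive_rate") {
      if (is.null(effect$alpha_linear)) {
        stop_arg("additive injection needs effect$alpha_linear; ",
                 "run calibrate_alpha_linear() first")
      }
      rate1 <- y0 + A * effect$alpha_linear
      n_clamped <- sum(rate1 < 0 & A > 0)
      if (n_clamped > 0) {
        warning(sprintf("%d state-year rate(s) clamped at 0 after additive injection",
                        n_clamped))
        rate1 <- pmax(rate1, 0)
      }
    } else {
      rate1 <- y0 * (1 + A * effect$s)
    }
    touched <- A > 0
    observed$crude_rate[touched] <- rate1[touched]
    observed$deaths[touched] <- as.integer(pmax(
      round(rate1[touched] * observed$population[touched] / 1e5), 0))
  }

  total_pop <- sum(tapply(baseline$population, baseline$state, function(p) p[1]))
  mean_annual_deaths <- sum(baseline$deaths) / length(panel_years(baseline))
  if (null_effect) {
    truth <- 0
    excess <- 0
  } else if (scale == "additive_rate") {
    truth <- effect$alpha_linear
    excess <- effect$alpha_linear * total_pop / 1e5
  } else {
    truth <- log(1 + effect$s)
    excess <- effect$s * mean_annual_deaths
  }

  structure(list(
    baseline = baseline, observed = observed, exposure = exposure,
    effect = effect, scale = scale, truth = truth,
    expected_excess_deaths = excess, n_clamped = n_clamped
  ), class = "simulated_panel")
}
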