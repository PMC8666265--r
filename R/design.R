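## Model specifications and design construction.
##
## The benchmarked model grid crosses four regression families with link
## functions, weighting schemes, and SE estimators:
##   twfe      two-way fixed effects (state + year indicators)
##   detrended twfe plus state-specific linear time slopes
##   ar        change-coded policy term + single lagged outcome + year
##             indicators (no state indicators)
##   gee       linear marginal model with AR(1) working correlation,
##             clustered by state

MODEL_FAMILIES <- c("twfe", "detrended", "ar", "gee")
MODEL_LINKS <- c("linear", "log_linear", "poisson", "negbin")
MODEL_WEIGHTINGS <- c("population", "unweighted", "offset")

#' Specify one model cell
#'
#' Validates a (family, link, weighting) combination against the benchmark
#' grid rules: GEE is linear-link only; Poisson/negative-binomial models are
#' count models with a log-population offset (never analytic weights);
#' linear/log-linear models are either population-weighted or unweighted;
#' the detrended family is only run with linear and negative-binomial links.
#'
#' @param family one of `"twfe"`, `"detrended"`, `"ar"`, `"gee"`.
#' @param link one of `"linear"`, `"log_linear"`, `"poisson"`, `"negbin"`.
#' @param weighting one of `"population"`, `"unweighted"`, `"offset"`.
#' @return A `model_spec` list with an `id` of the form
#'   `"family_link_weighting"` (e.g. `"ar_linear_unweighted"`).
#' @export
model_spec <- function(family, link, weighting) {
  family <- match.arg(family, MODEL_FAMILIES)
  link <- match.arg(link, MODEL_LINKS)
  weighting <- match.arg(weighting, MODEL_WEIGHTINGS)
  if (family == "gee" && link != "linear") {
    stop_arg("gee models are linear-link only")
  }
  if (link %in% c("poisson", "negbin")) {
    if (weighting != "offset") {
      stop_arg("count models use a log(population) offset, not analytic weights")
    }
  } else if (weighting == "offset") {
    stop_arg("offset weighting only applies to poisson/negbin links")
  }
  if (family == "detrended" && !(link %in% c("linear", "negbin"))) {
    stop_arg("detrended models are run with linear or negbin links only")
  }
  structure(list(
    family = family, link = link, weighting = weighting,
    id = paste(family, link, weighting, sep = "_")
  ), class = "model_spec")
}

#' Parse a compact model id
#'
#' @param id string `"family_link_weighting"`, e.g. `"twfe_negbin_offset"`.
#'   `log_linear` is spelled with its underscore (`"ar_log_linear_population"`).
#' @return A [model_spec()].
#' @export
parse_model_spec <- function(id) {
  for (fam in MODEL_FAMILIES) {
    pre <- paste0(fam, "_")
    if (startsWith(id, pre)) {
      rest <- substring(id, nchar(pre) + 1)
      for (lk in MODEL_LINKS) {
        mid <- paste0(lk, "_")
        if (startsWith(rest, mid)) {
          return(model_spec(fam, lk, substring(rest, nchar(mid) + 1)))
        }
      }
    }
  }
  stop_arg("cannot parse model id '", id, "'")
}

#' Enumerate the full benchmark model grid
#'
#' @return Character vector of the 17 model ids in the benchmark grid.
#' @export
model_grid <- function() {
  ids <- character(0)
  add <- function(f, l, w) ids <<- c(ids, model_spec(f, l, w)$id)
  for (w in c("population", "unweighted")) {
    add("twfe", "linear", w); add("twfe", "log_linear", w)
    add("detrended", "linear", w)
    add("ar", "linear", w); add("ar", "log_linear", w)
    add("gee", "linear", w)
  }
  for (l in c("negbin", "poisson")) {
    add("twfe", l, "offset"); add("ar", l, "offset")
  }
  add("detrended", "negbin", "offset")
  ids
}

#' Build the regression design for one model on a simulated panel
#'
#' Assembles the model frame, formula, weights/offset, and cluster ids for a
#' model cell. Outcomes by link: `crude_rate` (linear), `log(crude_rate)`
#' with a continuity correction replacing zero rates by `0.5/population*1e5`
#' (log_linear), or `deaths` with offset `log(population/1e5)`
#' (poisson/negbin). Regressors by family: policy exposure `A` (or its first
#' difference `A_change` for the AR family), all panel covariates, and state
#' indicators / state slope columns / a lagged link-native outcome / year
#' indicators as the family dictates. The AR design drops the first panel
#' year (no lag available). State slopes in the detrended design use a
#' centered time index, with the first state's slope absorbed by the year
#' indicators.
#'
#' @param sim a `simulated_panel` from [inject_effect()].
#' @param spec a [model_spec()].
#' @return A `did_design` list: `data` (model frame), `formula`,
#'   `alpha_term`, `cluster` (factor of state ids), `use_weights`,
#'   `n_obs_used`, `n_zero_rates`, `spec`.
#' @export
build_design <- function(sim, spec) {
  if (!inherits(sim, "simulated_panel")) {
    stop_arg("build_design expects a simulated_panel (see inject_effect)")
  }
  panel <- sim$observed
  ex <- sim$exposure
  years <- panel_years(panel)
  covs <- panel_covariates(panel)

  d <- data.frame(
    state = factor(panel$state),
    year = factor(panel$year, levels = years),
    population = panel$population,
    deaths = panel$deaths,
    crude_rate = panel$crude_rate,
    A = ex$A,
    A_change = ex$A_change,
    t_c = as.numeric(match(panel$year, years)) - (length(years) + 1) / 2,
    stringsAsFactors = FALSE
  )
  for (cv in covs) d[[cv]] <- panel[[cv]]

  n_zero <- sum(panel$crude_rate <= 0)
  rate_adj <- ifelse(panel$crude_rate <= 0,
                     0.5 / panel$population * 1e5, panel$crude_rate)

  d$y <- switch(spec$link,
    linear = d$crude_rate,
    log_linear = log(rate_adj),
    poisson = d$deaths,
    negbin = d$deaths
  )
  d$log_pop_off <- log(d$population / 1e5)
  ## link-native lagged outcome (log lagged rate for all log-scale links)
  lag_src <- if (spec$link == "linear") d$crude_rate else log(rate_adj)
  d$y_lag <- stats::ave(lag_src, d$state, FUN = function(x) c(NA_real_, x[-length(x)]))

  cov_terms <- covs
  rhs <- switch(spec$family,
    twfe = c("A", cov_terms, "state", "year"),
    detrended = c("A", cov_terms, "state", "year"),
    ar = c("A_change", cov_terms, "y_lag", "year"),
    gee = c("A", cov_terms, "year")
  )
  alpha_term <- if (spec$family == "ar") "A_change" else "A"

  if (spec$family == "detrended") {
    ## explicit slope columns for states 2..n (first absorbed by year effects)
    lv <- levels(d$state)
    slope_cols <- character(0)
    for (s in lv[-1]) {
      nm <- paste0("slope_", s)
      d[[nm]] <- d$t_c * (d$state == s)
      slope_cols <- c(slope_cols, nm)
    }
    rhs <- c(rhs, slope_cols)
  }

  if (spec$family == "ar") {
    keep <- !is.na(d$y_lag)
    d <- droplevels(d[keep, , drop = FALSE])
  }

  if (spec$link %in% c("poisson", "negbin")) {
    rhs <- c(rhs, "offset(log_pop_off)")
  }
  fml <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))

  structure(list(
    data = d,
    formula = fml,
    alpha_term = alpha_term,
    cluster = d$state,
    use_weights = identical(spec$weighting, "population"),
    n_obs_used = nrow(d),
    n_zero_rates = n_zero,
    spec = spec
  ), class = "did_design")
}
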