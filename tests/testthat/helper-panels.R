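# Small fixture builders used across test files.

# Balanced toy panel from a states x years matrix of crude rates.
# Populations default to 1e5 so deaths equal rates exactly.
toy_panel <- function(rates, first_year = 2000L, populations = NULL,
                      covariates = NULL) {
  n <- nrow(rates)
  T <- ncol(rates)
  if (is.null(populations)) populations <- rep(1e5, n)
  df <- expand.grid(year = first_year + 0:(T - 1),
                    state = sprintf("S%02d", seq_len(n)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$population <- rep(populations, each = T)
  df$crude_rate <- as.vector(t(rates))
  df$deaths <- round(df$crude_rate * df$population / 1e5)
  df$crude_rate <- df$deaths / df$population * 1e5  # keep exactly consistent
  if (!is.null(covariates)) for (nm in names(covariates)) df[[nm]] <- covariates[[nm]]
  state_panel(df)
}

# Wrap a panel plus a hand-specified exposure matrix (states x years, rows in
# state order) into a simulated_panel suitable for build_design / fit_model.
manual_sim <- function(panel, A, truth = 0) {
  states <- panel_states(panel)
  years <- panel_years(panel)
  ex <- expand.grid(year = years, state = states,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ex <- ex[order(ex$state, ex$year), c("state", "year")]
  ex$A <- as.vector(t(A))
  ex$A_change <- stats::ave(ex$A, ex$state, FUN = function(a) c(NA, diff(a)))
  rownames(ex) <- NULL
  class(ex) <- c("exposure_series", "data.frame")
  attr(ex, "phase_in") <- "instantaneous"
  structure(list(baseline = panel, observed = panel, exposure = ex,
                 effect = effect_spec("null"), scale = "additive_rate",
                 truth = truth, expected_excess_deaths = 0, n_clamped = 0L),
            class = "simulated_panel")
}

# Small autocorrelated random panel for estimator tests (defaults sized so
# fits stay fast).
small_baseline <- function(seed = 1, n_states = 12, n_years = 10, ...) {
  generate_baseline(baseline_config(n_states = n_states, n_years = n_years,
                                    seed = seed, ...))
}

# Null-effect simulated panel on a generated baseline with k treated states.
null_sim <- function(panel, k = 3, seed = 1, phase_in = "instantaneous") {
  asg <- assign_policy(panel, k, seed = seed)
  ex <- code_exposure(asg, panel, phase_in)
  inject_effect(panel, ex, effect_spec("null"), "additive_rate")
}
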