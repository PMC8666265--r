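## Lag-order diagnostics for AR models.

## Partial autocorrelations from autocorrelations via the Durbin-Levinson
## recursion (Yule-Walker).
pacf_from_acf <- function(r) {
  L <- length(r)
  pacf <- numeric(L)
  phi_prev <- numeric(0)
  for (k in seq_len(L)) {
    if (k == 1) {
      phi_k <- r[1]
    } else {
      num <- r[k] - sum(phi_prev * r[(k - 1):1])
      den <- 1 - sum(phi_prev * r[1:(k - 1)])
      phi_k <- num / den
    }
    pacf[k] <- phi_k
    phi_prev <- if (k == 1) phi_k else c(phi_prev - phi_k * rev(phi_prev), phi_k)
  }
  pacf
}

#' Partial-autocorrelation lag diagnostics for a panel outcome
#'
#' Computes the partial autocorrelation profile of the pooled within-state
#' outcome series (each state's series demeaned, autocovariances pooled
#' across states so short per-state series still give a stable estimate) and
#' suggests a lag order: the largest lag whose partial autocorrelation
#' exceeds the white-noise guidance band `1.96/sqrt(n)` (0 when none do).
#' A good lag order for an autoregressive analysis model is where the
#' profile cuts off.
#'
#' @param panel a `state_panel`.
#' @param max_lags number of lags to profile (must be `< T`).
#' @param outcome panel column to analyse (default `"crude_rate"`).
#' @param threshold guidance band; default `1.96/sqrt(n_obs)`.
#' @return A list: `pacf` (length `max_lags`), `threshold`,
#'   `suggested_order`, `degenerate` (`TRUE` for a constant series, in which
#'   case `pacf` is `NA`).
#' @export
ar_lag_diagnostics <- function(panel, max_lags = 10, outcome = "crude_rate",
                               threshold = NULL) {
  years <- panel_years(panel)
  T <- length(years)
  if (max_lags >= T) stop_arg("max_lags must be smaller than the number of years")
  series <- lapply(split(seq_len(nrow(panel)), panel$state), function(idx) {
    x <- panel[[outcome]][idx][order(panel$year[idx])]
    x - mean(x)
  })
  n_obs <- sum(lengths(series))
  denom <- sum(vapply(series, function(e) sum(e^2), numeric(1)))
  if (denom == 0) {
    return(list(pacf = rep(NA_real_, max_lags), threshold = NA_real_,
                suggested_order = NA_integer_, degenerate = TRUE))
  }
  r <- vapply(seq_len(max_lags), function(l) {
    num <- sum(vapply(series, function(e) {
      if (length(e) <= l) 0 else sum(e[seq_len(length(e) - l)] * e[-seq_len(l)])
    }, numeric(1)))
    num / denom
  }, numeric(1))
  pacf <- pacf_from_acf(r)
  threshold <- threshold %||% (1.96 / sqrt(n_obs))
  above <- which(abs(pacf) > threshold)
  suggested <- if (length(above) == 0) 0L else max(above)
  list(pacf = pacf, threshold = threshold,
       suggested_order = as.integer(suggested), degenerate = FALSE)
}
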