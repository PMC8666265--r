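## Model fitting and robust standard errors.

#' Heteroskedasticity-robust (Huber/sandwich) SE of one coefficient
#'
#' HC1-scaled sandwich standard error, `sqrt(diag(vcovHC(fit, "HC1")))[term]`.
#'
#' @param fit a fitted `lm`/`glm`/`negbin` object.
#' @param term coefficient name (default: the design's policy term must be
#'   supplied by the caller).
#' @return Scalar standard error.
#' @export
huber_se <- function(fit, term) {
  V <- sandwich::vcovHC(fit, type = "HC1")
  sqrt(V[term, term])
}

#' Cluster-robust (Liang-Zeger) SE of one coefficient
#'
#' Sandwich variance summing score contributions within clusters, with CR1
#' finite-sample scaling `G/(G-1) * (n-1)/(n-p)`. Inference against this SE
#' uses a t reference with `G - 1` degrees of freedom. With a single cluster
#' the estimator is degenerate and `NA` is returned.
#'
#' @param fit a fitted `lm`/`glm`/`negbin` object.
#' @param cluster vector/factor of cluster ids, one per observation used in
#'   the fit.
#' @param term coefficient name.
#' @return Scalar standard error (`NA` if fewer than 2 clusters).
#' @export
cluster_se <- function(fit, cluster, term) {
  if (length(unique(cluster)) < 2) return(NA_real_)
  V <- sandwich::vcovCL(fit, cluster = cluster, type = "HC1")
  sqrt(V[term, term])
}

fit_glm_family <- function(design) {
  d <- design$data
  spec <- design$spec
  w <- if (design$use_weights) d$population else NULL
  d$.wts <- w
  fml <- design$formula
  if (spec$link == "log_linear") {
    ## outcome already log-transformed in the design; ordinary least squares
  }
  fit <- switch(spec$link,
    linear = ,
    log_linear = if (design$use_weights) {
      stats::lm(fml, data = d, weights = .wts)
    } else {
      stats::lm(fml, data = d)
    },
    poisson = stats::glm(fml, family = stats::poisson(), data = d),
    negbin = MASS::glm.nb(fml, data = d)
  )
  fit
}

#' Fit one model cell to a simulated panel
#'
#' Builds the design with [build_design()] and fits it: least squares for
#' linear/log-linear links (optionally population-weighted), maximum
#' likelihood with a log link and population offset for Poisson and
#' negative-binomial counts (NB dispersion estimated by ML), or the iterated
#' estimating-equation AR(1) GEE for the GEE family. The policy coefficient
#' `alpha_hat` is the coefficient on exposure `A` (twfe/detrended/gee) or on
#' the change-coded `A_change` (ar), on the model's native scale (rate
#' difference for linear links, log-rate / log-IRR otherwise).
#'
#' Standard errors: `none` is the model-based SE, `huber` the HC1 sandwich,
#' `cluster` the CR1 cluster sandwich by state. Two-sided p-values use a
#' normal reference for `none`/`huber` and a t reference with `G - 1`
#' degrees of freedom for `cluster`. GEE models carry a single robust
#' (Liang-Zeger) SE under the key `"robust"`.
#'
#' Non-convergence (including an aliased policy coefficient or a fitting
#' error) yields `converged = FALSE` with `NA` estimates rather than an
#' error, so Monte Carlo loops can count and exclude failures.
#'
#' @param sim a `simulated_panel`.
#' @param spec a [model_spec()] (or a model id string).
#' @param se_methods subset of `c("none", "huber", "cluster")`; ignored for
#'   the GEE family.
#' @param keep_fit if `TRUE`, attach the underlying fitted object.
#' @return A `did_fit` list: `alpha_hat`, `se` (named), `p` (named),
#'   `gamma_hat` (AR lag coefficient, AR family only), `converged`,
#'   `n_obs_used`, `n_zero_rates`, `spec_id`, `df_cluster`.
#' @export
fit_model <- function(sim, spec, se_methods = c("none", "huber", "cluster"),
                      keep_fit = FALSE) {
  if (is.character(spec)) spec <- parse_model_spec(spec)
  se_methods <- match.arg(se_methods, c("none", "huber", "cluster"),
                          several.ok = TRUE)
  design <- build_design(sim, spec)

  failed <- function(msg) {
    structure(list(
      alpha_hat = NA_real_, se = numeric(0), p = numeric(0),
      gamma_hat = NA_real_, converged = FALSE,
      n_obs_used = design$n_obs_used, n_zero_rates = design$n_zero_rates,
      spec_id = spec$id, df_cluster = NA_integer_, message = msg
    ), class = "did_fit")
  }

  if (spec$family == "gee") {
    d <- design$data
    w <- if (design$use_weights) d$population else NULL
    g <- tryCatch(
      fit_gee_ar1(design$formula, data = d, id = d$state, weights = w),
      error = function(e) NULL
    )
    if (is.null(g) || !g$converged || !(design$alpha_term %in% names(g$coefficients))) {
      return(failed("gee did not converge"))
    }
    est <- g$coefficients[[design$alpha_term]]
    se <- c(robust = sqrt(g$vcov_robust[design$alpha_term, design$alpha_term]))
    p <- c(robust = 2 * stats::pnorm(-abs(est / se[["robust"]])))
    out <- list(
      alpha_hat = est, se = se, p = p, gamma_hat = NA_real_,
      converged = TRUE, n_obs_used = design$n_obs_used,
      n_zero_rates = design$n_zero_rates, spec_id = spec$id,
      df_cluster = NA_integer_, rho = g$rho
    )
    if (keep_fit) out$fit <- g
    return(structure(out, class = "did_fit"))
  }

  fit <- tryCatch(
    suppressWarnings(fit_glm_family(design)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed("fit error"))
  if (inherits(fit, "glm") && !isTRUE(fit$converged)) {
    return(failed("IWLS did not converge"))
  }
  cf <- stats::coef(fit)
  term <- design$alpha_term
  if (!(term %in% names(cf)) || is.na(cf[[term]])) {
    return(failed("aliased or missing policy coefficient"))
  }

  est <- cf[[term]]
  G <- length(unique(design$cluster))
  se <- numeric(0)
  p <- numeric(0)
  for (m in se_methods) {
    s <- tryCatch(switch(m,
      none = sqrt(stats::vcov(fit)[term, term]),
      huber = huber_se(fit, term),
      cluster = cluster_se(fit, design$cluster, term)
    ), error = function(e) NA_real_)
    se[[m]] <- s
    p[[m]] <- if (is.na(s)) NA_real_ else if (m == "cluster") {
      2 * stats::pt(-abs(est / s), df = G - 1)
    } else {
      2 * stats::pnorm(-abs(est / s))
    }
  }

  out <- list(
    alpha_hat = est,
    se = se, p = p,
    gamma_hat = if (spec$family == "ar") cf[["y_lag"]] else NA_real_,
    converged = TRUE,
    n_obs_used = design$n_obs_used,
    n_zero_rates = design$n_zero_rates,
    spec_id = spec$id,
    df_cluster = G - 1L
  )
  if (keep_fit) out$fit <- fit
  structure(out, class = "did_fit")
}

#' @export
print.did_fit <- function(x, ...) {
  cat(sprintf("model %s: alpha_hat = %.4g (converged: %s, n = %d)\n",
              x$spec_id, x$alpha_hat, x$converged, x$n_obs_used))
  if (length(x$se) > 0) {
    for (m in names(x$se)) {
      cat(sprintf("  se[%s] = %.4g, p = %.4g\n", m, x$se[[m]], x$p[[m]]))
    }
  }
  invisible(x)
}
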