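test_that("model grid enforces the family/link/weighting rules", {
  expect_error(model_spec("gee", "poisson", "offset"), "linear-link only")
  expect_error(model_spec("twfe", "poisson", "population"), "offset")
  expect_error(model_spec("twfe", "linear", "offset"), "poisson/negbin")
  expect_error(model_spec("detrended", "poisson", "offset"), "detrended")

  ids <- model_grid()
  expect_length(ids, 17)
  expect_length(unique(ids), 17)
  for (id in ids) expect_equal(parse_model_spec(id)$id, id)
})

test_that("linear TWFE reproduces the 2x2 double difference exactly", {
  # treated pre/post 10 -> 15, control pre/post 8 -> 9: DID = 5 - 1 = 4
  p <- toy_panel(rbind(c(10, 15), c(8, 9)), first_year = 2000L)
  sim <- manual_sim(p, rbind(c(0, 1), c(0, 0)))
  fit <- fit_model(sim, "twfe_linear_unweighted", se_methods = "none")
  expect_equal(fit$alpha_hat, 4.0, tolerance = 1e-10)
})

test_that("design dimensions follow the dummy-count arithmetic", {
  p <- generate_baseline(baseline_config(seed = 31))
  sim <- null_sim(p, k = 5, seed = 1)

  d <- build_design(sim, model_spec("twfe", "linear", "unweighted"))
  fit <- fit_model(sim, "twfe_linear_unweighted", se_methods = "none",
                   keep_fit = TRUE)
  # intercept + A + 1 covariate + 49 state + 17 year indicators
  expect_length(coef(fit$fit), 1 + 1 + 1 + 49 + 17)
  expect_equal(d$n_obs_used, 900)

  far <- fit_model(sim, "ar_linear_unweighted", se_methods = "none")
  expect_equal(far$n_obs_used, 850)  # first panel year dropped for the lag

  fdet <- fit_model(sim, "detrended_linear_unweighted", se_methods = "none",
                    keep_fit = TRUE)
  expect_length(coef(fdet$fit), 1 + 1 + 1 + 49 + 17 + 49)
  expect_false(anyNA(coef(fdet$fit)))
})

test_that("explicit state-slope columns match the unrestricted parameterization", {
  p <- small_baseline(seed = 32, n_states = 8, n_years = 10)
  sim <- null_sim(p, k = 3, seed = 2)
  fit <- fit_model(sim, "detrended_linear_unweighted", se_methods = "none",
                   keep_fit = TRUE)
  # unrestricted: all 8 state:t interactions; lm drops the aliased one, the
  # projection space (and hence the policy coefficient) must be identical
  d <- build_design(sim, model_spec("detrended", "linear", "unweighted"))$data
  un <- stats::lm(y ~ A + unemployment_rate + state + year + state:t_c, data = d)
  expect_equal(unname(coef(fit$fit)["A"]), unname(coef(un)["A"]),
               tolerance = 1e-8)
  expect_equal(sum(is.na(coef(un))), 1)  # one aliased slope in the naive form
})

test_that("population weighting is inert when all populations are equal", {
  p <- small_baseline(seed = 33, pop_log10_range = c(6, 6))
  expect_equal(length(unique(p$population)), 1)
  sim <- null_sim(p, k = 4, seed = 3)
  for (fam in c("twfe_linear", "ar_linear", "detrended_linear")) {
    fw <- fit_model(sim, paste0(fam, "_population"), se_methods = "none")
    fu <- fit_model(sim, paste0(fam, "_unweighted"), se_methods = "none")
    expect_equal(fw$alpha_hat, fu$alpha_hat, tolerance = 1e-9)
  }
})

test_that("count-model coefficients are invariant to population rescaling", {
  p <- small_baseline(seed = 34)
  for (id in c("twfe_poisson_offset", "twfe_negbin_offset")) {
    sim1 <- null_sim(p, k = 4, seed = 5)
    f1 <- fit_model(sim1, id, se_methods = "none", keep_fit = TRUE)

    df <- as.data.frame(p)
    df$population <- df$population * 10
    df$crude_rate <- df$deaths / df$population * 1e5
    p10 <- state_panel(df)
    sim10 <- null_sim(p10, k = 4, seed = 5)
    f10 <- fit_model(sim10, id, se_methods = "none", keep_fit = TRUE)

    c1 <- coef(f1$fit)
    c10 <- coef(f10$fit)
    expect_equal(c1[-1], c10[-1], tolerance = 1e-6)
    # offset log(pop) grows by log(10), so the intercept drops by log(10)
    expect_equal(unname(c10[1] - c1[1]), -log(10), tolerance = 1e-6)
  }
})

test_that("log-linear fits handle zero rates via continuity correction", {
  rates <- matrix(rep(c(5, 6, 7, 8, 9, 10, 11, 12, 13, 14), 4), nrow = 4,
                  byrow = TRUE)
  rates[1, 2] <- 0
  p <- toy_panel(rates, populations = rep(2e5, 4))
  sim <- manual_sim(p, rbind(c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
                             matrix(0, 3, 10)))
  fit <- fit_model(sim, "twfe_log_linear_unweighted", se_methods = "none")
  expect_true(fit$converged)
  expect_equal(fit$n_zero_rates, 1)
  expect_true(is.finite(fit$alpha_hat))
})

test_that("log-linear TWFE recovers zero exactly on a noise-free baseline", {
  # deterministic baseline: log rate is additive in state and year, so the
  # log-linear two-way fixed effects model fits it exactly
  p <- generate_baseline(baseline_config(seed = 35), deterministic = TRUE)
  sim <- null_sim(p, k = 10, seed = 6)
  fit <- fit_model(sim, "twfe_log_linear_unweighted", se_methods = "none")
  expect_lt(abs(fit$alpha_hat), 1e-10)
})

test_that("perfectly persistent outcomes give gamma = 1, alpha = 0", {
  rates <- matrix(rep(c(12, 7, 9, 15), each = 8), nrow = 4, byrow = TRUE)
  p <- toy_panel(rates)
  A <- rbind(c(0, 0, 0, 1, 1, 1, 1, 1),
             c(0, 0, 0, 0, 0, 1, 1, 1),
             rep(0, 8), rep(0, 8))
  sim <- manual_sim(p, A)
  fit <- fit_model(sim, "ar_linear_unweighted", se_methods = "none")
  expect_equal(fit$gamma_hat, 1, tolerance = 1e-8)
  expect_lt(abs(fit$alpha_hat), 1e-8)
})

test_that("Huber SE equals the brute-force HC1 sandwich", {
  p <- small_baseline(seed = 36, n_states = 5, n_years = 8)
  sim <- null_sim(p, k = 2, seed = 7)
  fit <- fit_model(sim, "twfe_linear_unweighted", se_methods = c("none", "huber"),
                   keep_fit = TRUE)
  X <- stats::model.matrix(fit$fit)
  e <- stats::residuals(fit$fit)
  n <- nrow(X); k <- ncol(X)
  XtXi <- solve(crossprod(X))
  V <- n / (n - k) * XtXi %*% crossprod(X * e, X * e) %*% XtXi
  expect_equal(fit$se[["huber"]], sqrt(V["A", "A"]), tolerance = 1e-10)
  # sanity: huber close to the model SE on homoskedastic-ish data
  expect_lt(abs(fit$se[["huber"]] / fit$se[["none"]] - 1), 1)
})

test_that("Huber SE exceeds the model SE with an extreme-variance point", {
  withr::local_seed(99)
  x <- c(rnorm(39), 4)  # last point at high leverage
  y <- 1 + 2 * x + rnorm(40, sd = 0.3)
  y[40] <- 1 + 2 * x[40] + 25  # ... and with a wild error
  fit <- stats::lm(y ~ x)
  expect_gt(huber_se(fit, "x"), sqrt(stats::vcov(fit)["x", "x"]))
})

test_that("cluster SE equals the brute-force Liang-Zeger formula", {
  p <- small_baseline(seed = 37, n_states = 4, n_years = 9)
  sim <- null_sim(p, k = 2, seed = 8)
  fit <- fit_model(sim, "twfe_linear_unweighted",
                   se_methods = c("cluster"), keep_fit = TRUE)
  X <- stats::model.matrix(fit$fit)
  e <- stats::residuals(fit$fit)
  cl <- build_design(sim, model_spec("twfe", "linear", "unweighted"))$cluster
  n <- nrow(X); k <- ncol(X); G <- length(unique(cl))
  XtXi <- solve(crossprod(X))
  meat <- matrix(0, k, k)
  for (g in unique(cl)) {
    sg <- colSums(X[cl == g, , drop = FALSE] * e[cl == g])
    meat <- meat + sg %o% sg
  }
  V <- G / (G - 1) * (n - 1) / (n - k) * XtXi %*% meat %*% XtXi
  expect_equal(fit$se[["cluster"]], sqrt(V["A", "A"]), tolerance = 1e-10)
  expect_equal(fit$df_cluster, 3L)
})

test_that("singleton clusters reduce the cluster sandwich to Huber", {
  withr::local_seed(5)
  x <- rnorm(30)
  y <- 2 + x + rnorm(30)
  fit <- stats::lm(y ~ x)
  expect_equal(cluster_se(fit, seq_len(30), "x"), huber_se(fit, "x"),
               tolerance = 1e-12)
  expect_true(is.na(cluster_se(fit, rep(1, 30), "x")))
})

test_that("cluster p-values use a t reference with G - 1 df", {
  p <- toy_panel(matrix(c(3, 4, 5, 6, 7, 5, 6, 8, 9, 9), nrow = 2, byrow = TRUE))
  sim <- manual_sim(p, rbind(c(0, 0, 1, 1, 1), rep(0, 5)))
  fit <- fit_model(sim, "twfe_linear_unweighted", se_methods = "cluster")
  t_stat <- fit$alpha_hat / fit$se[["cluster"]]
  expect_equal(fit$p[["cluster"]], 2 * stats::pt(-abs(t_stat), df = 1),
               tolerance = 1e-12)
})

test_that("change coding beats effect coding on change-model data", {
  # data generated from the autoregressive change model itself:
  # y_t = gamma * y_{t-1} + sigma_t + alpha * (A_t - A_{t-1}) + eps
  gamma <- 0.6
  alpha <- 2.0
  n_states <- 30; T <- 14
  bias_change <- numeric(80)
  bias_effect <- numeric(80)
  for (r in seq_len(80)) {
    withr::with_seed(4000 + r, {
      year_eff <- cumsum(rnorm(T, 0.2, 0.1))
      treated <- seq_len(10)
      e_years <- sample(5:(T - 3), 10, replace = TRUE)
      rows <- list()
      for (i in seq_len(n_states)) {
        A <- if (i %in% treated) as.numeric(seq_len(T) >= e_years[match(i, treated)]) else rep(0, T)
        dA <- c(0, diff(A))
        y <- numeric(T)
        y[1] <- rnorm(1, 10, 2)
        for (t in 2:T) {
          y[t] <- gamma * y[t - 1] + year_eff[t] + alpha * dA[t] + rnorm(1, 0, 0.5)
        }
        rows[[i]] <- data.frame(state = i, t = seq_len(T), y = y, A = A, dA = dA,
                                y_lag = c(NA, y[-T]))
      }
      d <- do.call(rbind, rows)
      d <- d[!is.na(d$y_lag), ]
      d$year <- factor(d$t)
      f_change <- stats::lm(y ~ dA + y_lag + year, data = d)
      f_effect <- stats::lm(y ~ A + y_lag + year, data = d)
      bias_change[r] <- coef(f_change)[["dA"]] - alpha
      bias_effect[r] <- coef(f_effect)[["A"]] - alpha
    })
  }
  expect_lt(abs(mean(bias_change)), abs(mean(bias_effect)))
  expect_lt(abs(mean(bias_change)), 0.2)
})

test_that("non-converging or aliased fits are flagged, not raised", {
  p <- toy_panel(matrix(c(3, 4, 5, 6, 7, 5, 6, 8, 9, 9), nrow = 2, byrow = TRUE))
  sim <- manual_sim(p, matrix(0, 2, 5))  # A constant: policy term aliased
  fit <- fit_model(sim, "twfe_linear_unweighted")
  expect_false(fit$converged)
  expect_true(is.na(fit$alpha_hat))
})
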