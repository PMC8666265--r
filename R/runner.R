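## Configuration-driven orchestration of the factorial experiment.
##
## A condition is a (k, size_class, phase_in) cell; every non-null condition
## is paired with the matching null condition (same k and phase_in), which
## supplies the Type I error and SE calibration sample. Child seeds are
## derived by hashing (master seed, condition key, sim index), so estimates
## for one model/condition never depend on which other models or conditions
## are in the grid, and all models within a simulation see the same data.

#' Experiment configuration
#'
#' @param baseline a [baseline_config()] for synthetic baselines, or a
#'   `state_panel` to use as a fixed observed baseline.
#' @param models character vector of model ids (default: full grid,
#'   [model_grid()]).
#' @param k numbers of treated states to cross (default `c(1, 5, 15, 30)`).
#' @param size_classes effect sizes to cross (default all four); `"null"` is
#'   added automatically when any non-null class is requested, since it is
#'   needed for calibration.
#' @param phase_ins exposure codings to cross (default both).
#' @param n_sims simulated datasets per condition arm (default 500 for desk
#'   runs; the canonical full-scale setting is 5000).
#' @param seed master seed.
#' @param level significance level (default 0.05).
#' @param fixed_baseline if `TRUE`, one baseline panel (from the baseline
#'   config's own seed) is reused across simulations and only assignments are
#'   redrawn -- the placebo-law design used with a single observed outcome
#'   history. If `FALSE` (default), each simulation redraws the baseline.
#' @param calibration_assignments assignments averaged over when calibrating
#'   `alpha_linear` (see [calibrate_alpha_linear()]).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(baseline = baseline_config(),
                              models = model_grid(),
                              k = c(1, 5, 15, 30),
                              size_classes = c("null", "small", "medium", "large"),
                              phase_ins = c("instantaneous", "linear_3yr"),
                              n_sims = 500, seed = 42L, level = 0.05,
                              fixed_baseline = FALSE,
                              calibration_assignments = 200) {
  size_classes <- match.arg(size_classes,
                            c("null", "small", "medium", "large"),
                            several.ok = TRUE)
  phase_ins <- match.arg(phase_ins, c("instantaneous", "linear_3yr"),
                         several.ok = TRUE)
  if (any(size_classes != "null") && !("null" %in% size_classes)) {
    size_classes <- c("null", size_classes)
  }
  if (n_sims < 1) stop_arg("n_sims must be >= 1")
  if (!(level > 0 && level < 1)) stop_arg("level must be in (0, 1)")
  for (id in models) parse_model_spec(id)  # validate ids early
  structure(list(
    baseline = baseline, models = models, k = as.integer(k),
    size_classes = size_classes, phase_ins = phase_ins,
    n_sims = as.integer(n_sims), seed = as.integer(seed), level = level,
    fixed_baseline = isTRUE(fixed_baseline),
    calibration_assignments = calibration_assignments
  ), class = "experiment_config")
}

reference_baseline <- function(config) {
  if (inherits(config$baseline, "state_panel")) {
    config$baseline
  } else {
    generate_baseline(config$baseline)
  }
}

condition_key <- function(condition) {
  paste0("k", condition$k, "_", condition$size_class, "_", condition$phase_in)
}

#' List the conditions implied by a configuration
#'
#' @param config an [experiment_config()].
#' @return data.frame with columns `k`, `size_class`, `phase_in`, `key`.
#' @export
experiment_conditions <- function(config) {
  g <- expand.grid(k = config$k, size_class = config$size_classes,
                   phase_in = config$phase_ins,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$key <- vapply(seq_len(nrow(g)), function(i) condition_key(g[i, ]), "")
  g
}

## SE methods recorded for a model id.
se_methods_for <- function(id) {
  if (parse_model_spec(id)$family == "gee") "robust" else c("none", "huber", "cluster")
}

## Calibrated additive effects, one per requested non-null size class.
calibrate_effects <- function(config, ref_panel, phase_in) {
  out <- list()
  for (sc in setdiff(config$size_classes, "null")) {
    s <- effect_spec(sc, "+")$s
    out[[sc]] <- calibrate_alpha_linear(
      ref_panel, s, k = max(config$k), phase_in = phase_in,
      n_assign = config$calibration_assignments,
      seed = hash_seed(config$seed, "calibration", sc, phase_in)
    )
  }
  out
}

#' Run all requested models on one condition
#'
#' For each simulation: derive a child seed from (master seed, condition,
#' sim); draw (or reuse) the baseline; assign the policy and code exposure;
#' inject the condition's effect on the additive scale for linear-link
#' models and on the multiplicative scale for log-scale models (so every
#' model is evaluated on data generated on its own scale, with
#' cross-scale magnitudes matched by calibration); fit every model and
#' record estimates, SEs, and p-values in long format. Non-null conditions
#' run matched positive and negative arms on the same simulated
#' assignments.
#'
#' @param config an [experiment_config()].
#' @param condition list/row with `k`, `size_class`, `phase_in`.
#' @param models model ids (default: `config$models`).
#' @param alpha_linear optional pre-calibrated additive effect for this
#'   size class (computed if missing and needed).
#' @return data.frame, one row per (sim, sign arm, model, SE method):
#'   columns `k`, `size_class`, `phase_in`, `sim`, `sign`, `model`,
#'   `se_method`, `alpha_hat`, `se`, `p`, `t`, `truth`, `converged`.
#' @export
run_condition <- function(config, condition, models = config$models,
                          alpha_linear = NULL) {
  key <- condition_key(condition)
  is_null_cond <- condition$size_class == "null"
  specs <- lapply(models, parse_model_spec)
  need_additive <- any(vapply(specs, function(s) s$link %in% c("linear"), TRUE))
  need_mult <- any(vapply(specs, function(s)
    s$link %in% c("log_linear", "poisson", "negbin"), TRUE))

  fixed_panel <- if (config$fixed_baseline) reference_baseline(config) else NULL
  if (!is_null_cond && need_additive && is.null(alpha_linear)) {
    ref <- fixed_panel %||% reference_baseline(config)
    s <- effect_spec(condition$size_class, "+")$s
    alpha_linear <- calibrate_alpha_linear(
      ref, s, k = condition$k, phase_in = condition$phase_in,
      n_assign = config$calibration_assignments,
      seed = hash_seed(config$seed, "calibration", condition$size_class,
                       condition$phase_in)
    )
  }

  signs <- if (is_null_cond) "0" else c("+", "-")
  rows <- vector("list", config$n_sims * length(signs) * length(models))
  ri <- 0
  for (j in seq_len(config$n_sims)) {
    seed_j <- hash_seed(config$seed, key, j)
    panel <- fixed_panel %||% {
      bc <- config$baseline
      bc$seed <- hash_seed(seed_j, "baseline")
      generate_baseline(bc)
    }
    asg <- assign_policy(panel, condition$k, seed = hash_seed(seed_j, "assign"))
    ex <- code_exposure(asg, panel, condition$phase_in)

    for (sgn in signs) {
      eff <- if (is_null_cond) effect_spec("null") else
        effect_spec(condition$size_class, sgn,
                    alpha_linear = if (sgn == "-") -abs(alpha_linear) else
                      abs(alpha_linear))
      sims <- list()
      if (need_additive) {
        sims$additive_rate <- inject_effect(panel, ex, eff, "additive_rate")
      }
      if (need_mult) {
        sims$multiplicative <- inject_effect(panel, ex, eff, "multiplicative")
      }
      for (mi in seq_along(models)) {
        spec <- specs[[mi]]
        scale <- if (spec$link == "linear") "additive_rate" else "multiplicative"
        sim <- sims[[scale]] %||% sims[[1]]
        fit <- fit_model(sim, spec)
        for (m in se_methods_for(models[mi])) {
          ri <- ri + 1
          se <- if (fit$converged) fit$se[[m]] else NA_real_
          p <- if (fit$converged) fit$p[[m]] else NA_real_
          rows[[ri]] <- data.frame(
            k = condition$k, size_class = condition$size_class,
            phase_in = condition$phase_in, sim = j, sign = sgn,
            model = models[mi], se_method = m,
            alpha_hat = fit$alpha_hat, se = se, p = p,
            t = if (!is.na(se) && se > 0) fit$alpha_hat / se else NA_real_,
            truth = sim$truth, converged = fit$converged,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, rows[seq_len(ri)])
}

#' Compute metrics rows from long-format estimates
#'
#' Aggregates a long estimates table (as produced by [run_condition()])
#' into one [condition_metrics()] row per (model, SE method, k, phase_in,
#' size_class) cell, using the matching null cell for Type I error and SE
#' calibration. Null cells themselves are emitted with Type I error and
#' RMSE only. Non-converged fits are excluded, with their count reported.
#'
#' @param estimates long estimates data.frame (possibly several conditions).
#' @param panel_context see [standardize_to_deaths()].
#' @param level significance level.
#' @return data.frame of metric rows.
#' @export
metrics_from_estimates <- function(estimates, panel_context, level = 0.05) {
  out <- list()
  cells <- unique(estimates[, c("model", "se_method", "k", "phase_in")])
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    sub <- estimates[estimates$model == cell$model &
                       estimates$se_method == cell$se_method &
                       estimates$k == cell$k &
                       estimates$phase_in == cell$phase_in, ]
    link <- parse_model_spec(cell$model)$link
    nul <- sub[sub$size_class == "null" & sub$converged, ]
    for (sc in setdiff(unique(sub$size_class), "null")) {
      pos <- sub[sub$size_class == sc & sub$sign == "+" & sub$converged, ]
      neg <- sub[sub$size_class == sc & sub$sign == "-" & sub$converged, ]
      if (nrow(pos) == 0 || nrow(neg) == 0 || nrow(nul) == 0) next
      truth <- c(pos$truth[1], neg$truth[1])
      expected_excess <- standardize_to_deaths(truth[1], link, panel_context)
      row <- condition_metrics(
        pos$alpha_hat, neg$alpha_hat, pos$t, neg$t, truth,
        nul$p, nul$t, link, panel_context, expected_excess, level
      )
      n_total <- sum(sub$size_class == sc)
      out[[length(out) + 1]] <- cbind(
        data.frame(model = cell$model, se_method = cell$se_method,
                   k = cell$k, phase_in = cell$phase_in, size_class = sc,
                   n_converged = nrow(pos) + nrow(neg),
                   n_nonconverged = n_total - nrow(pos) - nrow(neg),
                   stringsAsFactors = FALSE),
        row
      )
    }
    if (nrow(nul) > 0) {
      n_total <- sum(sub$size_class == "null")
      out[[length(out) + 1]] <- data.frame(
        model = cell$model, se_method = cell$se_method,
        k = cell$k, phase_in = cell$phase_in, size_class = "null",
        n_converged = nrow(nul), n_nonconverged = n_total - nrow(nul),
        directional_bias = mean(nul$alpha_hat),
        magnitude_bias = NA_real_,
        directional_bias_deaths = NA_real_, magnitude_bias_deaths = NA_real_,
        pct_directional_bias = NA_real_, pct_magnitude_bias = NA_real_,
        rmse_pos = rmse(nul$alpha_hat, 0), rmse_neg = NA_real_,
        type1_rate = type1_rate(nul$p, level),
        se_correction_factor = se_correction_factor(nul$t, level),
        correct_rejection_rate = NA_real_, meets_power_benchmark = NA,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Run the full experiment grid
#'
#' Runs every condition, archives per-condition long estimates as CSV
#' (`estimates_<key>.csv`), computes metrics (null calibrations first, by
#' construction of [metrics_from_estimates()]), and writes `metrics.csv`
#' plus a JSON run manifest with the configuration, per-condition seeds,
#' and warnings (e.g. models failing on more than 20% of simulations).
#' Conditions whose estimate archive already exists in `out_dir` are
#' re-used rather than recomputed, so a partially completed grid can be
#' resumed.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with `metrics` (data.frame), `manifest`.
#' @export
run_grid <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- experiment_conditions(config)
  ref <- reference_baseline(config)
  warnings_log <- character(0)

  est_all <- list()
  for (i in seq_len(nrow(conds))) {
    cond <- conds[i, ]
    path <- file.path(out_dir, paste0("estimates_", cond$key, ".csv"))
    if (file.exists(path)) {
      est <- utils::read.csv(path, stringsAsFactors = FALSE)
    } else {
      est <- run_condition(config, cond)
      utils::write.csv(est, path, row.names = FALSE)
    }
    conv <- tapply(est$converged, est$model, mean)
    bad <- names(conv)[conv < 0.8]
    if (length(bad) > 0) {
      warnings_log <- c(warnings_log, paste0(
        "condition ", cond$key, ": model(s) failing on >20% of sims: ",
        paste(bad, collapse = ", ")
      ))
    }
    est_all[[cond$key]] <- est
  }
  estimates <- do.call(rbind, est_all)
  metrics <- metrics_from_estimates(estimates, ref, config$level)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("didbench")),
    seed = config$seed, n_sims = config$n_sims, level = config$level,
    models = config$models, conditions = conds$key,
    fixed_baseline = config$fixed_baseline,
    baseline = if (inherits(config$baseline, "state_panel"))
      "user-supplied panel" else unclass(config$baseline),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(metrics = metrics, manifest = manifest))
}

#' Summarise a completed run directory
#'
#' Reads `metrics.csv` from a run directory and assembles a human-readable
#' report: bias by number of treated states and effect size, RMSE under the
#' null, Type I error by SE method and k, and correct-rejection grids.
#'
#' @param results_dir directory written by [run_grid()].
#' @return A `run_summary` list of data.frames (printed as sections).
#' @export
summarize_run <- function(results_dir) {
  path <- file.path(results_dir, "metrics.csv")
  if (!file.exists(path)) {
    stop_arg("no metrics.csv in '", results_dir,
             "'; is this a completed run directory?")
  }
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  nul <- m[m$size_class == "null", ]
  eff <- m[m$size_class != "null", ]
  out <- list(
    type1 = nul[, c("model", "se_method", "k", "phase_in",
                    "type1_rate", "se_correction_factor")],
    rmse_null = nul[, c("model", "se_method", "k", "phase_in", "rmse_pos")],
    bias = if (nrow(eff) > 0) {
      eff[, c("model", "se_method", "k", "phase_in", "size_class",
              "pct_directional_bias", "pct_magnitude_bias")]
    } else NULL,
    rejection = if (nrow(eff) > 0) {
      eff[, c("model", "se_method", "k", "phase_in", "size_class",
              "correct_rejection_rate", "meets_power_benchmark")]
    } else NULL
  )
  structure(out, class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("== Type I error (null conditions) ==\n")
  print(x$type1, row.names = FALSE)
  cat("\n== RMSE under the null ==\n")
  print(x$rmse_null, row.names = FALSE)
  if (!is.null(x$bias)) {
    cat("\n== Percent bias (effect conditions) ==\n")
    print(x$bias, row.names = FALSE)
  }
  if (!is.null(x$rejection)) {
    cat("\n== Calibrated correct-rejection rates ==\n")
    print(x$rejection, row.names = FALSE)
  }
  invisible(x)
}
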