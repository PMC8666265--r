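test_that("policy assignment respects the enactment window and k bounds", {
  p <- generate_baseline(baseline_config(seed = 1))
  expect_error(assign_policy(p, 50, seed = 1), "comparison group")
  expect_error(assign_policy(p, 0, seed = 1), "1 <= k")

  asg <- assign_policy(p, 1, seed = 11)
  expect_equal(nrow(asg$treated), 1)
  expect_true(asg$treated$year >= 2002 && asg$treated$year <= 2013)
  expect_true(asg$treated$month %in% 1:12)
  expect_identical(asg, assign_policy(p, 1, seed = 11))
})

test_that("treated states are sampled uniformly", {
  p <- small_baseline(seed = 1, n_states = 20, n_years = 12)
  n_draws <- 3000
  counts <- integer(20)
  names(counts) <- panel_states(p)
  for (j in seq_len(n_draws)) {
    asg <- assign_policy(p, 2, seed = j)
    counts[asg$treated$state] <- counts[asg$treated$state] + 1L
  }
  freq <- counts / n_draws
  # each state appears with probability 2/20 = 0.1; 4.5 binomial sds
  tol <- 4.5 * sqrt(0.1 * 0.9 / n_draws)
  expect_lt(max(abs(freq - 0.1)), tol)
})

test_that("instantaneous exposure codes the fraction of the enactment year", {
  p <- toy_panel(matrix(rep(5, 2 * 8), nrow = 2), first_year = 2000L)
  asg <- structure(list(
    treated = data.frame(state = "S01", year = 2003L, month = 7L),
    k = 1L
  ), class = "policy_assignment")
  ex <- code_exposure(asg, p, "instantaneous")
  a <- ex$A[ex$state == "S01"]
  expect_equal(a, c(0, 0, 0, 0.5, 1, 1, 1, 1))
  expect_true(all(ex$A[ex$state == "S02"] == 0))
  # change coding: first differences, first panel year unavailable
  expect_equal(ex$A_change[ex$state == "S01"], c(NA, 0, 0, 0.5, 0.5, 0, 0, 0))
})

test_that("3-year linear phase-in matches the brute-force monthly ramp", {
  p <- toy_panel(matrix(rep(5, 1 * 8), nrow = 1), first_year = 2000L)
  asg <- structure(list(
    treated = data.frame(state = "S01", year = 2001L, month = 1L),
    k = 1L
  ), class = "policy_assignment")
  ex <- code_exposure(asg, p, "linear_3yr")
  a <- ex$A[ex$state == "S01"]
  # oracle: monthly ramp value j/36 capped at 1, averaged within calendar year
  oracle <- vapply(2000:2007, function(y) {
    j <- 12 * (y - 2001) + (1:12 - 1)
    mean(ifelse(j < 0, 0, pmin(j / 36, 1)))
  }, numeric(1))
  expect_equal(a, oracle, tolerance = 1e-12)
  expect_equal(a[2], 11 / 72)
  expect_true(all(a[5:8] == 1))
})

test_that("exposure is monotone, bounded, and zero pre-enactment", {
  p <- generate_baseline(baseline_config(seed = 5))
  for (ph in c("instantaneous", "linear_3yr")) {
    asg <- assign_policy(p, 15, seed = 9)
    ex <- code_exposure(asg, p, ph)
    expect_true(all(ex$A >= 0 & ex$A <= 1))
    for (s in asg$treated$state) {
      a <- ex$A[ex$state == s]
      expect_true(all(diff(a) >= -1e-12))
      e_year <- asg$treated$year[asg$treated$state == s]
      expect_true(all(a[panel_years(p) < e_year] == 0))
    }
    untreated <- setdiff(panel_states(p), asg$treated$state)
    expect_true(all(ex$A[ex$state %in% untreated] == 0))
  }
})

test_that("alpha calibration is exact on a homogeneous panel", {
  p <- toy_panel(matrix(rep(8, 4 * 10), nrow = 4), first_year = 2000L)
  expect_equal(calibrate_alpha_linear(p, 0.05, k = 2, n_assign = 20), 0.05 * 8,
               tolerance = 1e-12)
  expect_error(calibrate_alpha_linear(p, 0), "nonzero")
})

test_that("alpha calibration matches a brute-force excess-death oracle", {
  p <- generate_baseline(baseline_config(seed = 21))
  s <- 0.05
  al <- calibrate_alpha_linear(p, s, k = 5, n_assign = 60, seed = 4)
  # oracle: excess deaths from actually injecting the multiplicative effect,
  # divided by excess deaths per unit additive alpha, averaged per assignment
  ratios <- vapply(seq_len(60), function(j) {
    asg <- assign_policy(p, 5, seed = didbench:::hash_seed(4, "calibrate", j))
    ex <- code_exposure(asg, p, "instantaneous")
    sim <- inject_effect(p, ex, effect_spec("small", "+"), "multiplicative")
    excess_mult <- sum((sim$observed$crude_rate - p$crude_rate) * p$population) / 1e5
    excess_per_alpha <- sum(ex$A * p$population) / 1e5
    excess_mult / excess_per_alpha
  }, numeric(1))
  expect_equal(al, mean(ratios), tolerance = 1e-9)
})

test_that("calibrated additive injection reproduces the multiplicative excess", {
  p <- generate_baseline(baseline_config(seed = 22))
  al <- calibrate_alpha_linear(p, 0.15, k = 15, n_assign = 200, seed = 2)
  excess <- function(sim) {
    sum((sim$observed$crude_rate - sim$baseline$crude_rate) *
          sim$baseline$population) / 1e5
  }
  ex_pair <- vapply(1:200, function(j) {
    asg <- assign_policy(p, 15, seed = 1000 + j)
    ex <- code_exposure(asg, p, "instantaneous")
    add <- inject_effect(p, ex, effect_spec("medium", "+", alpha_linear = al),
                         "additive_rate")
    mult <- inject_effect(p, ex, effect_spec("medium", "+"), "multiplicative")
    c(excess(add), excess(mult))
  }, numeric(2))
  # total excess deaths over replicate assignments match across the scales;
  # the exposure-weighted mean rate varies ~24% across assignments, so two
  # independent 200-draw averages agree to ~2.4% (1 MC se); 0.08 is ~3 se
  expect_lt(abs(sum(ex_pair[1, ]) / sum(ex_pair[2, ]) - 1), 0.08)
})

test_that("effect injection follows the potential-outcomes identity", {
  p <- generate_baseline(baseline_config(seed = 23))
  asg <- assign_policy(p, 10, seed = 3)
  ex <- code_exposure(asg, p, "instantaneous")

  nul <- inject_effect(p, ex, effect_spec("null"), "additive_rate")
  expect_identical(as.data.frame(nul$observed), as.data.frame(p))
  expect_equal(nul$truth, 0)

  eff <- effect_spec("small", "+")
  sim <- inject_effect(p, ex, eff, "multiplicative")
  y1 <- p$crude_rate * (1 + eff$s)  # fully treated potential outcome
  expect_equal(sim$observed$crude_rate, ex$A * y1 + (1 - ex$A) * p$crude_rate,
               tolerance = 1e-12)
  expect_true(all(sim$observed$crude_rate[ex$A == 0] == p$crude_rate[ex$A == 0]))
  expect_equal(sim$truth, log(1.05))
})

test_that("worked injection examples hold exactly", {
  p <- toy_panel(matrix(c(10, 10, 10, 10, 10, 8, 8, 8, 8, 8), nrow = 2,
                        byrow = TRUE), first_year = 2000L)
  A <- rbind(c(0, 0, 0.5, 1, 1), rep(0, 5))
  sim0 <- manual_sim(p, A)
  ex <- sim0$exposure

  mult <- inject_effect(p, ex, effect_spec("small", "+"), "multiplicative")
  expect_equal(mult$observed$crude_rate[mult$observed$state == "S01"],
               c(10, 10, 10 * 1.025, 10.5, 10.5))

  add <- inject_effect(p, ex, effect_spec("large", "+", alpha_linear = 1.16),
                       "additive_rate")
  expect_equal(add$observed$crude_rate[add$observed$state == "S01"][3], 10.58)
})

test_that("signed injections are symmetric about the baseline", {
  p <- generate_baseline(baseline_config(seed = 24))
  asg <- assign_policy(p, 8, seed = 5)
  ex <- code_exposure(asg, p, "linear_3yr")
  up <- inject_effect(p, ex, effect_spec("medium", "+"), "multiplicative")
  dn <- inject_effect(p, ex, effect_spec("medium", "-"), "multiplicative")
  expect_equal(up$observed$crude_rate - p$crude_rate,
               -(dn$observed$crude_rate - p$crude_rate), tolerance = 1e-12)
})

test_that("additive injections that would go negative are clamped and counted", {
  p <- toy_panel(matrix(c(0.5, 0.5, 0.5, 0.5, 0.5, 9, 9, 9, 9, 9), nrow = 2,
                        byrow = TRUE), populations = c(2e6, 2e6))
  A <- rbind(c(0, 0, 1, 1, 1), rep(0, 5))
  ex <- manual_sim(p, A)$exposure
  expect_warning(
    sim <- inject_effect(p, ex, effect_spec("large", "-", alpha_linear = -2),
                         "additive_rate"),
    "clamped"
  )
  expect_equal(sim$n_clamped, 3)
  expect_true(all(sim$observed$crude_rate >= 0))
})
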