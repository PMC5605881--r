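test_that("the parent compared with itself is exactly null in every draw", {
  ds <- make_benchmark_cohort("null", seed = 2)
  fit <- fit_fanova(ds, fanova_spec(),
                    mcmc_control(n_draws = 40, burnin = 20), seed = 2)
  for (cond in fit$levels$condition) {
    traj <- od_delta(fit, "parent", cond, parent = "parent",
                     standard = "standard")
    expect_true(all(attr(traj, "samples") == 0))
    nrm <- od_delta_norm(traj)
    expect_identical(nrm$norm_median, 0)
    expect_false(significance_call(traj, nrm)$significant)
  }
})

test_that("od_delta recovers a planted interaction effect under stress", {
  ds <- make_benchmark_cohort("cross_stress_demo", seed = 4)
  truth <- sim_truth(ds)
  fit <- fit_fanova(ds, fanova_spec(),
                    mcmc_control(n_draws = 200, burnin = 200), seed = 4)
  traj <- od_delta(fit, "mutB", "low_salt", parent = "parent",
                   standard = "standard")
  I <- truth$interactions[["strain:condition"]]
  true_delta <- I["mutB", "low_salt", ] - I["parent", "low_salt", ] -
    I["mutB", "standard", ] + I["parent", "standard", ]
  # truth lies within the pointwise 95% band almost everywhere and the
  # posterior mean tracks it within about one noise SD
  expect_gte(mean(traj$lower <= true_delta & true_delta <= traj$upper), 0.85)
  expect_gt(cor(traj$mean, true_delta), 0.95)
  expect_lt(max(abs(traj$mean - true_delta)), 0.1)
})

test_that("norm arithmetic matches the summed-square definition", {
  grid10 <- seq(1, 10)
  traj1 <- phenogp:::new_odelta_trajectory(
    matrix(1, nrow = 5, ncol = 10), grid10, "m", "c", "p")
  nrm <- od_delta_norm(traj1)
  expect_identical(unique(attr(nrm, "samples")), 10)
  expect_identical(nrm$norm_median, 10)

  # zero trajectory has zero norm
  traj0 <- phenogp:::new_odelta_trajectory(
    matrix(0, 3, 10), grid10, "m", "c", "p")
  expect_identical(od_delta_norm(traj0)$norm_median, 0)

  # halving the grid spacing on a smooth trajectory ~ doubles the norm
  f <- function(t) 0.5 * sin(t / 8)
  coarse <- seq(4, 48, by = 1)
  fine <- seq(4, 48, by = 0.5)
  n_coarse <- od_delta_norm(phenogp:::new_odelta_trajectory(
    matrix(f(coarse), 1), coarse, "m", "c", "p"))$norm_median
  n_fine <- od_delta_norm(phenogp:::new_odelta_trajectory(
    matrix(f(fine), 1), fine, "m", "c", "p"))$norm_median
  expect_equal(n_fine / n_coarse, 2, tolerance = 0.05)

  # pointwise same-sign increase never decreases the norm
  S <- matrix(rnorm(50), 5, 10)
  n1 <- od_delta_norm(phenogp:::new_odelta_trajectory(S, grid10, "m", "c", "p"))
  n2 <- od_delta_norm(phenogp:::new_odelta_trajectory(1.5 * S, grid10,
                                                      "m", "c", "p"))
  expect_true(all(attr(n2, "samples") >= attr(n1, "samples")))
})

test_that("significance calls flag exactly the band-excluding times", {
  grid <- seq(4, 40, by = 1)
  set.seed(31)
  # effect present only on [20, 30]
  eff <- ifelse(grid >= 20 & grid <= 30, 0.5, 0)
  S <- t(replicate(400, eff + rnorm(length(grid), sd = 0.05)))
  traj <- phenogp:::new_odelta_trajectory(S, grid, "m", "c", "p")
  call <- significance_call(traj)
  expect_true(call$significant)
  expect_identical(call$direction, "faster")
  iv <- attr(call, "intervals")
  expect_gte(min(iv$start), 19)
  expect_lte(max(iv$end), 31)

  # cross-check against direct quantile recomputation
  lo <- apply(S, 2, quantile, 0.025)
  hi <- apply(S, 2, quantile, 0.975)
  expect_equal(call$n_sig_times, sum(lo > 0 | hi < 0))

  # band straddling zero everywhere is never significant
  S0 <- t(replicate(400, rnorm(length(grid), sd = 0.05)))
  call0 <- significance_call(phenogp:::new_odelta_trajectory(S0, grid,
                                                             "m", "c", "p"))
  expect_false(call0$significant)
  expect_identical(nrow(attr(call0, "intervals")), 0L)
  expect_identical(call0$direction, "none")

  # a magnitude cutoff can veto an otherwise significant call
  call_cut <- significance_call(traj, cutoff = 1e6)
  expect_false(call_cut$significant)
})

test_that("a planted effect of 3x the noise SD is detected over its support", {
  grid <- seq(4, 40, by = 1)
  cfg <- sim_config(n_strains = 2, n_conditions = 1, n_bio = 3, n_tech = 2,
                    grid = grid,
                    magnitudes = list(strain = 0, condition = 0,
                                      interaction = 0, batch = 0),
                    noise_sd = 0.05,
                    strain_names = c("parent", "mut"))
  truth <- draw_true_effects(cfg, seed = 9)
  support <- grid >= 15
  eff <- ifelse(support, 0.15, 0)   # 3x noise SD once support is reached
  truth$effects$strain <- phenogp:::center_effects(
    rbind(parent = 0 * grid, mut = eff))
  ds <- simulate_dataset(cfg, truth, seed = 9)
  fit <- fit_fanova(ds, fanova_spec(effects = "strain",
                                    interactions = list()),
                    mcmc_control(n_draws = 1000, burnin = 300), seed = 9)
  traj <- od_delta(fit, "mut", parent = "parent")
  excl <- traj$lower > 0 | traj$upper < 0
  expect_gt(mean(excl[support]), 0.8)
})

test_that("heat-shock baseline subtraction removes pre-shock divergence", {
  grid <- seq(4, 48, by = 1)
  defect <- ifelse(grid >= 16, -0.6 * (1 - exp(-(grid - 16) / 5)), 0)
  for (offset in c(0, 0.4)) {
    eff <- phenogp:::center_effects(rbind(parent = 0 * grid,
                                          mut = offset + defect))
    fit <- fake_strain_fit(grid, eff, S = 200, draw_sd = 0.02)
    traj <- od_delta_heatshock(fit, "mut", "parent", shock_start = 16)
    expect_equal(min(traj$time), 16)
    target <- defect[grid >= 16]
    # recovered trajectory is the post-shock defect, independent of offset
    expect_lt(max(abs(traj$mean - target)), 0.02)
  }
  # strain = parent is identically zero
  eff <- phenogp:::center_effects(rbind(parent = 0 * grid, mut = defect))
  fit <- fake_strain_fit(grid, eff, S = 50)
  traj_p <- od_delta_heatshock(fit, "parent", "parent", shock_start = 16)
  expect_true(all(attr(traj_p, "samples") == 0))

  expect_error(od_delta_heatshock(fit, "mut", "parent", shock_start = 16.3),
               "grid", class = "phenogp_domain_error")
})

test_that("ranking orders by descending magnitude with lexicographic ties", {
  norms <- tibble::tibble(strain = c("a", "b", "c"),
                          norm_median = c(2, 1, 3))
  rk <- rank_mutants(norms)
  expect_identical(rk$strain, c("c", "a", "b"))
  expect_identical(rk$rank, 1:3)

  ties <- tibble::tibble(strain = c("zeta", "alpha"), norm_median = c(1, 1))
  expect_identical(rank_mutants(ties)$strain, c("alpha", "zeta"))

  expect_error(rank_mutants(tibble::tibble(strain = c("a", "a"),
                                           norm_median = c(1, 2))),
               class = "phenogp_domain_error")
})

test_that("the universal cutoff excludes non-credible and sub-top-decile strains", {
  # all strains flat: nobody's extremum is credibly nonzero, so the cutoff
  # sits above every magnitude and no mutant passes
  flat <- tidyr::expand_grid(strain = sprintf("s%02d", 1:8),
                             condition = c("standard", "ox")) |>
    dplyr::mutate(norm_median = runif(dplyr::n(), 0.01, 0.2),
                  extremal_significant = FALSE)
  cut_flat <- select_cutoff(flat, standard = "standard")
  expect_true(all(flat$norm_median < cut_flat))

  # 2 of 20 strains carry large, credible standard-condition effects
  set.seed(14)
  std <- tibble::tibble(
    strain = sprintf("s%02d", 1:20),
    condition = "standard",
    norm_median = c(runif(18, 0.01, 0.3), 5, 7),
    extremal_significant = c(rep(FALSE, 18), TRUE, TRUE))
  cut2 <- select_cutoff(std, standard = "standard")
  passing <- std$strain[std$norm_median >= cut2]
  expect_setequal(passing, c("s19", "s20"))

  expect_error(select_cutoff(std[1, ], standard = "standard"),
               class = "phenogp_domain_error")
})
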