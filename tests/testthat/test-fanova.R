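test_that("mean-only MCMC matches the closed-form GP-regression posterior", {
  grid <- seq(4, 13, by = 1)
  set.seed(21)
  curve <- gompertz_baseline(grid, A = 2, mumax = 0.4, lag = 5) - 0.8
  rows <- purrr::map_dfr(1:3, function(r) {
    tibble::tibble(strain = "s1", condition = "c1", batch = "b1",
                   bio_rep = paste0("r", r), tech_rep = "t1",
                   time = grid, value = curve + rnorm(length(grid), sd = 0.1))
  })
  ds <- growth_dataset(rows, normalized = TRUE, interval = 1)
  kern <- rbf_kernel(variance = 1, lengthscale = 30)
  spec <- fanova_spec(effects = character(0), interactions = list(),
                      kernels = list(mu = kern), noise_variance = 0.01)
  fit <- fit_fanova(ds, spec,
                    mcmc_control(n_draws = 2000, burnin = 200,
                                 sample_hyperparams = FALSE), seed = 4)
  obs <- tibble::tibble(time = rows$time, value = rows$value, coef_mu = 1)
  oracle <- conjugate_oracle(obs, grid, list(mu = kern), noise_var = 0.01)
  M <- mu_draws(fit)
  for (t in seq_along(grid)) {
    se <- mcse_batch(M[, t])
    expect_lt(abs(mean(M[, t]) - oracle$mean[t]), 3 * se)
  }
  # posterior variance agrees too (conjugate model, fixed hyperparameters)
  for (t in seq_along(grid)) {
    se_v <- mcse_batch((M[, t] - mean(M[, t]))^2)
    expect_lt(abs(var(M[, t]) - oracle$var[t]), 3 * se_v + 0.02 * oracle$var[t])
  }
})

test_that("near-zero noise makes the conditional mean interpolate the data", {
  grid <- seq(4, 13, by = 1)
  curve <- sin(grid / 3)
  rows <- tibble::tibble(strain = "s1", condition = "c1", batch = "b1",
                         bio_rep = "r1", tech_rep = "t1",
                         time = grid, value = curve)
  ds <- growth_dataset(rows, normalized = TRUE, interval = 1)
  spec <- fanova_spec(effects = character(0), interactions = list(),
                      kernels = list(mu = rbf_kernel(1, 30)),
                      noise_variance = 1e-10)
  fit <- fit_fanova(ds, spec,
                    mcmc_control(n_draws = 200, burnin = 50,
                                 sample_hyperparams = FALSE), seed = 2)
  expect_lt(max(abs(colMeans(mu_draws(fit)) - curve)), 1e-3)
})

test_that("identical data, spec and seed give bit-identical chains", {
  ds <- variant_data(list(strain = c("p", "m")), seed = 8)
  spec <- fanova_spec(effects = "strain", interactions = list())
  ctl <- mcmc_control(n_draws = 30, burnin = 20)
  f1 <- fit_fanova(ds, spec, ctl, seed = 11)
  f2 <- fit_fanova(ds, spec, ctl, seed = 11)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$hyper_draws, f2$hyper_draws)
  f3 <- fit_fanova(ds, spec, ctl, seed = 12)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("unobserved spec levels and missing interaction cells are errors", {
  ds <- variant_data(list(strain = c("p", "m"), condition = c("std", "ox")),
                     seed = 5)
  spec <- fanova_spec(levels = list(strain = c("p", "m", "ghost")))
  expect_error(fit_fanova(ds, spec, mcmc_control(10, 0), seed = 1),
               "ghost", class = "phenogp_validation_error")

  # drop one (strain, condition) cell: interaction becomes unfittable
  x <- tibble::as_tibble(ds)
  x <- x[!(x$strain == "m" & x$condition == "ox"), ]
  ds2 <- growth_dataset(x, normalized = TRUE, interval = 1)
  expect_error(fit_fanova(ds2, fanova_spec(), mcmc_control(10, 0), seed = 1),
               "unobserved", class = "phenogp_validation_error")

  expect_error(fit_fanova(normalize_growth(
    growth_dataset(dplyr::mutate(make_raw_table(times = seq(0, 6, 0.5)),
                                 time = time_h, value = od600))),
    fanova_spec(effects = "strain", interactions = list()),
    mcmc_control(2, 0), seed = 1), NA)
})

test_that("every fitted model variant satisfies the sum-to-zero constraints", {
  ctl <- mcmc_control(n_draws = 25, burnin = 15)

  # two effects with interaction (joint multi-condition model)
  ds3 <- variant_data(list(strain = c("p", "m1", "m2"),
                           condition = c("std", "ox")), seed = 1)
  fit3 <- fit_fanova(ds3, fanova_spec(), ctl, seed = 1)
  expect_lt(max_sum_to_zero_violation(fit3), 1e-8)

  # strain-only shock model
  ds10 <- variant_data(list(strain = c("p", "m1", "m2")), seed = 2)
  fit10 <- fit_fanova(ds10, fanova_spec(effects = "strain",
                                        interactions = list()), ctl,
                      seed = 2)
  expect_lt(max_sum_to_zero_violation(fit10), 1e-8)

  # three two-level effects, no interaction (complementation design)
  ds11 <- variant_data(list(strain = c("p", "m"),
                            vector = c("no", "yes"),
                            plasmid = c("no", "yes")), seed = 3)
  fit11 <- fit_fanova(ds11, fanova_spec(
    effects = c("strain", "vector", "plasmid"), interactions = list()),
    ctl, seed = 3)
  expect_lt(max_sum_to_zero_violation(fit11), 1e-8)

  # four effects with two interactions (extended complementation design)
  ds12 <- variant_data(list(strain = c("p", "m"),
                            condition = c("std", "ox"),
                            vector = c("no", "yes"),
                            plasmid = c("no", "yes")), seed = 4)
  fit12 <- fit_fanova(ds12, fanova_spec(
    effects = c("strain", "condition", "vector", "plasmid"),
    interactions = list(c("strain", "condition"),
                        c("condition", "plasmid"))), ctl, seed = 4)
  expect_lt(max_sum_to_zero_violation(fit12), 1e-8)
})

test_that("batch functions are modeled as an additional sum-to-zero set", {
  ds <- variant_data(list(strain = c("p", "m"), condition = c("std", "ox"),
                          batch = c("b1", "b2")), seed = 6)
  fit <- fit_fanova(ds, fanova_spec(batch = TRUE),
                    mcmc_control(n_draws = 20, burnin = 10), seed = 6)
  expect_true("batch" %in% names(fit$levels))
  B <- effect_draws(fit, "batch")
  expect_lt(max(abs(apply(B, c(1, 3), sum))), 1e-8)
})

test_that("tidy and glance summarize a fit", {
  ds <- variant_data(list(strain = c("p", "m"), condition = c("std", "ox")),
                     seed = 7)
  fit <- fit_fanova(ds, fanova_spec(), mcmc_control(20, 10), seed = 7)
  td <- tidy(fit)
  expect_true(all(c("term", "level", "time", "estimate", "conf.low",
                    "conf.high") %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate + 1e-12))
  expect_setequal(unique(td$term),
                  c("mu", "strain", "condition", "strain:condition"))
  gl <- glance(fit)
  expect_equal(gl$n_draws, 20)
  expect_equal(gl$n_latent_functions, 1 + 1 + 1 + 1)
  expect_gt(gl$noise_sd, 0)
})
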