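#' Simulation configuration for synthetic growth cohorts
#'
#' Describes a cohort with the same generative structure the FANOVA model
#' assumes: a shared baseline growth function plus sum-to-zero functional
#' effects of strain, condition, and batch, a doubly sum-to-zero
#' strain-condition interaction, replicate structure, and i.i.d. Gaussian
#' observation noise on the log2 scale. Defaults emulate the plate-reader
#' protocol the model targets: readings every 30 minutes out to 48 hours
#' (the first 4 h pre-trimmed), biological x technical replication, and a
#' noise SD of 0.05 log2-OD units.
#'
#' @param n_strains,n_conditions,n_batches Factor level counts (>= 1).
#' @param n_bio,n_tech Biological and technical replicates per cell.
#' @param grid Time grid in hours (default 4 to 48 h in 0.5-h steps).
#' @param magnitudes Named list of effect standard deviations (log2-OD
#'   units) used as the GP signal SD for `strain`, `condition`,
#'   `interaction`, `batch`. A magnitude of 0 switches a component off.
#' @param lengthscale RBF lengthscale (hours^2) for effect draws.
#' @param noise_sd Observation noise SD.
#' @param strain_names,condition_names,batch_names Optional level labels.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_strains = 3, n_conditions = 2, n_batches = 1,
                       n_bio = 2, n_tech = 2,
                       grid = seq(4, 48, by = 0.5),
                       magnitudes = list(strain = 0.5, condition = 0.5,
                                         interaction = 0.3, batch = 0.2),
                       lengthscale = 100,
                       noise_sd = 0.05,
                       strain_names = NULL,
                       condition_names = NULL,
                       batch_names = NULL) {
  stopifnot(n_strains >= 1, n_conditions >= 1, n_batches >= 1,
            n_bio >= 1, n_tech >= 1, length(grid) >= 2,
            all(diff(grid) > 0), noise_sd >= 0)
  strain_names <- strain_names %||%
    c("parent", sprintf("mut%02d", seq_len(max(0, n_strains - 1))))
  condition_names <- condition_names %||%
    c("standard", "low_salt", "paraquat", "peroxide",
      "heat_shock")[seq_len(n_conditions)]
  batch_names <- batch_names %||% sprintf("b%d", seq_len(n_batches))
  stopifnot(length(strain_names) == n_strains,
            length(condition_names) == n_conditions,
            length(batch_names) == n_batches)
  structure(list(n_strains = n_strains, n_conditions = n_conditions,
                 n_batches = n_batches, n_bio = n_bio, n_tech = n_tech,
                 grid = grid, magnitudes = magnitudes,
                 lengthscale = lengthscale, noise_sd = noise_sd,
                 strain_names = strain_names,
                 condition_names = condition_names,
                 batch_names = batch_names),
            class = "sim_config")
}

#' Modified-Gompertz baseline growth curve
#'
#' The standard three-phase (lag / exponential / stationary) log-growth
#' shape, `A * exp(-exp(mumax * e * (lag - t) / A + 1))`: near zero during
#' the lag phase, rising at maximum rate `mumax`, and saturating at the
#' carrying capacity `A`. Used only as a realistic baseline shape for the
#' simulated mean function — the analysis model itself is nonparametric.
#'
#' @param grid Time grid (hours).
#' @param A Carrying capacity (log2-OD units), > 0.
#' @param mumax Maximum growth rate (log2-OD per hour), > 0.
#' @param lag Lag time (hours), >= 0.
#' @return Numeric vector on `grid`; nondecreasing, tending to `A`.
#' @export
gompertz_baseline <- function(grid, A = 3, mumax = 0.25, lag = 2) {
  if (A <= 0 || mumax <= 0 || lag < 0) {
    abort("gompertz_baseline: need A > 0, mumax > 0, lag >= 0",
          class = "phenogp_domain_error")
  }
  A * exp(-exp(mumax * exp(1) * (lag - grid) / A + 1))
}

#' Draw ground-truth functional effects from the model's own prior
#'
#' Contrast functions for each factor (and the strain-condition
#' interaction) are drawn from a zero-mean GP with an RBF kernel (variance
#' `magnitude^2`, the configured lengthscale) and mapped through the
#' contrast basis, so every sum-to-zero constraint holds by construction.
#' The baseline is a [gompertz_baseline()] curve.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A `true_effects` list: `grid`, `mu`, `effects` (named list of
#'   level x time matrices), `interactions` (named list of
#'   level1 x level2 x time arrays), `noise_sd`.
#' @export
draw_true_effects <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  grid <- cfg$grid
  n_t <- length(grid)
  draw_set <- function(n_levels, magnitude) {
    if (n_levels < 2 || magnitude <= 0) {
      return(matrix(0, max(n_levels, 1), n_t))
    }
    K <- rbf_cov(grid, grid, rbf_kernel(magnitude^2, cfg$lengthscale))
    R <- chol_jitter(K, magnitude^2)
    contrasts <- t(R) %*% matrix(rnorm(n_t * (n_levels - 1)),
                                 n_t, n_levels - 1)
    effects_from_contrasts(contrast_basis(n_levels), t(contrasts))
  }
  effects <- list(
    strain = draw_set(cfg$n_strains, cfg$magnitudes$strain %||% 0),
    condition = draw_set(cfg$n_conditions, cfg$magnitudes$condition %||% 0),
    batch = draw_set(cfg$n_batches, cfg$magnitudes$batch %||% 0))
  rownames(effects$strain) <- cfg$strain_names
  rownames(effects$condition) <- cfg$condition_names
  rownames(effects$batch) <- cfg$batch_names
  interactions <- list()
  mag_i <- cfg$magnitudes$interaction %||% 0
  if (cfg$n_strains >= 2 && cfg$n_conditions >= 2 && mag_i > 0) {
    K <- rbf_cov(grid, grid, rbf_kernel(mag_i^2, cfg$lengthscale))
    R <- chol_jitter(K, mag_i^2)
    n_fns <- (cfg$n_strains - 1) * (cfg$n_conditions - 1)
    contrasts <- t(t(R) %*% matrix(rnorm(n_t * n_fns), n_t, n_fns))
    CK <- kronecker(contrast_basis(cfg$n_strains),
                    contrast_basis(cfg$n_conditions))
    M <- CK %*% contrasts                       # (n_s * n_c) x n_t, cond fastest
    arr <- aperm(array(M, dim = c(cfg$n_conditions, cfg$n_strains, n_t)),
                 c(2, 1, 3))
    dimnames(arr) <- list(cfg$strain_names, cfg$condition_names, NULL)
    interactions[["strain:condition"]] <- arr
  } else {
    arr <- array(0, dim = c(cfg$n_strains, cfg$n_conditions, n_t))
    dimnames(arr) <- list(cfg$strain_names, cfg$condition_names, NULL)
    interactions[["strain:condition"]] <- arr
  }
  structure(list(grid = grid,
                 mu = gompertz_baseline(grid),
                 effects = effects,
                 interactions = interactions,
                 noise_sd = cfg$noise_sd),
            class = "true_effects")
}

# center a raw (level x time) effect matrix so columns sum to zero
center_effects <- function(E) {
  sweep(E, 2, colMeans(E), "-")
}

# double-center a raw (level1 x level2 x time) interaction array so both
# margins sum to zero at every time
center_interaction <- function(M) {
  for (t in seq_len(dim(M)[3])) {
    slab <- M[, , t]
    slab <- sweep(slab, 1, rowMeans(slab), "-")
    slab <- sweep(slab, 2, colMeans(slab), "-")
    M[, , t] <- slab
  }
  M
}

# Add raw per-cell (strain x condition x time) effects to a truth record by
# ANOVA decomposition: grand mean into mu, centered row/column means into
# the strain and condition main effects, the double-centered remainder into
# the interaction. Keeps all sum-to-zero constraints while generating data
# whose cell means equal mu + main effects + raw cell effect exactly.
plant_cell_effects <- function(truth, raw) {
  n_t <- dim(raw)[3]
  grand <- apply(raw, 3, mean)
  rowm <- apply(raw, c(1, 3), mean)
  colm <- apply(raw, c(2, 3), mean)
  truth$mu <- truth$mu + grand
  truth$effects$strain <- truth$effects$strain +
    sweep(rowm, 2, grand, "-")
  truth$effects$condition <- truth$effects$condition +
    sweep(colm, 2, grand, "-")
  int <- raw
  for (t in seq_len(n_t)) {
    int[, , t] <- raw[, , t] -
      outer(rowm[, t], rep(1, dim(raw)[2])) -
      outer(rep(1, dim(raw)[1]), colm[, t]) + grand[t]
  }
  truth$interactions[["strain:condition"]] <-
    truth$interactions[["strain:condition"]] + int
  truth
}

#' Simulate a growth dataset from ground-truth effects
#'
#' Every replicate curve is the baseline plus its strain, condition, batch
#' and interaction effect functions plus i.i.d. Gaussian noise, generated
#' directly on the normalized (log2, trimmed) scale. The truth record is
#' attached as an attribute (see [sim_truth()]).
#'
#' @param cfg A [sim_config()].
#' @param truth A `true_effects` object matching `cfg` (default: drawn from
#'   the prior with the same seed).
#' @param seed Integer seed for the observation noise.
#' @return A normalized [growth_dataset()] with the truth in
#'   `attr(, "truth")`.
#' @export
simulate_dataset <- function(cfg, truth = NULL, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(truth)) truth <- draw_true_effects(cfg, seed = seed)
  stopifnot(inherits(truth, "true_effects"))
  n_t <- length(cfg$grid)
  if (nrow(truth$effects$strain) != cfg$n_strains ||
      nrow(truth$effects$condition) != cfg$n_conditions ||
      ncol(truth$effects$strain) != n_t) {
    abort("truth dimensions do not match the configuration",
          class = "phenogp_domain_error")
  }
  set.seed(as.integer(seed) + 1L)
  cells <- tidyr::expand_grid(
    strain = cfg$strain_names,
    condition = cfg$condition_names,
    batch = cfg$batch_names,
    bio_rep = sprintf("bio%d", seq_len(cfg$n_bio)),
    tech_rep = sprintf("tech%d", seq_len(cfg$n_tech)))
  I <- truth$interactions[["strain:condition"]]
  rows <- purrr::pmap_dfr(cells, function(strain, condition, batch,
                                          bio_rep, tech_rep) {
    i <- match(strain, cfg$strain_names)
    j <- match(condition, cfg$condition_names)
    b <- match(batch, cfg$batch_names)
    mu_curve <- truth$mu +
      truth$effects$strain[i, ] +
      truth$effects$condition[j, ] +
      I[i, j, ] +
      truth$effects$batch[b, ]
    tibble::tibble(strain = strain, condition = condition, batch = batch,
                   bio_rep = bio_rep, tech_rep = tech_rep,
                   time = cfg$grid,
                   value = mu_curve + rnorm(n_t, sd = truth$noise_sd))
  })
  ds <- growth_dataset(rows, normalized = TRUE,
                       interval = min(diff(cfg$grid)))
  attr(ds, "truth") <- truth
  ds
}

#' @rdname simulate_dataset
#' @param ds A simulated dataset.
#' @export
sim_truth <- function(ds) attr(ds, "truth")

#' Benchmark cohort presets
#'
#' Named synthetic cohorts used throughout the test suite and examples:
#'
#' * `"null"` — 3 strains x 2 conditions, no effects at all; used to
#'   calibrate the false-positive rate of the pointwise credible-band
#'   significance rule.
#' * `"small"` — 3 strains x 2 conditions on a 30-point grid with 4
#'   replicate curves per cell, effects drawn from the model's own GP
#'   prior; used for parameter-recovery checks.
#' * `"cross_stress_demo"` — 4 strains x 3 conditions; the planted strain
#'   `mutB` carries a growth defect under both stress conditions (but not
#'   under standard growth), emulating a cross-stress phenotype, and `mutC`
#'   a standard-condition defect.
#' * `"heatshock_demo"` — 3 strains, one shock condition on the full
#'   30-minute grid; `mutHS` diverges from the parent by a constant before
#'   the 16-h shock and develops a growth defect only after it.
#' * `"full_shape"` — the full cohort shape (28 strains x 5 conditions,
#'   biological quadruplicate x technical triplicate, 2 batches) with
#'   GP-drawn effects plus a planted strain with a standard-condition
#'   defect and stress improvement and a planted peroxide-defect strain;
#'   qualitative emulation only, for demos and load testing.
#'
#' @param preset Preset name.
#' @param seed Integer seed.
#' @return A normalized [growth_dataset()] with truth attached.
#' @export
make_benchmark_cohort <- function(preset = c("null", "small",
                                             "cross_stress_demo",
                                             "heatshock_demo",
                                             "full_shape"),
                                  seed = 1) {
  preset <- match.arg(preset)
  grid30 <- seq(4, 47.5, by = 1.5)
  switch(preset,
    null = {
      cfg <- sim_config(n_strains = 3, n_conditions = 2, n_bio = 2,
                        n_tech = 1, grid = grid30,
                        magnitudes = list(strain = 0, condition = 0,
                                          interaction = 0, batch = 0))
      truth <- draw_true_effects(cfg, seed = seed)
      simulate_dataset(cfg, truth, seed = seed)
    },
    small = {
      cfg <- sim_config(n_strains = 3, n_conditions = 2, n_bio = 2,
                        n_tech = 2, grid = grid30,
                        magnitudes = list(strain = 0.5, condition = 0.5,
                                          interaction = 0.3, batch = 0))
      simulate_dataset(cfg, seed = seed)
    },
    cross_stress_demo = {
      cfg <- sim_config(n_strains = 4, n_conditions = 3, n_bio = 2,
                        n_tech = 2, grid = grid30,
                        magnitudes = list(strain = 0, condition = 0,
                                          interaction = 0, batch = 0),
                        strain_names = c("parent", "mutA", "mutB", "mutC"),
                        condition_names = c("standard", "low_salt",
                                            "peroxide"))
      truth <- draw_true_effects(cfg, seed = seed)
      ramp <- 1 / (1 + exp(-(grid30 - 20) / 4))
      # stress conditions depress growth relative to standard
      cond_raw <- rbind(standard = 0 * ramp,
                        low_salt = -0.4 * ramp,
                        peroxide = -0.6 * ramp)
      truth$effects$condition <- center_effects(cond_raw)
      rownames(truth$effects$condition) <- cfg$condition_names
      # mutB: defect under both stresses only; mutC: standard-only defect
      I_raw <- array(0, dim = c(4, 3, length(grid30)),
                     dimnames = list(cfg$strain_names, cfg$condition_names,
                                     NULL))
      I_raw["mutB", "low_salt", ] <- -0.8 * ramp
      I_raw["mutB", "peroxide", ] <- -0.8 * ramp
      I_raw["mutC", "standard", ] <- -0.7 * ramp
      truth <- plant_cell_effects(truth, I_raw)
      simulate_dataset(cfg, truth, seed = seed)
    },
    heatshock_demo = {
      grid_hs <- seq(4, 48, by = 0.5)
      cfg <- sim_config(n_strains = 3, n_conditions = 1, n_bio = 2,
                        n_tech = 2, grid = grid_hs,
                        magnitudes = list(strain = 0, condition = 0,
                                          interaction = 0, batch = 0),
                        strain_names = c("parent", "mutA", "mutHS"),
                        condition_names = "heat_shock")
      truth <- draw_true_effects(cfg, seed = seed)
      defect <- ifelse(grid_hs >= 16,
                       -0.8 * (1 - exp(-(grid_hs - 16) / 6)), 0)
      # constant pre-shock divergence plus a post-shock-only defect
      E_raw <- rbind(parent = 0 * grid_hs,
                     mutA = 0 * grid_hs,
                     mutHS = 0.2 + defect)
      truth$effects$strain <- center_effects(E_raw)
      rownames(truth$effects$strain) <- cfg$strain_names
      simulate_dataset(cfg, truth, seed = seed)
    },
    full_shape = {
      cfg <- sim_config(n_strains = 28, n_conditions = 5, n_batches = 2,
                        n_bio = 4, n_tech = 3, grid = seq(4, 48, by = 0.5),
                        magnitudes = list(strain = 0.3, condition = 0.5,
                                          interaction = 0.3, batch = 0.1),
                        strain_names = c("parent",
                                         sprintf("mut%02d", 1:25),
                                         "trmB_like", "sirR_like"))
      truth <- draw_true_effects(cfg, seed = seed)
      grid <- cfg$grid
      ramp <- 1 / (1 + exp(-(grid - 20) / 4))
      I <- truth$interactions[["strain:condition"]]
      raw <- array(0, dim = dim(I), dimnames = dimnames(I))
      raw["trmB_like", "standard", ] <- -0.6 * ramp
      raw["trmB_like", "low_salt", ] <- 1.0 * ramp
      raw["trmB_like", "paraquat", ] <- 0.5 * ramp
      raw["sirR_like", "peroxide", ] <- -0.8 * ramp
      truth <- plant_cell_effects(truth, raw)
      simulate_dataset(cfg, truth, seed = seed)
    })
}
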