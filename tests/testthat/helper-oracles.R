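# Independent linear-Gaussian oracle for the FANOVA posterior with fixed
# hyperparameters. Builds the dense design matrix over all latent
# coordinates (mu, strain contrast, condition contrast, interaction
# contrast on the grid) and computes the exact conjugate posterior by
# direct matrix algebra — no code shared with the sampler beyond the kernel
# definition it checks against.
conjugate_oracle <- function(obs, grid, kernels, noise_var, jitter = NULL) {
  n_t <- length(grid)
  groups <- names(kernels)
  rbf <- function(k) {
    d2 <- outer(grid, grid, function(a, b) (a - b)^2)
    K <- k$variance * exp(-d2 / k$lengthscale)
    K + diag(if (is.null(jitter)) 1e-6 * k$variance else jitter, n_t)
  }
  Sigma0 <- matrix(0, n_t * length(groups), n_t * length(groups))
  for (gi in seq_along(groups)) {
    idx <- (gi - 1) * n_t + seq_len(n_t)
    Sigma0[idx, idx] <- rbf(kernels[[gi]])
  }
  X <- matrix(0, nrow(obs), n_t * length(groups))
  for (r in seq_len(nrow(obs))) {
    g <- match(obs$time[r], grid)
    for (gi in seq_along(groups)) {
      X[r, (gi - 1) * n_t + g] <- obs[[paste0("coef_", groups[gi])]][r]
    }
  }
  P <- solve(Sigma0) + crossprod(X) / noise_var
  Sigma_post <- solve(P)
  mean_post <- Sigma_post %*% (t(X) %*% obs$value) / noise_var
  list(mean = as.vector(mean_post), var = diag(Sigma_post),
       Sigma = Sigma_post, X = X, Sigma0 = Sigma0)
}

# batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) chain
mcse_batch <- function(x, n_batch = 40) {
  n <- length(x)
  b <- floor(n / n_batch)
  bm <- colMeans(matrix(x[seq_len(b * n_batch)], nrow = b))
  max(stats::sd(bm) / sqrt(n_batch), 1e-10)
}

# exhaustive enumeration oracle for the upper-tail hypergeometric
# probability: enumerate every n-subset of an N-universe whose first K
# elements are marked, and count subsets with overlap >= k
hyper_tail_enum <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# build a gp_fanova-shaped object whose strain-effect draws are a known
# deterministic effect matrix plus optional draw-level jitter, for testing
# the metric layer without running MCMC
fake_strain_fit <- function(grid, effects, S = 100, draw_sd = 0.0,
                            seed = 42) {
  set.seed(seed)
  stopifnot(abs(colSums(effects)) < 1e-10)
  n <- nrow(effects); n_t <- length(grid)
  C <- phenogp::contrast_basis(n)
  contrasts <- t(C) %*% effects              # (n-1) x n_t
  draws <- array(NA_real_, c(S, n - 1, n_t))
  for (s in seq_len(S)) {
    draws[s, , ] <- contrasts + matrix(rnorm((n - 1) * n_t, sd = draw_sd),
                                       n - 1, n_t)
  }
  structure(list(grid = grid,
                 levels = list(strain = rownames(effects)),
                 basis = list(strain = C),
                 spec = phenogp::fanova_spec(effects = "strain",
                                             interactions = list()),
                 draws = list(mu = array(0, c(S, 1, n_t)), strain = draws),
                 hyper_draws = tibble::tibble(noise_variance = rep(draw_sd^2 + 1e-12, S)),
                 n_draws = S, n_obs = 0L, seed = seed,
                 mcmc = phenogp::mcmc_control(n_draws = S, burnin = 0)),
            class = "gp_fanova")
}

# small raw-OD growth table for I/O tests
make_raw_table <- function(n_strains = 2, n_conditions = 1, n_reps = 3,
                           times = seq(0, 48, by = 0.5)) {
  tidyr::expand_grid(
    strain = sprintf("s%d", seq_len(n_strains)),
    condition = sprintf("c%d", seq_len(n_conditions)),
    batch = "b1",
    bio_rep = sprintf("r%d", seq_len(n_reps)),
    tech_rep = "t1",
    time_h = times) |>
    dplyr::mutate(od600 = 0.05 * 2^(pmin(time_h / 8, 5)) *
                    exp(0.01 * (seq_along(time_h) %% 7)))
}
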