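#' Fit a Gaussian-process functional ANOVA by MCMC
#'
#' Decomposes the observed (log2-scale) growth curves into a latent mean
#' function plus sum-to-zero functional effects of the declared factors,
#' their declared interactions, and optionally a batch function, all
#' evaluated on the shared time grid. Each latent contrast function carries
#' a GP prior with an RBF covariance; observation noise is i.i.d. Gaussian
#' with one shared variance. The sampler alternates Gibbs updates of every
#' latent function block (each full conditional is multivariate normal,
#' combining the GP prior with the Gaussian likelihood of the residuals
#' attributed to that block) with univariate slice-sampling updates of the
#' kernel hyperparameters and the noise variance in log space under bounded
#' log-uniform priors.
#'
#' @param ds A normalized [growth_dataset()].
#' @param spec A [fanova_spec()].
#' @param mcmc An [mcmc_control()].
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   draws.
#' @return A `gp_fanova` object holding the time grid, factor levels and
#'   contrast bases, arrays of posterior draws of every latent contrast
#'   function, and hyperparameter draws.
#' @export
fit_fanova <- function(ds, spec, mcmc = mcmc_control(), seed = 1) {
  stopifnot(inherits(ds, "growth_dataset"), inherits(spec, "fanova_spec"),
            inherits(mcmc, "mcmc_control"))
  if (!is_normalized(ds)) {
    abort("fit_fanova requires a normalized dataset (see normalize_growth)",
          class = "phenogp_validation_error")
  }
  x <- tibble::as_tibble(ds)
  grid <- time_grid(ds)
  n_t <- length(grid)
  N <- nrow(x)
  g <- match(x$time, grid)
  y <- x$value

  # factor levels (sorted for determinism), checked against any declared set
  levels <- list()
  for (e in spec$effects) {
    if (!e %in% names(x)) {
      abort(paste0("effect column not in data: ", e),
            class = "phenogp_schema_error")
    }
    obs_lev <- sort(unique(x[[e]]))
    lev <- if (!is.null(spec$levels[[e]])) as.character(spec$levels[[e]]) else obs_lev
    if (length(setdiff(lev, obs_lev)) > 0) {
      abort(paste0("factor level(s) in spec but unobserved in data for '", e,
                   "': ", paste(setdiff(lev, obs_lev), collapse = ", ")),
            class = "phenogp_validation_error")
    }
    if (length(setdiff(obs_lev, lev)) > 0) {
      abort(paste0("observed level(s) of '", e, "' not declared in spec: ",
                   paste(setdiff(obs_lev, lev), collapse = ", ")),
            class = "phenogp_validation_error")
    }
    if (length(lev) < 2) {
      abort(paste0("effect '", e, "' needs >= 2 levels"),
            class = "phenogp_domain_error")
    }
    levels[[e]] <- lev
  }
  # interactions require every level pair observed
  for (pair in spec$interactions) {
    cells <- table(x[[pair[1]]], x[[pair[2]]])
    if (any(cells == 0)) {
      miss <- which(cells == 0, arr.ind = TRUE)
      abort(paste0("interaction ", pair[1], ":", pair[2],
                   " declared but level pair(s) unobserved, e.g. (",
                   rownames(cells)[miss[1, 1]], ", ",
                   colnames(cells)[miss[1, 2]], ")"),
            class = "phenogp_validation_error")
    }
  }

  basis <- lapply(levels, function(lev) contrast_basis(length(lev)))

  # latent groups: mu, one per effect, one per interaction; each holds
  # n_fns contrast functions sharing a kernel. Coefficients are sparse per
  # function (only observations of levels with nonzero contrast weight).
  groups <- list()
  groups$mu <- list(name = "mu", n_fns = 1L,
                    fns = list(list(idx = seq_len(N),
                                    coef = rep(1, N))))
  for (e in spec$effects) {
    C <- basis[[e]]
    li <- match(x[[e]], levels[[e]])
    fns <- lapply(seq_len(ncol(C)), function(k) {
      cf <- C[li, k]
      idx <- which(cf != 0)
      list(idx = idx, coef = cf[idx])
    })
    groups[[e]] <- list(name = e, n_fns = ncol(C), fns = fns)
  }
  for (pair in spec$interactions) {
    gname <- paste(pair, collapse = ":")
    C1 <- basis[[pair[1]]]; C2 <- basis[[pair[2]]]
    l1 <- match(x[[pair[1]]], levels[[pair[1]]])
    l2 <- match(x[[pair[2]]], levels[[pair[2]]])
    fns <- list()
    for (k in seq_len(ncol(C1))) {
      for (l in seq_len(ncol(C2))) {
        cf <- C1[l1, k] * C2[l2, l]
        idx <- which(cf != 0)
        fns[[length(fns) + 1L]] <- list(idx = idx, coef = cf[idx])
      }
    }
    groups[[gname]] <- list(name = gname, n_fns = length(fns), fns = fns)
  }

  # per-function likelihood weights on the grid: w_g = sum of squared coefs
  accumulate <- function(idx, vals) {
    s <- numeric(n_t)
    if (length(idx) > 0) {
      o <- rowsum(vals, g[idx])
      s[as.integer(rownames(o))] <- o[, 1]
    }
    s
  }
  for (gn in names(groups)) {
    groups[[gn]]$fns <- lapply(groups[[gn]]$fns, function(f) {
      f$w <- accumulate(f$idx, f$coef^2)
      f
    })
  }

  # priors and initial hyperparameters
  step <- min(diff(grid))
  span <- max(grid) - min(grid)
  ell_bounds <- spec$ell_bounds %||% c(step^2, (4 * span)^2)
  s2_bounds <- spec$sigma2_bounds
  noise_bounds <- spec$noise_bounds
  clip <- function(v, b) min(max(v, b[1]), b[2])
  hyper <- list()
  for (gn in names(groups)) {
    k0 <- spec$kernels[[gn]] %||%
      rbf_kernel(variance = 1,
                 lengthscale = clip((span / 3)^2, ell_bounds))
    hyper[[gn]] <- c(sigma2 = clip(k0$variance, s2_bounds),
                     ell = clip(k0$lengthscale, ell_bounds))
  }
  s2e <- clip(spec$noise_variance %||% max(0.1 * var(y), 1e-4), noise_bounds)

  # state
  fvals <- lapply(groups, function(grp) matrix(0, grp$n_fns, n_t))
  fitted <- numeric(N)

  n_keep <- mcmc$n_draws
  total_iter <- mcmc$burnin + n_keep * mcmc$thin
  draws <- lapply(groups, function(grp) array(NA_real_,
                                              dim = c(n_keep, grp$n_fns, n_t)))
  hyper_draws <- matrix(NA_real_, n_keep, 2 * length(groups) + 1)
  colnames(hyper_draws) <- c(
    as.vector(t(outer(names(groups), c("sigma2", "ell"), paste, sep = "."))),
    "noise_variance")

  set.seed(as.integer(seed))
  keep_i <- 0L

  group_loglik <- function(F, sigma2, ell) {
    K <- rbf_cov(grid, grid, rbf_kernel(sigma2, ell))
    R <- chol_jitter(K, sigma2)
    sum(apply(F, 1, mvn_logpdf0, cholK = R))
  }

  for (it in seq_len(total_iter)) {
    # --- Gibbs updates of every latent function block ---
    for (gn in names(groups)) {
      grp <- groups[[gn]]
      hp <- hyper[[gn]]
      K <- rbf_cov(grid, grid, rbf_kernel(hp[["sigma2"]], hp[["ell"]]))
      R <- chol_jitter(K, hp[["sigma2"]])
      Kinv <- chol2inv(R)
      for (fi in seq_len(grp$n_fns)) {
        f <- grp$fns[[fi]]
        fold <- fvals[[gn]][fi, ]
        r <- y[f$idx] - fitted[f$idx] + f$coef * fold[g[f$idx]]
        s <- accumulate(f$idx, f$coef * r)
        Q <- Kinv + diag(f$w / s2e, n_t)
        cholQ <- chol(Q)
        m <- backsolve(cholQ, backsolve(cholQ, s / s2e, transpose = TRUE))
        fnew <- m + backsolve(cholQ, rnorm(n_t))
        fvals[[gn]][fi, ] <- fnew
        fitted[f$idx] <- fitted[f$idx] + f$coef * (fnew - fold)[g[f$idx]]
      }
    }

    # --- slice-sampling updates of hyperparameters (log space) ---
    if (mcmc$sample_hyperparams) {
      for (gn in names(groups)) {
        hp <- hyper[[gn]]
        lp_s2 <- function(u) group_loglik(fvals[[gn]], exp(u), hp[["ell"]])
        new_s2 <- slice_sample(lp_s2, log(hp[["sigma2"]]), w = mcmc$slice_w,
                               bounds = log(s2_bounds))
        hp[["sigma2"]] <- exp(new_s2)
        lp_ell <- function(u) group_loglik(fvals[[gn]], hp[["sigma2"]], exp(u))
        new_ell <- slice_sample(lp_ell, log(hp[["ell"]]), w = mcmc$slice_w,
                                bounds = log(ell_bounds))
        hp[["ell"]] <- exp(new_ell)
        hyper[[gn]] <- hp
      }
      resid <- y - fitted
      SS <- sum(resid^2)
      lp_noise <- function(u) -0.5 * N * u - SS / (2 * exp(u))
      s2e <- exp(slice_sample(lp_noise, log(s2e), w = mcmc$slice_w,
                              bounds = log(noise_bounds)))
    }

    # --- record ---
    if (it > mcmc$burnin && (it - mcmc$burnin) %% mcmc$thin == 0) {
      keep_i <- keep_i + 1L
      for (gn in names(groups)) draws[[gn]][keep_i, , ] <- fvals[[gn]]
      hyper_draws[keep_i, ] <- c(unlist(hyper), noise_variance = s2e)
    }
  }

  structure(list(grid = grid,
                 levels = levels,
                 basis = basis,
                 spec = spec,
                 draws = draws,
                 hyper_draws = tibble::as_tibble(hyper_draws),
                 n_draws = n_keep,
                 n_obs = N,
                 seed = as.integer(seed),
                 mcmc = mcmc),
            class = "gp_fanova")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gp_fanova <- function(x, ...) {
  cat(sprintf(
    "<gp_fanova> %d draws | %d obs on %d grid points | groups: %s\n",
    x$n_draws, x$n_obs, length(x$grid),
    paste(names(x$draws), collapse = ", ")))
  invisible(x)
}

#' Posterior draws of reconstructed effect functions
#'
#' Maps contrast-function draws back through the contrast basis:
#' `alpha_i(t) = c_i' alpha_star(t)`, so every returned draw satisfies the
#' sum-to-zero constraint across levels at each grid time.
#'
#' @param fit A `gp_fanova` fit.
#' @param factor Effect name declared in the spec.
#' @return Array `[draw, level, time]` with level dimnames.
#' @export
effect_draws <- function(fit, factor) {
  stopifnot(inherits(fit, "gp_fanova"))
  if (!factor %in% names(fit$levels)) {
    abort(paste0("unknown effect: ", factor), class = "phenogp_domain_error")
  }
  A <- fit$draws[[factor]]             # S x (n-1) x n_t
  C <- fit$basis[[factor]]             # n x (n-1)
  S <- dim(A)[1]; n_t <- dim(A)[3]; n <- nrow(C)
  # contract over the contrast dimension
  Am <- matrix(aperm(A, c(2, 1, 3)), nrow = dim(A)[2])  # (n-1) x (S*n_t)
  E <- C %*% Am                                          # n x (S*n_t)
  out <- aperm(array(E, dim = c(n, S, n_t)), c(2, 1, 3))
  dimnames(out) <- list(NULL, fit$levels[[factor]], NULL)
  out
}

#' Posterior draws of reconstructed interaction functions
#'
#' @param fit A `gp_fanova` fit.
#' @param pair Character pair naming the interaction, e.g.
#'   `c("strain", "condition")`.
#' @return Array `[draw, level1, level2, time]`; each draw sums to zero over
#'   each margin at every time.
#' @export
interaction_draws <- function(fit, pair) {
  stopifnot(inherits(fit, "gp_fanova"))
  gname <- paste(pair, collapse = ":")
  if (!gname %in% names(fit$draws)) {
    abort(paste0("unknown interaction: ", gname),
          class = "phenogp_domain_error")
  }
  A <- fit$draws[[gname]]              # S x (n1-1)(n2-1) x n_t
  C1 <- fit$basis[[pair[1]]]; C2 <- fit$basis[[pair[2]]]
  n1 <- nrow(C1); n2 <- nrow(C2)
  CK <- kronecker(C1, C2)              # rows (i,j) j fastest; cols (k,l) l fastest
  S <- dim(A)[1]; n_t <- dim(A)[3]
  Am <- matrix(aperm(A, c(2, 1, 3)), nrow = dim(A)[2])
  E <- CK %*% Am                       # (n1*n2) x (S*n_t)
  out <- aperm(array(E, dim = c(n2, n1, S, n_t)), c(3, 2, 1, 4))
  dimnames(out) <- list(NULL, fit$levels[[pair[1]]], fit$levels[[pair[2]]],
                        NULL)
  out
}

#' Posterior draws of the mean function
#'
#' @param fit A `gp_fanova` fit.
#' @return Matrix `[draw, time]`.
#' @export
mu_draws <- function(fit) {
  stopifnot(inherits(fit, "gp_fanova"))
  fit$draws$mu[, 1, ]
}

#' Serialize a fit to JSON
#'
#' Writes the grid, the MCMC configuration echo, hyperparameter draws and
#' all latent contrast-function draws as a single JSON document — a
#' plain-text posterior archive that downstream tooling can parse without R.
#'
#' @param fit A `gp_fanova` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fanova_json <- function(fit, path) {
  stopifnot(inherits(fit, "gp_fanova"))
  obj <- list(
    grid = fit$grid,
    levels = fit$levels,
    n_draws = fit$n_draws,
    seed = fit$seed,
    mcmc = unclass(fit$mcmc),
    hyper_draws = fit$hyper_draws,
    draws = fit$draws
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
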