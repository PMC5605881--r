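#' Declare a functional-ANOVA model
#'
#' A `fanova_spec` names the factors of the growth experiment whose latent
#' functional effects are modeled, the factor pairs given interaction
#' functions, and whether a batch function is included. The observation model
#' for a reading at time `t` is
#' `y(t) = mu(t) + sum of effect functions + sum of interaction functions
#' (+ batch function) + eps`, with i.i.d. Gaussian noise `eps` and every
#' effect set constrained to sum to zero across its levels at each time
#' (interactions sum to zero over each margin). Identifiability is enforced
#' by parameterizing each effect set through [contrast_basis()] contrasts,
#' each contrast function carrying a shared Gaussian-process prior with an
#' [rbf_kernel()] covariance per group.
#'
#' @param effects Character vector of factor column names (e.g.
#'   `c("strain", "condition")`). May be empty for a mean-only model.
#' @param interactions List of length-2 character vectors; each pair must be
#'   declared in `effects`.
#' @param batch Logical; include a sum-to-zero batch function `gamma(t)`
#'   (one latent function set over the `batch` column). Used when replicate
#'   batches of experiments introduce systematic trajectory shifts.
#' @param levels Optional named list fixing the expected levels per factor;
#'   a level declared here but absent from the data is a fit-time error.
#' @param kernels Optional named list of [rbf_kernel()] objects giving the
#'   initial (or, when hyperparameter sampling is off, fixed) kernel per
#'   latent group. Group names: `"mu"`, each effect name, `"a:b"` for an
#'   interaction, `"batch"`. Unnamed groups get defaults.
#' @param noise_variance Initial (or fixed) observation-noise variance.
#' @param sigma2_bounds,noise_bounds Support of the log-uniform priors on
#'   the signal and noise variances.
#' @param ell_bounds Support of the log-uniform prior on the lengthscale;
#'   `NULL` derives `[(grid step)^2, (4 * grid span)^2]` from the data at
#'   fit time.
#'
#' @return A `fanova_spec` object.
#' @export
fanova_spec <- function(effects = c("strain", "condition"),
                        interactions = list(c("strain", "condition")),
                        batch = FALSE,
                        levels = NULL,
                        kernels = NULL,
                        noise_variance = NULL,
                        sigma2_bounds = c(1e-4, 1e4),
                        ell_bounds = NULL,
                        noise_bounds = c(1e-6, 1e2)) {
  effects <- as.character(effects)
  if (isTRUE(batch)) effects <- union(effects, "batch")
  for (pair in interactions) {
    if (length(pair) != 2 || !all(pair %in% effects)) {
      abort("each interaction must be a pair of declared effects",
            class = "phenogp_domain_error")
    }
  }
  structure(list(effects = effects,
                 interactions = interactions,
                 batch = isTRUE(batch),
                 levels = levels,
                 kernels = kernels,
                 noise_variance = noise_variance,
                 sigma2_bounds = sigma2_bounds,
                 ell_bounds = ell_bounds,
                 noise_bounds = noise_bounds),
            class = "fanova_spec")
}

#' @export
print.fanova_spec <- function(x, ...) {
  ints <- if (length(x$interactions) == 0) "none" else
    paste(vapply(x$interactions, paste, "", collapse = ":"), collapse = ", ")
  cat("<fanova_spec>\n",
      " effects:      ", paste(x$effects, collapse = ", "), "\n",
      " interactions: ", ints, "\n", sep = "")
  invisible(x)
}

#' MCMC configuration
#'
#' @param n_draws Number of retained posterior draws.
#' @param burnin Number of discarded warm-up iterations.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param sample_hyperparams If `FALSE`, kernel hyperparameters and the
#'   noise variance stay fixed at their `fanova_spec` values (used for
#'   conjugate checks against closed-form linear-Gaussian posteriors).
#' @param slice_w Initial slice-sampling bracket width in log-parameter
#'   space.
#' @return An `mcmc_control` list.
#' @export
mcmc_control <- function(n_draws = 1000, burnin = 1000, thin = 1,
                         sample_hyperparams = TRUE, slice_w = 1) {
  stopifnot(n_draws >= 1, burnin >= 0, thin >= 1)
  structure(list(n_draws = n_draws, burnin = burnin, thin = thin,
                 sample_hyperparams = sample_hyperparams,
                 slice_w = slice_w),
            class = "mcmc_control")
}
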