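#' Tidy posterior summaries of a fitted GP FANOVA
#'
#' One row per latent function per grid time, with the posterior mean and
#' pointwise 95% credible bounds of the *reconstructed* (sum-to-zero)
#' effects, the interaction functions, and the mean function.
#'
#' @param x A `gp_fanova` fit.
#' @param ... Unused.
#' @return A tibble with columns `term`, `level`, `time`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @method tidy gp_fanova
#' @export
tidy.gp_fanova <- function(x, ...) {
  summarise_draws <- function(D, term, level) {
    qs <- apply(D, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    tibble::tibble(term = term, level = level, time = x$grid,
                   estimate = colMeans(D),
                   conf.low = qs[1, ], conf.high = qs[2, ])
  }
  out <- list(summarise_draws(mu_draws(x), "mu", NA_character_))
  for (e in names(x$levels)) {
    A <- effect_draws(x, e)
    for (lev in x$levels[[e]]) {
      out[[length(out) + 1]] <- summarise_draws(A[, lev, , drop = TRUE],
                                                e, lev)
    }
  }
  for (gname in names(x$draws)) {
    parts <- strsplit(gname, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) next
    I <- interaction_draws(x, parts)
    for (l1 in x$levels[[parts[1]]]) {
      for (l2 in x$levels[[parts[2]]]) {
        out[[length(out) + 1]] <- summarise_draws(
          I[, l1, l2, , drop = TRUE], gname, paste(l1, l2, sep = ":"))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' One-row model summary of a fitted GP FANOVA
#'
#' @param x A `gp_fanova` fit.
#' @param ... Unused.
#' @return A tibble with `n_obs`, `n_grid`, `n_draws`, `n_latent_functions`,
#'   `noise_sd` (posterior median of the observation-noise SD).
#' @method glance gp_fanova
#' @export
glance.gp_fanova <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_grid = length(x$grid),
    n_draws = x$n_draws,
    n_latent_functions = sum(vapply(x$draws, function(a) dim(a)[2], 0)),
    noise_sd = median(sqrt(x$hyper_draws$noise_variance)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Export a phenotype summary table as CSV
#'
#' Writes the per strain x condition summary (magnitude quartiles,
#' significance, direction, and within-condition severity rank) produced by
#' [phenotype_summaries()].
#'
#' @param summaries A [phenotype_summaries()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_summary <- function(summaries, path) {
  summaries <- tibble::as_tibble(summaries)
  out <- summaries |>
    dplyr::group_by(condition) |>
    dplyr::mutate(rank = rank(-norm_median, ties.method = "first")) |>
    dplyr::ungroup()
  readr::write_csv(out, path)
  invisible(path)
}
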