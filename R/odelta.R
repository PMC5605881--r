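#' Posterior OD-delta trajectory of a mutant versus its parent
#'
#' The OD-delta function is the difference in (log2) growth level between a
#' mutant and the parent strain over the time course. Under the standard
#' condition it is the strain contrast there,
#' `alpha_i - alpha_parent + (ab)_{i,std} - (ab)_{parent,std}`; under a
#' stress condition it is the strain-parent contrast under stress *minus*
#' the same contrast under standard,
#' `(ab)_{i,j} - (ab)_{parent,j} - (ab)_{i,std} + (ab)_{parent,std}`, so a
#' mutant that differs from the parent identically under stress and standard
#' growth shows no stress phenotype. Both forms are computed per posterior
#' draw; any model terms absent from the fitted spec contribute zero.
#'
#' @param fit A `gp_fanova` fit.
#' @param strain,parent Strain labels present in the fit.
#' @param condition Condition label present in the fit (ignored, and may be
#'   `NULL`, for a strain-only fit).
#' @param standard Label of the standard (reference) condition.
#' @return An `odelta_trajectory`: a tibble with columns `time`, `mean`,
#'   `lower`, `upper` (pointwise 2.5%/97.5% posterior quantiles) and the
#'   per-draw sample matrix in `attr(, "samples")`.
#' @export
od_delta <- function(fit, strain, condition = NULL, parent,
                     standard = "standard") {
  stopifnot(inherits(fit, "gp_fanova"))
  strain_factor <- strain_factor_name(fit)
  check_level(fit, strain_factor, strain)
  check_level(fit, strain_factor, parent)
  has_condition <- "condition" %in% names(fit$levels)
  if (has_condition) {
    if (is.null(condition)) abort("condition must be given for this model")
    check_level(fit, "condition", condition)
    check_level(fit, "condition", standard)
  }
  S <- fit$n_draws; n_t <- length(fit$grid)
  D <- matrix(0, S, n_t)
  int_name <- paste(strain_factor, "condition", sep = ":")
  has_int <- int_name %in% names(fit$draws)
  if (!has_condition || identical(condition, standard)) {
    A <- effect_draws(fit, strain_factor)
    D <- A[, strain, ] - A[, parent, ]
    if (has_int) {
      I <- interaction_draws(fit, c(strain_factor, "condition"))
      D <- D + I[, strain, standard, ] - I[, parent, standard, ]
    }
  } else {
    if (has_int) {
      I <- interaction_draws(fit, c(strain_factor, "condition"))
      D <- I[, strain, condition, ] - I[, parent, condition, ] -
        I[, strain, standard, ] + I[, parent, standard, ]
    }
    # without an interaction the strain-parent contrast is condition-free
    # and the stress-vs-standard difference is identically zero
  }
  if (S == 1) D <- matrix(D, nrow = 1)
  new_odelta_trajectory(D, fit$grid, strain, condition %||% NA_character_,
                        parent)
}

strain_factor_name <- function(fit) {
  if ("strain" %in% names(fit$levels)) return("strain")
  names(fit$levels)[1]
}

check_level <- function(fit, factor, level) {
  if (!factor %in% names(fit$levels) || !level %in% fit$levels[[factor]]) {
    abort(paste0("unknown level '", level, "' for factor '", factor, "'"),
          class = "phenogp_domain_error")
  }
}

new_odelta_trajectory <- function(samples, grid, strain, condition, parent) {
  qs <- apply(samples, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- tibble::tibble(
    time = grid,
    mean = colMeans(samples),
    lower = qs[1, ],
    upper = qs[2, ])
  structure(out,
            class = c("odelta_trajectory", class(tibble::tibble())),
            samples = samples,
            strain = strain,
            condition = condition,
            parent = parent)
}

#' @export
print.odelta_trajectory <- function(x, ...) {
  cat(sprintf("<odelta_trajectory> %s vs %s (%s), %d draws on %d grid points\n",
              attr(x, "strain"), attr(x, "parent"), attr(x, "condition"),
              nrow(attr(x, "samples")), nrow(x)))
  NextMethod()
}

#' OD-delta for a shock experiment with pre-shock baseline removal
#'
#' For the strain-only shock model the metric is the strain-minus-parent
#' effect difference restricted to the post-shock window, with the same
#' draw's difference evaluated at the shock-start grid point subtracted.
#' This removes any differential growth the two strains accumulated before
#' the shock began, so the trajectory reflects the response to the shock
#' itself.
#'
#' @param fit A `gp_fanova` fit of a strain-only model.
#' @param strain,parent Strain labels.
#' @param shock_start Shock onset (hours); must be a grid point.
#' @return An `odelta_trajectory` on the post-shock grid.
#' @export
od_delta_heatshock <- function(fit, strain, parent, shock_start = 16.0) {
  stopifnot(inherits(fit, "gp_fanova"))
  strain_factor <- strain_factor_name(fit)
  check_level(fit, strain_factor, strain)
  check_level(fit, strain_factor, parent)
  i0 <- match(TRUE, abs(fit$grid - shock_start) < 1e-9)
  if (is.na(i0)) {
    abort(paste0("shock_start = ", shock_start, " h is not on the time grid"),
          class = "phenogp_domain_error")
  }
  A <- effect_draws(fit, strain_factor)
  D <- A[, strain, ] - A[, parent, ]
  if (fit$n_draws == 1) D <- matrix(D, nrow = 1)
  keep <- fit$grid >= shock_start - 1e-9
  D <- D[, keep, drop = FALSE] - D[, i0]
  new_odelta_trajectory(D, fit$grid[keep], strain, "heat_shock", parent)
}

#' Summed-square magnitude of an OD-delta trajectory
#'
#' The phenotype-severity statistic: for each posterior draw, the sum over
#' the grid of the squared OD-delta values. The sum is unnormalized (no
#' square root, no grid-step weighting), so its scale depends on the grid
#' density — halving the grid spacing roughly doubles the value. The default
#' analysis grid is fixed at 30-minute steps, making values comparable
#' across strains and conditions fit on the same grid.
#'
#' @param traj An `odelta_trajectory`.
#' @return An `odelta_norm`: a one-row tibble with `strain`, `condition`,
#'   `norm_median`, `norm_q1`, `norm_q3`, with the per-draw values in
#'   `attr(, "samples")`.
#' @export
od_delta_norm <- function(traj) {
  stopifnot(inherits(traj, "odelta_trajectory"))
  if (nrow(traj) == 0) abort("empty trajectory grid")
  S <- attr(traj, "samples")
  norms <- rowSums(S^2)
  structure(tibble::tibble(
    strain = attr(traj, "strain"),
    condition = attr(traj, "condition"),
    norm_median = median(norms),
    norm_q1 = quantile(norms, 0.25, names = FALSE),
    norm_q3 = quantile(norms, 0.75, names = FALSE)),
    class = c("odelta_norm", class(tibble::tibble())),
    samples = norms)
}

#' Credible-interval significance call for one mutant x condition
#'
#' A growth phenotype is called at every grid time where the pointwise 95%
#' credible band of OD-delta excludes zero. The call is significant when at
#' least one such time exists and, if a magnitude cutoff is supplied, the
#' posterior median of the summed-square magnitude is at least the cutoff.
#' Direction is read from the sign of the posterior mean over the
#' significant runs: `"faster"` when the mutant grows above the parent,
#' `"slower"` below, `"mixed"` when both occur.
#'
#' @param traj An `odelta_trajectory`.
#' @param norm Optional matching [od_delta_norm()]; computed if missing.
#' @param cutoff Optional nonnegative magnitude cutoff; `NULL` applies none.
#' @return A `phenotype_call`: one-row tibble with `strain`, `condition`,
#'   `significant`, `direction`, `norm_median`, `n_sig_times`; the maximal
#'   significant time windows are in `attr(, "intervals")`.
#' @export
significance_call <- function(traj, norm = NULL, cutoff = NULL) {
  stopifnot(inherits(traj, "odelta_trajectory"))
  if (is.null(norm)) norm <- od_delta_norm(traj)
  if (!identical(norm$strain, attr(traj, "strain")) ||
      !identical(norm$condition, attr(traj, "condition"))) {
    abort("norm does not match the trajectory's strain/condition",
          class = "phenogp_domain_error")
  }
  excl <- traj$lower > 0 | traj$upper < 0
  intervals <- runs_to_intervals(traj$time, excl)
  direction <- "none"
  if (any(excl)) {
    signs <- unique(sign(traj$mean[excl]))
    direction <- if (all(signs > 0)) "faster"
      else if (all(signs < 0)) "slower" else "mixed"
  }
  significant <- any(excl) &&
    (is.null(cutoff) || norm$norm_median >= cutoff)
  structure(tibble::tibble(
    strain = attr(traj, "strain"),
    condition = attr(traj, "condition"),
    significant = significant,
    direction = direction,
    norm_median = norm$norm_median,
    n_sig_times = sum(excl)),
    class = c("phenotype_call", class(tibble::tibble())),
    intervals = intervals)
}

runs_to_intervals <- function(time, flag) {
  if (!any(flag)) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start = time[starts[keep]], end = time[ends[keep]])
}

#' Rank mutants by phenotype severity within one condition
#'
#' Orders strains by descending posterior-median summed-square magnitude;
#' ties break lexicographically by strain label.
#'
#' @param norms A tibble with one row per strain (columns `strain`,
#'   `norm_median`), e.g. rows of [od_delta_norm()] bound together.
#' @return The input arranged by rank with a `rank` column prepended.
#' @export
rank_mutants <- function(norms) {
  norms <- tibble::as_tibble(norms)
  if (anyDuplicated(norms$strain)) {
    abort("duplicate strain(s) in ranking input",
          class = "phenogp_domain_error")
  }
  out <- norms[order(-norms$norm_median, norms$strain), , drop = FALSE]
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' Universal magnitude cutoff for cross-condition phenotype comparison
#'
#' Chooses the smallest summed-square-magnitude value that (i) excludes
#' every strain-condition pair whose extremal posterior-mean OD-delta value
#' (its maximum and its minimum over the time course) lies inside its own
#' 95% credible band — i.e. pairs whose largest excursions are not credibly
#' nonzero — and (ii) excludes, under the standard condition, every mutant
#' outside the top 10% of magnitude medians. The returned value is the
#' larger of the two implied bounds plus a vanishing offset so that
#' comparisons with `>= cutoff` implement strict exclusion.
#'
#' @param summaries A tibble with one row per strain x condition and columns
#'   `strain`, `condition`, `norm_median`, `extremal_significant` (logical:
#'   does the band exclude zero at the argmax or argmin of the posterior
#'   mean?). Build it with [phenotype_summaries()].
#' @param standard Label of the standard condition.
#' @return A single numeric cutoff.
#' @export
select_cutoff <- function(summaries, standard = "standard") {
  summaries <- tibble::as_tibble(summaries)
  need <- c("strain", "condition", "norm_median", "extremal_significant")
  if (!all(need %in% names(summaries))) {
    abort(paste0("summaries must have columns: ", paste(need, collapse = ", ")),
          class = "phenogp_schema_error")
  }
  if (dplyr::n_distinct(summaries$strain) < 2) {
    abort("select_cutoff needs at least 2 strains",
          class = "phenogp_domain_error")
  }
  std <- summaries[summaries$condition == standard, , drop = FALSE]
  if (nrow(std) == 0) {
    abort(paste0("no rows for the standard condition '", standard, "'"),
          class = "phenogp_domain_error")
  }
  b1 <- suppressWarnings(
    max(summaries$norm_median[!summaries$extremal_significant]))
  if (!is.finite(b1)) b1 <- 0
  b2 <- quantile(std$norm_median, 0.9, names = FALSE)
  bound <- max(b1, b2)
  bound + 1e-9 * max(1, abs(bound))
}

#' Per strain x condition phenotype summaries from a fitted model
#'
#' Convenience pipeline layer: computes the OD-delta trajectory, magnitude,
#' and band/extremum diagnostics for every mutant x condition of a fit, as
#' the input to [select_cutoff()], [classify_phenotypes()] and
#' [build_phenotype_network()].
#'
#' @param fit A `gp_fanova` fit.
#' @param parent Parent strain label.
#' @param standard Standard condition label.
#' @param cutoff Optional magnitude cutoff applied to the significance calls.
#' @return A tibble with one row per mutant x condition: `strain`,
#'   `condition`, `significant`, `direction`, `norm_median`, `norm_q1`,
#'   `norm_q3`, `extremal_significant`, `extremal_sign`, `extremal_value`.
#' @export
phenotype_summaries <- function(fit, parent, standard = "standard",
                                cutoff = NULL) {
  stopifnot(inherits(fit, "gp_fanova"))
  strain_factor <- strain_factor_name(fit)
  strains <- setdiff(fit$levels[[strain_factor]], parent)
  conditions <- if ("condition" %in% names(fit$levels))
    fit$levels$condition else NA_character_
  purrr::map_dfr(strains, function(s) {
    purrr::map_dfr(conditions, function(cond) {
      traj <- od_delta(fit, s,
                       condition = if (is.na(cond)) NULL else cond,
                       parent = parent, standard = standard)
      norm <- od_delta_norm(traj)
      call <- significance_call(traj, norm, cutoff = cutoff)
      i_max <- which.max(traj$mean); i_min <- which.min(traj$mean)
      extremal_sig <- (traj$lower[i_max] > 0 | traj$upper[i_max] < 0) ||
        (traj$lower[i_min] > 0 | traj$upper[i_min] < 0)
      ext_val <- if (abs(traj$mean[i_max]) >= abs(traj$mean[i_min]))
        traj$mean[i_max] else traj$mean[i_min]
      tibble::tibble(
        strain = s,
        condition = if (is.na(cond)) "all" else cond,
        significant = call$significant,
        direction = call$direction,
        norm_median = norm$norm_median,
        norm_q1 = norm$norm_q1,
        norm_q3 = norm$norm_q3,
        extremal_significant = extremal_sig,
        extremal_sign = sign(ext_val),
        extremal_value = ext_val)
    })
  })
}
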