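# shared tiny dataset builders for the model variants ------------------------

variant_data <- function(factors, grid = seq(4, 13, by = 1), n_rep = 2,
                         seed = 3, noise_sd = 0.05) {
  set.seed(seed)
  cells <- do.call(tidyr::expand_grid,
                   c(lapply(factors, function(l) l),
                     list(bio_rep = sprintf("r%d", seq_len(n_rep)))))
  mu <- gompertz_baseline(grid, A = 2, mumax = 0.3, lag = 5) - 1
  rows <- purrr::pmap_dfr(cells, function(...) {
    args <- list(...)
    shift <- sum(vapply(seq_along(factors), function(i) {
      0.2 * (match(args[[names(factors)[i]]], factors[[i]]) - 1)
    }, numeric(1)))
    tibble::tibble(!!!args, tech_rep = "t1",
                   time = grid,
                   value = mu + shift * grid / max(grid) +
                     rnorm(length(grid), sd = noise_sd))
  })
  for (f in setdiff(c("strain", "condition", "batch"), names(rows))) {
    rows[[f]] <- "x1"
  }
  growth_dataset(rows, normalized = TRUE, interval = min(diff(grid)))
}

max_sum_to_zero_violation <- function(fit) {
  viol <- 0
  for (e in names(fit$levels)) {
    A <- effect_draws(fit, e)
    viol <- max(viol, max(abs(apply(A, c(1, 3), sum))))
  }
  for (gname in names(fit$draws)) {
    parts <- strsplit(gname, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) next
    I <- interaction_draws(fit, parts)
    viol <- max(viol, max(abs(apply(I, c(1, 3, 4), sum))))
    viol <- max(viol, max(abs(apply(I, c(1, 2, 4), sum))))
  }
  viol
}
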