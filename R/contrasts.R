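#' Orthonormal sum-to-zero contrast basis
#'
#' Builds the deterministic `n x (n - 1)` matrix `C` whose columns form an
#' orthonormal basis of the sum-to-zero subspace of `R^n` (Helmert-style
#' contrasts, orthonormalized). Writing a factor's `n` effect functions as
#' `alpha = C %*% alpha_star`, where `alpha_star` holds `n - 1` unconstrained
#' contrast functions, enforces the identifiability constraint
#' `sum_i alpha_i(t) = 0` for every `t` by construction. Because `C` has
#' orthonormal columns, an exchangeable (shared) Gaussian-process prior on
#' the contrast functions induces an exchangeable prior on the effects.
#'
#' @param n_levels Number of factor levels (>= 2).
#' @return A matrix of dimension `n_levels x (n_levels - 1)`; columns sum to
#'   zero and are orthonormal.
#' @export
#' @examples
#' C <- contrast_basis(4)
#' colSums(C)            # ~ 0
#' crossprod(C)          # identity(3)
contrast_basis <- function(n_levels) {
  if (!is.numeric(n_levels) || length(n_levels) != 1 || n_levels < 2 ||
      n_levels != round(n_levels)) {
    abort("n_levels must be a single integer >= 2",
          class = "phenogp_domain_error")
  }
  n <- as.integer(n_levels)
  C <- stats::contr.helmert(n)          # columns sum to zero
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")  # already orthogonal; normalize
  dimnames(C) <- NULL
  C
}

#' Map contrast functions to effect functions
#'
#' Applies `alpha_i(t) = c_i' alpha_star(t)`: given the values of the
#' `n - 1` contrast functions on a time grid, reconstructs the `n` effect
#' functions. The per-time sums of the reconstructed effects are zero up to
#' round-off.
#'
#' @param basis A [contrast_basis()] matrix (`n x (n - 1)`).
#' @param contrast_fns Matrix of contrast-function values, one row per
#'   contrast function, one column per grid time (`(n - 1) x n_t`). A vector
#'   is taken as a single contrast function.
#' @return An `n x n_t` matrix of effect-function values.
#' @export
effects_from_contrasts <- function(basis, contrast_fns) {
  if (is.vector(contrast_fns)) contrast_fns <- matrix(contrast_fns, nrow = 1)
  if (ncol(basis) != nrow(contrast_fns)) {
    abort(sprintf(
      "dimension mismatch: basis has %d contrasts but %d contrast functions supplied",
      ncol(basis), nrow(contrast_fns)),
      class = "phenogp_domain_error")
  }
  basis %*% contrast_fns
}
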