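#' Radial-basis-function (squared-exponential) kernel
#'
#' Covariance function `kappa(t1, t2) = sigma2 * exp(-(t1 - t2)^2 / ell)`.
#' Note the parameterization: the lengthscale `ell` divides the *squared*
#' distance directly (units of hours squared), rather than the `2 * l^2`
#' convention used elsewhere in the GP literature. With this form the
#' correlation between readings `d` hours apart is `exp(-d^2 / ell)`.
#'
#' @param variance Signal variance `sigma2 > 0`; sets the marginal variance
#'   of the latent function.
#' @param lengthscale Decay parameter `ell > 0` in hours^2; larger values
#'   give smoother (more slowly varying) functions.
#' @return An object of class `rbf_kernel`.
#' @export
rbf_kernel <- function(variance = 1, lengthscale = 100) {
  if (!is.numeric(variance) || variance <= 0 ||
      !is.numeric(lengthscale) || lengthscale <= 0) {
    abort("rbf_kernel: variance and lengthscale must be strictly positive",
          class = "phenogp_domain_error")
  }
  structure(list(variance = variance, lengthscale = lengthscale),
            class = "rbf_kernel")
}

#' @export
print.rbf_kernel <- function(x, ...) {
  cat(sprintf("<rbf_kernel> sigma2 = %g, ell = %g h^2\n",
              x$variance, x$lengthscale))
  invisible(x)
}

#' Evaluate an RBF covariance matrix
#'
#' @param times_a,times_b Numeric time vectors (hours).
#' @param kernel An [rbf_kernel()].
#' @return The `length(times_a) x length(times_b)` covariance matrix; the
#'   square case (`times_b` missing or identical) is exactly symmetric.
#' @export
rbf_cov <- function(times_a, times_b = times_a, kernel) {
  stopifnot(inherits(kernel, "rbf_kernel"))
  d2 <- outer(times_a, times_b, function(a, b) (a - b)^2)
  K <- kernel$variance * exp(-d2 / kernel$lengthscale)
  if (length(times_a) == length(times_b) &&
      isTRUE(all.equal(times_a, times_b))) {
    K <- (K + t(K)) / 2
  }
  K
}

# Cholesky with escalating diagonal jitter. Starts at 1e-6 * sigma2 and
# multiplies by 10 up to 1e-2 * sigma2 before giving up.
chol_jitter <- function(K, sigma2 = mean(diag(K))) {
  jit <- 1e-6 * sigma2
  for (i in 1:5) {
    R <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jit <- jit * 10
    if (jit > 1e-2 * sigma2) break
  }
  abort(sprintf(
    "covariance matrix not positive definite after jitter escalation to %g (dim %d, diag range [%g, %g])",
    jit, nrow(K), min(diag(K)), max(diag(K))),
    class = "phenogp_numerical_error")
}

# log N(x; 0, K) using a precomputed upper Cholesky factor of K
mvn_logpdf0 <- function(x, cholK) {
  z <- backsolve(cholK, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(cholK))) - 0.5 * sum(z^2)
}
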