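#' Univariate slice sampler (step-out and shrinkage)
#'
#' One transition of Neal-style univariate slice sampling from an unnormalized
#' log density. Used internally to sample kernel hyperparameters and the
#' noise variance in log space, where the bounded log-uniform priors become
#' flat. The proposal never leaves `bounds`: the step-out is clipped to the
#' bounds and shrinkage only ever narrows the bracket.
#'
#' @param logpost Function of one real argument returning the unnormalized
#'   log posterior density.
#' @param current Current value; `logpost(current)` must be finite.
#' @param w Initial bracket width.
#' @param bounds Length-2 numeric; hard support of the target.
#' @param max_steps Maximum number of step-out expansions per side.
#' @return The new value (a single numeric). Deterministic given the RNG
#'   state.
#' @export
slice_sample <- function(logpost, current, w = 1,
                         bounds = c(-Inf, Inf), max_steps = 50) {
  if (current < bounds[1] || current > bounds[2]) {
    abort("slice_sample: current value outside bounds",
          class = "phenogp_domain_error")
  }
  f0 <- logpost(current)
  if (!is.finite(f0)) {
    abort("slice_sample: log posterior not finite at the current value",
          class = "phenogp_domain_error")
  }
  logy <- f0 - stats::rexp(1)

  # step out
  u <- runif(1)
  lo <- current - w * u
  hi <- lo + w
  lo <- max(lo, bounds[1])
  hi <- min(hi, bounds[2])
  steps <- max_steps
  while (steps > 0 && lo > bounds[1] && logpost(lo) > logy) {
    lo <- max(lo - w, bounds[1]); steps <- steps - 1
  }
  steps <- max_steps
  while (steps > 0 && hi < bounds[2] && logpost(hi) > logy) {
    hi <- min(hi + w, bounds[2]); steps <- steps - 1
  }

  # shrinkage
  repeat {
    prop <- runif(1, lo, hi)
    if (logpost(prop) > logy) return(prop)
    if (prop < current) lo <- prop else hi <- prop
    if (hi - lo < 1e-12) return(current)
  }
}
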