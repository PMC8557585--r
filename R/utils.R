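# Internal helpers: classed conditions and seed scoping.

vq_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vq_error", "error", "condition")))
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded generators never disturb an enclosing
#' simulation.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Gaussian draw truncated to [lo, hi] by clamping; adequate for speckle
# backgrounds where the tails beyond the 8-bit range are tiny.
clamped_normal <- function(n, mean, sd, lo = 0, hi = 255) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
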