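#' @importFrom methods new validObject setClass setGeneric setMethod setValidity is slot
#' @importFrom stats rnorm rbinom rexp rpois runif lm pf pchisq resid coef
#'   prcomp anova sd var aggregate as.formula complete.cases
#' @importFrom utils combn read.csv write.csv write.table read.delim
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; restore the
# caller's RNG afterwards so seeded helpers do not perturb the session stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# nth harmonic-type sums used throughout the site-frequency statistics
harmonic_a1 <- function(n) if (n < 2) 0 else sum(1 / seq_len(n - 1))
harmonic_a2 <- function(n) if (n < 2) 0 else sum(1 / seq_len(n - 1)^2)

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
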