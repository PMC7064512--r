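#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats rnorm runif rgamma rbinom plogis qlogis setNames
#'   model.matrix pchisq logLik AIC sd quantile cor complete.cases rmultinom
#' @importFrom utils head tail write.table read.delim
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.  All exported stochastic operations route
# their randomness through this so identical seeds give identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Logit and empirical logit
#'
#' `logit()` is the plain log-odds transform. `empirical_logit()` maps a
#' count pair to `log((k + 0.5) / (n - k + 0.5))`, i.e. the logit of the
#' corrected proportion `(k + 0.5) / (n + 1)`, which stays finite at
#' proportions of exactly 0 or 1.
#'
#' @param p probability in (0, 1).
#' @param k,n number of successes and number of trials.
#' @return numeric vector of log-odds.
#' @examples
#' empirical_logit(5, 13)   # log(5.5 / 8.5)
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @export
empirical_logit <- function(k, n) log((k + 0.5) / (n - k + 0.5))

stop_param <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_param(sprintf("`%s` must be a single number in [%s, %s]",
                       name, format(min), format(max)))
  }
  invisible(x)
}
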