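#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm runif qnorm var sd cor dnorm pnorm setNames
#' @importFrom utils head modifyList
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p) - log1p(-p)

# numerically safe log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# probability maps are clamped away from {0,1} before any logit
PROB_EPS <- 1e-6

clamp_prob <- function(p) clamp(p, PROB_EPS, 1 - PROB_EPS)

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "finemapvi_input_error")

stop_numeric <- function(msg, ...) abort(sprintf(msg, ...), class = "finemapvi_numeric_error")
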