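#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov var sd prcomp pt pnorm qnorm quantile rnorm
#'   runif rbinom lm coef optimize median qchisq pchisq complete.cases
#'   model.matrix setNames aggregate
#' @importFrom utils head tail
NULL

# derive a stream of child seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 1

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1

# sample skewness (moment estimator, type 1); used by trait classification
sample_skewness <- function(x) e1071::skewness(x, type = 1)
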