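#' @useDynLib fagnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq pnorm qt rnorm runif sd cor lm coef rgamma
#' @importFrom utils read.csv write.csv
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x > 0

# derive a child RNG seed that stays inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483587L)
}
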