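#' @importFrom methods new validObject is slot
#' @importFrom stats cor pbinom plogis pnorm pt qnorm quantile rbinom rnorm
#'   runif sd t.test uniroot var
#' @importFrom utils head read.csv write.csv
NULL

# Internal: stop with a classed condition so callers can test on the class.
stop2 <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "recallFC_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Frobenius norm
fnorm <- function(x) sqrt(sum(x^2))

# Largest singular value (spectral norm)
specnorm <- function(x) {
  if (all(x == 0)) return(0)
  svd(x, nu = 0, nv = 0)$d[1L]
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Run code under a fixed RNG seed without disturbing the caller's stream.
# A NULL seed uses (and advances) the current stream.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
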