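#' @importFrom rlang abort warn %||%
#' @importFrom stats setNames
NULL

# x * log(x) with the 0 log 0 := 0 convention, by masking (no epsilon floors)
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}

# x * log(x / y) with 0 * log(0/y) := 0 and 0 * log(0/0) := 0
xlogxy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * (log(x[pos]) - log(y[pos]))
  out
}

# numerically stable log(sum(exp(x))); tolerates -Inf entries
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Convert nats to bits
#'
#' All quantities in imotiv are natural-log entropies and divergences (nats);
#' this is the single conversion point for reporting in bits.
#'
#' @param x numeric vector of values in nats.
#' @return `x / log(2)`, in bits.
#' @export
#' @examples
#' nats_to_bits(log(2)) # 1 bit
nats_to_bits <- function(x) x / log(2)

# shared normalization tolerance for probability vectors / matrix slices
.prob_tol <- 1e-12

stop_not_prob <- function(p, what = "probability vector") {
  if (any(!is.finite(p))) {
    abort(sprintf("%s has non-finite entries at index %s", what,
                  paste(which(!is.finite(p)), collapse = ", ")))
  }
  if (any(p < 0)) {
    abort(sprintf("%s has negative entries at index %s", what,
                  paste(which(p < 0), collapse = ", ")))
  }
  if (abs(sum(p) - 1) > 1e-8) {
    abort(sprintf("%s sums to %.12g, not 1", what, sum(p)))
  }
  invisible(p)
}
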