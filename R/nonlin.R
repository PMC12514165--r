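#' Double-exponential output nonlinearity
#'
#' The parametric output activation `f(x) = a * exp(-exp(k * x - s)) + b`
#' used by all nonlinear encoders: `b` is the baseline rate, `a` the
#' saturated rate, `s` the threshold and `k` the gain. In population models
#' each output neuron carries its own quadruple. No sign constraints are
#' imposed on the parameters, so the function can be increasing (`k < 0`)
#' or decreasing (`k > 0`) in its argument; fitting is free to choose
#' either orientation. The inner exponent `k * x - s` is clamped to
#' `[-30, 30]` before exponentiation to guard against overflow.
#'
#' @param x numeric vector or matrix.
#' @param a,b,k,s parameters (scalars, or vectors recycled along rows when
#'   `x` is a matrix).
#' @return `f(x)`, same shape as `x`.
#' @examples
#' double_exponential(0, a = 1, b = 0, k = 1, s = 0)  # exp(-1)
#' @export
double_exponential <- function(x, a = 1, b = 0, k = 1, s = 0) {
  u <- pmin(pmax(k * x - s, -30), 30)
  a * exp(-exp(u)) + b
}

# forward with cache for backpropagation; x is N x T, params length-N
# vectors applied per row
dexp_forward <- function(x, a, b, k, s) {
  u_raw <- x * k - s
  inb <- (u_raw > -30) & (u_raw < 30)
  u <- pmin(pmax(u_raw, -30), 30)
  e <- exp(u)
  E <- exp(-e)
  list(out = a * E + b, cache = list(x = x, e = e, E = E, inb = inb,
                                     a = a, k = k))
}

# returns list(d_x, d_a, d_b, d_k, d_s); d_out is N x T
dexp_backward <- function(cache, d_out) {
  with(cache, {
    common <- d_out * a * E * (-e) * inb   # d(out)/d(u) chained
    list(d_x = common * k,
         d_a = rowSums(d_out * E),
         d_b = rowSums(d_out),
         d_k = rowSums(common * x),
         d_s = -rowSums(common))
  })
}
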