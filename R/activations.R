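# Pointwise activations and their derivatives. Each entry returns the
# activation value from the pre-activation and the derivative from the pair
# (pre-activation, activation value), so tanh/sigmoid reuse the forward value.
.activations <- list(
  tanh = list(
    f = function(x) tanh(x),
    grad = function(pre, val) 1 - val^2
  ),
  relu = list(
    f = function(x) pmax(x, 0),
    grad = function(pre, val) (pre > 0) * 1
  ),
  sigmoid = list(
    f = function(x) 1 / (1 + exp(-x)),
    grad = function(pre, val) val * (1 - val)
  ),
  identity = list(
    f = function(x) x,
    grad = function(pre, val) {
      if (is.matrix(pre)) matrix(1, nrow(pre), ncol(pre)) else rep(1, length(pre))
    }
  )
)

activation_fun <- function(name) {
  a <- .activations[[name]]
  if (is.null(a))
    stop("unknown activation '", name, "'; available: ",
         paste(names(.activations), collapse = ", "))
  a
}
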