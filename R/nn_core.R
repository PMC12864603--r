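# Numeric primitives shared by both encoders and the fusion head: parameter
# initialization, activations, Adam with decoupled weight decay, binary
# cross-entropy, dropout. All gradients in this package are hand-derived and
# verified against central-difference numerical gradients in the test suite.

init_mat <- function(nr, nc, fan_in = nr) {
  a <- sqrt(1 / max(fan_in, 1))
  matrix(runif(nr * nc, -a, a), nr, nc)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

relu <- function(x) pmax(x, 0)

#' Count trainable parameters in a nested parameter list
#'
#' @param params A (nested) list of numeric arrays.
#' @return The total number of scalar entries.
#' @export
param_count <- function(params) {
  if (is.numeric(params)) return(length(params))
  if (is.list(params)) return(sum(vapply(params, param_count, numeric(1))))
  0
}

# Apply FUN(elementwise) to two parallel nested lists of numerics;
# non-numeric leaves (e.g. block-kind tags) pass through untouched.
map2_params <- function(a, b, fun) {
  if (is.numeric(a)) return(fun(a, b))
  if (!is.list(a)) return(a)
  out <- lapply(seq_along(a), function(i) map2_params(a[[i]], b[[i]], fun))
  names(out) <- names(a)
  out
}

map_params <- function(a, fun) {
  if (is.numeric(a)) return(fun(a))
  if (!is.list(a)) return(a)
  out <- lapply(a, map_params, fun = fun)
  names(out) <- names(a)
  out
}

zeros_like <- function(params) map_params(params, function(x) x * 0)

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# One Adam step with decoupled weight decay (decay applied directly to the
# weights, not through the gradient).
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v, function(m, v) {
    (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- map2_params(params, upd, function(p, u) {
    p - lr * u - lr * weight_decay * p
  })
  list(params = params, state = state)
}

# Mean binary cross-entropy from logits, with gradient.
bce_with_logits <- function(logits, y) {
  n <- length(logits)
  loss <- mean(softplus(logits) - y * logits)
  grad <- (sigmoid(logits) - y) / n
  list(loss = loss, grad = grad)
}

# Inverted dropout: scales kept units by 1/(1-rate) so evaluation needs no
# rescaling. Returns the mask to reuse in the backward pass.
dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, mask = NULL))
  }
  mask <- (matrix(runif(length(x)), nrow(x), ncol(x)) >= rate) / (1 - rate)
  list(out = x * mask, mask = mask)
}
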