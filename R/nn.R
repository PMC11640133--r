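# Minimal dense-network machinery: layers, manual backprop, Adam, clipping.
# Parameters live in flat named lists of matrices/vectors so the optimizer can
# walk them generically; forward passes cache what backward needs.

#' @keywords internal
nn_init_dense <- function(n_in, n_out) {
  # uniform(-1/sqrt(n_in), 1/sqrt(n_in)) for weights and biases
  bound <- 1 / sqrt(n_in)
  list(
    W = matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out),
    b = stats::runif(n_out, -bound, bound)
  )
}

#' @keywords internal
nn_init_batchnorm <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d))
}

# Dense ---------------------------------------------------------------------

# column-wise broadcast helpers (faster than sweep(): no aperm)
col_add <- function(x, v) x + rep(v, each = nrow(x))
col_sub <- function(x, v) x - rep(v, each = nrow(x))
col_mul <- function(x, v) x * rep(v, each = nrow(x))

nn_dense_forward <- function(x, W, b) {
  col_add(x %*% W, b)
}

# returns list(dx, dW, db)
nn_dense_backward <- function(dout, x, W) {
  list(
    dx = dout %*% t(W),
    dW = crossprod(x, dout),
    db = colSums(dout)
  )
}

# Batch normalization --------------------------------------------------------
# Column-wise; biased batch variance; running stats updated with momentum.

nn_bn_forward_train <- function(x, gamma, beta, eps = 1e-5) {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- col_sub(x, mu)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- col_mul(xc, istd)
  out <- col_add(col_mul(xhat, gamma), beta)
  list(out = out, cache = list(xhat = xhat, istd = istd, mu = mu, v = v))
}

nn_bn_forward_eval <- function(x, gamma, beta, rm, rv, eps = 1e-5) {
  xhat <- col_mul(col_sub(x, rm), 1 / sqrt(rv + eps))
  col_add(col_mul(xhat, gamma), beta)
}

# returns list(dx, dgamma, dbeta)
nn_bn_backward <- function(dout, cache, gamma) {
  n <- nrow(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- col_mul(dout, gamma)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- col_mul(dxhat - rep(m1, each = n) - col_mul(xhat, m2), cache$istd)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ReLU / dropout --------------------------------------------------------------

nn_relu <- function(x) {
  x[x < 0] <- 0
  x
}

nn_relu_backward <- function(dout, x) {
  dout * (x > 0)
}

# inverted dropout; p = drop probability
nn_dropout_forward <- function(x, p) {
  keep <- 1 - p
  mask <- matrix(stats::rbinom(length(x), 1, keep), nrow(x)) / keep
  list(out = x * mask, mask = mask)
}

# Softmax / cross-entropy -----------------------------------------------------

nn_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# weighted-mean negative log likelihood; labels are 1-based column indices
nn_ce_loss <- function(probs, labels, weights = NULL) {
  n <- nrow(probs)
  if (is.null(weights)) weights <- rep(1, n)
  p <- probs[cbind(seq_len(n), labels)]
  p <- pmax(p, 1e-12)
  sum(weights * (-log(p))) / sum(weights)
}

# gradient of nn_ce_loss w.r.t. logits
nn_ce_grad <- function(probs, labels, weights = NULL) {
  n <- nrow(probs)
  if (is.null(weights)) weights <- rep(1, n)
  g <- probs
  g[cbind(seq_len(n), labels)] <- g[cbind(seq_len(n), labels)] - 1
  g * (weights / sum(weights))
}

# Adam -------------------------------------------------------------------------

#' @keywords internal
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

# Clip gradients to a global L2 norm, then take one Adam step.
# Returns list(params, state, grad_norm).
#' @keywords internal
adam_step <- function(params, grads, state, lr,
                      clip = NULL, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (!is.null(clip) && is.finite(gnorm) && gnorm > clip) {
    scale <- clip / gnorm
    grads <- lapply(grads, function(g) g * scale)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state, grad_norm = gnorm)
}

# zero-filled gradient skeleton matching params
#' @keywords internal
zero_grads <- function(params) lapply(params, function(p) p * 0)
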