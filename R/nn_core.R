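# Minimal dense neural-network primitives (forward + analytic backward) and
# an Adam optimizer with linear warmup/decay. Parameters live in flat named
# lists of numeric arrays so optimizer state and gradient accumulation are
# simple name-wise maps.

# Sigmoid-weighted GELU (x * sigmoid(1.702 x)): the standard fast
# approximation of the Gaussian-CDF form, used consistently in forward and
# backward passes.
gelu <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  x * s
}

gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s + 1.702 * x * s * (1 - s)
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

softplus_ <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Row-wise softmax of a matrix.
softmax_rows <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

# Row-wise layer normalisation. Returns y plus backward cache.
layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- Xc * inv
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * inv
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# Seeded Gaussian matrix with fan-based scaling.
.winit <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (nr + nc))
  matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
}

# Elementwise map over two flat parameter lists.
params_map2 <- function(a, b, f) {
  out <- a
  for (nm in names(a)) out[[nm]] <- f(a[[nm]], b[[nm]])
  out
}

params_zero_like <- function(p) lapply(p, function(x) x * 0)

# Accumulate gradients: a + b for names present in b.
grads_add <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

# Batch accumulator: first call copies (detaching from the per-sample
# gradient list), later calls add in place via compiled code.
grads_accumulate <- function(acc, g) {
  if (is.null(acc)) return(lapply(g, function(x) x * 1))
  for (nm in names(g)) {
    if (is.null(acc[[nm]])) acc[[nm]] <- g[[nm]] * 1
    else cpp_add_inplace(acc[[nm]], g[[nm]])
  }
  acc
}

grads_scale <- function(g, s) lapply(g, function(x) x * s)

# Global-norm gradient clipping (in place; the accumulator is loop-owned).
clip_global_norm <- function(g, max_norm = 1.0) {
  tot <- sqrt(cpp_global_norm_sq(g))
  if (is.finite(tot) && tot > max_norm) cpp_scale_inplace(g, max_norm / tot)
  g
}

clip_global_norm_r <- function(g, max_norm = 1.0) {
  tot <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
  if (is.finite(tot) && tot > max_norm) g <- grads_scale(g, max_norm / tot)
  g
}

#' Linear warmup / linear decay learning-rate schedule
#'
#' Ramps linearly from 0 to `lr_peak` over `warmup_steps`, then decays
#' linearly to 0 at `total_steps`.
#'
#' @param step Current step (1-based).
#' @param lr_peak Peak learning rate.
#' @param warmup_steps Warmup length (>= 0).
#' @param total_steps Total schedule length.
#' @return Learning rate for `step`.
#' @export
lr_schedule <- function(step, lr_peak, warmup_steps, total_steps) {
  if (warmup_steps > 0 && step <= warmup_steps)
    return(lr_peak * step / warmup_steps)
  if (total_steps <= warmup_steps) return(lr_peak)
  max(0, lr_peak * (total_steps - step) / (total_steps - warmup_steps))
}

#' Adam optimizer state
#'
#' @param params Flat named parameter list.
#' @param beta1,beta2 Moment decay rates (defaults 0.9 / 0.99).
#' @param eps Numerical floor.
#' @param weight_decay L2 coefficient added to gradients.
#' @return Optimizer state list.
#' @export
adam_init <- function(params, beta1 = 0.9, beta2 = 0.99, eps = 1e-8,
                      weight_decay = 1e-4) {
  list(m = params_zero_like(params), v = params_zero_like(params),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay)
}

#' One Adam step
#'
#' Dispatches to a compiled in-place kernel that reproduces this reference
#' loop bit for bit (moment buffers are loop-owned and updated in place;
#' parameters are copied once per step so snapshots stay intact).
#'
#' @param params Parameter list.
#' @param grads Gradient list (same names).
#' @param state State from [adam_init()].
#' @param lr Learning rate for this step.
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  # align grads to params by name (missing -> NULL, parameter frozen)
  g_aligned <- grads[match(names(params), names(grads))]
  params <- lapply(params, function(x) x + 0)
  cpp_adam_update(params, g_aligned, state$m, state$v, lr, b1, b2,
                  bc1, bc2, state$eps, state$weight_decay, 1.0)
  list(params = params, state = state)
}

# Reference R implementation (parity-checked against the compiled path).
adam_step_r <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (state$weight_decay > 0) g <- g + state$weight_decay * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}

# Smooth-L1 (Huber, delta = 1) loss over an array; returns mean loss and
# elementwise d(loss)/d(pred) already divided by the element count.
smooth_l1 <- function(pred, target, mask = NULL) {
  u <- pred - target
  if (!is.null(mask)) u <- u * mask
  au <- abs(u)
  l <- ifelse(au < 1, 0.5 * u^2, au - 0.5)
  n <- if (is.null(mask)) length(u) else max(sum(mask), 1)
  grad <- pmin(pmax(u, -1), 1)
  if (!is.null(mask)) grad <- grad * mask
  list(loss = sum(l) / n, grad = grad / n)
}
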