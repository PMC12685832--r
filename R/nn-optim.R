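# Optimization ----------------------------------------------------------------
#
# Adam over arbitrary nested parameter lists, plus the cosine-annealing
# learning-rate schedule used by the training protocol.

tree_zero <- function(x) {
  if (is.list(x)) lapply(x, tree_zero) else x * 0
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

# One Adam step; returns list(params, state). Operates recursively so any
# nesting of parameter lists works.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  step_leaf <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      step_leaf(p, g, m, v)
    }
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

# elementwise sum of two gradient trees
tree_add <- function(x, y) {
  if (is.list(x)) Map(tree_add, x, y) else x + y
}

tree_scale <- function(x, s) {
  if (is.list(x)) lapply(x, tree_scale, s = s) else x * s
}

#' Cosine-annealing learning rate
#'
#' The rate starts at `lr0` at epoch 0, reaches `lr_min` at epoch `period`
#' and mirrors back up, giving a cycle of length `2 * period` (the standard
#' closed-form cosine-annealing schedule with `T_max = period`).
#'
#' @param epoch Zero-based epoch index.
#' @param lr0 Peak learning rate.
#' @param period Half-cycle length in epochs (default 10).
#' @param lr_min Floor learning rate (default 0).
#' @return Learning rate for the epoch.
#' @export
cosine_lr <- function(epoch, lr0, period = 10, lr_min = 0) {
  t <- epoch %% (2 * period)
  if (t > period) t <- 2 * period - t
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * t / period))
}
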