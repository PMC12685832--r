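# Minimal neural-network core -------------------------------------------------
#
# Dense matrix-algebra implementations of the layers the two branches need:
# 1-D/2-D convolution via im2col, ReLU, global average pooling, linear maps,
# layer normalization and multi-head self-attention. Every layer exposes an
# explicit forward (returning a cache) and backward (returning parameter and
# input gradients), which is what the Grad-CAM hooks and the cooperative
# training loop consume. All state is plain R lists, so checkpoints are
# ordinary serializable objects and runs are bit-stable on CPU.

he_init <- function(nin, nout, sd = sqrt(2 / nin)) {
  matrix(stats::rnorm(nin * nout, 0, sd), nin, nout)
}

# ---- 1-D convolution (valid, strided; compiled im2col + BLAS kernels) -------

conv1d_forward <- function(spec, par, X) {
  out <- .conv1d_fwd(X, par$W, par$b, spec$k, spec$stride)
  list(out = out, cache = list(X = X))
}

conv1d_backward <- function(spec, par, cache, dOut) {
  r <- .conv1d_bwd(cache$X, par$W, dOut, spec$k, spec$stride)
  list(dX = r$dX, grads = list(W = r$dW, b = as.vector(r$db)))
}

# ---- 2-D convolution (zero padding, strided; compiled kernels) --------------

conv2d_forward <- function(spec, par, X) {
  out <- .conv2d_fwd(X, par$W, par$b, spec$k, spec$stride, spec$pad)
  list(out = out, cache = list(X = X))
}

conv2d_backward <- function(spec, par, cache, dOut) {
  r <- .conv2d_bwd(cache$X, par$W, dOut, spec$k, spec$stride, spec$pad)
  list(dX = r$dX, grads = list(W = r$dW, b = as.vector(r$db)))
}

# ---- Pointwise and pooling ---------------------------------------------------

relu_forward <- function(X) X * (X > 0)
relu_backward <- function(X, dOut) dOut * (X > 0)

# global average pool over the trailing spatial dims of [N, C, ...]
gap_forward <- function(X) {
  d <- dim(X)
  sp <- prod(d[-(1:2)])
  matrix(rowMeans(matrix(X, d[1] * d[2], sp)), d[1], d[2])
}

gap_backward <- function(X, dFeat) {
  d <- dim(X)
  sp <- prod(d[-(1:2)])
  array(rep(as.vector(dFeat), sp) / sp, d)
}

# mean + max pool over time for [N, C, L]: peak-sensitive waveform readout
# (QRS amplitudes live in the max, baseline morphology in the mean)
gmp_forward <- function(X) {
  d <- dim(X)
  m <- matrix(X, d[1] * d[2], d[3])
  idx <- max.col(m, ties.method = "first")
  vals <- m[cbind(seq_len(nrow(m)), idx)]
  list(feat = cbind(matrix(rowMeans(m), d[1], d[2]),
                    matrix(vals, d[1], d[2])),
       idx = idx)
}

gmp_backward <- function(X, cache, dFeat) {
  d <- dim(X)
  C <- d[2]
  dmean <- gap_backward(X, dFeat[, seq_len(C), drop = FALSE])
  dm <- matrix(0, d[1] * d[2], d[3])
  dm[cbind(seq_len(nrow(dm)), cache$idx)] <-
    as.vector(dFeat[, C + seq_len(C), drop = FALSE])
  dmean + array(dm, d)
}

# ---- Linear -----------------------------------------------------------------

linear_forward <- function(par, X) sweep(X %*% par$W, 2, par$b, "+")

linear_backward <- function(par, X, dY) {
  list(dX = dY %*% t(par$W),
       grads = list(W = crossprod(X, dY), b = colSums(dY)))
}

# ---- Layer normalization (per row over features) ----------------------------

layernorm_forward <- function(par, X, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  si <- 1 / sqrt(v + eps)
  xhat <- xc * si
  Y <- sweep(sweep(xhat, 2, par$g, "*"), 2, par$b, "+")
  list(out = Y, cache = list(xhat = xhat, si = si))
}

layernorm_backward <- function(par, cache, dY) {
  xhat <- cache$xhat; si <- cache$si
  dxhat <- sweep(dY, 2, par$g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- si * (dxhat - m1 - xhat * m2)
  list(dX = dX,
       grads = list(g = colSums(dY * xhat), b = colSums(dY)))
}

# ---- Multi-head self-attention ----------------------------------------------

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

# Xm: (B*T) x d token matrix, rows ordered batch-fastest (row = b + B*(t-1))
mhsa_forward <- function(arch, par, Xm, B, T) {
  d <- arch$embed_dim; nh <- arch$n_heads; dh <- d %/% nh
  Q <- sweep(Xm %*% par$Wq, 2, par$bq, "+")
  K <- sweep(Xm %*% par$Wk, 2, par$bk, "+")
  V <- sweep(Xm %*% par$Wv, 2, par$bv, "+")
  O <- matrix(0, B * T, d)
  attn <- array(0, c(B, nh, T, T))
  for (b in seq_len(B)) {
    rows <- seq(b, by = B, length.out = T)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- softmax_rows(tcrossprod(Q[rows, cols, drop = FALSE],
                                   K[rows, cols, drop = FALSE]) / sqrt(dh))
      attn[b, h, , ] <- A
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
    }
  }
  out <- sweep(O %*% par$Wo, 2, par$bo, "+")
  list(out = out, attn = attn,
       cache = list(Xm = Xm, Q = Q, K = K, V = V, O = O, attn = attn,
                    B = B, T = T))
}

mhsa_backward <- function(arch, par, cache, dOut) {
  d <- arch$embed_dim; nh <- arch$n_heads; dh <- d %/% nh
  B <- cache$B; T <- cache$T
  dWo <- crossprod(cache$O, dOut)
  dbo <- colSums(dOut)
  dO <- dOut %*% t(par$Wo)
  dQ <- matrix(0, B * T, d); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- seq(b, by = B, length.out = T)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$attn[b, h, , ]
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOb, Vb)
      dV[rows, cols] <- crossprod(A, dOb)
      dS <- A * (dA - rowSums(A * dA))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] / sqrt(dh)
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) /
        sqrt(dh)
    }
  }
  dXm <- dQ %*% t(par$Wq) + dK %*% t(par$Wk) + dV %*% t(par$Wv)
  list(dX = dXm,
       grads = list(Wq = crossprod(cache$Xm, dQ), bq = colSums(dQ),
                    Wk = crossprod(cache$Xm, dK), bk = colSums(dK),
                    Wv = crossprod(cache$Xm, dV), bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

# ---- Transformer encoder block (pre-LN) -------------------------------------

block_init <- function(d, nh, dff) {
  s <- sqrt(1 / d)
  list(
    ln1 = list(g = rep(1, d), b = rep(0, d)),
    attn = list(Wq = he_init(d, d, s), bq = rep(0, d),
                Wk = he_init(d, d, s), bk = rep(0, d),
                Wv = he_init(d, d, s), bv = rep(0, d),
                Wo = he_init(d, d, s), bo = rep(0, d)),
    ln2 = list(g = rep(1, d), b = rep(0, d)),
    ffn = list(W1 = he_init(d, dff), b1 = rep(0, dff),
               W2 = he_init(dff, d, sqrt(1 / dff)), b2 = rep(0, d))
  )
}

block_forward <- function(arch, par, Xm, B, T) {
  l1 <- layernorm_forward(par$ln1, Xm)
  at <- mhsa_forward(arch, par$attn, l1$out, B, T)
  X2 <- Xm + at$out
  l2 <- layernorm_forward(par$ln2, X2)
  H1 <- linear_forward(list(W = par$ffn$W1, b = par$ffn$b1), l2$out)
  A1 <- relu_forward(H1)
  H2 <- linear_forward(list(W = par$ffn$W2, b = par$ffn$b2), A1)
  out <- X2 + H2
  list(out = out, attn = at$attn,
       cache = list(l1 = l1, at = at, X2 = X2, l2 = l2, H1 = H1, A1 = A1))
}

block_backward <- function(arch, par, cache, dOut) {
  ffn2 <- linear_backward(list(W = par$ffn$W2, b = par$ffn$b2),
                          cache$A1, dOut)
  dH1 <- relu_backward(cache$H1, ffn2$dX)
  ffn1 <- linear_backward(list(W = par$ffn$W1, b = par$ffn$b1),
                          cache$l2$out, dH1)
  l2b <- layernorm_backward(par$ln2, cache$l2$cache, ffn1$dX)
  dX2 <- dOut + l2b$dX
  atb <- mhsa_backward(arch, par$attn, cache$at$cache, dX2)
  l1b <- layernorm_backward(par$ln1, cache$l1$cache, atb$dX)
  dXm <- dX2 + l1b$dX
  list(dX = dXm,
       grads = list(ln1 = l1b$grads, attn = atb$grads, ln2 = l2b$grads,
                    ffn = list(W1 = ffn1$grads$W, b1 = ffn1$grads$b,
                               W2 = ffn2$grads$W, b2 = ffn2$grads$b)))
}
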