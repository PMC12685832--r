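# ECG branch: shared per-lead 1-D CNN + Transformer with class token ----------

#' ECG encoder configuration
#'
#' A shared 1-D convolutional tower embeds every lead into `embed_dim`
#' dimensions (global average pooling over time followed by a linear
#' projection); the 12 lead embeddings, with learned lead-identity
#' embeddings, are prepended with a class token and passed through a
#' Transformer encoder whose class-token output feeds a linear scoring head.
#'
#' @param embed_dim Per-lead embedding width (default 256); must be divisible
#'   by `n_heads`.
#' @param cnn_scale Width multiplier for the convolutional tower, letting
#'   desk-scale runs shrink it (default 1 gives channels 16/32/64).
#' @param n_transformer_layers Number of encoder blocks (default 4).
#' @param n_heads Attention heads per block (default 8).
#' @param n_leads Number of leads (default 12).
#' @param use_lead_embedding Add learned lead-identity embeddings (leads form
#'   a set, not a sequence, so these replace positional encodings). Disabling
#'   them makes the encoder exactly lead-permutation equivariant.
#' @param ffn_mult Feed-forward width multiplier inside each block.
#' @param final_norm Apply a layer norm to the encoder output before the
#'   scoring head (standard for pre-LN encoders; a flag so shallow
#'   configurations can trade it away).
#' @return Object of class `ecg_encoder_config`.
#' @export
ecg_encoder_config <- function(embed_dim = 256L, cnn_scale = 1,
                               n_transformer_layers = 4L, n_heads = 8L,
                               n_leads = 12L, use_lead_embedding = TRUE,
                               ffn_mult = 2, final_norm = TRUE) {
  assert_that(embed_dim %% n_heads == 0,
              "embed_dim must be divisible by n_heads")
  assert_that(is_count(n_transformer_layers) && is_count(n_heads),
              "layer and head counts must be positive integers")
  channels <- pmax(2L, as.integer(round(c(16, 32, 64) * cnn_scale)))
  conv <- list(
    list(cin = 1L, cout = channels[1], k = 7L, stride = 4L),
    list(cin = channels[1], cout = channels[2], k = 5L, stride = 4L),
    list(cin = channels[2], cout = channels[3], k = 3L, stride = 2L)
  )
  structure(list(embed_dim = as.integer(embed_dim),
                 cnn_scale = cnn_scale,
                 n_transformer_layers = as.integer(n_transformer_layers),
                 n_heads = as.integer(n_heads),
                 n_leads = as.integer(n_leads),
                 use_lead_embedding = isTRUE(use_lead_embedding),
                 ffn_mult = ffn_mult,
                 final_norm = isTRUE(final_norm),
                 conv = conv),
            class = "ecg_encoder_config")
}

#' Initialize an untrained ECG branch
#'
#' @param config An [ecg_encoder_config()].
#' @param seed Optional integer seed for the weight initialization.
#' @return Object of class `coop_ecg_model` with fields `arch` and `params`.
#' @export
ecg_model_init <- function(config = ecg_encoder_config(), seed = NULL) {
  assert_that(inherits(config, "ecg_encoder_config"),
              "config must be an ecg_encoder_config()")
  with_seed(seed, {
    d <- config$embed_dim
    dff <- as.integer(round(d * config$ffn_mult))
    cf <- 2L * config$conv[[length(config$conv)]]$cout  # mean + max readout
    params <- list(
      conv = lapply(config$conv, function(s) {
        list(W = he_init(s$cin * s$k, s$cout), b = rep(0, s$cout))
      }),
      proj = list(W = he_init(cf, d, sqrt(1 / cf)), b = rep(0, d)),
      cls = stats::rnorm(d, 0, 0.02),
      blocks = lapply(seq_len(config$n_transformer_layers),
                      function(i) block_init(d, config$n_heads, dff)),
      head = list(W = he_init(d, 1L, sqrt(1 / d)), b = 0)
    )
    if (config$final_norm) params$ln_f <- list(g = rep(1, d), b = rep(0, d))
    if (config$use_lead_embedding) {
      params$lead <- matrix(stats::rnorm(config$n_leads * d, 0, 0.02),
                            config$n_leads, d)
    }
    structure(list(arch = config, params = params), class = "coop_ecg_model")
  })
}

# Shared tower over leads: segs [B, 12, L] -> list(emb (B*12) x d, caches).
# Rows of all per-lead matrices are ordered batch-fastest (row = b + B*(l-1)).
ecg_tower_forward <- function(model, segs) {
  cfg <- model$arch; par <- model$params
  B <- dim(segs)[1]
  N <- B * cfg$n_leads
  X <- array(matrix(segs, N, dim(segs)[3]), c(N, 1L, dim(segs)[3]))
  caches <- vector("list", length(cfg$conv))
  acts <- vector("list", length(cfg$conv))
  for (i in seq_along(cfg$conv)) {
    cv <- conv1d_forward(cfg$conv[[i]], par$conv[[i]], X)
    caches[[i]] <- list(conv = cv$cache, pre = cv$out)
    X <- relu_forward(cv$out)
    acts[[i]] <- X
  }
  pool <- gmp_forward(X)
  emb <- linear_forward(par$proj, pool$feat)
  list(emb = emb, feat = pool$feat, pool_idx = pool$idx, conv_act = X,
       caches = caches, B = B, N = N)
}

ecg_tower_backward <- function(model, tw, dEmb) {
  cfg <- model$arch; par <- model$params
  pj <- linear_backward(par$proj, tw$feat, dEmb)
  dA <- gmp_backward(tw$conv_act, list(idx = tw$pool_idx), pj$dX)
  dconv_act <- dA  # gradient at the final (post-ReLU) conv activations
  gconv <- vector("list", length(cfg$conv))
  for (i in rev(seq_along(cfg$conv))) {
    dPre <- relu_backward(tw$caches[[i]]$pre, dA)
    bk <- conv1d_backward(cfg$conv[[i]], par$conv[[i]],
                          tw$caches[[i]]$conv, dPre)
    gconv[[i]] <- bk$grads
    dA <- bk$dX
  }
  list(grads = list(conv = gconv, proj = pj$grads),
       dconv_act = dconv_act, dinput = dA)
}

# Full branch forward over a batch: segs [B, 12, L].
ecg_forward_batch <- function(model, segs) {
  cfg <- model$arch; par <- model$params
  tw <- ecg_tower_forward(model, segs)
  B <- tw$B; d <- cfg$embed_dim; T <- cfg$n_leads + 1L
  tokens <- array(0, c(B, T, d))
  tokens[, 1, ] <- matrix(par$cls, B, d, byrow = TRUE)
  lead_tok <- array(tw$emb, c(B, cfg$n_leads, d))
  if (cfg$use_lead_embedding) {
    for (l in seq_len(cfg$n_leads)) {
      lead_tok[, l, ] <- lead_tok[, l, ] +
        matrix(par$lead[l, ], B, d, byrow = TRUE)
    }
  }
  tokens[, 2:T, ] <- lead_tok
  Xm <- matrix(tokens, B * T, d)
  bl_caches <- vector("list", length(par$blocks))
  attn <- vector("list", length(par$blocks))
  for (i in seq_along(par$blocks)) {
    bf <- block_forward(cfg, par$blocks[[i]], Xm, B, T)
    bl_caches[[i]] <- bf$cache
    attn[[i]] <- bf$attn
    Xm <- bf$out
  }
  lnf <- if (cfg$final_norm) layernorm_forward(par$ln_f, Xm) else
    list(out = Xm, cache = NULL)
  cls_rows <- seq_len(B)  # row = b + B*(t-1), class token is t = 1
  cls_out <- lnf$out[cls_rows, , drop = FALSE]
  score <- as.vector(linear_forward(par$head, cls_out))
  list(score = score, attn = attn, conv_act = tw$conv_act,
       cache = list(tw = tw, bl = bl_caches, lnf = lnf, cls_out = cls_out,
                    B = B, T = T))
}

ecg_backward_batch <- function(model, fw, dscore) {
  cfg <- model$arch; par <- model$params
  B <- fw$cache$B; T <- fw$cache$T; d <- cfg$embed_dim
  hd <- linear_backward(par$head, fw$cache$cls_out,
                        matrix(dscore, B, 1))
  dLn <- matrix(0, B * T, d)
  dLn[seq_len(B), ] <- hd$dX
  if (cfg$final_norm) {
    lnb <- layernorm_backward(par$ln_f, fw$cache$lnf$cache, dLn)
    dXm <- lnb$dX
  } else {
    lnb <- NULL
    dXm <- dLn
  }
  gblocks <- vector("list", length(par$blocks))
  for (i in rev(seq_along(par$blocks))) {
    bb <- block_backward(cfg, par$blocks[[i]], fw$cache$bl[[i]], dXm)
    gblocks[[i]] <- bb$grads
    dXm <- bb$dX
  }
  dTok <- array(dXm, c(B, T, d))
  dcls <- colSums(matrix(dTok[, 1, ], B, d))
  dLead <- dTok[, 2:T, , drop = FALSE]
  grads <- list(conv = NULL, proj = NULL, cls = dcls, blocks = gblocks,
                head = hd$grads)
  if (cfg$final_norm) grads$ln_f <- lnb$grads
  if (cfg$use_lead_embedding) {
    glead <- matrix(0, cfg$n_leads, d)
    for (l in seq_len(cfg$n_leads)) {
      glead[l, ] <- colSums(matrix(dLead[, l, ], B, d))
    }
    grads$lead <- glead
  }
  dEmb <- matrix(dLead, B * cfg$n_leads, d)
  twb <- ecg_tower_backward(model, fw$cache$tw, dEmb)
  grads$conv <- twb$grads$conv
  grads$proj <- twb$grads$proj
  # order grads like params for the optimizer tree walk
  grads <- grads[names(model$params)]
  list(grads = grads, dconv_act = twb$dconv_act)
}

#' Embed the 12 leads of a segment with the shared convolutional tower
#'
#' Every lead is processed by the same weights (weight sharing), so row i of
#' the output depends only on lead i. Lead-identity embeddings and the
#' Transformer are not applied here.
#'
#' @param model A `coop_ecg_model`.
#' @param segment 12 x L numeric matrix (mV).
#' @return `n_leads` x `embed_dim` embedding matrix, rows named by lead.
#' @export
encode_leads <- function(model, segment) {
  assert_that(inherits(model, "coop_ecg_model"), "model must be a coop_ecg_model")
  assert_that(is.matrix(segment) && nrow(segment) == model$arch$n_leads,
              "segment must have one row per lead")
  segs <- array(0, c(1L, nrow(segment), ncol(segment)))
  segs[1, , ] <- segment
  emb <- ecg_tower_forward(model, segs)$emb
  rownames(emb) <- rownames(segment) %||% ecg_lead_names()
  emb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a single ECG segment
#'
#' @param model A `coop_ecg_model`.
#' @param segment 12 x L numeric matrix (mV), typically a 12 x 1000 segment.
#' @return List with `score` (pre-sigmoid scalar) and `aux` containing
#'   `attention` (per-layer arrays `heads x tokens x tokens`, token 1 being
#'   the class token) and `conv_activations` (final tower activations per
#'   lead).
#' @export
ecg_forward <- function(model, segment) {
  assert_that(inherits(model, "coop_ecg_model"), "model must be a coop_ecg_model")
  assert_that(is.matrix(segment) && nrow(segment) == model$arch$n_leads,
              "segment must have one row per lead")
  segs <- array(0, c(1L, nrow(segment), ncol(segment)))
  segs[1, , ] <- segment
  fw <- ecg_forward_batch(model, segs)
  attn <- lapply(fw$attn, function(a) {
    out <- array(a[1, , , ], dim(a)[2:4])
    out
  })
  list(score = fw$score[1],
       aux = list(attention = attn,
                  conv_activations = array(fw$conv_act,
                                           dim(fw$conv_act)[1:3])))
}
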