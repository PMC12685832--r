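# Image branch: 2-D CNN over chest-radiograph tensors -------------------------

#' Image encoder configuration
#'
#' A stack of stride-2 3x3 convolutions halves the spatial grid until it is
#' at most 8 pixels wide, followed by a stride-1 3x3 convolution whose
#' activations are the Grad-CAM target layer, global average pooling and a
#' linear scoring head. The `"efficientnet-style"` backbone widens the stem
#' and inserts an extra stride-1 convolution per stage, approximating the
#' compound-scaled reference architecture at desk scale; `"small-cnn"` keeps
#' every test CPU-fast.
#'
#' @param backbone `"small-cnn"` or `"efficientnet-style"`.
#' @param input_size Input side length in pixels (default 224, >= 32).
#' @param base_channels Channel width of the first stage.
#' @param pretrained If `TRUE`, requests externally pretrained weights; no
#'   weight files ship with the package, so initialization falls back to
#'   random with a warning.
#' @return Object of class `image_encoder_config`.
#' @export
image_encoder_config <- function(backbone = c("small-cnn",
                                              "efficientnet-style"),
                                 input_size = 224L,
                                 base_channels = NULL,
                                 pretrained = FALSE) {
  backbone <- match.arg(backbone)
  assert_that(input_size >= 32, "input_size must be at least 32 pixels")
  if (is.null(base_channels)) {
    base_channels <- if (backbone == "small-cnn") 8L else 16L
  }
  conv <- list()
  s <- as.integer(input_size)
  ch_in <- 1L
  ch <- as.integer(base_channels)
  while (s > 8L) {
    conv[[length(conv) + 1L]] <-
      list(cin = ch_in, cout = ch, k = 3L, stride = 2L, pad = 1L)
    if (backbone == "efficientnet-style") {
      conv[[length(conv) + 1L]] <-
        list(cin = ch, cout = ch, k = 3L, stride = 1L, pad = 1L)
    }
    ch_in <- ch
    ch <- min(ch * 2L, 64L)
    s <- (s + 1L) %/% 2L
  }
  conv[[length(conv) + 1L]] <-
    list(cin = ch_in, cout = ch_in, k = 3L, stride = 1L, pad = 1L)
  structure(list(backbone = backbone,
                 input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels),
                 pretrained = isTRUE(pretrained),
                 conv = conv,
                 final_grid = s),
            class = "image_encoder_config")
}

#' Initialize an untrained image branch
#'
#' @param config An [image_encoder_config()].
#' @param seed Optional integer seed.
#' @return Object of class `coop_image_model`.
#' @export
image_model_init <- function(config = image_encoder_config(), seed = NULL) {
  assert_that(inherits(config, "image_encoder_config"),
              "config must be an image_encoder_config()")
  if (config$pretrained) {
    warning("pretrained weights are not bundled; using random initialization")
  }
  with_seed(seed, {
    cf <- config$conv[[length(config$conv)]]$cout
    params <- list(
      conv = lapply(config$conv, function(sp) {
        list(W = he_init(sp$cin * sp$k * sp$k, sp$cout), b = rep(0, sp$cout))
      }),
      head = list(W = he_init(cf, 1L, sqrt(1 / cf)), b = 0)
    )
    structure(list(arch = config, params = params), class = "coop_image_model")
  })
}

# Per-sample input standardization: removes global brightness/contrast cues
# (per-image windowing already makes them unstable), so the branch reads
# morphology. Applied to the input itself, it needs no parameter backward.
standardize_images <- function(imgs) {
  B <- dim(imgs)[1]
  m <- matrix(imgs, B)
  mu <- rowMeans(m)
  sd_ <- sqrt(pmax(rowMeans((m - mu)^2), 1e-12))
  array((m - mu) / sd_, dim(imgs))
}

# imgs: [B, 1, S, S]
image_forward_batch <- function(model, imgs) {
  cfg <- model$arch; par <- model$params
  X <- standardize_images(imgs)
  caches <- vector("list", length(cfg$conv))
  for (i in seq_along(cfg$conv)) {
    cv <- conv2d_forward(cfg$conv[[i]], par$conv[[i]], X)
    caches[[i]] <- list(conv = cv$cache, pre = cv$out)
    X <- relu_forward(cv$out)
  }
  feat <- gap_forward(X)
  score <- as.vector(linear_forward(par$head, feat))
  list(score = score, conv_act = X,
       cache = list(caches = caches, conv_act = X, feat = feat))
}

image_backward_batch <- function(model, fw, dscore) {
  cfg <- model$arch; par <- model$params
  B <- length(fw$score)
  hd <- linear_backward(par$head, fw$cache$feat, matrix(dscore, B, 1))
  dA <- gap_backward(fw$cache$conv_act, hd$dX)
  dconv_act <- dA
  gconv <- vector("list", length(cfg$conv))
  for (i in rev(seq_along(cfg$conv))) {
    dPre <- relu_backward(fw$cache$caches[[i]]$pre, dA)
    bk <- conv2d_backward(cfg$conv[[i]], par$conv[[i]],
                          fw$cache$caches[[i]]$conv, dPre)
    gconv[[i]] <- bk$grads
    dA <- bk$dX
  }
  list(grads = list(conv = gconv, head = hd$grads),
       dconv_act = dconv_act, dinput = dA)
}

#' Score a single prepared image
#'
#' @param model A `coop_image_model`.
#' @param image 2-D numeric matrix in \[0, 1\] of the configured input size.
#' @param as_probability Apply the sigmoid and return a probability instead
#'   of the raw pre-sigmoid score. The cooperative objective always consumes
#'   raw scores; the sigmoid exists only for standalone probability reads.
#' @return List with `score` and `aux$conv_activations` (final convolutional
#'   feature maps, the Grad-CAM hook).
#' @export
image_forward <- function(model, image, as_probability = FALSE) {
  assert_that(inherits(model, "coop_image_model"),
              "model must be a coop_image_model")
  assert_that(is.matrix(image), "image must be a 2-D matrix")
  assert_that(nrow(image) == model$arch$input_size &&
                ncol(image) == model$arch$input_size,
              "image must be ", model$arch$input_size, "x",
              model$arch$input_size)
  imgs <- array(0, c(1L, 1L, nrow(image), ncol(image)))
  imgs[1, 1, , ] <- image
  fw <- image_forward_batch(model, imgs)
  s <- fw$score[1]
  list(score = if (as_probability) sigmoid(s) else s,
       aux = list(conv_activations = array(fw$conv_act[1, , , ],
                                           dim(fw$conv_act)[2:4])))
}
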