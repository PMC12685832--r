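test_that("lead encoding shares weights and is permutation-equivariant", {
  cfg <- tiny_ecg_config(use_lead_embedding = FALSE)
  m <- ecg_model_init(cfg, seed = 1)
  withr::with_seed(2, seg <- matrix(rnorm(12 * 1000, 0, 0.5), 12, 1000))
  emb <- encode_leads(m, seg)
  expect_equal(dim(emb), c(12L, 16L))
  # permuting two leads permutes the corresponding rows identically
  perm <- seg[c(2, 1, 3:12), ]
  emb_p <- encode_leads(m, perm)
  expect_equal(emb_p[1, ], emb[2, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(emb_p[2, ], emb[1, ], tolerance = 1e-12, ignore_attr = TRUE)
  # identical leads map to identical embeddings (shared weights)
  same <- matrix(rep(seg[1, ], 12), 12, byrow = TRUE)
  emb_s <- encode_leads(m, same)
  expect_equal(emb_s, emb_s[rep(1, 12), ], ignore_attr = TRUE)
  # default configuration gives 256-dimensional per-lead features
  expect_equal(ecg_encoder_config()$embed_dim, 256L)
  expect_error(ecg_encoder_config(embed_dim = 10, n_heads = 4),
               class = "coopAS_invalid_input")
})

test_that("ECG forward emits a finite scalar with normalized attention", {
  m <- ecg_model_init(tiny_ecg_config(n_transformer_layers = 2), seed = 3)
  withr::with_seed(4, seg <- matrix(rnorm(12 * 1000, 0, 0.5), 12, 1000))
  out <- ecg_forward(m, seg)
  expect_length(out$score, 1)
  expect_true(is.finite(out$score))
  expect_length(out$aux$attention, 2)
  for (a in out$aux$attention) {
    expect_equal(dim(a), c(2L, 13L, 13L))
    expect_true(all(a >= 0))
    expect_equal(apply(a, c(1, 2), sum), matrix(1, 2, 13), tolerance = 1e-9)
  }
  # determinism: same weights, same input, same score
  expect_identical(out$score, ecg_forward(m, seg)$score)
})

test_that("identical leads receive equal attention without identity embeddings", {
  m <- ecg_model_init(tiny_ecg_config(use_lead_embedding = FALSE), seed = 5)
  seg <- matrix(rep(sin(seq_len(1000) / 20), 12), 12, byrow = TRUE)
  out <- ecg_forward(m, seg)
  a <- out$aux$attention[[1]]
  # class-token query row: all 12 lead keys indistinguishable
  for (h in 1:2) {
    lead_att <- a[h, 1, 2:13]
    expect_lt(diff(range(lead_att)), 1e-10)
  }
})

test_that("image forward exposes scores and the Grad-CAM activation hook", {
  cfg <- tiny_image_config(input_size = 64)
  m <- image_model_init(cfg, seed = 6)
  withr::with_seed(7, img <- matrix(runif(64 * 64), 64, 64))
  t0 <- Sys.time()
  out <- image_forward(m, img)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  expect_true(is.finite(out$score))
  act <- out$aux$conv_activations
  expect_equal(dim(act)[2:3], c(cfg$final_grid, cfg$final_grid))
  # probability view is the sigmoid of the raw score
  expect_equal(image_forward(m, img, as_probability = TRUE)$score,
               1 / (1 + exp(-out$score)))
  expect_error(image_forward(m, img[1:32, 1:32]),
               class = "coopAS_invalid_input")
  expect_warning(image_model_init(image_encoder_config(input_size = 32,
                                                       pretrained = TRUE)),
                 "pretrained")
})

test_that("compiled convolution kernels match direct R computation", {
  withr::with_seed(20, {
    X1 <- array(rnorm(2 * 2 * 11), c(2, 2, 11))
    W1 <- matrix(rnorm(2 * 3 * 4), 2 * 3, 4)
    b1 <- rnorm(4)
  })
  k <- 3L; s <- 2L
  out <- coopAS:::.conv1d_fwd(X1, W1, b1, k, s)
  Lout <- (11 - k) %/% s + 1
  # direct-sum oracle
  for (n in 1:2) for (co in 1:4) for (l in 1:Lout) {
    acc <- b1[co]
    for (c in 1:2) for (kk in 1:k) {
      acc <- acc + X1[n, c, (l - 1) * s + kk] * W1[(c - 1) * k + kk, co]
    }
    expect_equal(out[n, co, l], acc, tolerance = 1e-12)
  }
  # backward against finite differences of the forward map
  withr::with_seed(21, dOut <- array(rnorm(length(out)), dim(out)))
  bk <- coopAS:::.conv1d_bwd(X1, W1, dOut, k, s)
  h <- 1e-6
  for (probe in list(c(1, 1, 3), c(2, 2, 7))) {
    Xp <- X1; Xp[probe[1], probe[2], probe[3]] <- Xp[probe[1], probe[2], probe[3]] + h
    Xm <- X1; Xm[probe[1], probe[2], probe[3]] <- Xm[probe[1], probe[2], probe[3]] - h
    num <- sum((coopAS:::.conv1d_fwd(Xp, W1, b1, k, s) -
                  coopAS:::.conv1d_fwd(Xm, W1, b1, k, s)) * dOut) / (2 * h)
    expect_equal(bk$dX[probe[1], probe[2], probe[3]], num, tolerance = 1e-5)
  }
  # 2-D with padding
  withr::with_seed(22, {
    X2 <- array(rnorm(2 * 1 * 8 * 8), c(2, 1, 8, 8))
    W2 <- matrix(rnorm(9 * 3), 9, 3)
    b2 <- rnorm(3)
  })
  out2 <- coopAS:::.conv2d_fwd(X2, W2, b2, 3L, 2L, 1L)
  expect_equal(dim(out2), c(2L, 3L, 4L, 4L))
  # padded direct oracle at a corner and an interior position
  direct2 <- function(n, co, ho, wo) {
    acc <- b2[co]
    for (ki in 1:3) for (kj in 1:3) {
      hi <- (ho - 1) * 2 + ki - 1  # pad 1
      wi <- (wo - 1) * 2 + kj - 1
      if (hi >= 1 && hi <= 8 && wi >= 1 && wi <= 8) {
        acc <- acc + X2[n, 1, hi, wi] * W2[(ki - 1) * 3 + kj, co]
      }
    }
    acc
  }
  expect_equal(out2[1, 2, 1, 1], direct2(1, 2, 1, 1), tolerance = 1e-12)
  expect_equal(out2[2, 3, 3, 2], direct2(2, 3, 3, 2), tolerance = 1e-12)
  # rotation kernel: identity at 0 degrees; 90 degrees maps a known pixel
  m <- matrix(0, 9, 9); m[3, 5] <- 1
  expect_equal(coopAS:::.rotate_bilinear(m, 0), m, ignore_attr = TRUE)
  r90 <- coopAS:::.rotate_bilinear(m, 90)
  expect_equal(sum(r90), 1, tolerance = 1e-9)
  expect_equal(which(r90 == max(r90), arr.ind = TRUE)[1, ],
               c(row = 5, col = 7), ignore_attr = TRUE)
})

test_that("both branches propagate nonzero gradients for Grad-CAM", {
  em <- ecg_model_init(tiny_ecg_config(), seed = 8)
  withr::with_seed(9, {
    segs <- array(rnorm(2 * 12 * 1000, 0, 0.5), c(2, 12, 1000))
    imgs <- array(runif(2 * 32 * 32), c(2, 1, 32, 32))
  })
  fw <- coopAS:::ecg_forward_batch(em, segs)
  bk <- coopAS:::ecg_backward_batch(em, fw, dscore = c(1, 1))
  expect_gt(max(abs(bk$dconv_act)), 0)
  im <- image_model_init(tiny_image_config(), seed = 10)
  fwi <- coopAS:::image_forward_batch(im, imgs)
  bki <- coopAS:::image_backward_batch(im, fwi, dscore = c(1, 1))
  expect_gt(max(abs(bki$dconv_act)), 0)
  expect_gt(max(abs(bki$dinput)), 0)
})
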