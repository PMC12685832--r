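# Shared fixtures, built in code at test time.

# Tiny desk-scale branch configs used throughout the suite.
tiny_ecg_config <- function(...) {
  args <- utils::modifyList(list(embed_dim = 16, cnn_scale = 0.25,
                                 n_transformer_layers = 1, n_heads = 2),
                            list(...))
  do.call(ecg_encoder_config, args)
}

tiny_image_config <- function(input_size = 32, ...) {
  image_encoder_config("small-cnn", input_size = input_size,
                       base_channels = 4, ...)
}

# A small synthetic cohort shared (lazily, once) across test files.
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(
        n_patients = 16, records_per_patient = 2, image_size = 32,
        target_prevalence = 0.3, seed = 421))
    }
    cache
  }
})

# A pass-through image model: positive centre taps on channel 1 everywhere,
# zero biases, head reading channel 1 only. Activations are then a strided
# subsampling of the (nonnegative) input, so relevance is analytically known.
passthrough_image_model <- function(input_size = 32) {
  cfg <- tiny_image_config(input_size = input_size)
  m <- image_model_init(cfg, seed = 1)
  for (i in seq_along(cfg$conv)) {
    sp <- cfg$conv[[i]]
    W <- matrix(0, sp$cin * sp$k * sp$k, sp$cout)
    centre <- (1 - 1) * sp$k * sp$k + (2 - 1) * sp$k + 2  # cin 1, tap (2,2)
    W[centre, 1] <- 1
    m$params$conv[[i]]$W <- W
    m$params$conv[[i]]$b <- rep(0, sp$cout)
  }
  m$params$head$W <- matrix(0, nrow(m$params$head$W), 1)
  m$params$head$W[1, 1] <- 1
  m$params$head$b <- 0
  m
}

# Minimal explicit-VR little-endian DICOM writer for synthetic test
# fixtures (uncompressed grayscale).
write_synthetic_dicom <- function(path, pixels, bits = 8,
                                  photometric = "MONOCHROME2") {
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, x %/% 16777216))
  elem_short <- function(group, el, vr, value) {
    c(u16(group), u16(el), charToRaw(vr), u16(length(value)), value)
  }
  pm <- charToRaw(photometric)
  if (length(pm) %% 2 == 1) pm <- c(pm, charToRaw(" "))
  px <- if (bits <= 8) {
    as.raw(as.vector(t(pixels)))
  } else {
    v <- as.vector(t(pixels))
    as.raw(rbind(v %% 256, v %/% 256))
  }
  body <- c(
    elem_short(0x0028, 0x0004, "CS", pm),
    elem_short(0x0028, 0x0010, "US", u16(nrow(pixels))),
    elem_short(0x0028, 0x0011, "US", u16(ncol(pixels))),
    elem_short(0x0028, 0x0100, "US", u16(bits)),
    elem_short(0x0028, 0x0103, "US", u16(0)),
    c(u16(0x7FE0), u16(0x0010), charToRaw("OB"), as.raw(c(0, 0)),
      u32(length(px)), px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 128)), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}
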