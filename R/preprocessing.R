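# Preprocessing & augmentation ------------------------------------------------

#' Augmentation configuration
#'
#' @param noise_range ECG noise half-range in mV: training noise is i.i.d.
#'   uniform in `[-noise_range, +noise_range]` per sample (default 0.1 mV).
#' @param rotation_limit Image rotation limit in degrees; angles are uniform
#'   in `[-rotation_limit, +rotation_limit]` (default 10).
#' @param autocontrast_prob Probability of applying autocontrast (full-range
#'   intensity stretch) to an image (default 0.25).
#' @param seed Optional integer seed.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(noise_range = 0.1, rotation_limit = 10,
                           autocontrast_prob = 0.25, seed = NULL) {
  assert_that(noise_range >= 0, "noise_range must be nonnegative")
  assert_that(rotation_limit >= 0, "rotation_limit must be nonnegative")
  assert_that(autocontrast_prob >= 0 && autocontrast_prob <= 1,
              "autocontrast_prob must lie in [0, 1]")
  structure(list(noise_range = noise_range, rotation_limit = rotation_limit,
                 autocontrast_prob = autocontrast_prob, seed = seed),
            class = "augment_config")
}

#' Extract a 2-second segment from a 12-lead recording
#'
#' In training mode a contiguous window with a uniformly drawn start offset
#' is cut; in eval mode the deterministic centre window. All 12 leads are cut
#' at the same offset.
#'
#' @param waveform 12 x N numeric matrix at `fs` Hz.
#' @param mode `"train"` (random offset) or `"eval"` (centre crop).
#' @param length_out Segment length in samples (default 1000 = 2 s at 500 Hz).
#' @param seed Optional integer seed (train mode only).
#' @return A 12 x `length_out` matrix (class `ecg_segment`).
#' @export
extract_segment <- function(waveform, mode = c("eval", "train"),
                            length_out = 1000L, seed = NULL) {
  mode <- match.arg(mode)
  assert_that(is.matrix(waveform) && nrow(waveform) == 12,
              "waveform must be a 12-row matrix")
  n <- ncol(waveform)
  if (n < length_out) {
    stop_coop("recording too short: ", n, " samples < ", length_out,
              class = "coopAS_short_recording")
  }
  start <- if (mode == "train") {
    with_seed(seed, sample.int(n - length_out + 1L, 1L))
  } else {
    (n - length_out) %/% 2L + 1L
  }
  seg <- waveform[, start:(start + length_out - 1L), drop = FALSE]
  structure(seg, class = c("ecg_segment", class(seg)))
}

#' Baseline-zero and noise-augment an ECG segment
#'
#' Per lead, the segment mean is subtracted (baseline calibration to 0), then
#' i.i.d. uniform noise in `[-noise_range, +noise_range]` mV is added per
#' sample. With `noise_range = 0` this is pure baseline zeroing and is
#' deterministic.
#'
#' @param segment 12 x L numeric matrix.
#' @param config An [augment_config()].
#' @param seed Optional integer seed.
#' @return Matrix of the same shape.
#' @export
augment_ecg <- function(segment, config = augment_config(), seed = NULL) {
  assert_that(is.matrix(segment) && nrow(segment) == 12,
              "segment must be a 12-row matrix")
  out <- segment - rowMeans(segment)
  if (config$noise_range > 0) {
    out <- out + with_seed(seed, matrix(
      stats::runif(length(out), -config$noise_range, config$noise_range),
      nrow(out), ncol(out)))
  }
  out
}

#' Prepare a raw intensity image for the image branch
#'
#' Min-max scales to \[0, 255\] and quantizes to 8 bit (a constant image maps
#' to all zeros), resizes to `out_size` x `out_size` with bilinear
#' interpolation, and rescales to \[0, 1\] floats.
#'
#' @param raw 2-D numeric matrix of intensities (any bit depth).
#' @param out_size Output side length in pixels (default 224).
#' @return `out_size` x `out_size` numeric matrix in \[0, 1\].
#' @export
prepare_image <- function(raw, out_size = 224L) {
  assert_that(is.matrix(raw) && length(raw) > 0 && is.numeric(raw[1]),
              "raw must be a nonempty 2-D numeric array")
  rng <- range(raw)
  img8 <- if (rng[2] > rng[1]) {
    floor((raw - rng[1]) / (rng[2] - rng[1]) * 255 + 0.5)
  } else {
    matrix(0, nrow(raw), ncol(raw))
  }
  if (nrow(img8) != out_size || ncol(img8) != out_size) {
    img8 <- as_plain_matrix(EBImage::resize(EBImage::Image(img8 / 255),
                                            w = out_size, h = out_size)) * 255
  }
  pmin(pmax(img8 / 255, 0), 1)
}

#' Augment an image tensor for training
#'
#' Rotates by an angle uniform in `[-rotation_limit, +rotation_limit]` about
#' the centre with zero fill, then applies autocontrast (full-range intensity
#' stretch) with probability `autocontrast_prob`. Shape is preserved.
#'
#' @param image 2-D numeric matrix in \[0, 1\].
#' @param config An [augment_config()].
#' @param seed Optional integer seed.
#' @return Matrix of the same shape.
#' @export
augment_image <- function(image, config = augment_config(), seed = NULL) {
  assert_that(is.matrix(image), "image must be a 2-D matrix")
  with_seed(seed, {
    out <- image
    if (config$rotation_limit > 0) {
      ang <- stats::runif(1, -config$rotation_limit, config$rotation_limit)
      out <- .rotate_bilinear(out, ang)  # centre-anchored, zero fill
    }
    if (stats::runif(1) < config$autocontrast_prob) {
      rng <- range(out)
      if (rng[2] > rng[1]) out <- (out - rng[1]) / (rng[2] - rng[1])
    }
    pmin(pmax(out, 0), 1)
  })
}
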