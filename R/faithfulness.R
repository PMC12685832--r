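# Faithfulness ablation -------------------------------------------------------
#
# Perturbation-based evaluation of saliency maps for the image branch:
# deletion replaces the saliency top-p% pixels with a Gaussian-blurred
# version of the image (in the model's normalized [0,1] space); insertion
# starts from the fully blurred image and restores the top-p% pixels.
# Scores along the coverage grid are summarized by the area over the
# perturbation curve (AOPC), with percentile-bootstrap confidence intervals
# over images.

#' Perturbation protocol
#'
#' @param mode `"deletion"` or `"insertion"`.
#' @param coverage_grid Strictly increasing coverage percentages in
#'   (0, 100\]; default `c(18, 30, 40, 50)`.
#' @param blur_sigma Gaussian blur SD in pixels; defaults to image_size / 8
#'   ("heavily blurred") when `NULL`.
#' @param aopc_variant `"score-drop"` (mean drop from the reference score;
#'   standard definition, default) or `"raw-average"` (mean of the raw curve
#'   scores).
#' @return Object of class `perturbation_protocol`.
#' @export
perturbation_protocol <- function(mode = c("deletion", "insertion"),
                                  coverage_grid = c(18, 30, 40, 50),
                                  blur_sigma = NULL,
                                  aopc_variant = c("score-drop",
                                                   "raw-average")) {
  mode <- match.arg(mode)
  aopc_variant <- match.arg(aopc_variant)
  assert_that(all(coverage_grid > 0) && all(coverage_grid <= 100) &&
                all(diff(coverage_grid) > 0),
              "coverage_grid must be strictly increasing within (0, 100]")
  assert_that(is.null(blur_sigma) || blur_sigma > 0,
              "blur_sigma must be positive")
  structure(list(mode = mode, coverage_grid = coverage_grid,
                 blur_sigma = blur_sigma, aopc_variant = aopc_variant),
            class = "perturbation_protocol")
}

#' Top-p% saliency mask
#'
#' Marks exactly `ceiling(p/100 * n_pixels)` pixels with the highest
#' saliency; ties are broken by R's column-major raster order
#' (deterministic), so a constant map selects the first pixels in that
#' order.
#'
#' @param saliency Numeric saliency matrix.
#' @param p Coverage percentage in (0, 100\].
#' @return Logical mask of the same shape.
#' @export
topk_mask <- function(saliency, p) {
  assert_that(is.matrix(saliency) && length(saliency) > 0,
              "saliency must be a nonempty matrix")
  assert_that(p > 0 && p <= 100, "p must lie in (0, 100]")
  k <- ceiling(p / 100 * length(saliency))
  ord <- order(-as.vector(saliency), seq_along(saliency))
  mask <- matrix(FALSE, nrow(saliency), ncol(saliency))
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Gaussian blur of an image matrix
#'
#' @param image 2-D numeric matrix.
#' @param sigma Blur SD in pixels; defaults to `nrow(image) / 8`.
#' @return Blurred matrix of the same shape.
#' @export
blur_image <- function(image, sigma = NULL) {
  if (is.null(sigma)) sigma <- nrow(image) / 8
  as_plain_matrix(EBImage::gblur(image, sigma = sigma))
}

#' Perturb an image under a pixel mask
#'
#' Deletion replaces masked pixels with the Gaussian-blurred image's values;
#' insertion starts from the fully blurred image and restores the original
#' values at masked pixels. Both operate in the model's normalized \[0, 1\]
#' space, so insertion at full coverage reproduces the original image
#' bit-exactly.
#'
#' @param image 2-D numeric matrix (normalized space).
#' @param mask Logical matrix of the same shape.
#' @param mode `"deletion"` or `"insertion"`.
#' @param blur_sigma Blur SD in pixels (default `nrow(image) / 8`).
#' @param blurred Optional precomputed blurred image (avoids recomputation
#'   along a curve).
#' @return Perturbed image matrix.
#' @export
perturb <- function(image, mask, mode = c("deletion", "insertion"),
                    blur_sigma = NULL, blurred = NULL) {
  mode <- match.arg(mode)
  assert_that(is.matrix(image) && is.logical(mask) &&
                all(dim(image) == dim(mask)),
              "mask shape must match the image")
  if (is.null(blurred)) blurred <- blur_image(image, blur_sigma)
  if (mode == "deletion") {
    out <- image
    out[mask] <- blurred[mask]
  } else {
    out <- blurred
    out[mask] <- image[mask]
  }
  out
}

#' Baseline saliency maps
#'
#' `"random"` draws i.i.d. uniform values, so its top-p% is an area-matched
#' random pixel set; `"uniform"` is a constant map whose top-p% falls to the
#' deterministic raster-order tie rule.
#'
#' @param kind `"random"` or `"uniform"`.
#' @param shape Length-2 integer vector (rows, cols).
#' @param seed Optional integer seed.
#' @return Saliency matrix.
#' @export
baseline_saliency <- function(kind = c("random", "uniform"), shape,
                              seed = NULL) {
  kind <- match.arg(kind)
  assert_that(length(shape) == 2 && all(shape >= 1),
              "shape must be two positive integers")
  if (kind == "uniform") return(matrix(1, shape[1], shape[2]))
  with_seed(seed, matrix(stats::runif(prod(shape)), shape[1], shape[2]))
}

as_score_fn <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "coop_fit")) model <- model$image_model
  assert_that(inherits(model, "coop_image_model"),
              "model must be a scoring function, coop_image_model or coop_fit")
  function(img) image_forward(model, img)$score
}

#' Perturbation curve over the coverage grid
#'
#' Evaluates the positive-class score at each grid coverage, perturbing
#' cumulatively from a single fixed reference (the masks are nested along
#' the grid because they share one saliency ordering).
#'
#' @param model Scoring `function(image) -> scalar`, a `coop_image_model`,
#'   or a `coop_fit` with an image branch.
#' @param image Prepared image matrix in normalized \[0, 1\] space.
#' @param saliency Saliency matrix aligned to the image.
#' @param protocol A [perturbation_protocol()].
#' @return Data frame (class `perturbation_curve`) with columns `coverage`
#'   and `score`; attributes `reference` (unperturbed score),
#'   `blurred_reference` (fully blurred score) and `mode`.
#' @export
perturbation_curve <- function(model, image, saliency,
                               protocol = perturbation_protocol()) {
  assert_that(inherits(protocol, "perturbation_protocol"),
              "protocol must be a perturbation_protocol()")
  assert_that(all(dim(image) == dim(saliency)),
              "saliency shape must match the image")
  score_fn <- as_score_fn(model)
  blurred <- blur_image(image, protocol$blur_sigma)
  scores <- vapply(protocol$coverage_grid, function(p) {
    m <- topk_mask(saliency, p)
    score_fn(perturb(image, m, protocol$mode, blurred = blurred))
  }, numeric(1))
  structure(data.frame(coverage = protocol$coverage_grid, score = scores),
            class = c("perturbation_curve", "data.frame"),
            reference = score_fn(image),
            blurred_reference = score_fn(blurred),
            mode = protocol$mode)
}

#' Area over the perturbation curve
#'
#' `"score-drop"` variant (standard): for deletion, the mean over the grid
#' of (reference - score_p); for insertion, the mean of
#' (score_p - blurred reference). `"raw-average"` variant: the plain mean of
#' the curve scores.
#'
#' @param curve A [perturbation_curve()] (or data frame with a `score`
#'   column).
#' @param reference Reference score; taken from the curve's attribute when
#'   missing.
#' @param variant `"score-drop"` or `"raw-average"`.
#' @param mode Perturbation mode; taken from the curve's attribute when
#'   missing.
#' @return Scalar AOPC.
#' @export
aopc <- function(curve, reference = NULL,
                 variant = c("score-drop", "raw-average"), mode = NULL) {
  variant <- match.arg(variant)
  assert_that(nrow(curve) > 0, "curve must be nonempty")
  if (variant == "raw-average") return(mean(curve$score))
  mode <- mode %||% attr(curve, "mode") %||% "deletion"
  if (is.null(reference)) {
    reference <- if (mode == "deletion") attr(curve, "reference") else
      attr(curve, "blurred_reference")
  }
  assert_that(!is.null(reference),
              "a reference score is required for the score-drop variant")
  if (mode == "deletion") mean(reference - curve$score) else
    mean(curve$score - reference)
}

#' Bootstrap confidence interval for per-image AOPC values
#'
#' Percentile bootstrap over images: resample with replacement, take the
#' mean per replicate, report the 2.5/97.5 percentiles.
#'
#' @param values Per-image AOPC values (length >= 2).
#' @param n Bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Object of class `aopc_result`: `point_estimate` (sample mean),
#'   `ci_low`, `ci_high`, `se` (bootstrap SD of the mean), `n_bootstrap`.
#' @export
bootstrap_aopc <- function(values, n = 1000L, conf = 0.95, seed = NULL) {
  assert_that(length(values) >= 2, "need at least 2 per-image values")
  reps <- with_seed(seed, vapply(seq_len(n), function(i) {
    mean(sample(values, replace = TRUE))
  }, numeric(1)))
  qs <- stats::quantile(reps, c((1 - conf) / 2, (1 + conf) / 2),
                        names = FALSE, type = 7)
  structure(list(point_estimate = mean(values),
                 ci_low = qs[1], ci_high = qs[2],
                 se = stats::sd(reps), n_bootstrap = n),
            class = "aopc_result")
}

#' @export
print.aopc_result <- function(x, ...) {
  cat(sprintf("AOPC %.4f (95%% CI %.4f-%.4f; %d bootstrap replicates)\n",
              x$point_estimate, x$ci_low, x$ci_high, x$n_bootstrap))
  invisible(x)
}
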