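# Interpretability ------------------------------------------------------------
#
# Two-phase decision-basis visualization for the ECG branch: Phase 1 reads
# the Transformer's class-token attention to find which leads the model
# focuses on; Phase 2 runs 1-D Grad-CAM on the shared convolutional tower
# per lead; their product is the final lead-by-time heatmap. The image
# branch uses standard 2-D Grad-CAM. All relevance targets the positive-class
# pre-sigmoid score.

resolve_branch <- function(model, branch) {
  if (inherits(model, "coop_fit")) {
    m <- if (branch == "ecg") model$ecg_model else model$image_model
    assert_that(!is.null(m), "fit has no ", branch, " branch")
    return(m)
  }
  model
}

#' Phase 1: lead attention of the Transformer
#'
#' Extracts the attention paid by the class-token query to the 12 lead
#' tokens, averaged over heads (last layer by default, or averaged over all
#' layers), renormalized to a probability vector over leads.
#'
#' @param model A `coop_ecg_model` or a `coop_fit` containing one.
#' @param segment 12 x L ECG segment (mV).
#' @param layers `"last"` or `"mean"` (average over all encoder layers).
#' @return Named numeric vector of 12 nonnegative weights summing to 1
#'   (class `lead_attention`).
#' @export
lead_attention <- function(model, segment, layers = c("last", "mean")) {
  layers <- match.arg(layers)
  model <- resolve_branch(model, "ecg")
  assert_that(inherits(model, "coop_ecg_model"),
              "model must be a coop_ecg_model")
  fw <- ecg_forward(model, segment)
  att <- fw$aux$attention
  assert_that(length(att) > 0, "model exposes no attention tensors")
  take <- if (layers == "last") att[length(att)] else att
  w <- Reduce(`+`, lapply(take, function(a) {
    # a: heads x tokens x tokens; class-token query row, lead keys
    colMeans(matrix(a[, 1, -1], dim(a)[1], dim(a)[3] - 1L))
  })) / length(take)
  w <- w / sum(w)
  names(w) <- ecg_lead_names()[seq_along(w)]
  structure(w, class = c("lead_attention", "numeric"))
}

#' Phase 2: 1-D Grad-CAM per lead
#'
#' Per lead, channel weights are the time-averaged gradients of the
#' positive-class score with respect to the final convolutional activations;
#' the relevance trace is the rectified weighted channel sum, linearly
#' upsampled to the segment length. An everywhere-zero gradient yields an
#' all-zero map with a warning.
#'
#' @inheritParams lead_attention
#' @param length_out Output trace length per lead (default `ncol(segment)`).
#' @return 12 x `length_out` nonnegative matrix, rows named by lead.
#' @export
gradcam_1d <- function(model, segment, length_out = ncol(segment)) {
  model <- resolve_branch(model, "ecg")
  assert_that(inherits(model, "coop_ecg_model"),
              "model must be a coop_ecg_model")
  segs <- array(0, c(1L, nrow(segment), ncol(segment)))
  segs[1, , ] <- segment
  fw <- ecg_forward_batch(model, segs)
  bk <- ecg_backward_batch(model, fw, dscore = 1)
  A <- fw$conv_act       # [12, C, Lf] (leads are the batch dimension)
  G <- bk$dconv_act
  if (all(G == 0)) {
    warning("all Grad-CAM gradients are zero; returning an all-zero map")
  }
  n_leads <- dim(A)[1]
  out <- matrix(0, n_leads, length_out)
  for (l in seq_len(n_leads)) {
    Al <- matrix(A[l, , ], dim(A)[2], dim(A)[3])
    Gl <- matrix(G[l, , ], dim(G)[2], dim(G)[3])
    wts <- rowMeans(Gl)
    cam <- pmax(colSums(Al * wts), 0)
    out[l, ] <- upsample_linear(cam, length_out)
  }
  rownames(out) <- ecg_lead_names()[seq_len(n_leads)]
  out
}

#' Attention-weighted ECG heatmap
#'
#' Row i of the final heatmap is the Phase-1 attention weight of lead i
#' times its raw Phase-2 Grad-CAM trace. Display normalization (global max
#' to 1) is optional and separate from the raw map.
#'
#' @param attention A [lead_attention()] vector.
#' @param traces Matrix of per-lead relevance traces ([gradcam_1d()]).
#' @param normalize Scale the result so its maximum is 1 (display only).
#' @return Matrix of the same shape as `traces`.
#' @export
weighted_ecg_heatmap <- function(attention, traces, normalize = FALSE) {
  assert_that(length(attention) == nrow(traces),
              "attention length must match the number of trace rows")
  out <- as.numeric(attention) * traces
  if (normalize && max(out) > 0) out <- out / max(out)
  out
}

#' Export a relevance map as NPY or PNG overlay
#'
#' PNG export rescales the map to \[0, 1\] and, when a base image is given,
#' blends it as a red overlay on the grayscale image; NPY export writes the
#' raw values.
#'
#' @param map Relevance matrix (e.g. from [gradcam_2d()] or
#'   [weighted_ecg_heatmap()]).
#' @param path Output path ending in `.png` or `.npy`.
#' @param image Optional base image in \[0, 1\] of the same shape (PNG only).
#' @param alpha Overlay opacity in \[0, 1\] (PNG only).
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(map, path, image = NULL, alpha = 0.5) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "npy") {
    npy_write(map, path)
  } else if (ext == "png") {
    m <- if (max(map) > 0) map / max(map) else map
    if (is.null(image)) {
      png::writePNG(pmin(pmax(m, 0), 1), path)
    } else {
      assert_that(all(dim(image) == dim(map)),
                  "base image shape must match the map")
      rgb <- array(0, c(nrow(m), ncol(m), 3))
      base <- pmin(pmax(image, 0), 1)
      rgb[, , 1] <- pmin(base * (1 - alpha * m) + alpha * m, 1)
      rgb[, , 2] <- base * (1 - alpha * m)
      rgb[, , 3] <- base * (1 - alpha * m)
      png::writePNG(rgb, path)
    }
  } else {
    stop_coop("unsupported heatmap format: .", ext,
              class = "coopAS_format_error")
  }
  invisible(path)
}

#' 2-D Grad-CAM for the image branch
#'
#' Standard Grad-CAM: channel weights are spatially averaged gradients of
#' the positive-class score with respect to the final convolutional feature
#' maps; the map is the rectified weighted channel sum, bilinearly upsampled
#' to the input resolution.
#'
#' @param model A `coop_image_model` or a `coop_fit` containing one.
#' @param image Prepared 2-D image matrix in \[0, 1\].
#' @return Nonnegative relevance matrix aligned to the input image.
#' @export
gradcam_2d <- function(model, image) {
  model <- resolve_branch(model, "image")
  assert_that(inherits(model, "coop_image_model"),
              "model must be a coop_image_model")
  imgs <- array(0, c(1L, 1L, nrow(image), ncol(image)))
  imgs[1, 1, , ] <- image
  fw <- image_forward_batch(model, imgs)
  bk <- image_backward_batch(model, fw, dscore = 1)
  A <- fw$conv_act  # [1, C, Hf, Wf]
  G <- bk$dconv_act
  if (all(G == 0)) {
    warning("all Grad-CAM gradients are zero; returning an all-zero map")
  }
  C <- dim(A)[2]; Hf <- dim(A)[3]; Wf <- dim(A)[4]
  wts <- vapply(seq_len(C), function(c) mean(G[1, c, , ]), numeric(1))
  cam <- matrix(0, Hf, Wf)
  for (c in seq_len(C)) cam <- cam + wts[c] * matrix(A[1, c, , ], Hf, Wf)
  cam <- pmax(cam, 0)
  if (Hf == nrow(image) && Wf == ncol(image)) return(cam)
  out <- as_plain_matrix(EBImage::resize(EBImage::Image(cam),
                                         w = nrow(image), h = ncol(image)))
  pmax(out, 0)
}
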