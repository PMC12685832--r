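# Cooperative objective -------------------------------------------------------
#
# Two branches emit scalar pre-sigmoid scores f_ecg and f_cxr per sample. The
# cooperative objective is the mean over samples of
#
#     1/2 * (y - (f_ecg + f_cxr))^2  +  rho/2 * (f_ecg - f_cxr)^2 ,
#
# a squared-error prediction term on the summed score plus a rho-weighted
# agreement penalty on the score difference. rho = 0 reduces to early fusion
# (joint fitting of the sum); large rho forces the two marginal predictions
# to align, approaching late fusion in the additive/linear setting.

check_score_pairs <- function(y, f_ecg, f_cxr, rho) {
  assert_that(is.numeric(rho) && length(rho) == 1L && is.finite(rho) &&
                rho >= 0, "rho must be a nonnegative scalar")
  assert_that(length(y) > 0, "batch must be nonempty")
  assert_that(length(y) == length(f_ecg) && length(y) == length(f_cxr),
              "y, f_ecg and f_cxr must have equal length")
  assert_that(all(y %in% c(0, 1)), "labels must be 0/1")
  assert_that(all(is.finite(f_ecg)) && all(is.finite(f_cxr)),
              "branch scores must be finite")
}

#' Cooperative loss
#'
#' Mean over the batch of
#' `1/2 (y - (f_ecg + f_cxr))^2 + rho/2 (f_ecg - f_cxr)^2`.
#'
#' @param y Binary labels (0/1 vector).
#' @param f_ecg,f_cxr Scalar branch scores (pre-sigmoid), same length as `y`.
#' @param rho Nonnegative agreement-penalty weight.
#' @return Scalar loss.
#' @export
cooperative_loss <- function(y, f_ecg, f_cxr, rho) {
  check_score_pairs(y, f_ecg, f_cxr, rho)
  mean(0.5 * (y - (f_ecg + f_cxr))^2 + 0.5 * rho * (f_ecg - f_cxr)^2)
}

#' Per-sample gradients of the cooperative loss
#'
#' For one sample,
#' `g_ecg = -[y - (f_ecg + f_cxr)] + rho (f_ecg - f_cxr)` and
#' `g_cxr = -[y - (f_ecg + f_cxr)] + rho (f_cxr - f_ecg)`:
#' the prediction term pulls the sum toward `y`, the agreement term pulls
#' the difference toward 0.
#'
#' @inheritParams cooperative_loss
#' @return List with vectors `g_ecg` and `g_cxr` (gradients of the
#'   per-sample loss with respect to each branch score).
#' @export
loss_gradients <- function(y, f_ecg, f_cxr, rho) {
  check_score_pairs(y, f_ecg, f_cxr, rho)
  resid <- y - (f_ecg + f_cxr)
  diff <- f_ecg - f_cxr
  list(g_ecg = -resid + rho * diff,
       g_cxr = -resid - rho * diff)
}

#' Fused score of the additive two-branch model
#'
#' The canonical fused output is the raw sum `f_ecg + f_cxr`; the probability
#' view applies the sigmoid to the sum. The two are rank-equivalent, so AUROC
#' is identical either way.
#'
#' @param f_ecg,f_cxr Branch scores.
#' @param type `"score"` (raw sum) or `"prob"` (sigmoid of the sum).
#' @return Numeric vector.
#' @export
fused_score <- function(f_ecg, f_cxr, type = c("score", "prob")) {
  type <- match.arg(type)
  assert_that(all(is.finite(f_ecg)) && all(is.finite(f_cxr)),
              "branch scores must be finite")
  s <- f_ecg + f_cxr
  if (type == "prob") sigmoid(s) else s
}

#' Closed-form cooperative solution for linear branches
#'
#' With linear branches `f_ecg = X_ecg beta_e`, `f_cxr = X_cxr beta_c`, the
#' stationarity conditions of the cooperative objective form one linear
#' system:
#' \deqn{X_e'((1+\rho) X_e \beta_e + (1-\rho) X_c \beta_c) = X_e' y}
#' \deqn{X_c'((1-\rho) X_e \beta_e + (1+\rho) X_c \beta_c) = X_c' y}
#' solved exactly here. At `rho = 0` this is ordinary least squares on the
#' column-concatenated design; as `rho` grows the two marginal predictions
#' are forced together. Serves as the verification oracle for the
#' gradient-trained linear model.
#'
#' @param X_ecg n x p design for the first branch.
#' @param X_cxr n x q design for the second branch.
#' @param y Response vector of length n.
#' @param rho Nonnegative agreement weight.
#' @return List with `beta_ecg` and `beta_cxr`.
#' @export
linear_closed_form <- function(X_ecg, X_cxr, y, rho) {
  assert_that(is.matrix(X_ecg) && is.matrix(X_cxr),
              "designs must be matrices")
  assert_that(nrow(X_ecg) == nrow(X_cxr) && nrow(X_ecg) == length(y),
              "designs and response must have matching rows")
  assert_that(rho >= 0, "rho must be nonnegative")
  p <- ncol(X_ecg); q <- ncol(X_cxr)
  A <- rbind(
    cbind((1 + rho) * crossprod(X_ecg), (1 - rho) * crossprod(X_ecg, X_cxr)),
    cbind((1 - rho) * crossprod(X_cxr, X_ecg), (1 + rho) * crossprod(X_cxr))
  )
  b <- c(crossprod(X_ecg, y), crossprod(X_cxr, y))
  beta <- tryCatch(solve(A, b), error = function(e) {
    stop_coop("cooperative stationarity system is singular ",
              "(rank-deficient designs): ", conditionMessage(e),
              class = "coopAS_rank_error")
  })
  list(beta_ecg = beta[seq_len(p)], beta_cxr = beta[p + seq_len(q)])
}

#' Fit the linear cooperative model by full-batch gradient descent
#'
#' Minimizes the cooperative objective over linear branch coefficients by
#' plain gradient descent with a step size of `1/L`, `L` being the largest
#' Hessian eigenvalue (guaranteeing monotone convergence on this quadratic).
#' Exists to demonstrate that gradient training recovers the closed-form
#' solution, e.g. the concatenated-OLS coefficients at `rho = 0`.
#'
#' @inheritParams linear_closed_form
#' @param max_iter Iteration cap.
#' @param tol Stop when the gradient max-norm falls below this.
#' @param lr Step size; computed from the Hessian spectrum when `NULL`.
#' @return List with `beta_ecg`, `beta_cxr`, `n_iter`, `converged`.
#' @export
train_cooperative_linear <- function(X_ecg, X_cxr, y, rho = 0,
                                     max_iter = 50000L, tol = 1e-9,
                                     lr = NULL) {
  assert_that(rho >= 0, "rho must be nonnegative")
  n <- length(y)
  p <- ncol(X_ecg); q <- ncol(X_cxr)
  H <- rbind(
    cbind((1 + rho) * crossprod(X_ecg), (1 - rho) * crossprod(X_ecg, X_cxr)),
    cbind((1 - rho) * crossprod(X_cxr, X_ecg), (1 + rho) * crossprod(X_cxr))
  ) / n
  if (is.null(lr)) {
    L <- max(eigen(0.5 * (H + t(H)), symmetric = TRUE,
                   only.values = TRUE)$values)
    lr <- 1 / L
  }
  beta <- rep(0, p + q)
  g0 <- c(crossprod(X_ecg, y), crossprod(X_cxr, y)) / n
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    grad <- as.vector(H %*% beta) - g0
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    beta <- beta - lr * grad
  }
  list(beta_ecg = beta[seq_len(p)], beta_cxr = beta[p + seq_len(q)],
       n_iter = it, converged = converged)
}
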