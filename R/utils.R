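#' @keywords internal
#' @useDynLib coopAS, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Internal validation helpers ------------------------------------------------

stop_coop <- function(..., class) {
  stop(structure(
    class = c(class, "coopAS_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, ..., class = "coopAS_invalid_input") {
  if (!isTRUE(ok)) stop_coop(..., class = class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x < 1
}

#' Run code under a temporary RNG seed
#'
#' Sets the seed if one is given, restoring the caller's RNG state afterwards,
#' so seeded calls never disturb the global random stream. With `seed = NULL`
#' the expression consumes the ambient stream as usual.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a base seed, staying inside the
# 32-bit signed integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# strip EBImage's Image class back to a plain base matrix
as_plain_matrix <- function(x) {
  m <- EBImage::imageData(x)
  matrix(as.numeric(m), nrow(m), ncol(m))
}

# Linear interpolation of a vector onto n points covering the same support.
upsample_linear <- function(v, n) {
  if (length(v) == n) return(v)
  if (length(v) == 1L) return(rep(v, n))
  stats::approx(x = seq(0, 1, length.out = length(v)), y = v,
                xout = seq(0, 1, length.out = n))$y
}
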