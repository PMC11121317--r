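# User-facing layer primitives. Internally activations are (H*W) x C matrices
# (column-major spatial order); these wrappers accept and return H x W x C
# arrays, which is the natural shape for inspection and testing.

.as_actmat <- function(x) {
  stopifnot(length(dim(x)) == 3)
  d <- dim(x)
  matrix(x, nrow = d[1] * d[2], ncol = d[3])
}

.as_actarr <- function(m, H, W) array(m, dim = c(H, W, ncol(m)))

#' Leaky rectified linear unit
#'
#' `x` for positive inputs, `0.1 x` otherwise.
#' @param x Numeric vector/array.
#' @return Same shape as `x`.
#' @export
lrelu <- function(x) pmax(x, 0) + 0.1 * pmin(x, 0)

.lrelu_grad <- function(z) 0.1 + 0.9 * (z > 0)

#' 2D convolution with zero padding
#'
#' Computes \eqn{c_{ij} = \sum_{t=-k}^{k}\sum_{s=-k}^{k} F_{ts} \cdot
#' x_{i+t,j+s}} for every kernel, with zero padding of width `k` so the
#' spatial shape is preserved.
#'
#' @param x `H x W x C_in` numeric array.
#' @param kernels `(2k+1) x (2k+1) x C_in x C_out` numeric array; the first
#'   index is the row offset `t`, the second the column offset `s`.
#' @param bias Numeric vector of length `C_out` (default zeros).
#' @return `H x W x C_out` array.
#' @export
conv2d <- function(x, kernels, bias = NULL) {
  d <- dim(x); kd <- dim(kernels)
  stopifnot(length(d) == 3, length(kd) == 4, kd[1] == kd[2], kd[1] %% 2 == 1)
  if (kd[3] != d[3]) abort("kernel input channels do not match input tensor")
  if (is.null(bias)) bias <- numeric(kd[4])
  stopifnot(length(bias) == kd[4])
  k <- (kd[1] - 1) / 2
  Y <- cpp_conv_fwd(.as_actmat(x), d[1], d[2], k,
                    .kernels_to_mat(kernels), bias)
  .as_actarr(Y, d[1], d[2])
}

# ((2k+1)^2 * C_in) x C_out layout: channel fastest, then row offset t,
# then column offset s (must match the C++ im2col order)
.kernels_to_mat <- function(kernels) {
  kd <- dim(kernels)
  m <- aperm(kernels, c(3, 1, 2, 4))
  dim(m) <- c(kd[1] * kd[2] * kd[3], kd[4])
  m
}

.mat_to_kernels <- function(m, K, Cin) {
  Cout <- ncol(m)
  arr <- array(m, dim = c(Cin, K, K, Cout))
  aperm(arr, c(2, 3, 1, 4))
}

#' Pooling with a square window
#'
#' Max or average pooling over non-overlapping `s x s` windows. Max mode also
#' returns the within-window argmax positions needed by [unpool_max()].
#'
#' @param x `H x W x C` array with `H`, `W` divisible by `s`.
#' @param s Window size.
#' @param mode `"max"` or `"avg"`.
#' @return List with `out` (`H/s x W/s x C` array) and, in max mode, `idx`
#'   (same shape, 1-based linear indices into the `H x W` plane).
#' @export
pool <- function(x, s = 4, mode = c("max", "avg")) {
  mode <- match.arg(mode)
  d <- dim(x)
  stopifnot(length(d) == 3)
  if (d[1] %% s != 0 || d[2] %% s != 0) {
    abort("pooling requires spatial dimensions divisible by the window size")
  }
  m <- .as_actmat(x)
  if (mode == "max") {
    r <- cpp_pool_max(m, d[1], d[2], s)
    list(out = .as_actarr(r$P, d[1] / s, d[2] / s),
         idx = array(r$idx, dim = c(d[1] / s, d[2] / s, d[3])))
  } else {
    list(out = .as_actarr(cpp_pool_avg(m, d[1], d[2], s), d[1] / s, d[2] / s))
  }
}

#' Max unpooling
#'
#' Places each pooled value back at its recorded argmax position; all other
#' cells are zero. Exact adjoint of max pooling on the cached indices.
#'
#' @param p `Hp x Wp x C` array of pooled values.
#' @param idx Argmax indices as returned by [pool()] in max mode.
#' @param H,W Target spatial dimensions.
#' @return `H x W x C` array.
#' @export
unpool_max <- function(p, idx, H, W) {
  d <- dim(p)
  m <- cpp_unpool_max(.as_actmat(p), matrix(idx, nrow = d[1] * d[2]), H, W)
  .as_actarr(m, H, W)
}

#' Average unpooling
#'
#' Spreads each pooled value uniformly over its `s x s` window
#' (`value / s^2` per cell), so the total mass of the input is conserved.
#'
#' @param p `Hp x Wp x C` array of pooled values.
#' @param s Window size used when pooling.
#' @return `(Hp*s) x (Wp*s) x C` array.
#' @export
unpool_avg <- function(p, s = 4) {
  d <- dim(p)
  m <- cpp_unpool_avg(.as_actmat(p), d[1] * s, d[2] * s, s)
  .as_actarr(m, d[1] * s, d[2] * s)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binary cross-entropy loss
#'
#' \eqn{J = -\frac{1}{m}\sum_l [y_l \ln \hat y_l + (1-y_l)\ln(1-\hat y_l)]},
#' with scores clipped to `(eps, 1-eps)` for numerical safety.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels of the same length.
#' @param eps Clipping constant.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(scores, labels, eps = 1e-7) {
  if (length(scores) != length(labels)) {
    abort("scores and labels differ in length")
  }
  p <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
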