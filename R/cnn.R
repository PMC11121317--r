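# The pair-image classifier: two stacked ResNet blocks (3x3 convolutions,
# LReLU, skip connections; the first skip is a 1x1 projection from the
# 6-channel input to 32 feature channels), followed by parallel max- and
# average-pooling (window s), channelwise concatenation, flatten, dropout and
# a sigmoid dense head. Trained with Adam on binary cross-entropy, plateau LR
# decay and early stopping; 10-fold cross-validation yields a mean ensemble.

#' Training configuration
#'
#' @param channels Feature channels per convolutional layer.
#' @param k Kernel half-width (kernel size `2k+1`).
#' @param s Pooling window.
#' @param dropout Dropout rate on the flattened feature vector (train mode).
#' @param lr Initial Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param early_patience Epochs without validation improvement before stopping.
#' @param plateau_patience Epochs without improvement before the learning rate
#'   is multiplied by `plateau_factor`.
#' @param plateau_factor Learning-rate decay factor.
#' @param min_lr Floor for the learning rate.
#' @param eps Score clipping for the loss.
#' @return A list of class `epipair_config`.
#' @export
net_config <- function(channels = 32L, k = 1L, s = 4L, dropout = 0.75,
                       lr = 1e-3, batch_size = 32L, max_epochs = 200L,
                       early_patience = 10L, plateau_patience = 5L,
                       plateau_factor = 0.1, min_lr = 1e-6, eps = 1e-7) {
  structure(as.list(environment()), class = "epipair_config")
}

#' Stack a sample pair into a six-channel tensor
#'
#' Concatenates the paratope image (channels 1-3) and the epitope image
#' (channels 4-6) along the colour dimension.
#'
#' @param pair A `sample_pair` (see [make_positive()]) or a list with
#'   `paratope` and `epitope` patch images of identical size.
#' @return `H x W x 6` numeric array with values in \[0, 1\].
#' @export
pair_tensor <- function(pair) {
  p <- unclass(pair$paratope); e <- unclass(pair$epitope)
  stopifnot(identical(dim(p), dim(e)))
  arr <- array(0, dim = c(dim(p)[1], dim(p)[2], 6))
  arr[, , 1:3] <- p
  arr[, , 4:6] <- e
  arr
}

# ---- parameter initialisation -----------------------------------------------

# Kaiming normal for LReLU(0.1): sd = sqrt(2 / ((1 + a^2) * fan_in))
.kaiming_mat <- function(fan_in, n_out, a = 0.1) {
  matrix(rnorm(fan_in * n_out, sd = sqrt(2 / ((1 + a^2) * fan_in))),
         fan_in, n_out)
}

# Xavier normal: sd = sqrt(2 / (fan_in + fan_out))
.xavier_vec <- function(fan_in, fan_out = 1) {
  rnorm(fan_in, sd = sqrt(2 / (fan_in + fan_out)))
}

#' Initialise fold parameters
#'
#' Kaiming-normal initialisation for the convolutional layers (suited to the
#' LReLU activation), Xavier-normal for the dense head; biases start at zero.
#'
#' @param size Image side length (divisible by the pooling window).
#' @param config A [net_config()].
#' @return A list of class `epipair_fold` holding the layer parameters.
#' @export
init_params <- function(size, config = net_config()) {
  C <- config$channels; K <- 2 * config$k + 1
  nf <- 2L * (size %/% config$s)^2 * C
  params <- list(
    conv1a = list(W = .kaiming_mat(K * K * 6, C), b = numeric(C)),
    proj   = list(W = .kaiming_mat(6, C), b = numeric(C)),
    conv1b = list(W = .kaiming_mat(K * K * C, C), b = numeric(C)),
    conv2a = list(W = .kaiming_mat(K * K * C, C), b = numeric(C)),
    conv2b = list(W = .kaiming_mat(K * K * C, C), b = numeric(C)),
    dense  = list(w = .xavier_vec(nf), b = 0),
    size = as.integer(size), config = config
  )
  structure(params, class = "epipair_fold")
}

# ---- forward / backward (matrix form) ---------------------------------------

#' Forward pass of the pair classifier
#'
#' @param x `H x W x 6` pair tensor (see [pair_tensor()]).
#' @param params An `epipair_fold`.
#' @param train Logical; in train mode inverted dropout is applied to the
#'   flattened feature vector.
#' @return List with `score` in (0, 1) and `cache` (activations, pooling
#'   argmax indices, the flattened vector `f`, dropout mask and logit) as
#'   needed for backpropagation and attribution.
#' @export
nn_forward <- function(x, params, train = FALSE) {
  d <- dim(x)
  if (length(d) != 3 || d[1] != params$size || d[2] != params$size ||
      d[3] != 6) {
    abort(sprintf("expected a %d x %d x 6 input tensor", params$size,
                  params$size))
  }
  .nn_forward_mat(matrix(x, nrow = d[1] * d[2], ncol = 6), params, train)
}

.nn_forward_mat <- function(xm, params, train = FALSE) {
  H <- params$size; W <- params$size
  k <- params$config$k; s <- params$config$s
  cfg <- params$config
  conv_f <- cpp_conv_fwd

  c1 <- conv_f(xm, H, W, k, params$conv1a$W, params$conv1a$b)
  a1 <- cpp_lrelu(c1)
  c2 <- conv_f(a1, H, W, k, params$conv1b$W, params$conv1b$b)
  skip <- xm %*% params$proj$W
  skip <- sweep(skip, 2, params$proj$b, "+")
  z1 <- c2 + skip
  a2 <- cpp_lrelu(z1)

  c3 <- conv_f(a2, H, W, k, params$conv2a$W, params$conv2a$b)
  a3 <- cpp_lrelu(c3)
  c4 <- conv_f(a3, H, W, k, params$conv2b$W, params$conv2b$b)
  z2 <- c4 + a2
  a4 <- cpp_lrelu(z2)

  pm <- cpp_pool_max(a4, H, W, s)
  pa <- cpp_pool_avg(a4, H, W, s)
  f <- c(pm$P, pa)

  if (train && cfg$dropout > 0) {
    mask <- (runif(length(f)) >= cfg$dropout) / (1 - cfg$dropout)
  } else {
    mask <- NULL
  }
  fu <- if (is.null(mask)) f else f * mask
  logit <- sum(params$dense$w * fu) + params$dense$b
  list(
    score = .sigmoid(logit),
    cache = list(xm = xm, c1 = c1, a1 = a1, z1 = z1, a2 = a2, c3 = c3,
                 a3 = a3, z2 = z2, a4 = a4, Pmax = pm$P, idx = pm$idx,
                 Pavg = pa, f = f, mask = mask, logit = logit)
  )
}

# gradient of the loss w.r.t. all parameters for one sample, given
# dJ/dlogit (= score - label for BCE)
.nn_backward_mat <- function(cache, params, dlogit) {
  H <- params$size; W <- params$size
  k <- params$config$k; s <- params$config$s
  C <- params$config$channels
  np <- (H %/% s) * (W %/% s)
  conv_b <- cpp_conv_bwd

  fu <- if (is.null(cache$mask)) cache$f else cache$f * cache$mask
  dw <- dlogit * fu
  dbd <- dlogit
  df <- dlogit * params$dense$w
  if (!is.null(cache$mask)) df <- df * cache$mask

  dPmax <- matrix(df[seq_len(np * C)], np, C)
  dPavg <- matrix(df[np * C + seq_len(np * C)], np, C)
  da4 <- cpp_unpool_max(dPmax, cache$idx, H, W) +
    cpp_unpool_avg(dPavg, H, W, s)

  dz2 <- cpp_lrelu_bwd(cache$z2, da4)
  g2b <- conv_b(cache$a3, dz2, H, W, k, params$conv2b$W, TRUE)
  dc3 <- cpp_lrelu_bwd(cache$c3, g2b$dX)
  g2a <- conv_b(cache$a2, dc3, H, W, k, params$conv2a$W, TRUE)
  da2 <- g2a$dX + dz2

  dz1 <- cpp_lrelu_bwd(cache$z1, da2)
  g1b <- conv_b(cache$a1, dz1, H, W, k, params$conv1b$W, TRUE)
  dWp <- crossprod(cache$xm, dz1)
  dbp <- colSums(dz1)
  dc1 <- cpp_lrelu_bwd(cache$c1, g1b$dX)
  g1a <- conv_b(cache$xm, dc1, H, W, k, params$conv1a$W, FALSE)

  list(conv1a = list(W = g1a$dW, b = g1a$db),
       proj   = list(W = dWp, b = dbp),
       conv1b = list(W = g1b$dW, b = g1b$db),
       conv2a = list(W = g2a$dW, b = g2a$db),
       conv2b = list(W = g2b$dW, b = g2b$db),
       dense  = list(w = dw, b = dbd))
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  lapply(params[c("conv1a", "proj", "conv1b", "conv2a", "conv2b", "dense")],
         function(layer) list(m = zero_like(layer), v = zero_like(layer)))
}

.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (ly in names(grads)) {
    for (pn in names(grads[[ly]])) {
      g <- grads[[ly]][[pn]]
      state[[ly]]$m[[pn]] <- beta1 * state[[ly]]$m[[pn]] + (1 - beta1) * g
      state[[ly]]$v[[pn]] <- beta2 * state[[ly]]$v[[pn]] + (1 - beta2) * g^2
      mhat <- state[[ly]]$m[[pn]] / (1 - beta1^t)
      vhat <- state[[ly]]$v[[pn]] / (1 - beta2^t)
      params[[ly]][[pn]] <- params[[ly]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# ---- training ---------------------------------------------------------------

.scores_mat <- function(params, X, idx = seq_len(dim(X)[3])) {
  vapply(idx, function(i) {
    .nn_forward_mat(X[, , i], params, train = FALSE)$score
  }, 0)
}

#' Train one cross-validation fold
#'
#' Mini-batch Adam on binary cross-entropy with a plateau learning-rate
#' scheduler and early stopping on the validation loss; returns the
#' best-on-validation parameters. Fully reproducible given `seed`.
#'
#' @param X `(H*W) x 6 x N` array of tensorised sample pairs
#'   (see [dataset_tensors()]).
#' @param y 0/1 labels of length `N`.
#' @param subtrain_idx,val_idx Sample indices for the subtraining and
#'   validation sets (both non-empty, each containing both classes).
#' @param config A [net_config()].
#' @param seed Integer seed driving initialisation, shuffling and dropout.
#' @param size Image side length; inferred from `X` when `NULL`.
#' @param verbose Print per-epoch losses.
#' @return An `epipair_fold` with attributes `log` (tibble: epoch,
#'   subtrain_loss, val_loss, lr), `best_val_loss` and `epochs`.
#' @export
train_fold <- function(X, y, subtrain_idx, val_idx, config = net_config(),
                       seed = 1, size = NULL, verbose = FALSE) {
  stopifnot(length(subtrain_idx) > 0, length(val_idx) > 0)
  if (length(unique(y[subtrain_idx])) < 2) {
    abort("subtraining set must contain both classes")
  }
  if (is.null(size)) size <- as.integer(sqrt(dim(X)[1]))
  set.seed(as.integer(seed))
  params <- init_params(size, config)
  state <- .adam_init(params)
  lr <- config$lr
  t_step <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  n_bad <- 0L
  log <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(subtrain_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      grads <- NULL
      bl <- 0
      for (i in b) {
        fw <- .nn_forward_mat(X[, , i], params, train = TRUE)
        p <- min(max(fw$score, config$eps), 1 - config$eps)
        bl <- bl - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
        g <- .nn_backward_mat(fw$cache, params, fw$score - y[i])
        grads <- if (is.null(grads)) g else .acc_grads(grads, g)
      }
      grads <- .scale_grads(grads, 1 / length(b))
      if (!all(vapply(grads, function(l) all(vapply(l, function(x)
        all(is.finite(x)), TRUE)), TRUE))) {
        abort("training diverged: non-finite gradient")
      }
      t_step <- t_step + 1L
      upd <- .adam_step(params, grads, state, lr, t_step)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + bl
    }
    ep_loss <- ep_loss / length(ord)
    val_loss <- bce_loss(.scores_mat(params, X, val_idx), y[val_idx],
                         config$eps)
    if (!is.finite(ep_loss) || !is.finite(val_loss)) {
      abort("training diverged: non-finite loss")
    }
    log[[epoch]] <- tibble(epoch = epoch, subtrain_loss = ep_loss,
                           val_loss = val_loss, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  subtrain %.4f  val %.4f  lr %.2g",
                      epoch, ep_loss, val_loss, lr))
    }
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      n_bad <- 0L
    } else {
      n_bad <- n_bad + 1L
      if (n_bad %% config$plateau_patience == 0L) {
        lr <- max(lr * config$plateau_factor, config$min_lr)
      }
      if (n_bad >= config$early_patience) break
    }
  }
  out <- best$params
  attr(out, "log") <- bind_rows(log[!vapply(log, is.null, TRUE)])
  attr(out, "best_val_loss") <- best$loss
  attr(out, "epochs") <- best$epoch
  attr(out, "seed") <- seed
  out
}

.acc_grads <- function(a, b) {
  for (ly in names(a)) for (pn in names(a[[ly]])) {
    a[[ly]][[pn]] <- a[[ly]][[pn]] + b[[ly]][[pn]]
  }
  a
}

.scale_grads <- function(a, k) {
  for (ly in names(a)) for (pn in names(a[[ly]])) {
    a[[ly]][[pn]] <- a[[ly]][[pn]] * k
  }
  a
}

#' Train the cross-validated ensemble
#'
#' Runs [train_fold()] on each (subtrain, validation) pair of the split plan;
#' the resulting models score jointly as the arithmetic mean of their sigmoid
#' outputs.
#'
#' @param X `(H*W) x 6 x N` tensor array.
#' @param y 0/1 labels of length `N`.
#' @param fold_indices List of `n_folds` lists, each with integer vectors
#'   `subtrain` and `validation` indexing samples (see
#'   [dataset_fold_indices()]).
#' @param config A [net_config()].
#' @param seed Integer; fold `i` trains with seed `seed + i`.
#' @param verbose Print per-epoch losses.
#' @return An `epipair_ensemble` (list of folds plus the config).
#' @export
train_cv <- function(X, y, fold_indices, config = net_config(), seed = 1,
                     verbose = FALSE) {
  folds <- purrr::imap(fold_indices, function(fi, i) {
    train_fold(X, y, fi$subtrain, fi$validation, config,
               seed = as.integer(seed) + as.integer(i), verbose = verbose)
  })
  structure(list(folds = folds, config = config, seed = seed),
            class = "epipair_ensemble")
}

#' Score pair tensors with a model ensemble
#'
#' The ensemble score of a pair is the mean of the member models' sigmoid
#' outputs. A single `epipair_fold` is accepted and treated as an ensemble of
#' one.
#'
#' @param model An `epipair_ensemble` or `epipair_fold`.
#' @param X A single `H x W x 6` tensor or an `(H*W) x 6 x N` array.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
ensemble_score <- function(model, X) {
  folds <- if (inherits(model, "epipair_fold")) list(model) else model$folds
  if (length(dim(X)) == 3 && dim(X)[3] == 6 && dim(X)[1] == dim(X)[2]) {
    X <- array(matrix(X, ncol = 6), dim = c(dim(X)[1] * dim(X)[2], 6, 1))
  }
  per_fold <- vapply(folds, function(p) .scores_mat(p, X),
                     numeric(dim(X)[3]))
  rowMeans(matrix(per_fold, nrow = dim(X)[3]))
}

#' @export
print.epipair_ensemble <- function(x, ...) {
  cat("<epipair_ensemble> ", length(x$folds), " fold(s), image size ",
      x$folds[[1]]$size, "\n", sep = "")
  invisible(x)
}

#' @export
print.epipair_fold <- function(x, ...) {
  cat("<epipair_fold> image size ", x$size, ", ",
      attr(x, "epochs") %||% NA, " best epoch\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
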