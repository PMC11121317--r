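# broom-style accessors for fitted objects.

#' Training log of a fold
#'
#' @param x An `epipair_fold`.
#' @param ... Unused.
#' @return Tibble: epoch, subtrain_loss, val_loss, lr.
#' @method tidy epipair_fold
#' @export
tidy.epipair_fold <- function(x, ...) attr(x, "log")

#' One-row summary of a fold
#'
#' @param x An `epipair_fold`.
#' @param ... Unused.
#' @return Tibble: image size, best epoch, best validation loss, parameter
#'   count, seed.
#' @method glance epipair_fold
#' @export
glance.epipair_fold <- function(x, ...) {
  n_par <- sum(vapply(
    x[c("conv1a", "proj", "conv1b", "conv2a", "conv2b", "dense")],
    function(l) length(l[[1]]) + length(l[[2]]), 0
  ))
  tibble(size = x$size, best_epoch = attr(x, "epochs"),
         best_val_loss = attr(x, "best_val_loss"),
         n_parameters = n_par, seed = attr(x, "seed"))
}

#' Per-fold summary of an ensemble
#'
#' @param x An `epipair_ensemble`.
#' @param ... Unused.
#' @return One row per fold, as in [glance.epipair_fold()].
#' @method tidy epipair_ensemble
#' @export
tidy.epipair_ensemble <- function(x, ...) {
  bind_rows(purrr::imap(x$folds, function(f, i) {
    mutate(glance(f), fold = as.integer(i), .before = 1)
  }))
}

#' One-row summary of an ensemble
#'
#' @param x An `epipair_ensemble`.
#' @param ... Unused.
#' @return Tibble: number of folds, image size, total parameters, seed.
#' @method glance epipair_ensemble
#' @export
glance.epipair_ensemble <- function(x, ...) {
  per <- tidy(x)
  tibble(n_folds = length(x$folds), size = x$folds[[1]]$size,
         n_parameters = sum(per$n_parameters), seed = x$seed)
}

#' Plot the training curves of a fold
#'
#' @param object An `epipair_fold`.
#' @param ... Unused.
#' @return A ggplot of subtrain and validation loss per epoch.
#' @method autoplot epipair_fold
#' @export
autoplot.epipair_fold <- function(object, ...) {
  log <- tidy(object)
  df <- tidyr::pivot_longer(log[, c("epoch", "subtrain_loss", "val_loss")],
                            -"epoch", names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "binary cross-entropy") +
    ggplot2::theme_minimal()
}

#' Serialise an ensemble to a directory
#'
#' Writes one RDS-free plain-JSON checkpoint per fold plus a descriptor.
#'
#' @param ensemble An `epipair_ensemble`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::imap_chr(ensemble$folds, function(f, i) {
    path <- file.path(dir, sprintf("fold%02d.json", as.integer(i)))
    payload <- list(
      size = f$size,
      layers = purrr::map(
        f[c("conv1a", "proj", "conv1b", "conv2a", "conv2b")],
        function(l) list(W = as.vector(l$W), dim = dim(l$W), b = l$b)
      ),
      dense = list(w = f$dense$w, b = f$dense$b)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    basename(path)
  })
  jsonlite::write_json(
    list(folds = files, seed = ensemble$seed,
         config = unclass(ensemble$config)),
    file.path(dir, "ensemble.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Load an ensemble written by [write_ensemble()]
#'
#' @param dir Checkpoint directory.
#' @return An `epipair_ensemble`.
#' @export
read_ensemble <- function(dir) {
  desc <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                              simplifyVector = TRUE)
  config <- do.call(net_config, as.list(desc$config))
  folds <- purrr::map(desc$folds, function(fn) {
    p <- jsonlite::read_json(file.path(dir, fn), simplifyVector = TRUE)
    fold <- purrr::map(p$layers, function(l) {
      list(W = matrix(l$W, l$dim[1], l$dim[2]), b = l$b)
    })
    fold$dense <- list(w = p$dense$w, b = p$dense$b)
    fold$size <- as.integer(p$size)
    fold$config <- config
    structure(fold, class = "epipair_fold")
  })
  structure(list(folds = folds, config = config, seed = desc$seed),
            class = "epipair_ensemble")
}
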