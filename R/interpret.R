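# Weight-activation attribution. The dense head computes the logit as a dot
# product w . f; the dot product equals the sum over the Hadamard product
# w * f, so each element of w * f is that feature's signed contribution to
# the logit. Reshaping the Hadamard product back to the pooled grid and
# unpooling (max: place at the cached argmax; avg: spread value/s^2 over the
# window) projects the contributions onto the image plane.

#' Backproject a model's decision onto the image plane
#'
#' Computes the Hadamard product of the dense weights with the flattened
#' pooled features, splits it into its max-pooling and average-pooling halves,
#' unpools each back to the full image resolution, averages over the feature
#' channels and combines the two maps (summing conserves the total
#' contribution; `combine = "mean"` halves it). Positive cells mark
#' pro-binding contributions, negative cells anti-binding ones.
#'
#' @param x `H x W x 6` pair tensor.
#' @param params An `epipair_fold`.
#' @param combine `"sum"` (default, mass-conserving) or `"mean"`.
#' @return A `feature_map`: list with `map` (`H x W` signed matrix), `logit`,
#'   `bias`, `score`. `sum(w * f) + bias` reconstructs the logit exactly.
#' @export
feature_map <- function(x, params, combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  fw <- nn_forward(x, params, train = FALSE)
  cache <- fw$cache
  if (is.null(cache$idx)) abort("forward cache lacks pooling indices")
  H <- params$size; W <- params$size
  s <- params$config$s; C <- params$config$channels
  np <- (H %/% s) * (W %/% s)

  h <- params$dense$w * cache$f
  hmax <- matrix(h[seq_len(np * C)], np, C)
  havg <- matrix(h[np * C + seq_len(np * C)], np, C)
  up_max <- cpp_unpool_max(hmax, cache$idx, H, W)
  up_avg <- cpp_unpool_avg(havg, H, W, s)
  mmax <- matrix(rowMeans(up_max), H, W)
  mavg <- matrix(rowMeans(up_avg), H, W)
  map <- if (combine == "sum") mmax + mavg else (mmax + mavg) / 2
  structure(list(map = map, logit = cache$logit, bias = params$dense$b,
                 score = fw$score, combine = combine),
            class = "feature_map")
}

#' Average attribution maps over an ensemble
#'
#' @param x `H x W x 6` pair tensor.
#' @param ensemble An `epipair_ensemble`.
#' @param combine Passed to [feature_map()].
#' @return A `feature_map` whose `map`, `logit` and `score` are fold means.
#' @export
ensemble_feature_map <- function(x, ensemble, combine = "sum") {
  maps <- purrr::map(ensemble$folds, function(p) feature_map(x, p, combine))
  structure(list(
    map = Reduce(`+`, purrr::map(maps, "map")) / length(maps),
    logit = mean(purrr::map_dbl(maps, "logit")),
    bias = mean(purrr::map_dbl(maps, "bias")),
    score = mean(purrr::map_dbl(maps, "score")),
    combine = combine
  ), class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat("<feature_map> ", nrow(x$map), "x", ncol(x$map),
      sprintf(", logit %.4f (score %.4f)\n", x$logit, x$score), sep = "")
  invisible(x)
}

#' Plot an attribution map with a diverging palette
#'
#' @param object A `feature_map`.
#' @param ... Unused.
#' @return A ggplot object; red marks pro-binding, blue anti-binding pixels.
#' @method autoplot feature_map
#' @export
autoplot.feature_map <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object$map)),
                    col = seq_len(ncol(object$map)))
  df$value <- object$map[as.matrix(df[, 1:2])]
  lim <- max(abs(df$value), 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "contribution",
                  title = sprintf("score %.3f", object$score)) +
    ggplot2::theme_void()
}
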