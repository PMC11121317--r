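# Patch imaging: each interface patch is reduced to its PCA plane, projected
# to (u, v, depth) coordinates, coloured by residue physicochemistry and
# rasterised into an RGB image. The epitope view is mirrored about the u axis
# so that a cognate pair superimposes: the two patches are rendered from
# mutually opposed viewpoints and only coincide after one reflection.

#' Imaging configuration
#'
#' @param scale Pixels per Angstrom (default 2: a 100-pixel crop spans 50 A,
#'   which covers typical interfaces of ~30 A with margin).
#' @param size Final image side in pixels (100 or 64); rendering happens on a
#'   canvas twice this size and is cropped centrally.
#' @param mode `"residue"` (one circle per residue at its Cmu, radius from the
#'   residue volume) or `"atom"` (one 1-Angstrom circle per heavy side-chain
#'   atom).
#' @param scheme `"PIH"` (polarizability/isoelectric point/hydrophobicity as
#'   RGB) or `"four_color"` (aromatics green, positives red, negatives blue,
#'   others white).
#' @param knockout Subset of `c("P","I","H")`; knocked-out channels are forced
#'   to zero (ablation switch).
#' @param d_max Depth at which transparency reaches its floor, Angstrom.
#' @param alpha_min Opacity floor.
#' @param distance Logical; `FALSE` disables the depth-to-transparency map
#'   (all circles fully opaque).
#' @return A list of class `epipair_imaging_config`.
#' @export
imaging_config <- function(scale = 2, size = 100L, mode = c("residue", "atom"),
                           scheme = c("PIH", "four_color"),
                           knockout = character(), d_max = 6, alpha_min = 0.1,
                           distance = TRUE) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  stopifnot(size %in% c(100L, 64L), scale > 0,
            all(knockout %in% c("P", "I", "H")))
  structure(list(scale = scale, size = as.integer(size), mode = mode,
                 scheme = scheme, knockout = knockout, d_max = d_max,
                 alpha_min = alpha_min, distance = distance),
            class = "epipair_imaging_config")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# points used for the PCA frame and the projection: Cmu pseudoatoms in residue
# mode, heavy side-chain atoms in atom mode (C-alpha stands in for residues
# with no resolved side-chain atom, so every residue remains visible)
.patch_points <- function(patch, mode) {
  if (mode == "residue") {
    tibble(res_id = patch$res_id, aa = patch$aa,
           x = patch$cmu_x, y = patch$cmu_y, z = patch$cmu_z,
           point_id = patch$res_id)
  } else {
    at <- attr(patch, "atoms")
    side <- at[at$is_side, ]
    no_side <- setdiff(patch$res_id, unique(side$res_id))
    if (length(no_side)) {
      ca <- at[!at$is_side & at$elety == "CA" & at$res_id %in% no_side, ]
      side <- bind_rows(side, ca)
    }
    side <- side[order(side$res_id, side$elety), ]
    aa_of <- setNames(patch$aa, patch$res_id)
    tibble(res_id = side$res_id, aa = unname(aa_of[side$res_id]),
           x = side$x, y = side$y, z = side$z,
           point_id = paste0(side$res_id, "/", side$elety))
  }
}

#' Build the oriented PCA frame of a patch
#'
#' `e1` and `e2` are the top-two principal axes of the patch point cloud
#' (Cmu coordinates in residue mode, atom coordinates in atom mode); `n` is
#' the third axis, sign-fixed to point from the patch centroid towards the
#' partner patch. The in-plane sign convention makes the frame reproducible
#' under rigid motions: `e1` is flipped so the third central moment of the
#' projected u coordinates is non-negative (exact ties resolved by flipping so
#' the maximum-u point has the lexicographically smallest identifier), and
#' `e2 = n x e1` completes a right-handed orthonormal triple.
#'
#' @param patch An `interface_patch` from [find_interface()].
#' @param mode `"residue"` or `"atom"`.
#' @return A list of class `oriented_frame`: `origin`, `e1`, `e2`, `n`.
#' @export
build_frame <- function(patch, mode = "residue") {
  pts <- .patch_points(patch, mode)
  X <- as.matrix(pts[, c("x", "y", "z")])
  if (nrow(X) < 3) abort("frame requires at least 3 points")
  origin <- unname(colMeans(X))
  Xc <- sweep(X, 2, origin)
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  if (ev$values[2] <= 1e-9 * max(ev$values[1], 1e-12)) {
    abort("degenerate patch: points are (nearly) collinear")
  }
  e1 <- ev$vectors[, 1]
  n <- ev$vectors[, 3]
  to_partner <- unname(attr(patch, "partner_centroid")) - origin
  if (sum(n * to_partner) < 0) n <- -n

  u <- drop(Xc %*% e1)
  m3 <- mean(u^3)
  tol <- 1e-9 * (mean(u^2)^1.5 + 1e-12)
  if (abs(m3) <= tol) {
    id_pos <- pts$point_id[which.max(u)]
    id_neg <- pts$point_id[which.max(-u)]
    if (id_neg < id_pos) e1 <- -e1
  } else if (m3 < 0) {
    e1 <- -e1
  }
  e2 <- .cross3(n, e1)
  structure(list(origin = origin, e1 = e1, e2 = e2, n = n),
            class = "oriented_frame")
}

#' Project patch points onto an oriented frame
#'
#' `u = (x - origin) . e1`, `v = (x - origin) . e2`, and the unsigned depth
#' `D = |(x - origin) . n|`.
#'
#' @param patch An `interface_patch`.
#' @param frame An [build_frame()] result.
#' @param mode `"residue"` (points are Cmu, radius from the feature table) or
#'   `"atom"` (heavy side-chain atoms, radius 1 Angstrom).
#' @return Tibble: `point_id`, `res_id`, `aa`, `u`, `v`, `depth`, `radius`.
#' @export
project_patch <- function(patch, frame, mode = "residue") {
  pts <- .patch_points(patch, mode)
  Xc <- sweep(as.matrix(pts[, c("x", "y", "z")]), 2, frame$origin)
  ft <- .features()
  rad <- setNames(ft$radius, ft$aa)
  tibble(
    point_id = pts$point_id, res_id = pts$res_id, aa = pts$aa,
    u = drop(Xc %*% frame$e1),
    v = drop(Xc %*% frame$e2),
    depth = abs(drop(Xc %*% frame$n)),
    radius = if (mode == "atom") 1
             else unname(ifelse(is.na(rad[pts$aa]), 2.4, rad[pts$aa]))
  )
}

#' Residue colour under a colouring scheme
#'
#' In the `"PIH"` scheme the RGB channels carry the min-max scaled
#' polarizability, isoelectric point and hydrophobicity of the residue, with
#' knocked-out channels forced to zero. In the `"four_color"` scheme aromatic
#' residues (Phe/Tyr/Trp/His) are green, positively charged (Arg/Lys) red,
#' negatively charged (Asp/Glu) blue, all others white. Unknown residues
#' render white (logged once per call).
#'
#' @param aa Character vector of one-letter codes.
#' @param scheme `"PIH"` or `"four_color"`.
#' @param knockout Subset of `c("P","I","H")` to zero out.
#' @return `length(aa) x 3` matrix of RGB values in \[0, 1\].
#' @export
aa_colour <- function(aa, scheme = c("PIH", "four_color"),
                      knockout = character()) {
  scheme <- match.arg(scheme)
  ft <- .features()
  unknown <- !(aa %in% ft$aa)
  if (any(unknown)) {
    warn(paste0("unknown residue code(s) coloured white: ",
                paste(unique(aa[unknown]), collapse = ", ")))
  }
  if (scheme == "PIH") {
    i <- match(aa, ft$aa)
    rgb <- cbind(ft$P[i], ft$I[i], ft$H[i])
    rgb[unknown, ] <- 1
    for (ch in knockout) {
      rgb[, match(ch, c("P", "I", "H"))] <- 0
    }
  } else {
    rgb <- matrix(1, length(aa), 3)
    rgb[aa %in% c("F", "Y", "W", "H"), ] <- rep(c(0, 1, 0), each = sum(aa %in% c("F", "Y", "W", "H")))
    rgb[aa %in% c("R", "K"), ] <- rep(c(1, 0, 0), each = sum(aa %in% c("R", "K")))
    rgb[aa %in% c("D", "E"), ] <- rep(c(0, 0, 1), each = sum(aa %in% c("D", "E")))
  }
  colnames(rgb) <- c("r", "g", "b")
  rgb
}

#' Depth-to-transparency map
#'
#' Linear opacity `alpha = clamp(1 - D/d_max, alpha_min, 1)`; monotonically
#' non-increasing in the depth. With `distance = FALSE` (ablation of the
#' distance feature) every circle is fully opaque.
#'
#' @param depth Unsigned distance to the PCA plane, Angstrom.
#' @param d_max Depth at which the floor is reached.
#' @param alpha_min Opacity floor.
#' @param distance Logical toggle.
#' @return Opacities in \[`alpha_min`, 1\] (or all 1).
#' @export
alpha_from_depth <- function(depth, d_max = 6, alpha_min = 0.1,
                             distance = TRUE) {
  stopifnot(all(depth >= 0), d_max > 0)
  if (!distance) return(rep(1, length(depth)))
  pmin(pmax(1 - depth / d_max, alpha_min), 1)
}

#' Rasterise projected points into a patch image
#'
#' Applies the in-plane rotation and translation to the (u, v) coordinates,
#' then draws each point as a hard-edged filled circle (a pixel is covered iff
#' its centre lies inside the circle), alpha-composited over a white canvas in
#' descending-depth order (painter's algorithm: farthest first, so
#' plane-proximal residues dominate overlaps). The canvas is twice the final
#' size and cropped centrally. Rasterisation is analytic, so output is
#' bit-identical for identical input.
#'
#' @param points Tibble with columns `u`, `v`, `depth`, `radius`, `r`, `g`,
#'   `b`, `alpha` and `point_id` (tie-break for equal depths).
#' @param size Final image side in pixels.
#' @param scale Pixels per Angstrom.
#' @param rotation In-plane rotation in degrees (counter-clockwise), applied
#'   before rasterising.
#' @param translation Length-2 displacement `(du, dv)` in Angstrom.
#' @param side,mode Metadata stored on the image.
#' @return A `patch_image`: `size x size x 3` array in \[0, 1\] with
#'   attributes `side`, `mode`, `scale`, `angle`.
#' @export
render_patch <- function(points, size = 100L, scale = 2, rotation = 0,
                         translation = c(0, 0), side = "paratope",
                         mode = "residue") {
  stopifnot(size %in% c(100L, 64L))
  canvas <- 2L * size
  img <- array(1, dim = c(canvas, canvas, 3))
  if (nrow(points) > 0) {
    th <- rotation * pi / 180
    # geometry is quantised to 1e-6 Angstrom before rasterising: well below
    # any physical precision, well above floating-point noise, so rigidly
    # moved or rotation-composed copies of a patch rasterise bit-identically
    u <- round(points$u * cos(th) - points$v * sin(th) + translation[1], 6)
    v <- round(points$u * sin(th) + points$v * cos(th) + translation[2], 6)
    depth <- round(points$depth, 6)
    alpha <- round(points$alpha, 6)
    ord <- order(-depth, points$point_id)
    centre <- (canvas + 1) / 2
    half_span <- centre / scale
    for (i in ord) {
      ui <- u[i]; vi <- v[i]; rad <- points$radius[i]
      if (ui + rad < -half_span || ui - rad > half_span ||
          vi + rad < -half_span || vi - rad > half_span) {
        warn(paste0("point ", points$point_id[i],
                    " falls outside the canvas and is clipped"))
        next
      }
      # pixel centres: column c has u = (c - centre)/scale, row r has
      # v = (centre - r)/scale (v axis points up)
      c0 <- max(1L, floor(centre + (ui - rad) * scale))
      c1 <- min(canvas, ceiling(centre + (ui + rad) * scale))
      r0 <- max(1L, floor(centre - (vi + rad) * scale))
      r1 <- min(canvas, ceiling(centre - (vi - rad) * scale))
      if (c0 > c1 || r0 > r1) next
      cc <- c0:c1; rr <- r0:r1
      du <- (cc - centre) / scale - ui
      dv <- (centre - rr) / scale - vi
      covered <- outer(dv^2, du^2, "+") <= rad^2
      if (!any(covered)) next
      a <- alpha[i]
      col <- c(points$r[i], points$g[i], points$b[i])
      for (ch in 1:3) {
        block <- img[rr, cc, ch, drop = FALSE]
        dim(block) <- dim(covered)
        block[covered] <- a * col[ch] + (1 - a) * block[covered]
        img[rr, cc, ch] <- block
      }
    }
  }
  off <- size %/% 2L
  out <- img[(off + 1L):(off + size), (off + 1L):(off + size), , drop = FALSE]
  structure(out, side = side, mode = mode, scale = scale, angle = rotation,
            class = "patch_image")
}

# colour + transparency columns for a projected point table
.colour_points <- function(proj, config) {
  rgb <- aa_colour(proj$aa, config$scheme, config$knockout)
  proj$r <- rgb[, 1]; proj$g <- rgb[, 2]; proj$b <- rgb[, 3]
  proj$alpha <- alpha_from_depth(proj$depth, config$d_max, config$alpha_min,
                                 config$distance)
  proj
}

#' Render the paratope/epitope image pair of a complex
#'
#' Both patches are projected in their own oriented PCA frames (each normal
#' facing its partner, so a cognate pair is rendered as two mutually facing
#' views); the epitope projection is then mirrored about the u axis so that
#' spatially corresponding residues land at corresponding pixels. An extra
#' rotation/translation can be applied to the epitope, which is how negative
#' samples and screening rotations are produced.
#'
#' @param x An `abag_complex`.
#' @param config An [imaging_config()].
#' @param interface Optional pre-computed [find_interface()] result.
#' @param epitope_rotation Degrees, applied to the (mirrored) epitope.
#' @param epitope_translation `(du, dv)` Angstrom, applied to the epitope.
#' @return An `image_pair`: list with `paratope` and `epitope` patch images,
#'   the coloured point tables `para_points`/`epi_points` (epitope already
#'   mirrored, before the extra transform), the `config` and `complex_id`.
#' @export
imagify_complex <- function(x, config = imaging_config(), interface = NULL,
                            epitope_rotation = 0,
                            epitope_translation = c(0, 0)) {
  if (is.null(interface)) interface <- find_interface(x)
  pf <- build_frame(interface$paratope, config$mode)
  ef <- build_frame(interface$epitope, config$mode)
  pp <- .colour_points(project_patch(interface$paratope, pf, config$mode),
                       config)
  ep <- .colour_points(project_patch(interface$epitope, ef, config$mode),
                       config)
  ep$v <- -ep$v  # mirror about the u axis
  structure(list(
    paratope = render_patch(pp, config$size, config$scale,
                            side = "paratope", mode = config$mode),
    epitope = render_patch(ep, config$size, config$scale,
                           rotation = epitope_rotation,
                           translation = epitope_translation,
                           side = "epitope", mode = config$mode),
    para_points = pp, epi_points = ep,
    config = config, complex_id = x$id
  ), class = "image_pair")
}

#' Re-render the epitope image of a pair with a new transform
#'
#' @param pair An `image_pair`.
#' @param rotation Degrees.
#' @param translation `(du, dv)` Angstrom.
#' @return A `patch_image`.
#' @export
rerender_epitope <- function(pair, rotation = 0, translation = c(0, 0)) {
  render_patch(pair$epi_points, pair$config$size, pair$config$scale,
               rotation = rotation, translation = translation,
               side = "epitope", mode = pair$config$mode)
}

#' Write a patch image as 8-bit PNG
#' @param img A `patch_image`.
#' @param path Output path.
#' @export
write_patch_image <- function(img, path) {
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' @export
print.patch_image <- function(x, ...) {
  cat("<patch_image> ", attr(x, "side"), " ", dim(x)[1], "x", dim(x)[2],
      " (", attr(x, "mode"), " mode, ", attr(x, "scale"), " px/A, angle ",
      attr(x, "angle"), ")\n", sep = "")
  invisible(x)
}

#' Plot a patch image
#'
#' @param object A `patch_image`.
#' @param ... Unused.
#' @return A ggplot raster of the RGB image.
#' @method autoplot patch_image
#' @export
autoplot.patch_image <- function(object, ...) {
  d <- dim(object)
  df <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(object[, , 1][as.matrix(df[, 1:2])],
                            object[, , 2][as.matrix(df[, 1:2])],
                            object[, , 3][as.matrix(df[, 1:2])])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(attr(object, "side"), "image"),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}
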