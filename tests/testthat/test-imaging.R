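# PCA frames, projection, colouring, transparency and rasterisation.

test_that("feature table is min-max scaled with unique extremes", {
  ft <- feature_table()
  expect_equal(nrow(ft), 20)
  for (col in c("P", "I", "H")) {
    expect_true(all(ft[[col]] >= 0 & ft[[col]] <= 1))
    expect_equal(sum(ft[[col]] == 0), 1)
    expect_equal(sum(ft[[col]] == 1), 1)
  }
  expect_true(all(ft$radius > 0))
  # hydropathy extremes: Ile most hydrophobic, Arg least
  expect_equal(ft$aa[ft$H == 1], "I")
  expect_equal(ft$aa[ft$H == 0], "R")
  # tryptophan is the largest residue
  expect_equal(ft$aa[which.max(ft$radius)], "W")
})

test_that("frame normal faces the partner centroid", {
  pts <- rbind(c(3, 0, 0), c(-1, 0, 0), c(0, 2, 0), c(0, -2, 0))
  up <- build_frame(make_patch(pts, partner_centroid = c(0, 0, 5)))
  expect_equal(up$n, c(0, 0, 1), tolerance = 1e-9)
  dn <- build_frame(make_patch(pts, partner_centroid = c(0, 0, -5)))
  expect_equal(dn$n, c(0, 0, -1), tolerance = 1e-9)
})

test_that("frames are right-handed orthonormal triples", {
  set.seed(7)
  for (rep in 1:20) {
    pts <- cbind(rnorm(8, sd = 4), rnorm(8, sd = 2), rnorm(8, sd = 0.5))
    fr <- build_frame(make_patch(pts, partner_centroid = c(0, 0, 30)))
    M <- cbind(fr$e1, fr$e2, fr$n)
    expect_equal(crossprod(M), diag(3), tolerance = 1e-9)
    expect_equal(det(M), 1, tolerance = 1e-9)
  }
})

test_that("frames are equivariant under rigid motions", {
  set.seed(8)
  pts <- cbind(16 * (rbeta(12, 2, 5) - 2 / 7), rnorm(12, sd = 2),
               rnorm(12, sd = 0.4))
  partner <- c(1, 0, 6)
  f0 <- build_frame(make_patch(pts, partner))
  for (rep in 1:10) {
    R <- rand_rotation()
    tr <- rnorm(3, sd = 20)
    pts_r <- sweep(pts %*% t(R), 2, -tr)
    fr <- build_frame(make_patch(pts_r, drop(R %*% partner) + tr))
    expect_equal(fr$e1, drop(R %*% f0$e1), tolerance = 1e-6)
    expect_equal(fr$n, drop(R %*% f0$n), tolerance = 1e-6)
    expect_equal(fr$origin, drop(R %*% f0$origin) + tr, tolerance = 1e-6)
  }
})

test_that("degenerate (collinear) patches are rejected", {
  pts <- cbind(1:5, 0, 0)
  expect_error(build_frame(make_patch(pts, c(0, 0, 5))), "degenerate")
})

test_that("projection preserves squared distances (Pythagoras)", {
  set.seed(9)
  pts <- cbind(rnorm(10, sd = 5), rnorm(10, sd = 3), rnorm(10))
  patch <- make_patch(pts, c(0, 0, 20))
  fr <- build_frame(patch)
  pr <- project_patch(patch, fr)
  d2 <- rowSums(sweep(pts, 2, fr$origin)^2)
  expect_equal(pr$u^2 + pr$v^2 + pr$depth^2, d2, tolerance = 1e-9)
  expect_true(all(pr$depth >= 0))
  # in-plane distances never exceed 3D distances
  for (i in 1:9) for (j in (i + 1):10) {
    d3 <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    d2p <- sqrt((pr$u[i] - pr$u[j])^2 + (pr$v[i] - pr$v[j])^2)
    expect_lte(d2p, d3 + 1e-9)
  }
})

test_that("points on the frame axes project to the expected coordinates", {
  pts <- rbind(c(4, 0, 0), c(-2, 0, 0), c(0, 3, 0), c(0, -3, 0), c(-2, 0, 0))
  patch <- make_patch(pts, c(0, 0, 5))
  fr <- build_frame(patch)
  origin_pt <- matrix(fr$origin, 1)
  p2 <- make_patch(rbind(pts, fr$origin, fr$origin + 3 * fr$n), c(0, 0, 5))
  pr <- project_patch(p2, fr)
  n <- nrow(pr)
  expect_equal(c(pr$u[n - 1], pr$v[n - 1], pr$depth[n - 1]), c(0, 0, 0),
               tolerance = 1e-9)
  expect_equal(pr$depth[n], 3, tolerance = 1e-9)
  expect_equal(c(pr$u[n], pr$v[n]), c(0, 0), tolerance = 1e-9)
})

test_that("colour schemes follow the feature table and the four-colour rule", {
  expect_equal(unname(aa_colour("D", "four_color")[1, ]), c(0, 0, 1))
  expect_equal(unname(aa_colour("R", "four_color")[1, ]), c(1, 0, 0))
  expect_equal(unname(aa_colour("W", "four_color")[1, ]), c(0, 1, 0))
  expect_equal(unname(aa_colour("S", "four_color")[1, ]), c(1, 1, 1))
  ft <- feature_table()
  for (aa in c("A", "W", "I", "R")) {
    expect_equal(unname(aa_colour(aa, "PIH")[1, ]),
                 unname(unlist(ft[ft$aa == aa, c("P", "I", "H")])))
  }
  # knock-out forces the corresponding channel to zero for every residue
  ko <- aa_colour(ft$aa, "PIH", knockout = "I")
  expect_true(all(ko[, 2] == 0))
  expect_equal(ko[, c(1, 3)], aa_colour(ft$aa, "PIH")[, c(1, 3)])
  # the most hydrophobic residue saturates the third channel
  expect_equal(unname(aa_colour("I", "PIH")[1, 3]), 1)
  expect_warning(col <- aa_colour("X", "PIH"), "unknown")
  expect_equal(unname(col[1, ]), c(1, 1, 1))
})

test_that("depth maps linearly to opacity with a clamp floor", {
  expect_equal(alpha_from_depth(0), 1)
  expect_equal(alpha_from_depth(6, d_max = 6, alpha_min = 0.1), 0.1)
  expect_equal(alpha_from_depth(3, d_max = 6, alpha_min = 0), 0.5)
  expect_equal(alpha_from_depth(100, d_max = 6, alpha_min = 0.1), 0.1)
  expect_equal(alpha_from_depth(c(0, 3, 6), distance = FALSE), c(1, 1, 1))
  d <- seq(0, 10, by = 0.5)
  a <- alpha_from_depth(d)
  expect_true(all(diff(a) <= 0))
})

test_that("rendering draws hard-edged circles over a white canvas", {
  empty <- render_patch(tibble::tibble(
    u = numeric(), v = numeric(), depth = numeric(), radius = numeric(),
    r = numeric(), g = numeric(), b = numeric(), alpha = numeric(),
    point_id = character()
  ), size = 64L, scale = 2)
  expect_true(all(empty == 1))

  one <- tibble::tibble(u = 0, v = 0, depth = 0, radius = 3, r = 1, g = 0,
                        b = 0, alpha = 1, point_id = "p")
  img <- render_patch(one, size = 64L, scale = 2)
  expect_equal(img[32, 32, ], c(1, 0, 0))   # centre pixel pure red
  expect_equal(img[1, 1, ], c(1, 1, 1))     # corner untouched
  expect_true(all(img >= 0 & img <= 1))

  # identity transform and full-turn rotation are bit-exact no-ops
  expect_identical(render_patch(one, 64L, 2),
                   render_patch(one, 64L, 2, rotation = 0,
                                translation = c(0, 0)))
  expect_identical(px(render_patch(one, 64L, 2)),
                   px(render_patch(one, 64L, 2, rotation = 360)))
})

test_that("rotation acts in coordinate space and composes exactly", {
  pt <- tibble::tibble(u = 5, v = 0, depth = 0, radius = 2, r = 0, g = 0,
                       b = 1, alpha = 1, point_id = "p")
  img90 <- render_patch(pt, 64L, 2, rotation = 90)
  # (5, 0) rotated 90 deg CCW lands at (0, 5)
  pt2 <- pt; pt2$u <- 0; pt2$v <- 5
  expect_identical(px(img90), px(render_patch(pt2, 64L, 2)))
  # rotating the coordinates by +60 and rendering at -60 restores the image
  th <- 60 * pi / 180
  rot <- pt
  rot$u <- pt$u * cos(th) - pt$v * sin(th)
  rot$v <- pt$u * sin(th) + pt$v * cos(th)
  expect_identical(px(render_patch(rot, 64L, 2, rotation = -60)),
                   px(render_patch(pt, 64L, 2)))
})

test_that("translation shifts circle centres by scale times the offset", {
  pt <- tibble::tibble(u = 0, v = 0, depth = 0, radius = 1.5, r = 0, g = 1,
                       b = 0, alpha = 1, point_id = "p")
  base <- render_patch(pt, 64L, 2)
  moved <- render_patch(pt, 64L, 2, translation = c(10, 0))
  nb <- which(base[, , 1] == 0, arr.ind = TRUE)     # green circle pixels
  nm <- which(moved[, , 1] == 0, arr.ind = TRUE)
  expect_equal(colMeans(nm)[["col"]] - colMeans(nb)[["col"]], 20)
  expect_equal(colMeans(nm)[["row"]], colMeans(nb)[["row"]])
})

test_that("painter's algorithm lets plane-proximal residues win overlaps", {
  two <- tibble::tibble(
    u = c(0, 0.5), v = 0, depth = c(5, 0), radius = 2,
    r = c(1, 0), g = c(0, 0), b = c(0, 1), alpha = 1,
    point_id = c("far", "near")
  )
  img <- render_patch(two, 64L, 2)
  expect_equal(img[32, 33, ], c(0, 0, 1))  # overlap shows the near circle
})

test_that("the image pair of a complex is invariant under rigid motions", {
  cx <- generate_toy_complex(seed = 55)
  cfg <- imaging_config(size = 64L)
  base <- imagify_complex(cx, cfg)
  set.seed(56)
  for (rep in 1:8) {
    moved <- transform_complex(cx, rand_rotation(), rnorm(3, sd = 30))
    pair <- imagify_complex(moved, cfg)
    expect_identical(px(pair$paratope), px(base$paratope))
    expect_identical(px(pair$epitope), px(base$epitope))
  }
})

test_that("cognate pairs superimpose after the epitope mirror", {
  cx <- generate_toy_complex(seed = 77, jitter = 0, n_paratope = 8)
  pair <- imagify_complex(cx, imaging_config(size = 64L))
  pp <- pair$para_points
  ep <- pair$epi_points
  # matched construction pairs residue i with epitope residue i
  d <- sqrt((pp$u - ep$u)^2 + (pp$v - ep$v)^2)
  expect_true(all(d * pair$config$scale <= 1))  # within one pixel
  # mismatched layouts fail the same alignment bound
  mis <- generate_toy_complex(seed = 77, jitter = 0, n_paratope = 8,
                              mode = "mismatched")
  mp <- imagify_complex(mis, imaging_config(size = 64L))
  iface <- find_interface(mis)
  dm <- tryCatch({
    k <- min(nrow(mp$para_points), nrow(mp$epi_points))
    sqrt((mp$para_points$u[1:k] - mp$epi_points$u[1:k])^2 +
           (mp$para_points$v[1:k] - mp$epi_points$v[1:k])^2)
  }, error = function(e) Inf)
  expect_gt(max(dm) * mp$config$scale, 1)
})

test_that("atom mode draws one 1-Angstrom circle per side-chain atom", {
  ab <- rbind(c(0, 0, 0), c(2.5, 0, 0), c(0, 2.5, 0))
  ag <- rbind(c(0, 0, 5), c(2.5, 0, 5), c(0, 2.5, 5))
  cx <- make_point_complex(ab, ag, aa_ab = c("K", "K", "K"))
  iface <- find_interface(cx)
  pr <- project_patch(iface$paratope, build_frame(iface$paratope, "atom"),
                      mode = "atom")
  expect_equal(nrow(pr), 3)  # one CB per residue in the point constructor
  expect_true(all(pr$radius == 1))
})

test_that("channel knock-out zeroes exactly that channel under full opacity", {
  cx <- generate_toy_complex(seed = 91)
  cfg <- imaging_config(size = 64L, knockout = "P", distance = FALSE)
  pair <- imagify_complex(cx, cfg)
  img <- unclass(pair$paratope)
  covered <- img[, , 1] < 1 | img[, , 2] < 1 | img[, , 3] < 1
  expect_true(any(covered))
  expect_true(all(img[, , 1][covered] == 0))
  expect_true(all(img[, , 1][!covered] == 1))
  # the untouched channels match the un-knocked render
  full <- imagify_complex(cx, imaging_config(size = 64L, distance = FALSE))
  expect_identical(img[, , 2], unclass(full$paratope)[, , 2])
})
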