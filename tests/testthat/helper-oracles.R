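# Independent brute-force oracles and small constructors used across the
# suite. The oracles deliberately share no code with the implementation.

# direct triple-loop evaluation of the padded convolution sum
oracle_conv2d <- function(x, kernels, bias = NULL) {
  d <- dim(x); kd <- dim(kernels)
  k <- (kd[1] - 1) / 2
  if (is.null(bias)) bias <- numeric(kd[4])
  out <- array(0, dim = c(d[1], d[2], kd[4]))
  for (o in seq_len(kd[4])) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      acc <- 0
      for (t in -k:k) for (s in -k:k) {
        ii <- i + t; jj <- j + s
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
          for (c in seq_len(d[3])) {
            acc <- acc + kernels[t + k + 1, s + k + 1, c, o] * x[ii, jj, c]
          }
        }
      }
      out[i, j, o] <- acc + bias[o]
    }
  }
  out
}

# window-scan pooling oracle
oracle_pool <- function(x, s, mode) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] / s, d[2] / s, d[3]))
  for (c in seq_len(d[3])) {
    for (bi in seq_len(d[1] / s)) for (bj in seq_len(d[2] / s)) {
      win <- x[(bi - 1) * s + 1:s, (bj - 1) * s + 1:s, c]
      out[bi, bj, c] <- if (mode == "max") max(win) else mean(win)
    }
  }
  out
}

# all-pairs double-loop interface scan (contact rule + CDR-centre filter)
oracle_interface <- function(complex, cutoff = 6, cdr_radius = 40) {
  res <- complex$residues
  ab <- res[res$role %in% c("heavy", "light"), ]
  ag <- res[res$role == "antigen", ]
  pm <- matrix(FALSE, nrow(ab), nrow(ag))
  for (i in seq_len(nrow(ab))) for (j in seq_len(nrow(ag))) {
    d <- sqrt((ab$cmu_x[i] - ag$cmu_x[j])^2 +
                (ab$cmu_y[i] - ag$cmu_y[j])^2 +
                (ab$cmu_z[i] - ag$cmu_z[j])^2)
    pm[i, j] <- d <= cutoff
  }
  para <- ab[apply(pm, 1, any), ]
  epi <- ag[apply(pm, 2, any), ]
  if (nrow(para) == 0 || nrow(epi) == 0) return(NULL)
  ctr <- c(mean(para$cmu_x), mean(para$cmu_y), mean(para$cmu_z))
  near <- function(df) {
    keep <- sqrt((df$cmu_x - ctr[1])^2 + (df$cmu_y - ctr[2])^2 +
                   (df$cmu_z - ctr[3])^2) <= cdr_radius
    df[keep, ]
  }
  list(paratope = sort(near(para)$res_id), epitope = sort(near(epi)$res_id))
}

# proper random rotation via QR of a Gaussian matrix
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# minimal complex built from explicit Cmu points; each residue gets one
# side-chain atom at its Cmu (plus a CA nearby), so parse-level and
# residue-level views agree exactly
make_point_complex <- function(ab_pts, ag_pts, aa_ab = NULL, aa_ag = NULL,
                               id = "pt") {
  n_ab <- nrow(ab_pts); n_ag <- nrow(ag_pts)
  if (is.null(aa_ab)) aa_ab <- rep("A", n_ab)
  if (is.null(aa_ag)) aa_ag <- rep("S", n_ag)
  n_h <- max(1, ceiling(n_ab / 2))
  chain <- c(rep("H", n_h), rep("L", n_ab - n_h), rep("A", n_ag))
  if (n_ab == 1) chain <- c("H", rep("A", n_ag))
  # guarantee a light chain far away so the Fab contract holds
  pts <- rbind(ab_pts, ag_pts)
  aa <- c(aa_ab, aa_ag)
  role <- c(rep("heavy", sum(chain == "H")), rep("light", sum(chain == "L")),
            rep("antigen", n_ag))
  if (!any(chain == "L")) {
    chain <- c(chain, "L"); role <- c(role, "light")
    pts <- rbind(pts, c(500, 500, 500)); aa <- c(aa, "A")
  }
  resno <- stats::ave(seq_along(chain), chain, FUN = seq_along)
  res_id <- paste0(chain, ":", resno)
  atoms <- do.call(rbind, lapply(seq_along(aa), function(i) {
    data.frame(chain = chain[i], resno = resno[i], insert = "",
               res_id = res_id[i], elety = c("CA", "CB"),
               role = role[i], is_side = c(FALSE, TRUE),
               x = pts[i, 1] + c(1.5, 0), y = pts[i, 2], z = pts[i, 3])
  }))
  residues <- tibble::tibble(
    chain = chain, resno = resno, insert = "", res_id = res_id,
    resid = bio3d::aa123(aa), aa = aa, role = role, n_side = 1L,
    cmu_x = pts[, 1], cmu_y = pts[, 2], cmu_z = pts[, 3]
  )
  structure(list(id = id, residues = residues,
                 atoms = tibble::as_tibble(atoms), cdr = NULL, n_unk = 0L),
            class = "abag_complex")
}

# an interface_patch built directly from points (frame/projection tests)
make_patch <- function(pts, partner_centroid, aa = NULL, side = "paratope") {
  n <- nrow(pts)
  if (is.null(aa)) aa <- rep("A", n)
  tb <- tibble::tibble(
    chain = "H", resno = seq_len(n), insert = "",
    res_id = sprintf("H:%d", seq_len(n)),
    resid = bio3d::aa123(aa), aa = aa, role = "heavy", n_side = 1L,
    cmu_x = pts[, 1], cmu_y = pts[, 2], cmu_z = pts[, 3]
  )
  atoms <- tibble::tibble(
    chain = "H", resno = seq_len(n), insert = "",
    res_id = tb$res_id, elety = "CB", role = "heavy", is_side = TRUE,
    x = pts[, 1], y = pts[, 2], z = pts[, 3]
  )
  structure(tb, side = side, partner_centroid = partner_centroid,
            cdr_center = colMeans(pts), atoms = atoms, complex_id = "patch",
            class = c("interface_patch", class(tibble::tibble())))
}

# fixed-format PDB ATOM line builder for parser tests
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          alt = " ", occ = 1, icode = " ") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, alt, resn, chain, resno, icode, x, y, z, occ, 0)
}

# small random-weight fold for scoring tests (no training)
random_fold <- function(size = 16L, channels = 8L, seed = 1) {
  set.seed(seed)
  init_params(size, net_config(channels = channels))
}

# non-white pixel overlap fraction between the two images of a pair
pixel_overlap <- function(img_a, img_b) {
  na <- apply(unclass(img_a) < 1 - 1e-9, c(1, 2), any)
  nb <- apply(unclass(img_b) < 1 - 1e-9, c(1, 2), any)
  if (!any(na) || !any(nb)) return(0)
  sum(na & nb) / min(sum(na), sum(nb))
}

# pixel data of a patch_image, metadata attributes stripped
px <- function(img) {
  x <- unclass(img)
  attributes(x) <- list(dim = dim(x))
  x
}
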