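# Synthetic toy complexes and labelled image-pair tasks. The generator builds
# two roughly planar residue clouds facing each other 4-6 Angstrom apart;
# matched mode aligns the epitope layout with the paratope and pairs charged
# residues with their opposite charge, so the learnable signal is shape and
# colour complementarity. Geometric realism (backbone geometry, CDR loops,
# energetics) is deliberately not attempted.

.TOY_AA_POOL <- c("R", "K", "D", "E", "Y", "W", "F", "N", "Q", "S", "T",
                  "L", "I", "V", "A", "G")
.TOY_AA_WT <- c(3, 3, 3, 3, 3, 2, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1)
.TOY_NEUTRAL <- c("N", "Q", "S", "T", "L", "I", "V", "A", "G", "Y")

.complement_aa <- function(aa) {
  vapply(aa, function(a) {
    if (a %in% c("R", "K")) sample(c("D", "E"), 1)
    else if (a %in% c("D", "E")) sample(c("R", "K"), 1)
    else if (a %in% c("Y", "W", "F")) sample(c("Y", "W", "F"), 1)
    else sample(.TOY_NEUTRAL, 1)
  }, "")
}

# anisotropic, positively skewed planar cloud: distinct principal axes and a
# clearly signed third moment keep the PCA frame orientation stable
.toy_layout <- function(n) {
  cbind(a = 16 * (stats::rbeta(n, 2, 5) - 2 / 7),
        b = 7 * (runif(n) - 0.5))
}

.toy_atoms_for <- function(res_id, chain, resno, aa, cmu) {
  if (aa == "G") {
    return(tibble(chain = chain, resno = resno, insert = "",
                  res_id = res_id, elety = "CA", is_side = FALSE,
                  x = cmu[1], y = cmu[2], z = cmu[3]))
  }
  ca_off <- rnorm(3); ca_off <- 1.8 * ca_off / sqrt(sum(ca_off^2))
  k <- sample(1:3, 1)
  if (k == 1) {
    side <- matrix(cmu, 1)
  } else if (k == 2) {
    d <- rnorm(3); d <- 0.8 * d / sqrt(sum(d^2))
    side <- rbind(cmu + d, cmu - d)
  } else {
    d1 <- rnorm(3) * 0.6; d2 <- rnorm(3) * 0.6
    side <- rbind(cmu + d1, cmu + d2, cmu - d1 - d2)
  }
  tibble(chain = chain, resno = resno, insert = "", res_id = res_id,
         elety = c("CA", c("CB", "CG", "CD")[seq_len(k)]),
         is_side = c(FALSE, rep(TRUE, k)),
         x = c(cmu[1] + ca_off[1], side[, 1]),
         y = c(cmu[2] + ca_off[2], side[, 2]),
         z = c(cmu[3] + ca_off[3], side[, 3]))
}

#' Generate a synthetic toy antibody-antigen complex
#'
#' Places `n_paratope` antibody residues (split between a heavy and a light
#' chain) in a rough plane and `n_epitope` antigen residues facing them at the
#' given separation, plus `n_scaffold` non-interface antigen residues so the
#' antigen passes the 50-residue curation rule. In `"matched"` mode the
#' epitope layout mirrors the paratope and charged residues face their
#' opposite charge; in `"mismatched"` mode the epitope layout and composition
#' are drawn independently. Deterministic given `seed`.
#'
#' @param n_paratope,n_epitope Interface residue counts (at least 3 each).
#' @param n_scaffold Additional non-interface antigen residues.
#' @param separation Mean inter-patch distance, Angstrom (4-6 recommended;
#'   pairs stay within the 6-Angstrom contact rule).
#' @param mode `"matched"` or `"mismatched"`.
#' @param jitter In-plane standard deviation of the matched epitope layout,
#'   Angstrom.
#' @param seed Integer seed.
#' @param id Complex identifier.
#' @return An `abag_complex`.
#' @export
generate_toy_complex <- function(n_paratope = 10, n_epitope = n_paratope,
                                 n_scaffold = 45, separation = 5,
                                 mode = c("matched", "mismatched"),
                                 jitter = 0.25, seed = 1,
                                 id = sprintf("toy%d", seed)) {
  mode <- match.arg(mode)
  if (n_paratope < 3 || n_epitope < 3) {
    abort("toy complexes need at least 3 residues per side")
  }
  set.seed(as.integer(seed))

  lay_p <- .toy_layout(n_paratope)
  z_p <- runif(n_paratope, -1.2, 1.2)
  aa_p <- sample(.TOY_AA_POOL, n_paratope, replace = TRUE, prob = .TOY_AA_WT)

  if (mode == "matched") {
    base <- c(seq_len(min(n_paratope, n_epitope)),
              if (n_epitope > n_paratope)
                sample(n_paratope, n_epitope - n_paratope, replace = TRUE))
    lay_e <- lay_p[base, , drop = FALSE] +
      matrix(rnorm(2 * n_epitope, sd = jitter), ncol = 2)
    z_e <- z_p[base] + separation + runif(n_epitope, -0.6, 0.6)
    aa_e <- .complement_aa(aa_p[base])
  } else {
    lay_e <- .toy_layout(n_epitope)
    z_e <- separation + runif(n_epitope, -0.6, 0.6)
    aa_e <- sample(.TOY_AA_POOL, n_epitope, replace = TRUE, prob = .TOY_AA_WT)
  }

  # non-interface antigen scaffold, well beyond the contact cutoff
  sc_r <- 15 * sqrt(runif(n_scaffold))
  sc_t <- runif(n_scaffold, 0, 2 * pi)
  lay_s <- cbind(sc_r * cos(sc_t), sc_r * sin(sc_t))
  z_s <- separation + runif(n_scaffold, 9, 28)
  aa_s <- sample(.TOY_AA_POOL, n_scaffold, replace = TRUE)

  n_h <- ceiling(n_paratope / 2)
  chain <- c(rep("H", n_h), rep("L", n_paratope - n_h),
             rep("A", n_epitope + n_scaffold))
  resno <- c(seq_len(n_h), seq_len(n_paratope - n_h),
             seq_len(n_epitope + n_scaffold))
  role <- c(rep("heavy", n_h), rep("light", n_paratope - n_h),
            rep("antigen", n_epitope + n_scaffold))
  aa <- c(aa_p, aa_e, aa_s)
  cmu <- rbind(cbind(lay_p, z_p), cbind(lay_e, z_e), cbind(lay_s, z_s))
  res_id <- paste0(chain, ":", resno)

  atoms <- bind_rows(purrr::map(seq_along(aa), function(i) {
    .toy_atoms_for(res_id[i], chain[i], resno[i], aa[i], cmu[i, ])
  }))
  atoms$role <- role[match(atoms$res_id, res_id)]

  residues <- tibble(
    chain = chain, resno = resno, insert = "", res_id = res_id,
    resid = bio3d::aa123(aa), aa = aa, role = role,
    n_side = vapply(res_id, function(r)
      sum(atoms$is_side[atoms$res_id == r]), 0L),
    cmu_x = cmu[, 1], cmu_y = cmu[, 2], cmu_z = cmu[, 3]
  )
  structure(list(id = id, residues = residues,
                 atoms = atoms[, c("chain", "resno", "insert", "res_id",
                                   "elety", "role", "is_side",
                                   "x", "y", "z")],
                 cdr = NULL, n_unk = 0L),
            class = "abag_complex")
}

#' Write a complex as PDB text
#'
#' @param x An `abag_complex`.
#' @param path Optional output file; when `NULL` the PDB lines are returned.
#' @return The path (invisibly) or a character vector of PDB lines.
#' @export
as_pdb <- function(x, path = NULL) {
  stopifnot(inherits(x, "abag_complex"))
  at <- x$atoms
  ord <- order(match(at$chain, unique(at$chain)), at$resno,
               !grepl("^CA$", at$elety))
  at <- at[ord, ]
  resid3 <- x$residues$resid[match(at$res_id, x$residues$res_id)]
  out <- if (is.null(path)) tempfile(fileext = ".pdb") else path
  bio3d::write.pdb(file = out,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, chain = at$chain, resid = resid3,
                   elety = at$elety)
  if (is.null(path)) {
    lines <- readLines(out, warn = FALSE)
    unlink(out)
    lines
  } else {
    invisible(out)
  }
}

#' Generate a synthetic labelled image-pair task
#'
#' Builds `n_complexes` matched toy complexes, curates them through the
#' standard pipeline, images every kept complex, constructs positives and
#' negatives (per positive: `ratio` each of non-cognate, rotated and
#' translated negatives, drawn within one side of the train/test split) and
#' tensorises everything. The result feeds the trainer directly.
#'
#' @param n_complexes Number of toy complexes (at least 20).
#' @param seed Master seed: drives complex generation, the split plan and all
#'   negative-sample draws.
#' @param config An [imaging_config()] (the 64-pixel default keeps desk-scale
#'   training fast).
#' @param ratio Negatives of each kind per positive.
#' @param n_folds Cross-validation folds in the split plan.
#' @param toy Named list of extra arguments for [generate_toy_complex()].
#' @return An `epipair_dataset`: list with `pairs` (per-complex
#'   `image_pair`s), `X` (`(H*W) x 6 x N` tensor array), `manifest` (tibble:
#'   sample_id, complex_id, partner_id, label, provenance, angle, du, dv,
#'   split, fold), `plan` (a `split_plan`), `config`.
#' @export
generate_image_task <- function(n_complexes = 100, seed = 7,
                                config = imaging_config(size = 64L),
                                ratio = 1L, n_folds = 10L, toy = list()) {
  if (n_complexes < 20) abort("image tasks need at least 20 complexes")
  complexes <- purrr::map(seq_len(n_complexes), function(i) {
    do.call(generate_toy_complex,
            c(list(seed = as.integer(seed) + 7919L * i,
                   id = sprintf("toy%03d", i), mode = "matched"), toy))
  })
  report <- curate_complexes(complexes)
  kept <- report$id[report$status == "kept"]
  complexes <- purrr::keep(complexes, ~ .x$id %in% kept)
  ids <- vapply(complexes, `[[`, "", "id")

  plan <- build_splits(ids, test_frac = 0.2, n_folds = n_folds, seed = seed)
  side_of <- setNames(tidy(plan)$split, tidy(plan)$complex_id)
  fold_of <- setNames(tidy(plan)$fold, tidy(plan)$complex_id)

  pairs <- purrr::map(complexes, imagify_complex, config = config)
  names(pairs) <- ids

  angles <- setdiff(seq(-150, 180, by = 30), seq(-30, 30, by = 30))
  set.seed(as.integer(seed) + 1L)
  samples <- list()
  rows <- list()
  for (cid in ids) {
    pair <- pairs[[cid]]
    add <- function(s, sid, partner = NA_character_, angle = NA_real_,
                    du = NA_real_, dv = NA_real_) {
      samples[[sid]] <<- s
      rows[[sid]] <<- tibble(
        sample_id = sid, complex_id = cid, partner_id = partner,
        label = s$label, provenance = s$provenance, angle = angle,
        du = du, dv = dv, split = unname(side_of[cid]),
        fold = unname(fold_of[cid])
      )
    }
    add(make_positive(pair), paste0(cid, "_pos"))
    same_side <- setdiff(ids[side_of[ids] == side_of[cid]], cid)
    for (r in seq_len(ratio)) {
      partner <- sample(same_side, 1)
      add(make_noncognate(pair, pairs[[partner]]),
          sprintf("%s_non%d", cid, r), partner = partner)
      ang <- sample(angles, 1)
      add(make_rotated(pair, ang), sprintf("%s_rot%d", cid, r), angle = ang)
      th <- runif(1, 0, 2 * pi); mag <- runif(1, 8, 12)
      du <- mag * cos(th); dv <- mag * sin(th)
      add(make_translated(pair, du, dv), sprintf("%s_tra%d", cid, r),
          du = du, dv = dv)
    }
  }
  manifest <- bind_rows(rows)
  hw <- config$size^2
  X <- array(0, dim = c(hw, 6, nrow(manifest)))
  for (i in seq_len(nrow(manifest))) {
    X[, , i] <- matrix(pair_tensor(samples[[manifest$sample_id[i]]]),
                       nrow = hw, ncol = 6)
  }
  structure(list(pairs = pairs, X = X, manifest = manifest, plan = plan,
                 config = config),
            class = "epipair_dataset")
}

#' @export
print.epipair_dataset <- function(x, ...) {
  cat("<epipair_dataset> ", length(x$pairs), " complexes, ",
      nrow(x$manifest), " samples (", sum(x$manifest$label == 1),
      " positive), image size ", x$config$size, "\n", sep = "")
  invisible(x)
}

#' Tensor array of a dataset
#' @param ds An `epipair_dataset`.
#' @return `(H*W) x 6 x N` numeric array aligned with `ds$manifest`.
#' @export
dataset_tensors <- function(ds) ds$X

#' Per-fold sample indices of a dataset
#'
#' Maps the complex-level folds of the split plan to row indices of the
#' sample manifest (train-side samples only).
#'
#' @param ds An `epipair_dataset`.
#' @param folds Which folds (default all).
#' @return List of lists with integer vectors `subtrain` and `validation`.
#' @export
dataset_fold_indices <- function(ds, folds = seq_len(ds$plan$n_folds)) {
  m <- ds$manifest
  lapply(folds, function(f) {
    list(subtrain = which(m$split == "train" & m$fold != f),
         validation = which(m$split == "train" & m$fold == f))
  })
}

#' Write dataset images and manifest to disk
#'
#' @param ds An `epipair_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  m <- ds$manifest
  hw <- ds$config$size^2
  paths <- purrr::map_chr(seq_len(nrow(m)), function(i) {
    img <- array(ds$X[, , i], dim = c(ds$config$size, ds$config$size, 6))
    p <- file.path(dir, "images", paste0(m$sample_id[i], ".png"))
    # store the pair as a side-by-side 8-bit RGB strip
    png::writePNG(abind_channels(img), p)
    p
  })
  m$image_path <- paths
  out <- file.path(dir, "manifest.tsv")
  utils::write.table(m, out, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(train = ds$plan$train, test = ds$plan$test,
         folds = ds$plan$folds, seed = ds$plan$seed),
    file.path(dir, "split_plan.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out)
}

# 6-channel tensor -> side-by-side RGB strip for PNG export
abind_channels <- function(x) {
  H <- dim(x)[1]
  out <- array(0, dim = c(H, 2 * dim(x)[2], 3))
  out[, seq_len(dim(x)[2]), ] <- x[, , 1:3]
  out[, dim(x)[2] + seq_len(dim(x)[2]), ] <- x[, , 4:6]
  out
}
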