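# Desk-scale synthetic benchmark: the package's reproducible end-to-end
# experiment. A 100-complex matched toy task (64x64 images, 1:1:1
# non-cognate/rotated/translated negatives) is trained on a single
# cross-validation fold and evaluated on the held-out complexes; the trained
# model then drives the screening and pose-rescoring experiments.

#' Training configuration for the synthetic benchmark
#'
#' A short schedule sized for the easy, cleanly separable synthetic task:
#' a slightly higher learning rate and few epochs with tight early stopping.
#' Real-data training should start from [net_config()] instead.
#'
#' @return A [net_config()].
#' @export
benchmark_net_config <- function() {
  net_config(lr = 2e-3, max_epochs = 16L, early_patience = 4L,
             plateau_patience = 3L)
}

#' Run the synthetic end-to-end discrimination benchmark
#'
#' Generates the labelled image task, trains one cross-validation fold on the
#' training side and evaluates on the held-out test complexes.
#'
#' @param seed Master seed for data generation and training.
#' @param n_complexes Toy complexes in the task.
#' @param net Training configuration.
#' @param imaging Imaging configuration.
#' @param fold Which cross-validation fold to train.
#' @param verbose Print training progress.
#' @return List of class `epipair_benchmark`: `dataset`, `model` (an
#'   `epipair_ensemble` with one fold), `metrics` (held-out
#'   [evaluate_scores()] row), `scores` (per-test-sample tibble).
#' @export
run_synthetic_benchmark <- function(seed = 7, n_complexes = 100,
                                    net = benchmark_net_config(),
                                    imaging = imaging_config(size = 64L),
                                    fold = 1L, verbose = FALSE) {
  ds <- generate_image_task(n_complexes, seed = seed, config = imaging)
  fi <- dataset_fold_indices(ds, fold)[[1]]
  trained <- train_fold(ds$X, ds$manifest$label, fi$subtrain, fi$validation,
                        net, seed = seed + 1, verbose = verbose)
  model <- structure(list(folds = list(trained), config = net, seed = seed),
                     class = "epipair_ensemble")
  test_idx <- which(ds$manifest$split == "test")
  sc <- ensemble_score(model, ds$X[, , test_idx])
  structure(list(
    dataset = ds, model = model,
    metrics = evaluate_scores(sc, ds$manifest$label[test_idx]),
    scores = tibble(sample_id = ds$manifest$sample_id[test_idx],
                    label = ds$manifest$label[test_idx], score = sc)
  ), class = "epipair_benchmark")
}

#' @export
print.epipair_benchmark <- function(x, ...) {
  cat("<epipair_benchmark> held-out metrics:\n")
  print(x$metrics)
  invisible(x)
}

#' Screening self-retrieval experiment
#'
#' For each repeat, a held-out complex is chosen as target; its epitope is
#' screened against a library of `library_size` paratopes (the cognate one
#' plus decoys drawn from the other complexes). Success means the cognate
#' paratope ranks in the top `top_frac` of the library by max-over-rotation
#' score.
#'
#' @param bench An [run_synthetic_benchmark()] result.
#' @param n_repeats Seeded repeats.
#' @param library_size Paratopes per library.
#' @param top_frac Success bound on the cognate rank.
#' @param seed Seed for target/decoy draws.
#' @return Tibble: `repeat`, `target`, `cognate_rank`, `success`,
#'   `score0_consistent` (zero-angle score equals the plain ensemble score).
#' @export
run_screen_benchmark <- function(bench, n_repeats = 10, library_size = 50,
                                 top_frac = 0.1, seed = 1) {
  ds <- bench$dataset
  ids <- names(ds$pairs)
  test_ids <- tidy(ds$plan)$complex_id[tidy(ds$plan)$split == "test"]
  set.seed(as.integer(seed))
  rows <- purrr::map(seq_len(n_repeats), function(r) {
    target <- sample(test_ids, 1)
    decoys <- sample(setdiff(ids, target), library_size - 1)
    lib <- c(
      setNames(list(ds$pairs[[target]]$paratope), target),
      setNames(purrr::map(decoys, ~ ds$pairs[[.x]]$paratope), decoys)
    )
    res <- screen_library(ds$pairs[[target]], lib, bench$model)
    rank <- res$rank[res$paratope_id == target]
    plain <- ensemble_score(bench$model, pair_tensor(ds$pairs[[target]]))
    tibble(
      rep = r, target = target, cognate_rank = rank,
      success = rank <= ceiling(top_frac * library_size),
      score0_consistent =
        isTRUE(all.equal(res$score_0[res$paratope_id == target], plain,
                         tolerance = 0))
    )
  })
  bind_rows(rows)
}

#' Rotate the antigen of a complex about the interface axis
#'
#' Produces an incorrect docking pose: the antigen chains are rotated by
#' `angle_deg` about the axis joining the paratope and epitope centroids,
#' through their midpoint. The antibody is left untouched.
#'
#' @param x An `abag_complex`.
#' @param angle_deg Rotation angle in degrees.
#' @return The perturbed complex (id suffixed with the angle).
#' @export
make_decoy_pose <- function(x, angle_deg) {
  iface <- find_interface(x)
  p_ctr <- unname(attr(iface$epitope, "partner_centroid"))
  e_ctr <- unname(attr(iface$paratope, "partner_centroid"))
  axis <- e_ctr - p_ctr
  axis <- axis / sqrt(sum(axis^2))
  ctr <- (p_ctr + e_ctr) / 2
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)  # Rodrigues
  rot <- function(m) sweep(sweep(m, 2, ctr) %*% t(R), 2, -ctr)
  sel <- x$residues$role == "antigen"
  cm <- rot(as.matrix(x$residues[sel, c("cmu_x", "cmu_y", "cmu_z")]))
  x$residues$cmu_x[sel] <- cm[, 1]
  x$residues$cmu_y[sel] <- cm[, 2]
  x$residues$cmu_z[sel] <- cm[, 3]
  sel_a <- x$atoms$role == "antigen"
  am <- rot(as.matrix(x$atoms[sel_a, c("x", "y", "z")]))
  x$atoms$x[sel_a] <- am[, 1]
  x$atoms$y[sel_a] <- am[, 2]
  x$atoms$z[sel_a] <- am[, 3]
  x$id <- paste0(x$id, "_rot", angle_deg)
  x
}

#' Pose-rescoring experiment on synthetic decoys
#'
#' For `n_complexes` held-out complexes, the unperturbed cognate structure is
#' the near-native pose and `n_decoys` rotated placements (angles of at least
#' 60 degrees about the interface axis) are the incorrect poses; all are
#' imaged and scored by the benchmark model and the near-native rank is
#' recorded.
#'
#' @param bench An [run_synthetic_benchmark()] result.
#' @param n_complexes Held-out complexes to rescore.
#' @param n_decoys Decoy poses per complex.
#' @param seed Seed for decoy angle draws.
#' @return List with the [rescore_poses()] table, the per-complex summary and
#'   `average_rank`.
#' @export
run_rescore_benchmark <- function(bench, n_complexes = 10, n_decoys = 11,
                                  seed = 1) {
  ds <- bench$dataset
  test_ids <- tidy(ds$plan)$complex_id[tidy(ds$plan)$split == "test"]
  ids <- utils::head(test_ids, n_complexes)
  set.seed(as.integer(seed))
  poses <- bind_rows(purrr::map(ids, function(cid) {
    # regenerate the toy complex backing this id
    idx <- as.integer(sub("toy", "", cid))
    cx <- generate_toy_complex(seed = as.integer(ds$plan$seed) + 7919L * idx,
                               id = cid)
    angles <- sample(setdiff(seq(60, 300, by = 20), 0), n_decoys)
    bind_rows(
      tibble(complex_id = cid, pose_id = paste0(cid, "_native"),
             near_native = TRUE, record = list(cx)),
      bind_rows(purrr::map(angles, function(a) {
        tibble(complex_id = cid, pose_id = sprintf("%s_d%03d", cid, a),
               near_native = FALSE, record = list(make_decoy_pose(cx, a)))
      }))
    )
  }))
  scored <- rescore_poses(poses, bench$model, ds$config)
  sm <- summarise_rescore(scored)
  c(list(scores = scored), sm)
}
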