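# Positive/negative sample construction and the stratified split plan.
#
# A cognate complex gives the positive sample; negatives are built from
# cognate material by (i) pairing non-cognate paratopes and epitopes,
# (ii) rotating the epitope image by a multiple of 30 degrees with magnitude
# at least 60 (smaller rotations are treated as still-binding by the
# screening binder rule), and (iii) translating it by at least 8 Angstrom
# (larger than a typical residue circle, so the pose is unambiguously wrong).

.ROT_MIN <- 60
.TRANS_MIN <- 8

.new_sample <- function(paratope, epitope, label, provenance, meta = list()) {
  structure(list(paratope = paratope, epitope = epitope, label = label,
                 provenance = provenance, meta = meta),
            class = "sample_pair")
}

#' Positive (cognate) sample from a complex
#'
#' @param pair An `image_pair` from [imagify_complex()] (or an `abag_complex`,
#'   which is imaged with `config`).
#' @param config Imaging configuration used when `pair` is a complex.
#' @return A `sample_pair` with label 1 and provenance `"cognate"`.
#' @export
make_positive <- function(pair, config = imaging_config()) {
  if (inherits(pair, "abag_complex")) pair <- imagify_complex(pair, config)
  .new_sample(pair$paratope, pair$epitope, 1L, "cognate",
              list(complex_id = pair$complex_id))
}

#' Non-cognate negative sample
#'
#' Pairs the paratope image of one complex with the epitope image of another;
#' both images are the complexes' native renders, unchanged.
#'
#' @param pair_a,pair_b `image_pair`s of two different complexes.
#' @return A `sample_pair` with label 0.
#' @export
make_noncognate <- function(pair_a, pair_b) {
  if (identical(pair_a$complex_id, pair_b$complex_id)) {
    abort("non-cognate pairing requires two different complexes")
  }
  .new_sample(pair_a$paratope, pair_b$epitope, 0L,
              "noncognate",
              list(complex_id = pair_a$complex_id,
                   partner_id = pair_b$complex_id))
}

#' Rotated negative sample
#'
#' Re-renders the epitope with an extra in-plane rotation. Angles must be
#' multiples of 30 degrees with magnitude at least 60 (and not equivalent to
#' 0), so the negative can never duplicate the positive.
#'
#' @param pair An `image_pair`.
#' @param angle_deg Rotation in degrees.
#' @return A `sample_pair` with label 0.
#' @export
make_rotated <- function(pair, angle_deg) {
  a <- angle_deg %% 360
  if (angle_deg %% 30 != 0 || a == 0 || min(a, 360 - a) < .ROT_MIN) {
    abort(paste0("rotation angle must be a multiple of 30 with |angle| >= ",
                 .ROT_MIN, " degrees"))
  }
  .new_sample(pair$paratope, rerender_epitope(pair, rotation = angle_deg),
              0L, "rotated",
              list(complex_id = pair$complex_id, angle = angle_deg))
}

#' Translated negative sample
#'
#' Re-renders the epitope displaced by `(du, dv)`; the displacement magnitude
#' must be at least 8 Angstrom.
#'
#' @param pair An `image_pair`.
#' @param du,dv Displacement in Angstrom.
#' @return A `sample_pair` with label 0.
#' @export
make_translated <- function(pair, du, dv) {
  if (sqrt(du^2 + dv^2) < .TRANS_MIN) {
    abort(paste0("translation magnitude must be >= ", .TRANS_MIN,
                 " Angstrom"))
  }
  .new_sample(pair$paratope,
              rerender_epitope(pair, translation = c(du, dv)),
              0L, "translated",
              list(complex_id = pair$complex_id, du = du, dv = dv))
}

#' Build the stratified train/test and cross-validation split plan
#'
#' Complexes are shuffled and split 80/20 into train and test; the train side
#' is partitioned into `n_folds` folds, fold `i` serving as the validation
#' set of cross-validation round `i` (90/10 subtrain/validation with the
#' default 10 folds). Samples inherit the assignment of their paratope-source
#' complex, so a constant per-complex negative:positive ratio keeps every
#' fold stratified exactly.
#'
#' @param ids Complex identifiers (at least 10).
#' @param test_frac Fraction of complexes held out for testing.
#' @param n_folds Number of cross-validation folds.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `split_plan`: list with `train`, `test`, `folds` (each a list
#'   with `subtrain` and `validation` id vectors), `seed`, `n_folds`.
#' @export
build_splits <- function(ids, test_frac = 0.2, n_folds = 10L, seed = 1) {
  ids <- as.character(ids)
  if (length(ids) < 10) abort("need at least 10 complexes to build splits")
  if (anyDuplicated(ids)) abort("complex ids must be unique")
  set.seed(as.integer(seed))
  shuffled <- sample(ids)
  n_test <- round(length(ids) * test_frac)
  test <- sort(shuffled[seq_len(n_test)])
  train <- shuffled[-seq_len(n_test)]
  if (length(train) < n_folds) {
    abort("too few complexes for the requested number of folds")
  }
  fold_of <- rep(seq_len(n_folds), length.out = length(train))
  folds <- lapply(seq_len(n_folds), function(f) {
    list(subtrain = sort(train[fold_of != f]),
         validation = sort(train[fold_of == f]))
  })
  structure(list(train = sort(train), test = test, folds = folds,
                 fold_of = setNames(fold_of, train),
                 seed = seed, n_folds = n_folds, test_frac = test_frac),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> ", length(x$train), " train / ", length(x$test),
      " test complexes, ", x$n_folds, " folds (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Split plan as a tibble
#'
#' @param x A `split_plan`.
#' @param ... Unused.
#' @return Tibble: `complex_id`, `split` (`"train"`/`"test"`), `fold`
#'   (validation fold of train complexes, `NA` for test).
#' @method tidy split_plan
#' @export
tidy.split_plan <- function(x, ...) {
  bind_rows(
    tibble(complex_id = names(x$fold_of), split = "train",
           fold = as.integer(x$fold_of)),
    tibble(complex_id = x$test, split = "test", fold = NA_integer_)
  ) %>% arrange(.data$complex_id)
}
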