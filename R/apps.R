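# End-to-end drivers: docking-pose rescoring and rotation-sweep paratope
# library screening.

#' Rescore docking poses with a model ensemble
#'
#' Every pose is imaged through the standard pipeline and scored by the
#' ensemble; per complex, poses are ranked by descending score (ties broken
#' deterministically by pose id) and the rank of the near-native pose is the
#' quantity of interest. A pose with no interface under the contact rule is
#' assigned score 0 and ends in the worst tied rank, with a log message.
#'
#' @param poses Tibble with columns `complex_id`, `pose_id`, `near_native`
#'   (logical; exactly one `TRUE` per complex) and either a `record`
#'   list-column of `abag_complex` objects or `pdb_path` plus `heavy_chain`,
#'   `light_chain`, `antigen_chains` columns.
#' @param model An `epipair_ensemble` (or single fold).
#' @param config An [imaging_config()].
#' @return Tibble: `complex_id`, `pose_id`, `near_native`, `score`, `rank`.
#' @export
rescore_poses <- function(poses, model, config = imaging_config()) {
  stopifnot(all(c("complex_id", "pose_id", "near_native") %in% names(poses)))
  bad <- poses %>% group_by(.data$complex_id) %>%
    summarise(k = sum(.data$near_native)) %>% filter(.data$k != 1)
  if (nrow(bad) > 0) {
    abort("each complex must flag exactly one near-native pose")
  }
  score_one <- function(i) {
    rec <- if ("record" %in% names(poses)) poses$record[[i]] else {
      parse_complex(
        poses$pdb_path[i],
        chains = list(heavy = poses$heavy_chain[i],
                      light = poses$light_chain[i],
                      antigen = strsplit(poses$antigen_chains[i], ",")[[1]]),
        id = poses$pose_id[i]
      )
    }
    tryCatch({
      pair <- imagify_complex(rec, config)
      ensemble_score(model, pair_tensor(pair))
    }, error = function(e) {
      message("pose ", poses$pose_id[i], " has no scorable interface (",
              conditionMessage(e), "); score set to 0")
      0
    })
  }
  out <- poses %>%
    select("complex_id", "pose_id", "near_native") %>%
    mutate(score = vapply(seq_len(nrow(poses)), score_one, 0)) %>%
    group_by(.data$complex_id) %>%
    arrange(desc(.data$score), .data$pose_id, .by_group = TRUE) %>%
    mutate(rank = row_number()) %>%
    ungroup() %>%
    arrange(.data$complex_id, .data$rank)
  out
}

#' Summarise a rescoring run
#'
#' @param scores Output of [rescore_poses()].
#' @return List with `per_complex` (tibble: complex_id, near-native rank,
#'   number of poses) and `average_rank` (mean near-native rank).
#' @export
summarise_rescore <- function(scores) {
  per <- scores %>%
    group_by(.data$complex_id) %>%
    summarise(near_native_rank = .data$rank[.data$near_native],
              n_poses = n(), .groups = "drop")
  list(per_complex = per, average_rank = mean(per$near_native_rank))
}

#' Screen a paratope library against a target epitope
#'
#' The epitope is re-rendered at the 12 rotations that are multiples of 30
#' degrees; every (paratope, rotated epitope) pair is scored by the ensemble.
#' A paratope is a binder if its score at 0, +30 and -30 degrees all reach
#' the threshold; the library is ranked by `rank_metric` (max over the 12
#' angle scores by default, mean via `metric = "mean"`).
#'
#' @param epitope An `image_pair` whose epitope is the screening target
#'   ([imagify_complex()] output; its projected epitope points are rotated in
#'   coordinate space, so no pixel interpolation occurs).
#' @param library Named list of paratope `patch_image`s (names are paratope
#'   ids), or a list of `image_pair`s (their paratope images are used).
#' @param model An `epipair_ensemble` (or single fold).
#' @param tau Binder threshold.
#' @param metric `"max"` or `"mean"` over the angle scores.
#' @return A `screen_result` tibble, ranked: `paratope_id`, `rank`,
#'   `rank_metric`, `binder`, and one `score_<angle>` column per rotation.
#' @export
screen_library <- function(epitope, library, model, tau = 0.5,
                           metric = c("max", "mean")) {
  metric <- match.arg(metric)
  if (length(library) == 0) abort("paratope library is empty")
  if (is.null(names(library)) || any(!nzchar(names(library)))) {
    abort("library entries must be named by paratope id")
  }
  angles <- seq(0, 330, by = 30)
  size <- epitope$config$size
  epi_imgs <- purrr::map(angles, function(a) rerender_epitope(epitope, a))

  rows <- purrr::imap(library, function(entry, pid) {
    pimg <- if (inherits(entry, "image_pair")) entry$paratope else entry
    if (!is.array(pimg) || !identical(dim(pimg)[1:2], c(size, size))) {
      message("library entry ", pid, " unreadable or mis-sized; skipped")
      return(NULL)
    }
    sc <- vapply(epi_imgs, function(ei) {
      ensemble_score(model, pair_tensor(list(paratope = pimg, epitope = ei)))
    }, 0)
    row <- tibble(paratope_id = pid,
                  rank_metric = if (metric == "max") max(sc) else mean(sc),
                  binder = sc[angles == 0] >= tau &
                    sc[angles == 30] >= tau & sc[angles == 330] >= tau)
    for (j in seq_along(angles)) {
      row[[paste0("score_", angles[j])]] <- sc[j]
    }
    row
  })
  out <- bind_rows(purrr::compact(rows)) %>%
    arrange(desc(.data$rank_metric), .data$paratope_id) %>%
    mutate(rank = row_number()) %>%
    select("paratope_id", "rank", "rank_metric", "binder",
           dplyr::everything())
  structure(out, class = c("screen_result", class(out)))
}
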