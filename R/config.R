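# YAML-backed configuration for the command-line workflow.

#' Default pipeline configuration
#'
#' @return Nested list with `imaging` (see [imaging_config()]), `net`
#'   (see [net_config()]) and `sampling` (`ratio`, `test_frac`, `n_folds`)
#'   sections.
#' @export
default_config <- function() {
  list(
    imaging = unclass(imaging_config()),
    net = unclass(net_config()),
    sampling = list(ratio = 1L, test_frac = 0.2, n_folds = 10L)
  )
}

#' Load a YAML configuration
#'
#' Values from the file override the defaults section-wise; unknown keys are
#' rejected.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return As [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) abort(paste0("unknown config section: ", sec))
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]])) {
        abort(paste0("unknown config key: ", sec, ".", key))
      }
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  cfg
}

#' Build the typed config objects from a config list
#'
#' @param cfg A list as returned by [load_config()].
#' @return List with `imaging` ([imaging_config()]) and `net`
#'   ([net_config()]) objects plus the `sampling` list.
#' @export
materialise_config <- function(cfg) {
  list(
    imaging = do.call(imaging_config, cfg$imaging),
    net = do.call(net_config, cfg$net),
    sampling = cfg$sampling
  )
}
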