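# Run configuration: a single YAML/JSON document (plus a global seed) fully
# determines a pipeline run.  Component seeds are derived from the global
# seed with derive_seed(), so each stage can be replayed independently.

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "copnet-out",
    data_dir = NULL,            # where manifest.csv lives; default out_dir
    log_level = "info",
    tasks = c("T1", "T2", "T3", "T4"),
    methods = c("MSRC"),
    store_features = FALSE,
    sway = list(preset = "easy"),
    windowing = list(n_in = 200L, stride = 100L, standardize = TRUE),
    model = list(),             # overrides passed to model_spec()
    train = list()              # overrides passed to train_config()
  )
}

merge_checked <- function(base, user, where) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L) {
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
  }
  base[names(user)] <- user
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration file, fills in defaults, and
#' rejects unknown keys.  `overrides` (e.g. from command-line flags) are
#' applied last.
#'
#' @param path Optional path to a `.yaml`/`.yml`/`.json` file.
#' @param overrides Named list of top-level overrides.
#' @return A validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  user <- list()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
  }
  for (u in list(user, overrides)) {
    if (length(u) == 0L) next
    nested <- intersect(names(u), c("sway", "windowing", "model", "train"))
    flat <- setdiff(names(u), nested)
    cfg <- merge_checked(cfg, u[flat], "top level")
    for (sec in nested) {
      known <- switch(sec,
        sway = setdiff(names(formals(sway_params)), "seed"),
        windowing = c("n_in", "stride", "standardize"),
        model = setdiff(names(formals(model_spec)), "kind"),
        train = setdiff(names(formals(train_config)), "seed")
      )
      unknown <- setdiff(names(u[[sec]]), known)
      if (length(unknown) > 0L) {
        stop("unknown config key(s) in section '", sec, "': ",
             paste(unknown, collapse = ", "))
      }
      cfg[[sec]][names(u[[sec]])] <- u[[sec]]
    }
  }
  bad_tasks <- setdiff(cfg$tasks, names(cop_tasks()))
  if (length(bad_tasks) > 0L) {
    stop("invalid task name(s): ", paste(bad_tasks, collapse = ", "),
         "; valid tasks are ", paste(names(cop_tasks()), collapse = ", "))
  }
  valid_methods <- c("MSRC", "NN", "DNN", "DSCNN", "WORES")
  bad_methods <- setdiff(cfg$methods, valid_methods)
  if (length(bad_methods) > 0L) {
    stop("invalid method(s): ", paste(bad_methods, collapse = ", "),
         "; valid methods are ", paste(valid_methods, collapse = ", "))
  }
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$data_dir)) cfg$data_dir <- cfg$out_dir
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' Round-trips with [load_run_config()].
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a dataset manifest and its recordings
#'
#' The manifest is a CSV with columns `subject_id, level, path, fs`; paths
#' are resolved relative to the manifest's directory.
#'
#' @param path Path to `manifest.csv`.
#' @return Named list of [cop_recording()].
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "level", "path", "fs")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  base <- dirname(path)
  recs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_recording(p, man$subject_id[i], man$level[i], man$fs[i])
  })
  names(recs) <- man$subject_id
  recs
}
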