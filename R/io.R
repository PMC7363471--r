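#' Write / read a trajectory as wide CSV
#'
#' Columns: `time` followed by one column per region (the mixed output).
#' State variables are not serialised; re-simulate from the recorded
#' configuration if they are needed.
#'
#' @param traj an `ii_trajectory`.
#' @param path CSV path.
#' @return `read_trajectory()` returns a tibble (`time` + regions);
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$time, traj$output, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Run configuration: serialise and restore
#'
#' A run configuration bundles everything needed to reproduce a simulation:
#' scenario, integration settings, coupling, forward-model settings and the
#' seed. It round-trips losslessly through JSON (or YAML when the `yaml`
#' package is available).
#'
#' @param scenario scenario name (see [build_epi_map()]).
#' @param config an [integration_config()].
#' @param coupling an [coupling_parameters()].
#' @param tr repetition time in seconds.
#' @param gain neural-to-BOLD gain.
#' @return `run_config()` returns a list of class `ii_run_config`.
#' @export
run_config <- function(scenario = "spike_free",
                       config = integration_config(),
                       coupling = coupling_parameters(), tr = 3.6,
                       gain = 0.1) {
  structure(list(scenario = scenario, config = unclass(config),
                 coupling = unclass(coupling), tr = tr, gain = gain),
            class = "ii_run_config")
}

#' @rdname run_config
#' @param rc an `ii_run_config`.
#' @param path output path; format chosen by extension (`.json` or
#'   `.yaml`/`.yml`).
#' @export
write_run_config <- function(rc, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("the yaml package is required for YAML output")
    yaml::write_yaml(unclass(rc), path)
  } else {
    jsonlite::write_json(unclass(rc), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("the yaml package is required for YAML input")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  rc <- run_config()
  for (nm in names(raw)) {
    if (nm %in% c("config", "coupling")) {
      for (k in names(raw[[nm]])) rc[[nm]][[k]] <- raw[[nm]][[k]]
    } else rc[[nm]] <- raw[[nm]]
  }
  rc$config$keep_every <- as.integer(rc$config$keep_every)
  rc$config$seed <- as.integer(rc$config$seed)
  class(rc$config) <- "ii_config"
  class(rc$coupling) <- "ii_coupling"
  rc
}
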