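#' Read and write trial logs
#'
#' Trial logs are UTF-8 comma-separated files with a header row, no row
#' index, the exact [generate_session()] column names, and 0-based trial
#' indices within each session. Writing then reading then writing again is
#' byte-identical.
#'
#' @param trials A `prl_session`, [prl_cohort()] or trial data frame.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns a trial data frame.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "prl_cohort")) trials <- trials$trials
  df <- as.data.frame(trials)
  df$misleading <- as.logical(df$misleading)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  df$misleading <- as.logical(df$misleading)
  df
}

#' Write a machine-readable run log
#'
#' Records the command, seed, settings and package version of a run as
#' JSON next to its outputs.
#'
#' @param path Output file.
#' @param command Command label.
#' @param seed Integer seed used.
#' @param settings Named list of settings.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, command, seed, settings = list()) {
  log <- list(command = command, seed = seed, settings = settings,
              package = "revlearn",
              version = as.character(utils::packageVersion("revlearn")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

read_yaml_config <- function(path) {
  if (is.null(path)) return(list())
  yaml::read_yaml(path)
}

task_config_from_list <- function(x) {
  defaults <- task_config()
  keep <- intersect(names(x), c("n_runs", "sequences_per_run",
                                "criterion_min", "criterion_max",
                                "p_misleading", "max_trials_per_run",
                                "rng_seed"))
  do.call(task_config, utils::modifyList(
    defaults[c("n_runs", "sequences_per_run", "criterion_min",
               "criterion_max", "p_misleading", "max_trials_per_run")],
    x[keep]))
}
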