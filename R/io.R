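#' Write / read a design as CSV + JSON
#'
#' The trial list goes to CSV (columns `index`, `phase`, `length_class`,
#' `n_pairs`, `sequence` with space-separated syllables, `label`,
#' `foil_subset`, `repeat_probe`, `grammar_of_sequence`, `test_position`);
#' the configuration (experiment, group, seed, all counts) goes to JSON.
#' `read_design()` reassembles an `agl_design` and checks the schema.
#'
#' @param design An `agl_design`.
#' @param trials_path Path for the trial CSV.
#' @param config_path Path for the config JSON.
#' @return `write_design` returns the paths invisibly; `read_design`
#'   returns an `agl_design`.
#' @export
write_design <- function(design, trials_path, config_path) {
  stopifnot(inherits(design, "agl_design"))
  utils::write.csv(design$trials, trials_path, row.names = FALSE,
                   quote = FALSE)
  cfg <- design$config
  jsonlite::write_json(
    list(experiment = design$experiment, group = design$group,
         seed = design$seed,
         learning_per_length = cfg$learning_per_length,
         test_per_length_per_label = cfg$test_per_length_per_label,
         test_correct = cfg$test_correct,
         foils_per_subset = cfg$foils_per_subset,
         repeat_probe_rate = cfg$repeat_probe_rate,
         lengths = as.list(cfg$lengths)),
    config_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(trials = trials_path, config = config_path))
}

#' @rdname write_design
#' @export
read_design <- function(trials_path, config_path) {
  cfg_json <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  need <- c("experiment", "group", "seed")
  miss <- setdiff(need, names(cfg_json))
  if (length(miss)) {
    stop("config JSON missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  config <- agl_config(
    experiment = cfg_json$experiment,
    learning_per_length = cfg_json$learning_per_length,
    test_per_length_per_label = cfg_json$test_per_length_per_label,
    test_correct = cfg_json$test_correct,
    foils_per_subset = cfg_json$foils_per_subset,
    repeat_probe_rate = cfg_json$repeat_probe_rate,
    lengths = unlist(cfg_json$lengths)
  )
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  cols <- c("index", "phase", "length_class", "n_pairs", "sequence",
            "label", "foil_subset", "repeat_probe", "grammar_of_sequence",
            "test_position")
  miss <- setdiff(cols, names(trials))
  if (length(miss)) {
    stop("trials CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  trials <- trials[cols]
  trials$repeat_probe <- as.logical(trials$repeat_probe)
  trials$test_position <- suppressWarnings(as.integer(trials$test_position))
  structure(
    list(experiment = as.integer(cfg_json$experiment),
         group = match_dependency(cfg_json$group),
         seed = as.integer(cfg_json$seed),
         config = config, trials = trials),
    class = "agl_design"
  )
}

#' Write / read response logs as CSV
#'
#' One row per (participant, test trial): columns `participant_id`,
#' `group`, `policy`, `position`, `trial_index`, `answer` ("yes"/"no").
#' Reading validates the schema and reports the first offending row on
#' malformed answers.
#'
#' @param logs Response-log data frame.
#' @param path CSV path.
#' @return `read_responses` returns the log data frame (empty file gives an
#'   empty data frame with a warning); `write_responses` returns `path`
#'   invisibly.
#' @export
write_responses <- function(logs, path) {
  utils::write.csv(logs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  logs <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("participant_id", "group", "policy", "position", "trial_index",
            "answer")
  if (nrow(logs) == 0L) {
    warning("empty response log: ", path, call. = FALSE)
    return(stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols))
  }
  miss <- setdiff(cols, names(logs))
  if (length(miss)) {
    stop("response CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!logs$answer %in% c("yes", "no"))
  if (length(bad)) {
    stop("malformed answer at row ", bad[1], " of ", path,
         " (must be 'yes' or 'no')", call. = FALSE)
  }
  logs[cols]
}

#' Serialize an analysis report to JSON
#'
#' Writes the full report (per-participant measures, group tests, ANOVA
#' tables, strategy diagnostics) as structured JSON, and optionally the
#' per-participant measures as a flat CSV.
#'
#' @param report An `agl_report`.
#' @param path JSON path.
#' @param measures_path Optional CSV path for per-participant measures.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, measures_path = NULL) {
  stopifnot(inherits(report, "agl_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  if (!is.null(measures_path)) {
    utils::write.csv(report$participants, measures_path, row.names = FALSE)
  }
  invisible(path)
}
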