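#' Read and write trial-level data
#'
#' Trials travel as UTF-8 CSV with a mandatory header and columns
#' `participant_id, block, trial_in_block, cue, congruency, target_identity,
#' target_location, foil_location, is_catch, rt_ms, correct`. An empty
#' `rt_ms` cell encodes a withheld response (catch trials). Columns beyond
#' the mandatory set are preserved and returned alongside the records.
#'
#' @param path file path.
#' @return `read_trials()` returns the trial data.frame; any extra columns
#'   are kept and their names recorded in the `"extra_columns"` attribute.
#' @export
read_trials <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  mandatory <- c("participant_id", "block", "trial_in_block", "cue",
                 "congruency", "target_identity", "target_location",
                 "foil_location", "is_catch", "rt_ms", "correct")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing))
    stop_domain("trial file is missing mandatory column(s): ",
                paste(missing, collapse = ", "))
  num <- function(col) {
    v <- raw[[col]]
    v[v == ""] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop_domain("non-numeric ", col, " at row ", bad[1],
                  " (value \"", v[bad[1]], "\")")
    out
  }
  out <- data.frame(
    participant_id = raw$participant_id,
    block = as.integer(num("block")),
    trial_in_block = as.integer(num("trial_in_block")),
    cue = raw$cue,
    congruency = raw$congruency,
    target_identity = ifelse(raw$target_identity == "", NA_character_,
                             raw$target_identity),
    target_location = as.integer(num("target_location")),
    foil_location = as.integer(num("foil_location")),
    is_catch = as.logical(num_or_logical(raw$is_catch)),
    rt_ms = num("rt_ms"),
    correct = as.logical(num_or_logical(raw$correct)),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(raw), mandatory)
  for (e in extra) out[[e]] <- raw[[e]]
  attr(out, "extra_columns") <- extra
  out
}

num_or_logical <- function(v) {
  v[v == ""] <- NA
  ifelse(toupper(v) %in% c("TRUE", "T", "1"), TRUE,
         ifelse(toupper(v) %in% c("FALSE", "F", "0"), FALSE, NA))
}

#' @rdname read_trials
#' @param trials a trial data.frame as produced by [build_schedule()] or
#'   [generate_cohort()].
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_trials
#' @export
read_gaze <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "trial_index", "t_ms", "x_norm", "y_norm")
  missing <- setdiff(need, names(g))
  if (length(missing))
    stop_domain("gaze file is missing column(s): ",
                paste(missing, collapse = ", "))
  g
}
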