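# JSON-lines serialization of experiment logs: one JSON object per line.
# Line types: "meta" (participant id + arm), "event" (one answer record) and
# "proficiency" (per-phase snapshot of the engine's proficiency levels).

#' Write an experiment log as JSON-lines
#'
#' One JSON object per line: a `meta` line, then one `event` line per answer
#' record (with the choice set as a JSON array) and one `proficiency` line
#' per phase snapshot.
#'
#' @param log an `experiment_log`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "experiment_log"))
  ev <- log$events
  lines <- character(1L + nrow(ev) + length(unique(log$proficiency$phase)))
  lines[1L] <- jsonlite::toJSON(list(type = "meta",
                                     participant_id = log$participant_id,
                                     arm = log$arm), auto_unbox = TRUE)
  for (i in seq_len(nrow(ev))) {
    lines[1L + i] <- jsonlite::toJSON(list(
      type = "event", phase = ev$phase[i], module = ev$module[i],
      time_days = ev$time_days[i], item_index = ev$item_index[i],
      correct_abbrev = ev$correct[i],
      choice_abbrevs = strsplit(ev$choices[i], "|", fixed = TRUE)[[1L]],
      selected_abbrev = ev$selected[i], is_correct = ev$is_correct[i]),
      auto_unbox = TRUE, digits = I(17))  # 17 sig. digits: lossless doubles
  }
  off <- 1L + nrow(ev)
  for (ph in unique(log$proficiency$phase)) {
    snap <- log$proficiency[log$proficiency$phase == ph, , drop = FALSE]
    off <- off + 1L
    lines[off] <- jsonlite::toJSON(list(
      type = "proficiency", phase = ph,
      levels = as.list(stats::setNames(snap$level, snap$abbreviation))),
      auto_unbox = TRUE)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an experiment log from JSON-lines
#'
#' Inverse of [write_log()]. A malformed line raises an error naming the file
#' and line number.
#'
#' @param path path to a `.jsonl` log file.
#' @return An `experiment_log`.
#' @export
read_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty log file: ", path, call. = FALSE)
  objs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    objs[[i]] <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        stop("corrupt log line: ", path, " line ", i, ": ",
             conditionMessage(e), call. = FALSE)
      })
    if (is.null(objs[[i]]$type)) {
      stop("corrupt log line: ", path, " line ", i, ": missing 'type' field",
           call. = FALSE)
    }
  }
  types <- vapply(objs, function(o) o$type, character(1))
  meta <- objs[[which(types == "meta")[1L]]]
  if (is.null(meta)) stop("log has no meta line: ", path, call. = FALSE)
  evs <- objs[types == "event"]
  events <- data.frame(
    phase = vapply(evs, function(o) o$phase, character(1)),
    module = vapply(evs, function(o) o$module, character(1)),
    time_days = vapply(evs, function(o) as.numeric(o$time_days), numeric(1)),
    item_index = vapply(evs, function(o) as.integer(o$item_index), integer(1)),
    correct = vapply(evs, function(o) o$correct_abbrev, character(1)),
    choices = vapply(evs, function(o) paste(o$choice_abbrevs, collapse = "|"),
                     character(1)),
    selected = vapply(evs, function(o) o$selected_abbrev, character(1)),
    is_correct = vapply(evs, function(o) isTRUE(o$is_correct), logical(1)),
    stringsAsFactors = FALSE)
  profs <- objs[types == "proficiency"]
  proficiency <- do.call(rbind, lapply(profs, function(o) {
    data.frame(phase = o$phase, abbreviation = names(o$levels),
               level = as.integer(unlist(o$levels)), stringsAsFactors = FALSE)
  }))
  structure(list(participant_id = as.integer(meta$participant_id),
                 arm = meta$arm, events = events, proficiency = proficiency),
            class = "experiment_log")
}

#' Write a list of experiment logs to a directory
#'
#' Files are named `participant_<id>.jsonl`.
#'
#' @param logs list of `experiment_log`s.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_logs <- function(logs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (log in logs) {
    write_log(log, file.path(dir, sprintf("participant_%03d.jsonl",
                                          log$participant_id)))
  }
  invisible(dir)
}

#' Read all experiment logs from a directory
#'
#' @param dir directory containing `.jsonl` files written by [write_logs()].
#' @return List of `experiment_log`s, in file-name order.
#' @export
read_logs <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.jsonl$", full.names = TRUE))
  if (!length(files)) {
    stop("no .jsonl log files found in ", dir, call. = FALSE)
  }
  lapply(files, read_log)
}
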