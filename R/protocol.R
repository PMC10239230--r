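# Experiment schedule runner: pretest on day 0, 50-question training days on
# days 1-2 and 4-5, midterm on day 3, posttest on day 6 and a delayed test on
# day 20 (elapsed-day convention with the pretest as day 0). Tests present
# every catalog species once, with the whole catalog as the choice set, and
# give no feedback; training items come from the quiz engine and do give
# feedback.

#' Default experiment schedule
#'
#' @return Data frame with columns `phase`, `day` (elapsed days, pretest = 0)
#'   and `type` (`"test"` or `"training"`).
#' @export
default_schedule <- function() {
  data.frame(
    phase = c("pretest", "training1", "training2", "midterm",
              "training3", "training4", "posttest", "delayed"),
    day = c(0, 1, 2, 3, 4, 5, 6, 20),
    type = c("test", "training", "training", "test",
             "training", "training", "test", "test"),
    stringsAsFactors = FALSE
  )
}

#' Protocol configuration
#'
#' @param schedule ordered phase table as in [default_schedule()]; day
#'   offsets must be strictly increasing.
#' @param questions_per_training_day training items per training day,
#'   default 50.
#' @param session_duration length of one training session in days over which
#'   item timestamps are evenly spaced; default 0.02 days (about 30 minutes).
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(schedule = default_schedule(),
                            questions_per_training_day = 50L,
                            session_duration = 0.02) {
  questions_per_training_day <- as.integer(questions_per_training_day)
  stopifnot(is.data.frame(schedule),
            all(c("phase", "day", "type") %in% names(schedule)),
            all(schedule$type %in% c("test", "training")),
            !is.unsorted(schedule$day, strictly = TRUE),
            !anyDuplicated(schedule$phase),
            questions_per_training_day >= 1L,
            session_duration >= 0)
  structure(list(schedule = schedule,
                 questions_per_training_day = questions_per_training_day,
                 session_duration = session_duration),
            class = "protocol_config")
}

# Deterministic, 32-bit-safe per-participant seed (exact in doubles for any
# plausible master seed and id).
participant_seed <- function(master_seed, participant_id) {
  as.integer((as.numeric(master_seed) %% 2147483647 * 1000003 +
                as.numeric(participant_id) * 7919) %% 2147483647)
}

#' Run one test module
#'
#' Presents every catalog species once, in uniformly shuffled order; the
#' choice set of every item is the whole catalog. No proficiency update and,
#' unless the learner config sets `test_feedback = TRUE`, no memory update:
#' correct answers are withheld until after the delayed test.
#'
#' @param learner a `learner_state`.
#' @param catalog a `species_catalog`.
#' @param phase phase label recorded on the events.
#' @param time test time in days (all items share it).
#' @return List with `records` (one `AnswerRecord` data frame row per
#'   species: `phase`, `module`, `time_days`, `item_index`, `correct`,
#'   `choices` (pipe-separated), `selected`, `is_correct`) and the (possibly
#'   updated) `learner`.
#' @export
run_test <- function(learner, catalog, phase, time) {
  ab <- species_abbrevs(catalog)
  ord <- ab[sample.int(length(ab))]
  selected <- character(length(ord))
  for (i in seq_along(ord)) {
    item <- structure(list(correct = ord[i], distracters = setdiff(ab, ord[i]),
                           presented_order = ab, item_index = i, time = time),
                      class = "quiz_item")
    selected[i] <- answer_item(learner, item, time)
    if (learner$config$test_feedback) {
      learner <- observe_feedback(learner, item, time)
    }
  }
  records <- data.frame(phase = phase, module = "test", time_days = time,
                        item_index = seq_along(ord), correct = ord,
                        choices = paste(ab, collapse = "|"),
                        selected = selected, is_correct = selected == ord,
                        stringsAsFactors = FALSE)
  list(records = records, learner = learner)
}

#' Run one training day
#'
#' Generates `questions_per_training_day` items with [next_item()], answers
#' each with [answer_item()], updates proficiency with [update_proficiency()]
#' and applies [observe_feedback()] (the answer screen reveals the correct
#' species, so every item is an exposure). Item timestamps are evenly spaced
#' across `session_duration` starting at the day offset.
#'
#' @param state named integer proficiency vector.
#' @param learner a `learner_state`.
#' @param catalog a `species_catalog`.
#' @param config an [engine_config()].
#' @param protocol a [protocol_config()].
#' @param phase phase label recorded on the events.
#' @param day day offset of the session start.
#' @param start_index global training question number of the first item.
#' @return List with `records` (as in [run_test()] with `module =
#'   "training"`), updated `state` and `learner`.
#' @export
run_training_day <- function(state, learner, catalog, config, protocol,
                             phase, day, start_index = 1L) {
  n <- protocol$questions_per_training_day
  times <- if (n == 1L) day else
    day + (seq_len(n) - 1) * (protocol$session_duration / (n - 1))
  correct <- selected <- choices <- character(n)
  for (q in seq_len(n)) {
    item <- next_item(state, catalog, config,
                      item_index = start_index + q - 1L, time = times[q])
    sel <- answer_item(learner, item, times[q])
    state <- update_proficiency(state, item$correct, sel)
    learner <- observe_feedback(learner, item, times[q])
    correct[q] <- item$correct
    selected[q] <- sel
    choices[q] <- paste(item$presented_order, collapse = "|")
  }
  records <- data.frame(phase = phase, module = "training", time_days = times,
                        item_index = start_index + seq_len(n) - 1L,
                        correct = correct, choices = choices,
                        selected = selected, is_correct = selected == correct,
                        stringsAsFactors = FALSE)
  list(records = records, state = state, learner = learner)
}

#' Run one simulated participant through the full protocol
#'
#' Executes the configured schedule (default: pretest, two training days,
#' midterm, two training days, posttest, delayed test) with a single RNG
#' stream seeded from `(master_seed, participant_id)`, so a run is fully
#' reproducible and the pretest is identical across arms for the same
#' participant id.
#'
#' @param arm `"adaptive"` or `"baseline"`; sets the engine mode.
#' @param catalog a `species_catalog`.
#' @param learner_config a [learner_config()] (`NULL` = defaults).
#' @param protocol a [protocol_config()] (`NULL` = defaults).
#' @param engine an [engine_config()] whose `mode` is overridden by `arm`
#'   (`NULL` = defaults).
#' @param participant_id integer participant identifier.
#' @param master_seed integer master seed of the experiment.
#' @return An `experiment_log`: list with `participant_id`, `arm`, `events`
#'   (all answer records in time order; training items carry the global
#'   training question number 1..200 in `item_index`, test items their
#'   position within the test) and `proficiency` (long data frame of
#'   engine-proficiency snapshots taken after each phase).
#' @export
run_participant <- function(arm = c("adaptive", "baseline"),
                            catalog = builtin_catalog(),
                            learner_config = NULL,
                            protocol = NULL,
                            engine = NULL,
                            participant_id = 1L,
                            master_seed = 1L) {
  arm <- match.arg(arm)
  if (is.null(learner_config)) learner_config <- birdquiz::learner_config()
  if (is.null(protocol)) protocol <- birdquiz::protocol_config()
  if (is.null(engine)) engine <- birdquiz::engine_config()
  engine$mode <- arm

  set.seed(participant_seed(master_seed, participant_id))
  state <- new_proficiency(catalog)
  learner <- new_learner(catalog, learner_config)

  sched <- protocol$schedule
  events <- vector("list", nrow(sched))
  snapshots <- vector("list", nrow(sched))
  train_index <- 1L
  for (i in seq_len(nrow(sched))) {
    if (sched$type[i] == "test") {
      res <- run_test(learner, catalog, sched$phase[i], sched$day[i])
      learner <- res$learner
    } else {
      res <- run_training_day(state, learner, catalog, engine, protocol,
                              sched$phase[i], sched$day[i], train_index)
      state <- res$state
      learner <- res$learner
      train_index <- train_index + protocol$questions_per_training_day
    }
    events[[i]] <- res$records
    snapshots[[i]] <- data.frame(phase = sched$phase[i],
                                 abbreviation = names(state),
                                 level = unname(state),
                                 stringsAsFactors = FALSE)
  }
  structure(list(participant_id = as.integer(participant_id), arm = arm,
                 events = do.call(rbind, events),
                 proficiency = do.call(rbind, snapshots)),
            class = "experiment_log")
}

#' Run a two-arm simulated cohort
#'
#' Participants `1..n_per_arm` are assigned to the adaptive arm and
#' `n_per_arm + 1 .. 2 * n_per_arm` to the baseline arm, each with an
#' independent RNG stream derived from `master_seed`.
#'
#' @inheritParams run_participant
#' @param n_per_arm participants per arm.
#' @param verbose print progress every 10 participants.
#' @return List of `2 * n_per_arm` `experiment_log`s.
#' @export
run_cohort <- function(n_per_arm, catalog = builtin_catalog(),
                       learner_config = NULL, protocol = NULL, engine = NULL,
                       master_seed = 1L, verbose = FALSE) {
  stopifnot(n_per_arm >= 1L)
  ids <- seq_len(2L * n_per_arm)
  arms <- rep(c("adaptive", "baseline"), each = n_per_arm)
  logs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    logs[[i]] <- run_participant(arms[i], catalog, learner_config, protocol,
                                 engine, participant_id = ids[i],
                                 master_seed = master_seed)
    if (verbose && i %% 10L == 0L) {
      message("simulated ", i, "/", length(ids), " participants")
    }
  }
  logs
}

#' @export
print.experiment_log <- function(x, ...) {
  cat("experiment_log: participant ", x$participant_id, " (", x$arm, "), ",
      nrow(x$events), " events over ", length(unique(x$events$phase)),
      " phases\n", sep = "")
  invisible(x)
}
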