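# Derived explanatory variables and outcome summaries computed from
# experiment logs alone: test scores, per-species training question counts,
# inverse lag time (1/days between the last training exposure and a test),
# median question interval (in training-question units), per-species accuracy
# with binomial SE, confusion matrices, and a permutation test for the
# adaptive-vs-baseline arm contrast.

phase_time <- function(log, phase) {
  rows <- log$events$phase == phase
  if (!any(rows)) {
    stop("phase not found in log: ", phase, call. = FALSE)
  }
  min(log$events$time_days[rows])
}

#' Test scores of one participant
#'
#' The score of a test phase is the number of correct answers; the maximum is
#' the catalog size (one item per species).
#'
#' @param log an `experiment_log`.
#' @param phase a test phase name, or `NULL` for a named vector over all test
#'   phases present in the log.
#' @return Integer score, or named integer vector.
#' @export
test_scores <- function(log, phase = NULL) {
  ev <- log$events
  if (is.null(phase)) {
    phases <- unique(ev$phase[ev$module == "test"])
    return(vapply(phases, function(p) test_scores(log, p), integer(1)))
  }
  rows <- ev$phase == phase & ev$module == "test"
  if (!any(rows)) {
    stop("test phase not found in log: ", phase, call. = FALSE)
  }
  sum(ev$is_correct[rows])
}

#' Number of training questions on a species
#'
#' Counts training items whose correct choice is the species, optionally only
#' those asked before a given phase.
#'
#' @param log an `experiment_log`.
#' @param species a species abbreviation.
#' @param upto_phase optional phase name; only training items with timestamps
#'   strictly before that phase's time are counted.
#' @return Non-negative integer count.
#' @export
training_question_count <- function(log, species, upto_phase = NULL) {
  ev <- log$events
  rows <- ev$module == "training" & ev$correct == species
  if (!is.null(upto_phase)) {
    rows <- rows & ev$time_days < phase_time(log, upto_phase)
  }
  sum(rows)
}

#' Inverse lag time of a species at a test
#'
#' The reciprocal of the time (days) between a species' last appearance as a
#' training correct choice and the test. A species never trained before the
#' test has no lag: the value is `NA`, not zero (zero would fabricate an
#' infinite lag).
#'
#' @param log an `experiment_log`.
#' @param species a species abbreviation.
#' @param test_phase a test phase name.
#' @return Rate in 1/days, or `NA_real_` when the species was never a
#'   training correct choice before the test.
#' @export
inverse_lag_time <- function(log, species, test_phase = "posttest") {
  t_test <- phase_time(log, test_phase)
  ev <- log$events
  rows <- ev$module == "training" & ev$correct == species &
    ev$time_days < t_test
  if (!any(rows)) return(NA_real_)
  1 / (t_test - max(ev$time_days[rows]))
}

#' Median question interval of a species
#'
#' Median of the successive differences of the global training question
#' numbers at which the species was the correct choice, in question units
#' (back-to-back occurrences have interval 1). Needs at least two
#' occurrences; otherwise `NA`.
#'
#' @param log an `experiment_log`.
#' @param species a species abbreviation.
#' @return Median interval in questions, or `NA_real_`.
#' @export
median_question_interval <- function(log, species) {
  ev <- log$events
  idx <- sort(ev$item_index[ev$module == "training" & ev$correct == species])
  if (length(idx) < 2L) return(NA_real_)
  stats::median(diff(idx))
}

#' Per-species training metrics of one participant
#'
#' Convenience table of the three derived explanatory variables for every
#' species: training question count (before `test_phase`), inverse lag time
#' at `test_phase` and median question interval.
#'
#' @param log an `experiment_log`.
#' @param test_phase reference test phase, default `"posttest"`.
#' @return Data frame with one row per species.
#' @export
species_metrics <- function(log, test_phase = "posttest") {
  species <- unique(log$proficiency$abbreviation)
  data.frame(
    participant_id = log$participant_id,
    arm = log$arm,
    species = species,
    n_training_questions = vapply(species, function(s)
      training_question_count(log, s, upto_phase = test_phase), integer(1)),
    inverse_lag = vapply(species, function(s)
      inverse_lag_time(log, s, test_phase), numeric(1)),
    median_question_interval = vapply(species, function(s)
      median_question_interval(log, s), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-species accuracy at a test, across participants
#'
#' @param logs list of `experiment_log`s.
#' @param species a species abbreviation.
#' @param test_phase a test phase name.
#' @param arm optional arm filter (`"adaptive"`/`"baseline"`).
#' @return List with `accuracy` (proportion correct), `se`
#'   (`sqrt(p*(1-p)/n)`) and `n` (participants).
#' @export
species_accuracy <- function(logs, species, test_phase = "posttest",
                             arm = NULL) {
  if (!is.null(arm)) {
    logs <- Filter(function(l) l$arm == arm, logs)
  }
  if (!length(logs)) stop("no logs", if (!is.null(arm)) paste0(" in arm ", arm),
                          call. = FALSE)
  x <- vapply(logs, function(l) {
    ev <- l$events
    row <- ev$phase == test_phase & ev$module == "test" & ev$correct == species
    if (!any(row)) stop("species ", species, " not tested in phase ",
                        test_phase, call. = FALSE)
    ev$is_correct[row][1L]
  }, logical(1))
  p <- mean(x)
  list(accuracy = p, se = sqrt(p * (1 - p) / length(x)), n = length(x))
}

#' Confusion matrix of a test phase
#'
#' Entry `(i, j)` counts test items with correct species `i` answered as
#' species `j`; every row sums to the number of participants (each test asks
#' each species exactly once).
#'
#' @param logs list of `experiment_log`s.
#' @param test_phase a test phase name.
#' @param arm optional arm filter.
#' @param catalog optional `species_catalog` fixing the row/column order;
#'   default is the species order of the first log's snapshots.
#' @return Integer matrix with species abbreviations as dimnames.
#' @export
confusion_matrix <- function(logs, test_phase = "posttest", arm = NULL,
                             catalog = NULL) {
  if (!is.null(arm)) logs <- Filter(function(l) l$arm == arm, logs)
  if (!length(logs)) stop("no logs to tabulate", call. = FALSE)
  species <- if (!is.null(catalog)) species_abbrevs(catalog) else
    unique(logs[[1L]]$proficiency$abbreviation)
  m <- matrix(0L, length(species), length(species),
              dimnames = list(correct = species, selected = species))
  for (l in logs) {
    ev <- l$events
    rows <- ev$phase == test_phase & ev$module == "test"
    if (!any(rows)) stop("phase not found in log ", l$participant_id, ": ",
                         test_phase, call. = FALSE)
    for (i in which(rows)) {
      m[ev$correct[i], ev$selected[i]] <- m[ev$correct[i], ev$selected[i]] + 1L
    }
  }
  m
}

#' Permutation test for a difference in group means
#'
#' Two-sided Monte-Carlo permutation test of the difference in means under
#' random relabeling; the add-one estimator guarantees
#' `p >= 1 / (n_perm + 1)`.
#'
#' @param scores_a,scores_b numeric score vectors of the two groups.
#' @param n_perm number of label permutations, default 10000 (>= 100).
#' @return P-value in `(0, 1]`.
#' @export
permutation_arm_test <- function(scores_a, scores_b, n_perm = 10000L) {
  stopifnot(length(scores_a) >= 1L, length(scores_b) >= 1L, n_perm >= 100L)
  obs <- mean(scores_a) - mean(scores_b)
  pool <- c(scores_a, scores_b)
  na <- length(scores_a)
  idx <- seq_along(pool)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    pick <- sample.int(length(pool), na)
    d <- mean(pool[pick]) - mean(pool[setdiff(idx, pick)])
    if (abs(d) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Per-arm score summary of a cohort
#'
#' @param logs list of `experiment_log`s.
#' @return Data frame with one row per participant and test phase
#'   (`participant_id`, `arm`, `phase`, `score`).
#' @export
score_table <- function(logs) {
  do.call(rbind, lapply(logs, function(l) {
    sc <- test_scores(l)
    data.frame(participant_id = l$participant_id, arm = l$arm,
               phase = names(sc), score = unname(sc),
               stringsAsFactors = FALSE)
  }))
}

#' Mean and SE of test scores by arm and phase
#'
#' @param logs list of `experiment_log`s.
#' @return Data frame with `arm`, `phase`, `n`, `mean_score`, `se`.
#' @export
summarize_scores <- function(logs) {
  tab <- score_table(logs)
  out <- do.call(rbind, lapply(split(tab, list(tab$arm, tab$phase), drop = TRUE),
    function(g) {
      data.frame(arm = g$arm[1L], phase = g$phase[1L], n = nrow(g),
                 mean_score = mean(g$score),
                 se = stats::sd(g$score) / sqrt(nrow(g)),
                 stringsAsFactors = FALSE)
    }))
  phases <- unique(tab$phase)
  out <- out[order(match(out$phase, phases), out$arm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export metrics CSVs from a set of logs
#'
#' Writes `scores.csv` (participant, arm, phase, score),
#' `species_metrics.csv` (per participant and species: question count,
#' inverse lag, median question interval at the posttest),
#' `species_accuracy.csv` (per arm, phase and species: accuracy and SE) and
#' one `confusion_<phase>.csv` per test phase (long format: arm, correct,
#' selected, count). All UTF-8 with headers.
#'
#' @param logs list of `experiment_log`s.
#' @param dir output directory (created if missing).
#' @param catalog optional `species_catalog` fixing species order.
#' @return The directory, invisibly.
#' @export
export_metrics <- function(logs, dir, catalog = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(score_table(logs), file.path(dir, "scores.csv"),
                   row.names = FALSE)
  has_post <- any(logs[[1L]]$events$phase == "posttest")
  ref_phase <- if (has_post) "posttest" else
    utils::tail(unique(logs[[1L]]$events$phase[logs[[1L]]$events$module == "test"]), 1L)
  sm <- do.call(rbind, lapply(logs, species_metrics, test_phase = ref_phase))
  utils::write.csv(sm, file.path(dir, "species_metrics.csv"),
                   row.names = FALSE)
  arms <- unique(vapply(logs, function(l) l$arm, character(1)))
  test_phases <- unique(logs[[1L]]$events$phase[logs[[1L]]$events$module == "test"])
  species <- if (!is.null(catalog)) species_abbrevs(catalog) else
    unique(logs[[1L]]$proficiency$abbreviation)
  acc <- do.call(rbind, lapply(test_phases, function(ph) {
    do.call(rbind, lapply(arms, function(a) {
      do.call(rbind, lapply(species, function(s) {
        r <- species_accuracy(logs, s, ph, arm = a)
        data.frame(arm = a, phase = ph, species = s, accuracy = r$accuracy,
                   se = r$se, n = r$n, stringsAsFactors = FALSE)
      }))
    }))
  }))
  utils::write.csv(acc, file.path(dir, "species_accuracy.csv"),
                   row.names = FALSE)
  for (ph in test_phases) {
    long <- do.call(rbind, lapply(arms, function(a) {
      m <- confusion_matrix(logs, ph, arm = a, catalog = catalog)
      data.frame(arm = a,
                 correct = rep(rownames(m), times = ncol(m)),
                 selected = rep(colnames(m), each = nrow(m)),
                 count = as.vector(m), stringsAsFactors = FALSE)
    }))
    utils::write.csv(long, file.path(dir, paste0("confusion_", ph, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
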