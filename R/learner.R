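# Simulated trainee with half-life memory dynamics: recall probability decays
# as 2^(-dt/h) since the last exposure, and each feedback exposure multiplies
# the half-life by 1 + (alpha - 1) * (1 - r)^beta, where r is the recall
# probability at exposure time. Larger gaps (lower r) consolidate more — the
# spacing effect; back-to-back exposures (r near 1) consolidate almost
# nothing. Guessing is confused toward species with similar songs.

#' Learner simulator configuration
#'
#' @param initial_half_life `h0`, baseline retention half-life in days before
#'   any consolidation (the first exposure multiplies it by
#'   `consolidation_gain`); default 0.02 days, about half an hour — a fresh,
#'   fragile memory trace.
#' @param consolidation_gain `alpha > 1`, maximum multiplicative half-life
#'   gain per exposure (attained when recall probability has decayed to 0);
#'   default 4.
#' @param spacing_exponent `beta` in `[0, 1]`, curvature of the
#'   spacing benefit `(1 - r)^beta`; default 0.5.
#' @param similarity_confusion_weight `gamma >= 1`, guessing weight put on
#'   species whose song is similar to the correct one, relative to weight 1
#'   for every other choice; default 3.
#' @param test_feedback should test items update the memory state? Default
#'   `FALSE`: tests expose without feedback, mirroring a protocol in which
#'   correct answers are withheld until after the delayed test.
#' @return A `learner_config` list.
#' @export
learner_config <- function(initial_half_life = 0.02,
                           consolidation_gain = 4,
                           spacing_exponent = 0.5,
                           similarity_confusion_weight = 3,
                           test_feedback = FALSE) {
  stopifnot(initial_half_life > 0, consolidation_gain > 1,
            spacing_exponent >= 0, spacing_exponent <= 1,
            similarity_confusion_weight >= 1,
            is.logical(test_feedback))
  structure(list(initial_half_life = initial_half_life,
                 consolidation_gain = consolidation_gain,
                 spacing_exponent = spacing_exponent,
                 similarity_confusion_weight = similarity_confusion_weight,
                 test_feedback = test_feedback),
            class = "learner_config")
}

#' Create a naive simulated learner
#'
#' @param catalog a `species_catalog`.
#' @param config a [learner_config()].
#' @return A `learner_state`: per-species half-life (days), last exposure
#'   time (days, `NA` if never exposed), exposure count, plus the catalog's
#'   similarity map used for confused guessing.
#' @export
new_learner <- function(catalog, config = learner_config()) {
  ab <- species_abbrevs(catalog)
  sim_map <- lapply(ab, function(a) similar_species(catalog, a)$similar_abbrev)
  names(sim_map) <- ab
  structure(list(config = config,
                 half_life = stats::setNames(rep(config$initial_half_life,
                                                 length(ab)), ab),
                 last_exposure = stats::setNames(rep(NA_real_, length(ab)), ab),
                 exposures = stats::setNames(integer(length(ab)), ab),
                 similar = sim_map),
            class = "learner_state")
}

#' Recall probability of a species at a given time
#'
#' Never-exposed species have recall probability 0. Otherwise recall decays
#' exponentially: `2^(-dt / half_life)` with `dt` the days since the last
#' exposure.
#'
#' @param learner a `learner_state`.
#' @param species a species abbreviation.
#' @param time current time in days.
#' @return A probability in `[0, 1]`.
#' @export
#' @examples
#' l <- new_learner(builtin_catalog())
#' recall_prob(l, "Hyam", 3) # never exposed: 0
recall_prob <- function(learner, species, time) {
  stopifnot(species %in% names(learner$exposures))
  if (learner$exposures[[species]] == 0L) return(0)
  dt <- time - learner$last_exposure[[species]]
  if (dt < 0) {
    stop("recall queried at time ", time, ", before last exposure of ",
         species, " at ", learner$last_exposure[[species]], call. = FALSE)
  }
  2^(-dt / learner$half_life[[species]])
}

#' Answer a quiz item as the simulated learner
#'
#' With probability [recall_prob()] of the correct species the learner
#' answers correctly. Otherwise it guesses among the presented choices with
#' weight `similarity_confusion_weight` on species whose song is similar to
#' the correct one and weight 1 elsewhere (the correct species stays in the
#' guess pool at weight 1, so a recall failure can still produce a lucky hit).
#'
#' @param learner a `learner_state`.
#' @param item a `quiz_item` (its `presented_order` is the choice set).
#' @param time answer time in days.
#' @return The selected species abbreviation.
#' @export
answer_item <- function(learner, item, time) {
  r <- recall_prob(learner, item$correct, time)
  if (stats::runif(1L) < r) return(item$correct)
  choices <- item$presented_order
  w <- rep(1, length(choices))
  w[choices %in% learner$similar[[item$correct]]] <-
    learner$config$similarity_confusion_weight
  w[choices == item$correct] <- 1
  choices[sample.int(length(choices), 1L, prob = w)]
}

#' Apply feedback from a training exposure
#'
#' Training items end with the correct answer revealed, so each one is an
#' exposure to the correct species regardless of the answer given. The
#' half-life is multiplied by `1 + (alpha - 1) * (1 - r)^beta` where `r` is
#' the recall probability at exposure time (`r = 0` on the first exposure,
#' giving the maximal boost), then the exposure is recorded. The boost is
#' monotone decreasing in `r`: longer gaps consolidate more.
#'
#' @param learner a `learner_state`.
#' @param item the `quiz_item` just answered.
#' @param time exposure time in days.
#' @return The updated `learner_state`.
#' @export
observe_feedback <- function(learner, item, time) {
  sp <- item$correct
  r <- if (learner$exposures[[sp]] == 0L) 0 else recall_prob(learner, sp, time)
  cfg <- learner$config
  boost <- 1 + (cfg$consolidation_gain - 1) * (1 - r)^cfg$spacing_exponent
  learner$half_life[[sp]] <- learner$half_life[[sp]] * boost
  learner$exposures[[sp]] <- learner$exposures[[sp]] + 1L
  learner$last_exposure[[sp]] <- time
  learner
}

#' @export
print.learner_state <- function(x, ...) {
  cat("learner_state: ", sum(x$exposures > 0), "/", length(x$exposures),
      " species exposed; median half-life ",
      format(stats::median(x$half_life)), " days\n", sep = "")
  invisible(x)
}
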