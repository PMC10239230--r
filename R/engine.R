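# Adaptive and baseline quiz item generators plus the proficiency bookkeeping
# that drives them. Proficiency is a per-species non-negative integer: +1 when
# the species is answered correctly as the correct choice, -1 (floored at 0)
# on both the correct species and the wrongly selected distracter otherwise.
# A species is "mastered" once its level reaches the mastery threshold
# (default 3, i.e. level > 2); mastered species mostly leave the question pool
# but return for review with probability P = p * w*N_u / (N_u + w*N_m).

#' Quiz engine configuration
#'
#' @param mode `"adaptive"` (proficiency-driven selection) or `"baseline"`
#'   (uniformly random correct choice and distracters).
#' @param n_choices choices per item, one correct plus `n_choices - 1`
#'   distracters. Default 5.
#' @param max_review_probability cap `p` of the review mechanism, default 0.25.
#' @param review_weight weight `w` of the review mechanism, default 0.5.
#' @param mastery_threshold a species is mastered when its proficiency level
#'   reaches this value; default 3 (i.e. mastered means level > 2).
#' @param review_numerator which numerator the review-probability formula
#'   uses: `"printed"` gives `p*w*N_u / (N_u + w*N_m)` (the published form,
#'   under which review vanishes as every species is mastered);
#'   `"mastered_variant"` gives `p*w*N_m / (N_u + w*N_m)`, which grows toward
#'   `p` with mastery. `N_u`/`N_m` are the unmastered/mastered species counts.
#' @return An `engine_config` list.
#' @export
engine_config <- function(mode = c("adaptive", "baseline"),
                          n_choices = 5L,
                          max_review_probability = 0.25,
                          review_weight = 0.5,
                          mastery_threshold = 3L,
                          review_numerator = c("printed", "mastered_variant")) {
  mode <- match.arg(mode)
  review_numerator <- match.arg(review_numerator)
  n_choices <- as.integer(n_choices)
  mastery_threshold <- as.integer(mastery_threshold)
  stopifnot(n_choices >= 2L, mastery_threshold >= 1L,
            max_review_probability >= 0, max_review_probability <= 1,
            review_weight > 0)
  structure(list(mode = mode, n_choices = n_choices,
                 max_review_probability = max_review_probability,
                 review_weight = review_weight,
                 mastery_threshold = mastery_threshold,
                 review_numerator = review_numerator),
            class = "engine_config")
}

#' Initial proficiency state
#'
#' Every catalog species starts at proficiency level zero.
#'
#' @param catalog a `species_catalog`.
#' @return Named integer vector of zeros, one entry per species abbreviation.
#' @export
new_proficiency <- function(catalog) {
  ab <- species_abbrevs(catalog)
  stats::setNames(integer(length(ab)), ab)
}

#' Review probability
#'
#' Probability that a training item's correct choice is drawn from the
#' mastered pool rather than the unmastered pool. With `p` the maximum review
#' probability, `w` the review weight, `N_u` unmastered and `N_m` mastered
#' species counts, the `printed` form is `p * w*N_u / (N_u + w*N_m)` and the
#' `mastered_variant` form is `p * w*N_m / (N_u + w*N_m)`. The result is
#' clamped to `[0, 1]`.
#'
#' @param n_unmastered,n_mastered non-negative counts, not both zero.
#' @param config an [engine_config()].
#' @return A probability.
#' @export
#' @examples
#' review_probability(26, 0) # p * w = 0.125 at the defaults
review_probability <- function(n_unmastered, n_mastered,
                               config = engine_config()) {
  stopifnot(n_unmastered >= 0, n_mastered >= 0)
  if (n_unmastered + n_mastered < 1) {
    stop("review_probability needs at least one species", call. = FALSE)
  }
  num <- switch(config$review_numerator,
                printed = config$review_weight * n_unmastered,
                mastered_variant = config$review_weight * n_mastered)
  p <- config$max_review_probability * num /
    (n_unmastered + config$review_weight * n_mastered)
  min(max(p, 0), 1)
}

#' Is a proficiency level mastered?
#'
#' @param level non-negative integer proficiency level.
#' @param config an [engine_config()].
#' @return `TRUE` iff `level >= mastery_threshold`.
#' @export
is_mastered <- function(level, config = engine_config()) {
  stopifnot(all(level >= 0))
  level >= config$mastery_threshold
}

# Uniform draw from a character pool (sample() would misbehave on length 1).
pick_one <- function(pool) {
  pool[sample.int(length(pool), 1L)]
}

# Take k of cands ranked by proficiency (highest or lowest first), ties
# broken uniformly at random. `tiebreak` orders candidates of equal level;
# passing an explicit permutation makes the pick deterministic, which the
# test-suite oracles use to enumerate the tie-break distribution exactly.
rank_pick <- function(cands, state, k, highest, tiebreak = NULL) {
  if (k <= 0L || !length(cands)) return(character(0))
  k <- min(k, length(cands))
  if (is.null(tiebreak)) tiebreak <- sample.int(length(cands))
  lev <- unname(state[cands])
  ord <- order(if (highest) -lev else lev, tiebreak)
  cands[ord[seq_len(k)]]
}

#' Select the correct choice for a training item
#'
#' In adaptive mode the correct species is drawn uniformly from the
#' unmastered pool, except that with [review_probability()] it is drawn
#' uniformly from the mastered pool instead (review item); if either pool is
#' empty the other is used. In baseline mode the draw is uniform over the
#' whole catalog.
#'
#' @param state named integer proficiency vector (see [new_proficiency()]).
#' @param config an [engine_config()].
#' @return A species abbreviation.
#' @export
select_correct <- function(state, config = engine_config()) {
  abbrevs <- names(state)
  stopifnot(length(abbrevs) >= 1L)
  if (config$mode == "baseline") {
    return(pick_one(abbrevs))
  }
  mastered <- abbrevs[state >= config$mastery_threshold]
  unmastered <- abbrevs[state < config$mastery_threshold]
  if (!length(mastered)) return(pick_one(unmastered))
  if (!length(unmastered)) return(pick_one(mastered))
  p_rev <- review_probability(length(unmastered), length(mastered), config)
  if (stats::runif(1L) < p_rev) pick_one(mastered) else pick_one(unmastered)
}

#' Select the distracters for a training item
#'
#' Adaptive mode composes the `n_choices - 1` distracters by tier of the
#' correct species' proficiency level L (ties in any proficiency ranking are
#' broken uniformly at random):
#' \itemize{
#'   \item L = 0: the highest-proficiency species.
#'   \item L = 1: half highest-proficiency, half lowest-proficiency, with the
#'     easier (E-level) similar species of the correct choice substituted for
#'     one low slot when it exists.
#'   \item L >= 2 (including review items): all similar species of the correct
#'     choice (E before D), then lowest-proficiency fillers.
#' }
#' Baseline mode samples uniformly without replacement from the catalog minus
#' the correct species.
#'
#' @param state named integer proficiency vector.
#' @param correct abbreviation of the correct species.
#' @param catalog a `species_catalog` (source of the similarity relation).
#' @param config an [engine_config()].
#' @param tiebreaks optional list with integer permutations `stage1`/`stage2`
#'   overriding the random tie-breaks (used by enumeration oracles in tests).
#' @return Character vector of `n_choices - 1` distinct abbreviations, never
#'   containing `correct`.
#' @export
select_distracters <- function(state, correct, catalog,
                               config = engine_config(), tiebreaks = list()) {
  abbrevs <- names(state)
  k <- config$n_choices - 1L
  if (length(abbrevs) < config$n_choices) {
    stop("catalog too small: ", length(abbrevs), " species but ",
         config$n_choices, " choices per item", call. = FALSE)
  }
  stopifnot(correct %in% abbrevs)
  cands <- setdiff(abbrevs, correct)
  if (config$mode == "baseline") {
    return(cands[sample.int(length(cands), k)])
  }
  L <- state[[correct]]
  sims <- similar_species(catalog, correct)
  if (L == 0L) {
    rank_pick(cands, state, k, highest = TRUE, tiebreak = tiebreaks$stage1)
  } else if (L == 1L) {
    k_high <- as.integer(ceiling(k / 2))
    k_low <- k - k_high
    highs <- rank_pick(cands, state, k_high, highest = TRUE,
                       tiebreak = tiebreaks$stage1)
    rest <- setdiff(cands, highs)
    esim <- setdiff(sims$similar_abbrev[sims$similarity_level == "E"], highs)
    sub <- if (length(esim) && k_low >= 1L) esim[1L] else character(0)
    lows <- c(sub, rank_pick(setdiff(rest, sub), state, k_low - length(sub),
                             highest = FALSE, tiebreak = tiebreaks$stage2))
    c(highs, lows)
  } else {
    simpick <- intersect(sims$similar_abbrev, cands)
    simpick <- simpick[seq_len(min(length(simpick), k))]
    fill <- rank_pick(setdiff(cands, simpick), state, k - length(simpick),
                      highest = FALSE, tiebreak = tiebreaks$stage1)
    c(simpick, fill)
  }
}

#' Update proficiency after an answer
#'
#' A correct answer increments the correct species' level by one. An
#' incorrect answer decrements both the correct species and the wrongly
#' selected distracter by one, floored at zero. All other species are
#' untouched. The same bookkeeping runs in baseline mode (where it never
#' influences selection).
#'
#' @param state named integer proficiency vector.
#' @param correct abbreviation of the item's correct species.
#' @param selected abbreviation the respondent selected.
#' @return The updated proficiency vector.
#' @export
update_proficiency <- function(state, correct, selected) {
  stopifnot(correct %in% names(state), selected %in% names(state))
  if (selected == correct) {
    state[[correct]] <- state[[correct]] + 1L
  } else {
    state[[correct]] <- max(0L, state[[correct]] - 1L)
    state[[selected]] <- max(0L, state[[selected]] - 1L)
  }
  state
}

#' Generate the next quiz item
#'
#' Runs [select_correct()] then [select_distracters()] and shuffles the five
#' choices into a uniformly random presentation order. Deterministic given the
#' RNG seed and call sequence.
#'
#' @param state named integer proficiency vector.
#' @param catalog a `species_catalog`.
#' @param config an [engine_config()].
#' @param item_index integer tag recorded on the item (training question
#'   number).
#' @param time timestamp of the item, in days.
#' @return A `quiz_item`: list with `correct`, `distracters`,
#'   `presented_order`, `item_index`, `time`.
#' @export
next_item <- function(state, catalog, config = engine_config(),
                      item_index = NA_integer_, time = NA_real_) {
  correct <- select_correct(state, config)
  distracters <- select_distracters(state, correct, catalog, config)
  choices <- c(correct, distracters)
  structure(list(correct = correct,
                 distracters = distracters,
                 presented_order = choices[sample.int(length(choices))],
                 item_index = as.integer(item_index),
                 time = as.numeric(time)),
            class = "quiz_item")
}

#' @export
print.quiz_item <- function(x, ...) {
  cat("quiz_item #", x$item_index, " @ day ", format(x$time), ": ",
      paste(x$presented_order, collapse = " "), " (correct: ", x$correct,
      ")\n", sep = "")
  invisible(x)
}
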