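# Fixtures are built in code; nothing is read from disk except the bundled
# catalog CSV shipped with the package.

# Construct a species_catalog directly from vectors (validated).
make_catalog <- function(abbrevs, similar_from = character(),
                         similar_to = character(), levels = character(),
                         song_type = NULL) {
  n <- length(abbrevs)
  species <- data.frame(
    id = seq_len(n),
    english_name = paste("Species", abbrevs),
    binomial = paste("Genus", tolower(abbrevs)),
    abbreviation = abbrevs,
    song_type = song_type %||% rep("song", n),
    stringsAsFactors = FALSE)
  similar <- data.frame(abbreviation = similar_from,
                        similar_abbrev = similar_to,
                        similarity_level = levels,
                        stringsAsFactors = FALSE)
  validate_catalog(structure(list(species = species, similar = similar),
                             class = "species_catalog"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 6-species catalog with an E pair (Bbbb-Cccc) and a D pair (Dddd-Eeee);
# Aaaa and Ffff have no similar species.
tiny_catalog <- function() {
  make_catalog(c("Aaaa", "Bbbb", "Cccc", "Dddd", "Eeee", "Ffff"),
               similar_from = c("Bbbb", "Cccc", "Dddd", "Eeee"),
               similar_to = c("Cccc", "Bbbb", "Eeee", "Dddd"),
               levels = c("E", "E", "D", "D"))
}

# Learner that recalls everything with probability 1 at any time.
make_perfect_learner <- function(catalog) {
  l <- new_learner(catalog)
  l$exposures[] <- 1L
  l$last_exposure[] <- 0
  l$half_life[] <- Inf
  l
}

# Write a catalog CSV from raw rows (for load_catalog error-path tests).
write_raw_catalog <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("id,english_name,binomial,abbreviation,song_type,similar_abbrev,similarity_level",
               rows), path)
  path
}

# Minimal hand-built experiment log for the metrics oracles: 10 training
# items across two days plus a 5-species posttest at day 6.
# Training correct choices (global indices 1..10):
#   Hyam at 1, 3, 6, 9; Cedi at 2, 5, 7, 10; Pamo at 4, 8.
# Coma and Coco never trained.
fixture_log <- function() {
  train_correct <- c("Hyam", "Cedi", "Hyam", "Pamo", "Cedi",
                     "Hyam", "Cedi", "Pamo", "Hyam", "Cedi")
  train_times <- c(1.000, 1.002, 1.004, 1.006, 1.008,
                   5.000, 5.002, 5.004, 5.006, 5.008)
  train_selected <- train_correct
  train_selected[4] <- "Cedi"  # one wrong training answer
  species <- c("Hyam", "Cedi", "Pamo", "Coma", "Coco")
  test_selected <- c("Hyam", "Cedi", "Cedi", "Coco", "Coco")  # 3 of 5 correct
  events <- rbind(
    data.frame(phase = "training1", module = "training",
               time_days = train_times, item_index = 1:10,
               correct = train_correct,
               choices = paste(species, collapse = "|"),
               selected = train_selected,
               is_correct = train_selected == train_correct,
               stringsAsFactors = FALSE),
    data.frame(phase = "posttest", module = "test", time_days = 6,
               item_index = 1:5, correct = species,
               choices = paste(species, collapse = "|"),
               selected = test_selected,
               is_correct = test_selected == species,
               stringsAsFactors = FALSE))
  structure(list(participant_id = 1L, arm = "adaptive", events = events,
                 proficiency = data.frame(phase = "posttest",
                                          abbreviation = species,
                                          level = 0L,
                                          stringsAsFactors = FALSE)),
            class = "experiment_log")
}

# The pinned acceptance cohort is used by two criteria; simulate it once.
acceptance_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_cohort(30, master_seed = 2021L)
    cache
  }
})
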