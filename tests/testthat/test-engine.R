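test_that("review probability matches hand substitution in both forms", {
  cfg <- engine_config()
  # printed form p*w*N_u/(N_u + w*N_m), p = 0.25, w = 0.5
  cases <- list(
    list(nu = 0L, nm = 26L, expected = 0),
    list(nu = 26L, nm = 0L, expected = 0.125),
    list(nu = 13L, nm = 13L, expected = 1.625 / 19.5),     # 0.08333...
    list(nu = 1L, nm = 25L, expected = 0.125 / 13.5),      # 0.00925925...
    list(nu = 20L, nm = 6L, expected = 2.5 / 23))          # 0.10869565...
  for (cs in cases) {
    expect_equal(review_probability(cs$nu, cs$nm, cfg), cs$expected,
                 info = sprintf("printed N_u=%d N_m=%d", cs$nu, cs$nm))
  }
  vcfg <- engine_config(review_numerator = "mastered_variant")
  expect_equal(review_probability(0L, 26L, vcfg), 0.25)  # -> p as N_u -> 0
  expect_equal(review_probability(26L, 0L, vcfg), 0)
  expect_equal(review_probability(13L, 13L, vcfg), 1.625 / 19.5)
  expect_error(review_probability(0L, 0L, cfg), "at least one")
})

test_that("review probability bounds hold over the count grid", {
  cfg <- engine_config()
  vcfg <- engine_config(review_numerator = "mastered_variant")
  cap <- cfg$max_review_probability * cfg$review_weight
  for (nu in 0:26) {
    for (nm in 0:26) {
      if (nu + nm == 0L) next
      p <- review_probability(nu, nm, cfg)
      expect_true(p >= 0 && p <= cap + 1e-12)
      if (nu == 0L) expect_equal(p, 0)
      pv <- review_probability(nu, nm, vcfg)
      expect_true(pv >= 0 && pv <= cfg$max_review_probability + 1e-12)
    }
  }
})

test_that("mastery threshold means level above two at the defaults", {
  cfg <- engine_config()
  expect_true(is_mastered(3L, cfg))
  expect_false(is_mastered(2L, cfg))
  expect_false(is_mastered(0L, cfg))
  expect_true(is_mastered(2L, engine_config(mastery_threshold = 2L)))
})

test_that("proficiency updates: +1 correct, -1/-1 incorrect, floored at 0", {
  cat26 <- builtin_catalog()
  state <- new_proficiency(cat26)
  state[["Hyam"]] <- 2L
  state <- update_proficiency(state, "Hyam", "Hyam")
  expect_equal(state[["Hyam"]], 3L)  # now mastered
  state[["Cedi"]] <- 1L
  state[["Pamo"]] <- 2L
  state <- update_proficiency(state, "Cedi", "Pamo")
  expect_equal(state[["Cedi"]], 0L)
  expect_equal(state[["Pamo"]], 1L)
  before <- state
  state <- update_proficiency(state, "Cedi", "Hyam")  # Cedi already at 0
  expect_equal(state[["Cedi"]], 0L)
  expect_equal(state[["Hyam"]], 2L)
  expect_equal(state[setdiff(names(state), c("Cedi", "Hyam"))],
               before[setdiff(names(before), c("Cedi", "Hyam"))])
  expect_error(update_proficiency(state, "Xxxx", "Hyam"))
})

test_that("proficiency stays non-negative and deltas are +1/-1/-2 with floor", {
  set.seed(101)
  cat26 <- builtin_catalog()
  ab <- species_abbrevs(cat26)
  state <- new_proficiency(cat26)
  for (i in 1:500) {
    correct <- sample(ab, 1)
    selected <- sample(ab, 1)
    before <- state
    state <- update_proficiency(state, correct, selected)
    expect_true(all(state >= 0L))
    delta <- sum(state) - sum(before)
    if (selected == correct) {
      expect_equal(delta, 1L)
    } else {
      expect_equal(delta, -as.integer(before[[correct]] > 0) -
                     as.integer(before[[selected]] > 0))
    }
  }
})

test_that("correct-choice selection is uniform at the all-zero start and in baseline", {
  set.seed(202)
  cat26 <- builtin_catalog()
  ab <- species_abbrevs(cat26)
  zero <- new_proficiency(cat26)
  draws <- replicate(10000, select_correct(zero, engine_config()))
  expect_gt(stats::chisq.test(table(factor(draws, levels = ab)))$p.value, 0.01)
  mixed <- zero
  mixed[1:10] <- 5L  # mastered species must not matter in baseline mode
  draws_b <- replicate(10000, select_correct(mixed, engine_config(mode = "baseline")))
  expect_gt(stats::chisq.test(table(factor(draws_b, levels = ab)))$p.value, 0.01)
})

test_that("mastered species are selected at the review probability (3 SE)", {
  set.seed(303)
  cat26 <- builtin_catalog()
  cfg <- engine_config()
  state <- new_proficiency(cat26)
  state[1:10] <- 3L  # 10 mastered, 16 unmastered
  p_rev <- review_probability(16L, 10L, cfg)
  n <- 10000
  mastered_set <- names(state)[state >= 3L]
  draws <- replicate(n, select_correct(state, cfg))
  freq <- mean(draws %in% mastered_set)
  expect_lt(abs(freq - p_rev), 3 * sqrt(p_rev * (1 - p_rev) / n))
  # only nonempty pool is used when everything is mastered
  all_m <- new_proficiency(cat26) + 5L
  expect_true(select_correct(all_m, cfg) %in% names(all_m))
  # mastered_variant approaches p when almost everything is mastered
  vcfg <- engine_config(review_numerator = "mastered_variant")
  state2 <- new_proficiency(cat26) + 5L
  state2[["Hyam"]] <- 0L
  p2 <- review_probability(1L, 25L, vcfg)
  draws2 <- replicate(n, select_correct(state2, vcfg))
  freq2 <- mean(draws2 != "Hyam")
  expect_lt(abs(freq2 - p2), 3 * sqrt(p2 * (1 - p2) / n))
})

test_that("distracters are always distinct and exclude the correct species", {
  set.seed(404)
  cat26 <- builtin_catalog()
  ab <- species_abbrevs(cat26)
  for (mode in c("adaptive", "baseline")) {
    cfg <- engine_config(mode = mode)
    for (i in 1:200) {
      state <- stats::setNames(sample(0:4, 26, replace = TRUE), ab)
      correct <- sample(ab, 1)
      d <- select_distracters(state, correct, cat26, cfg)
      expect_length(d, 4L)
      expect_equal(anyDuplicated(d), 0L)
      expect_false(correct %in% d)
    }
  }
  expect_error(select_distracters(stats::setNames(0:3, ab[1:4]), ab[1],
                                  cat26, engine_config()), "too small")
})

test_that("a proficient similar species appears among the distracters", {
  cat26 <- builtin_catalog()
  state <- new_proficiency(cat26)
  state[["Pami"]] <- 2L
  set.seed(1)
  for (i in 1:20) {
    expect_true("Pova" %in% select_distracters(state, "Pami", cat26,
                                               engine_config()))
  }
})

test_that("distracter-set distribution matches exhaustive tier enumeration", {
  cat6 <- tiny_catalog()
  cfg <- engine_config()
  ab <- species_abbrevs(cat6)
  n <- 20000
  cases <- list(
    # L = 0 with a tie among the high-proficiency pool
    list(correct = "Aaaa", levels = c(0L, 2L, 2L, 1L, 0L, 0L)),
    # L = 1 with an E-similar available for the low slot
    list(correct = "Bbbb", levels = c(3L, 1L, 0L, 2L, 1L, 0L)),
    # L = 2: all similars first, then lowest-proficiency fillers
    list(correct = "Dddd", levels = c(1L, 0L, 2L, 2L, 1L, 0L)),
    # L = 3 review item, no similar species at all
    list(correct = "Aaaa", levels = c(3L, 1L, 1L, 0L, 2L, 2L)))
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    state <- stats::setNames(cs$levels, ab)
    dist <- oracle_distracter_dist(state, cs$correct, cat6, cfg)
    expect_equal(sum(dist), 1, tolerance = 1e-12)
    set.seed(5000 + ci)
    keys <- replicate(n, set_key(select_distracters(state, cs$correct, cat6, cfg)))
    expect_true(all(unique(keys) %in% names(dist)))
    for (k in names(dist)) {
      se <- sqrt(dist[[k]] * (1 - dist[[k]]) / n)
      expect_true(abs(mean(keys == k) - dist[[k]]) < max(3 * se, 1e-9),
                  info = sprintf("case %d set %s", ci, k))
    }
  }
})

test_that("items hold n_choices distinct species and are seed-reproducible", {
  cat26 <- builtin_catalog()
  state <- new_proficiency(cat26)
  set.seed(99)
  item <- next_item(state, cat26, engine_config(), item_index = 1L, time = 0.5)
  expect_s3_class(item, "quiz_item")
  expect_length(item$presented_order, 5L)
  expect_equal(anyDuplicated(item$presented_order), 0L)
  expect_setequal(item$presented_order, c(item$correct, item$distracters))
  set.seed(99)
  expect_identical(next_item(state, cat26, engine_config(),
                             item_index = 1L, time = 0.5), item)
})

test_that("a perfect responder masters all species in 78 unmastered answers", {
  set.seed(77)
  cat26 <- builtin_catalog()
  cfg <- engine_config()
  state <- new_proficiency(cat26)
  unmastered_answers <- 0L
  total <- 0L
  while (!all(state >= cfg$mastery_threshold)) {
    item <- next_item(state, cat26, cfg)
    if (state[[item$correct]] < cfg$mastery_threshold) {
      unmastered_answers <- unmastered_answers + 1L
    }
    state <- update_proficiency(state, item$correct, item$correct)
    total <- total + 1L
    expect_lt(total, 1000L)  # guard against livelock
  }
  expect_equal(unmastered_answers, 78L)  # 3 correct answers x 26 species
})

test_that("late items for a perfect responder are mostly review-limited", {
  set.seed(88)
  cat26 <- builtin_catalog()
  cfg <- engine_config()
  state <- new_proficiency(cat26)
  mastered_correct <- logical(200)
  all_mastered_at <- NA_integer_
  for (i in 1:200) {
    if (is.na(all_mastered_at) && all(state >= cfg$mastery_threshold)) {
      all_mastered_at <- i
    }
    item <- next_item(state, cat26, cfg)
    mastered_correct[i] <- state[[item$correct]] >= cfg$mastery_threshold
    state <- update_proficiency(state, item$correct, item$correct)
  }
  # while unmastered species remain, review items are bounded by the clamped
  # review probability; once everything is mastered every item is a review
  expect_false(is.na(all_mastered_at))
  phase1 <- mastered_correct[seq_len(all_mastered_at - 1L)]
  cap <- cfg$max_review_probability * cfg$review_weight
  expect_lte(mean(phase1), cap + 3 * sqrt(cap * (1 - cap) / length(phase1)))
  expect_true(all(mastered_correct[all_mastered_at:200]))
})
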