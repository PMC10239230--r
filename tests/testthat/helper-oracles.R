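# Independent oracles: exhaustive enumerations kept free of the sampling
# paths they check.

# All permutations of 1..n as rows (n <= 6 here).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

set_key <- function(x) paste(sort(x), collapse = "|")

# Exact distracter-set distribution under the adaptive tier rule, obtained by
# enumerating every tie-break ordering with equal weight (the engine breaks
# proficiency ties with a uniformly random permutation). Returns named
# probabilities keyed by the sorted distracter set.
oracle_distracter_dist <- function(state, correct, catalog, config) {
  cands <- setdiff(names(state), correct)
  k <- config$n_choices - 1L
  L <- state[[correct]]
  sims <- similar_species(catalog, correct)
  acc <- new.env(parent = emptyenv())
  add <- function(set, p) {
    key <- set_key(set)
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
  }
  pick <- function(cc, kk, highest, perm) {
    birdquiz:::rank_pick(cc, state, kk, highest, tiebreak = perm)
  }
  enum2 <- function(first, cc, kk, highest, w) {
    # second-stage pick over cc, enumerating its tie-break orderings
    if (kk <= 0L || !length(cc)) {
      add(first, w)
      return(invisible())
    }
    p2 <- all_perms(length(cc))
    for (j in seq_len(nrow(p2))) {
      add(c(first, pick(cc, kk, highest, p2[j, ])), w / nrow(p2))
    }
  }
  if (L == 0L) {
    p1 <- all_perms(length(cands))
    for (i in seq_len(nrow(p1))) {
      add(pick(cands, k, TRUE, p1[i, ]), 1 / nrow(p1))
    }
  } else if (L == 1L) {
    k_high <- as.integer(ceiling(k / 2))
    k_low <- k - k_high
    p1 <- all_perms(length(cands))
    for (i in seq_len(nrow(p1))) {
      highs <- pick(cands, k_high, TRUE, p1[i, ])
      rest <- setdiff(cands, highs)
      esim <- setdiff(sims$similar_abbrev[sims$similarity_level == "E"], highs)
      sub <- if (length(esim) && k_low >= 1L) esim[1L] else character(0)
      enum2(c(highs, sub), setdiff(rest, sub), k_low - length(sub), FALSE,
            1 / nrow(p1))
    }
  } else {
    simpick <- intersect(sims$similar_abbrev, cands)
    simpick <- simpick[seq_len(min(length(simpick), k))]
    enum2(simpick, setdiff(cands, simpick), k - length(simpick), FALSE, 1)
  }
  unlist(as.list(acc))
}

# Exact two-sided permutation p-value by full enumeration of label
# assignments (small groups only).
exact_perm_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  obs <- mean(a) - mean(b)
  idx <- utils::combn(length(pool), na)
  ds <- apply(idx, 2L, function(i) mean(pool[i]) - mean(pool[-i]))
  mean(abs(ds) >= abs(obs) - 1e-12)
}
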