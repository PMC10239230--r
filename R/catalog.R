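# Species roster plus the expert-designated "similar song" relation that the
# adaptive engine uses for hard distracters. The similarity level is E
# (easier to tell apart) or D (more difficult).

CATALOG_COLUMNS <- c("id", "english_name", "binomial", "abbreviation",
                     "song_type", "similar_abbrev", "similarity_level")

#' Load a species catalog from CSV
#'
#' Reads a catalog of training target species. The CSV must have exactly the
#' columns `id,english_name,binomial,abbreviation,song_type,similar_abbrev,
#' similarity_level` (UTF-8, header required). `similar_abbrev` holds the
#' abbreviation(s) of confusable species (`;`-separated if more than one,
#' empty string if none) and `similarity_level` the matching `E`/`D` level(s).
#' The similarity relation must be symmetric with equal level on both ends.
#'
#' @param path path to a catalog CSV file.
#' @return A `species_catalog` object: a list with a `species` data frame
#'   (id, english_name, binomial, abbreviation, song_type) and a `similar`
#'   data frame (abbreviation, similar_abbrev, similarity_level).
#' @seealso [builtin_catalog()] for the bundled 26-species roster,
#'   [write_catalog()] for the inverse operation.
#' @export
#' @examples
#' cat26 <- builtin_catalog()
#' nrow(cat26$species)
load_catalog <- function(path) {
  if (!file.exists(path)) {
    stop("catalog file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!identical(names(raw), CATALOG_COLUMNS)) {
    stop("catalog header must be exactly: ",
         paste(CATALOG_COLUMNS, collapse = ","), call. = FALSE)
  }
  species <- data.frame(
    id           = suppressWarnings(as.integer(raw$id)),
    english_name = raw$english_name,
    binomial     = raw$binomial,
    abbreviation = raw$abbreviation,
    song_type    = raw$song_type,
    stringsAsFactors = FALSE
  )
  catalog <- structure(list(species = species, similar = parse_similar(raw)),
                       class = "species_catalog")
  validate_catalog(catalog)
}

# Expand the per-row ;-separated similar columns into a long relation.
parse_similar <- function(raw) {
  empty <- data.frame(abbreviation = character(), similar_abbrev = character(),
                      similarity_level = character(), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    sa <- raw$similar_abbrev[i]
    sl <- raw$similarity_level[i]
    if (is.na(sa) || !nzchar(sa)) {
      if (!is.na(sl) && nzchar(sl)) {
        stop("catalog row ", i, " (", raw$abbreviation[i],
             "): similarity_level given without similar_abbrev", call. = FALSE)
      }
      return(NULL)
    }
    to  <- strsplit(sa, ";", fixed = TRUE)[[1L]]
    lev <- strsplit(sl, ";", fixed = TRUE)[[1L]]
    if (length(to) != length(lev)) {
      stop("catalog row ", i, " (", raw$abbreviation[i],
           "): similar_abbrev and similarity_level counts differ", call. = FALSE)
    }
    data.frame(abbreviation = raw$abbreviation[i], similar_abbrev = to,
               similarity_level = lev, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Validate a species catalog
#'
#' Checks the structural invariants required by the quiz engine: at least 5
#' species (a five-choice item needs five distinct species), unique
#' abbreviations, ids contiguous from 1, song types in `{song, call}`, no
#' dangling similar references, and a symmetric similarity relation with the
#' same `E`/`D` level on both ends.
#'
#' @param catalog a `species_catalog`.
#' @return The catalog, invisibly, if valid; otherwise an error naming the
#'   offending row.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "species_catalog"))
  sp <- catalog$species
  if (nrow(sp) < 5L) {
    stop("catalog must contain at least 5 species (a quiz needs five ",
         "distinct choices); got ", nrow(sp), call. = FALSE)
  }
  dup <- sp$abbreviation[duplicated(sp$abbreviation)]
  if (length(dup)) {
    stop("duplicate abbreviation in catalog: ", dup[1L], " (row ",
         which(sp$abbreviation == dup[1L])[2L], ")", call. = FALSE)
  }
  if (anyNA(sp$id) || !identical(sp$id, seq_len(nrow(sp)))) {
    stop("species ids must be contiguous integers 1..", nrow(sp), call. = FALSE)
  }
  bad_song <- !(sp$song_type %in% c("song", "call"))
  if (any(bad_song)) {
    stop("song_type must be 'song' or 'call'; row ", which(bad_song)[1L],
         " has '", sp$song_type[which(bad_song)[1L]], "'", call. = FALSE)
  }
  sim <- catalog$similar
  if (nrow(sim)) {
    dangling <- !(sim$similar_abbrev %in% sp$abbreviation)
    if (any(dangling)) {
      i <- which(dangling)[1L]
      stop("dangling similar_to reference: ", sim$abbreviation[i], " -> ",
           sim$similar_abbrev[i], call. = FALSE)
    }
    if (any(sim$abbreviation == sim$similar_abbrev)) {
      i <- which(sim$abbreviation == sim$similar_abbrev)[1L]
      stop("species listed as similar to itself: ", sim$abbreviation[i],
           call. = FALSE)
    }
    bad_lev <- !(sim$similarity_level %in% c("E", "D"))
    if (any(bad_lev)) {
      i <- which(bad_lev)[1L]
      stop("similarity_level must be 'E' or 'D'; got '",
           sim$similarity_level[i], "' for ", sim$abbreviation[i], call. = FALSE)
    }
    key <- paste(sim$abbreviation, sim$similar_abbrev, sim$similarity_level)
    if (anyDuplicated(key)) {
      stop("duplicated similarity pair: ", key[duplicated(key)][1L],
           call. = FALSE)
    }
    reversed <- paste(sim$similar_abbrev, sim$abbreviation, sim$similarity_level)
    missing <- setdiff(reversed, key)
    if (length(missing)) {
      parts <- strsplit(missing[1L], " ", fixed = TRUE)[[1L]]
      stop("similarity relation not symmetric: ", parts[2L], " -> ", parts[1L],
           " (", parts[3L], ") has no back-reference", call. = FALSE)
    }
  }
  invisible(catalog)
}

#' The bundled 26-species training catalog
#'
#' Returns the packaged roster of the 26 bird species most frequently heard in
#' the acoustic-monitoring recordings the training tool was built around, with
#' four expert-designated confusable pairs: Large-billed Crow/Carrion Crow (E),
#' Chinese Hwamei/Narcissus Flycatcher (E), Japanese Tit/Varied Tit (E) and
#' Japanese Wagtail/White Wagtail (D).
#'
#' @return A validated `species_catalog` with 26 species.
#' @export
#' @examples
#' similar_species(builtin_catalog(), "Mogr")
builtin_catalog <- function() {
  path <- system.file("extdata", "species_catalog.csv", package = "birdquiz",
                      mustWork = TRUE)
  load_catalog(path)
}

#' Write a species catalog to CSV
#'
#' Inverse of [load_catalog()]: `load_catalog(write_catalog(x, f))`
#' reproduces `x` field for field.
#'
#' @param catalog a `species_catalog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  sp <- catalog$species
  sim <- catalog$similar
  joined <- vapply(sp$abbreviation, function(ab) {
    rows <- sim[sim$abbreviation == ab, , drop = FALSE]
    c(paste(rows$similar_abbrev, collapse = ";"),
      paste(rows$similarity_level, collapse = ";"))
  }, character(2))
  out <- data.frame(sp, similar_abbrev = joined[1L, ],
                    similarity_level = joined[2L, ],
                    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Species abbreviations in catalog order
#'
#' @param catalog a `species_catalog`.
#' @return Character vector of 4-letter species codes.
#' @export
species_abbrevs <- function(catalog) {
  catalog$species$abbreviation
}

#' Similar species of one species
#'
#' @param catalog a `species_catalog`.
#' @param abbrev a species abbreviation.
#' @return Data frame with columns `similar_abbrev` and `similarity_level`,
#'   ordered easier (`E`) before more difficult (`D`); zero rows when the
#'   species has no designated similar species.
#' @export
similar_species <- function(catalog, abbrev) {
  rows <- catalog$similar[catalog$similar$abbreviation == abbrev, , drop = FALSE]
  rows <- rows[order(match(rows$similarity_level, c("E", "D"))), , drop = FALSE]
  rownames(rows) <- NULL
  rows[, c("similar_abbrev", "similarity_level")]
}

#' @export
print.species_catalog <- function(x, ...) {
  cat("species_catalog: ", nrow(x$species), " species, ",
      nrow(x$similar) / 2, " similar pair(s)\n", sep = "")
  invisible(x)
}
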