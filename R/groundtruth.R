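# Ground-truth construction: CUI -> layman-term mappings are filtered down
# to the evaluable concept set (unigram terms, stemmed, corpus frequency
# strictly greater than min_freq, at least min_terms distinct terms per
# concept), then one seed term per concept is drawn at random; the rest of
# the concept's terms become its held-out synonyms.

#' Load concept-to-layman-term mappings from TSV
#'
#' Rows are `CUI<TAB>concept_name<TAB>term`; multiple rows per CUI are
#' allowed and grouped. Duplicate identical terms within a concept are
#' deduplicated.
#'
#' @param source Path to a TSV file, or a character vector of TSV lines.
#' @return Data.frame with columns `cui`, `preferred_name`, `term`
#'   (one row per unique concept/term pair), ordered by CUI.
#' @export
load_concept_mappings <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, encoding = "UTF-8")
  } else {
    as.character(source)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(cui = character(0), preferred_name = character(0),
                      term = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed concept mapping row (expected 3 tab-separated fields) ",
         "at line ", bad[1L], ": ", lines[bad[1L]], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  df <- data.frame(cui = m[, 1L], preferred_name = m[, 2L], term = m[, 3L],
                   stringsAsFactors = FALSE)
  # a concept's preferred name must be consistent across its rows
  df <- unique(df)
  df <- df[order(df$cui, df$term), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the filtered ground-truth concept set
#'
#' Applies the admission filters: only unigram layman terms are considered;
#' terms are stemmed and deduplicated; terms equal to the stemmed preferred
#' name are removed; a term survives only if its corpus frequency is
#' strictly greater than `min_freq`; a concept survives only if its
#' preferred name is a unigram and it retains at least `min_terms` distinct
#' surviving terms.
#'
#' @param records Data.frame from [load_concept_mappings()].
#' @param freqs Named integer vector of token frequencies from the
#'   preprocessed (unexpanded) corpus, as from [term_frequencies()].
#' @param min_freq Frequency threshold; terms must occur more than this
#'   many times (strict inequality; default 100).
#' @param min_terms Minimum surviving terms per admitted concept (default 2).
#' @param stemmer_id Stemmer identifier.
#' @param verbose Emit a summary message with exclusion counts.
#' @return A `ground_truth` object: list with `concepts` (data.frame
#'   `cui`, `preferred_name`, one row per admitted concept), `terms`
#'   (data.frame `cui`, `term` with stemmed surviving terms) and `stats`
#'   (exclusion bookkeeping).
#' @export
build_ground_truth <- function(records, freqs, min_freq = 100L,
                               min_terms = 2L,
                               stemmer_id = "snowball-english",
                               verbose = FALSE) {
  stem <- get_stemmer(stemmer_id)
  empty <- function(stats) {
    structure(list(
      concepts = data.frame(cui = character(0),
                            preferred_name = character(0),
                            stringsAsFactors = FALSE),
      terms = data.frame(cui = character(0), term = character(0),
                         stringsAsFactors = FALSE),
      stats = stats), class = "ground_truth")
  }
  n_raw_concepts <- length(unique(records$cui))
  if (nrow(records) == 0L) {
    return(empty(list(raw_concepts = 0L, admitted_concepts = 0L,
                      dropped_multiword_name = 0L, dropped_terms = 0L)))
  }

  # concepts whose preferred name is not a unigram are excluded outright
  is_unigram <- !grepl("\\s", records$preferred_name)
  dropped_mw <- length(unique(records$cui[!is_unigram]))
  records <- records[is_unigram, , drop = FALSE]

  # unigram terms only, then stem
  records <- records[!grepl("\\s", records$term), , drop = FALSE]
  if (nrow(records)) {
    records$term <- stem(tolower(records$term))
    records$name_stem <- stem(tolower(records$preferred_name))
    records <- records[records$term != records$name_stem, , drop = FALSE]
    records <- unique(records[, c("cui", "preferred_name", "term")])
  }
  n_terms_before <- nrow(records)

  # frequency filter: strictly more than min_freq occurrences
  f <- freqs[records$term]
  f[is.na(f)] <- 0L
  records <- records[f > min_freq, , drop = FALSE]

  # concept-size filter
  keep_cui <- names(which(table(records$cui) >= min_terms))
  records <- records[records$cui %in% keep_cui, , drop = FALSE]

  stats <- list(raw_concepts = n_raw_concepts,
                admitted_concepts = length(unique(records$cui)),
                dropped_multiword_name = dropped_mw,
                dropped_terms = n_terms_before - nrow(records))
  if (verbose) {
    message("ground truth: ", stats$admitted_concepts, "/",
            stats$raw_concepts, " concepts admitted (",
            stats$dropped_multiword_name, " multi-word names, ",
            stats$dropped_terms, " terms filtered)")
  }
  if (nrow(records) == 0L) return(empty(stats))

  concepts <- unique(records[, c("cui", "preferred_name")])
  concepts <- concepts[order(concepts$cui), , drop = FALSE]
  rownames(concepts) <- NULL
  terms <- records[order(records$cui, records$term), c("cui", "term")]
  rownames(terms) <- NULL
  structure(list(concepts = concepts, terms = terms, stats = stats),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$concepts), " concepts, ",
      nrow(x$terms), " layman terms\n", sep = "")
  invisible(x)
}

#' Assign one random seed term per concept
#'
#' Iterates concepts in sorted CUI order drawing from a single RNG stream
#' seeded once, so assignments are reproducible independent of input
#' order. The remaining terms of each concept become its held-out
#' synonyms.
#'
#' @param dataset A `ground_truth` object with >= 2 terms per concept.
#' @param rng_seed Integer seed for the draw.
#' @return Data.frame with columns `cui`, `seed_term`, `held_out`
#'   (list-column of character vectors).
#' @export
assign_seeds <- function(dataset, rng_seed) {
  stopifnot(inherits(dataset, "ground_truth"))
  cuis <- sort(unique(dataset$terms$cui))
  term_sets <- split(dataset$terms$term, dataset$terms$cui)[cuis]
  bad <- names(which(lengths(term_sets) < 2L))
  if (length(bad)) {
    stop("concept(s) with fewer than 2 terms cannot be seeded: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(rng_seed))
  seeds <- vapply(term_sets, function(ts) {
    ts <- sort(ts)
    ts[sample.int(length(ts), 1L)]
  }, character(1))
  held <- Map(function(ts, s) sort(setdiff(ts, s)), term_sets, seeds)
  out <- data.frame(cui = cuis, seed_term = unname(seeds),
                    stringsAsFactors = FALSE)
  out$held_out <- unname(held)
  out
}

#' Write seed assignments as TSV
#'
#' Rows are `CUI<TAB>seed<TAB>held_out,csv`.
#'
#' @param assignments Data.frame from [assign_seeds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  lines <- paste(assignments$cui, assignments$seed_term,
                 vapply(assignments$held_out, paste, character(1),
                        collapse = ","),
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("malformed assignment row")
  m <- do.call(rbind, parts)
  out <- data.frame(cui = m[, 1L], seed_term = m[, 2L],
                    stringsAsFactors = FALSE)
  out$held_out <- strsplit(m[, 3L], ",", fixed = TRUE)
  out
}
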