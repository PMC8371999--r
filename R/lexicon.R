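# Lexical resource contract: a resource answers (term, relation-kind)
# queries with related surface forms plus Resnik information-content
# similarity scores. Production deployments would adapt a full WordNet
# installation behind this contract; the package bundles a deterministic
# toy resource (JSON) used by the test suite and the synthetic benchmark.
#
# Resource JSON format:
#   taxonomy:  sense -> parent sense ("" or absent parent = root)
#   ic:        sense -> information content (non-negative real)
#   lemmas:    sense -> list of surface forms (multi-word joined by "_")
#   relations: sense -> {hyponyms: [senses], hypernyms: [senses]}

RELATION_KINDS <- c("synonym", "hyponym", "hypernym")

#' Load a toy lexical resource from JSON
#'
#' @param path Path to a resource JSON file (see package vignette for the
#'   schema), or a list already parsed from it.
#' @param version_tag Identifier recorded for provenance; queries against a
#'   fixed tag are pure and deterministic.
#' @param stemmer_id Stemmer used to normalize lemma surfaces so that
#'   inserted tokens unify with corpus vocabulary (each underscore-joined
#'   component is stemmed independently).
#' @return A `lexical_resource` object.
#' @export
load_lexical_resource <- function(path, version_tag = NULL,
                                  stemmer_id = "snowball-english") {
  raw <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    path
  }
  stem <- get_stemmer(stemmer_id)
  taxonomy <- vapply(raw$taxonomy, function(p) {
    if (is.null(p)) "" else as.character(p)
  }, character(1))
  ic <- vapply(raw$ic, as.numeric, numeric(1))
  if (any(ic < 0)) stop("information content must be non-negative")
  lemmas <- lapply(raw$lemmas, function(x) unlist(x, use.names = FALSE))
  relations <- lapply(raw$relations, function(r) {
    list(hyponyms = unlist(r$hyponyms, use.names = FALSE),
         hypernyms = unlist(r$hypernyms, use.names = FALSE))
  })

  stem_surface <- function(s) {
    vapply(strsplit(s, "_", fixed = TRUE), function(parts) {
      paste(stem(tolower(parts)), collapse = "_")
    }, character(1))
  }
  lemmas_stemmed <- lapply(lemmas, stem_surface)

  # inverted index: stemmed surface -> senses
  sense_of <- list()
  for (s in names(lemmas_stemmed)) {
    for (surf in lemmas_stemmed[[s]]) {
      sense_of[[surf]] <- c(sense_of[[surf]], s)
    }
  }

  structure(
    list(taxonomy = taxonomy, ic = ic, lemmas = lemmas_stemmed,
         relations = relations, sense_of = sense_of,
         version_tag = version_tag %||% "toy-0",
         stemmer_id = stemmer_id),
    class = "lexical_resource")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lexical_resource <- function(x, ...) {
  cat("<lexical_resource> ", length(x$taxonomy), " senses, version '",
      x$version_tag, "'\n", sep = "")
  invisible(x)
}

.ancestors <- function(resource, sense) {
  # sense itself plus all taxonomy ancestors up to the root
  out <- character(0)
  cur <- sense
  seen <- character(0)
  while (nzchar(cur) && !is.na(cur)) {
    if (cur %in% seen) stop("taxonomy cycle at sense '", cur, "'")
    seen <- c(seen, cur)
    out <- c(out, cur)
    if (!cur %in% names(resource$taxonomy)) break
    cur <- resource$taxonomy[[cur]]
  }
  out
}

#' Resnik information-content similarity between two senses
#'
#' The information content of the most informative common ancestor of the
#' two senses (each sense counts as its own ancestor, so
#' `resnik_score(a, a)` is `IC(a)`). Symmetric in its arguments.
#'
#' @param sense_a,sense_b Sense identifiers present in the resource
#'   taxonomy.
#' @param resource A `lexical_resource`.
#' @return Non-negative similarity score.
#' @export
resnik_score <- function(sense_a, sense_b, resource) {
  stopifnot(inherits(resource, "lexical_resource"))
  for (s in c(sense_a, sense_b)) {
    if (!s %in% names(resource$taxonomy)) {
      stop("sense not in taxonomy: '", s, "'", call. = FALSE)
    }
  }
  common <- intersect(.ancestors(resource, sense_a),
                      .ancestors(resource, sense_b))
  if (length(common) == 0L) return(0)
  ics <- resource$ic[common]
  ics[is.na(ics)] <- 0
  max(ics)
}

#' Fetch terms related to a query term
#'
#' Looks the term up across all senses of the resource (no word-sense
#' disambiguation: relations are unioned over senses, which matches how
#' ambiguous seed terms pick up synonyms of several meanings). Synonyms
#' are the other lemmas of each sense containing the term; hyponyms and
#' hypernyms are lemmas of the senses linked through the taxonomy
#' relations. The query term itself is excluded and duplicate surfaces
#' collapse to their maximum score.
#'
#' @param term Single stemmed token.
#' @param kind One of `"synonym"`, `"hyponym"`, `"hypernym"`.
#' @param resource A `lexical_resource`.
#' @param scored If `TRUE` (default) fill Resnik scores against the query
#'   term via [score_against_seed()].
#' @return Data.frame with columns `surface`, `kind`, `sense_id`, `score`
#'   (zero rows for unknown terms).
#' @export
fetch_related <- function(term, kind, resource, scored = TRUE) {
  stopifnot(length(term) == 1L, inherits(resource, "lexical_resource"))
  kind <- match.arg(kind, RELATION_KINDS)
  senses <- resource$sense_of[[term]]
  empty <- data.frame(surface = character(0), kind = character(0),
                      sense_id = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(senses)) return(empty)

  rows <- list()
  for (s in senses) {
    rel_senses <- switch(
      kind,
      synonym = s,
      hyponym = resource$relations[[s]]$hyponyms,
      hypernym = resource$relations[[s]]$hypernyms)
    for (rs in rel_senses) {
      surfs <- resource$lemmas[[rs]]
      surfs <- setdiff(surfs, term)
      if (length(surfs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          surface = surfs, kind = kind, sense_id = rs,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$surface, out$sense_id), , drop = FALSE]
  rownames(out) <- NULL
  if (scored) {
    out <- score_against_seed(term, out, resource)
  } else {
    out$score <- NA_real_
  }
  out
}

#' Score candidate related terms against a seed term
#'
#' Each candidate's score is the maximum Resnik similarity over all
#' (seed sense, candidate sense) pairs, where the candidate's senses are
#' every sense whose lemmas contain its surface. Duplicate surfaces are
#' collapsed keeping the maximum score.
#'
#' @param seed Stemmed seed token.
#' @param candidates Data.frame with a `surface` column (as from
#'   [fetch_related()]).
#' @param resource A `lexical_resource`.
#' @return Data.frame `surface`, `kind`, `sense_id`, `score`, one row per
#'   distinct surface.
#' @export
score_against_seed <- function(seed, candidates, resource) {
  stopifnot(inherits(resource, "lexical_resource"))
  if (nrow(candidates) == 0L) {
    candidates$score <- numeric(0)
    return(candidates)
  }
  seed_senses <- resource$sense_of[[seed]]
  score_one <- function(surface) {
    cand_senses <- resource$sense_of[[surface]]
    if (is.null(seed_senses) || is.null(cand_senses)) return(0)
    max(vapply(seed_senses, function(a) {
      max(vapply(cand_senses, function(b) {
        resnik_score(a, b, resource)
      }, numeric(1)))
    }, numeric(1)))
  }
  surfaces <- unique(candidates$surface)
  scores <- vapply(surfaces, score_one, numeric(1))
  keep <- candidates[!duplicated(candidates$surface), , drop = FALSE]
  keep <- keep[match(surfaces, keep$surface), , drop = FALSE]
  keep$score <- unname(scores)
  rownames(keep) <- NULL
  keep
}
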