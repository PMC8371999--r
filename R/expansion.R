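# Corpus expansion: scored relational synsets become a per-seed insertion
# plan (a left subset placed before every seed occurrence and a right
# subset after it), and the corpus is rewritten accordingly. Only original
# corpus positions are scanned, so inserted tokens are never themselves
# expanded.

#' Rank scored related terms and split them into left/right subsets
#'
#' Items are sorted by descending score (ties broken lexicographically by
#' surface) and truncated to at most `cap` items. `mode = "roundrobin"`
#' deals items alternately left, right, left, ... which balances the total
#' similarity mass of the two subsets; `mode = "halves"` places the first
#' half (rounded up) contiguously on the left and the rest on the right.
#' Both orders reproduce the descending-score ranking when read
#' left-then-right in assignment order.
#'
#' @param scored Data.frame with `surface` and `score` columns.
#' @param cap Maximum total number of inserted terms (default 10).
#' @param mode `"roundrobin"` (default) or `"halves"`.
#' @return List with character vectors `left` and `right`.
#' @export
rank_and_split <- function(scored, cap = 10L, mode = c("roundrobin", "halves")) {
  mode <- match.arg(mode)
  if (cap < 0L) stop("cap must be non-negative", call. = FALSE)
  if (nrow(scored) == 0L || cap == 0L) {
    return(list(left = character(0), right = character(0)))
  }
  stopifnot(all(!is.na(scored$score)))
  ord <- order(-scored$score, scored$surface)
  ranked <- scored$surface[ord]
  ranked <- ranked[seq_len(min(length(ranked), cap))]
  k <- length(ranked)
  if (mode == "roundrobin") {
    idx_left <- seq(1L, k, by = 2L)
  } else {
    idx_left <- seq_len(ceiling(k / 2))
  }
  list(left = ranked[idx_left], right = ranked[setdiff(seq_len(k), idx_left)])
}

#' Build expansion plans for a set of seed terms
#'
#' Queries the lexical resource for each distinct seed term, scores the
#' related terms against the seed and splits them with [rank_and_split()].
#' A term seeding several concepts gets exactly one plan (plans are keyed
#' by surface token, so relation lists are shared).
#'
#' @param seed_terms Character vector of stemmed seed tokens.
#' @param kind Relation kind: `"synonym"`, `"hyponym"` or `"hypernym"`.
#' @param resource A `lexical_resource`.
#' @param cap,mode Passed to [rank_and_split()].
#' @return Named list of plans (`seed_term`, `kind`, `left`, `right`,
#'   `cap`), one per distinct seed term with a non-empty relation set.
#' @export
build_expansion_plans <- function(seed_terms, kind, resource, cap = 10L,
                                  mode = c("roundrobin", "halves")) {
  mode <- match.arg(mode)
  kind <- match.arg(kind, RELATION_KINDS)
  plans <- list()
  for (seed in sort(unique(seed_terms))) {
    rel <- fetch_related(seed, kind, resource, scored = TRUE)
    if (nrow(rel) == 0L) next
    split <- rank_and_split(rel, cap = cap, mode = mode)
    if (length(split$left) + length(split$right) == 0L) next
    plans[[seed]] <- list(seed_term = seed, kind = kind,
                          left = split$left, right = split$right,
                          cap = as.integer(cap))
  }
  plans
}

#' Expand a corpus with per-seed insertion plans
#'
#' Rewrites every occurrence of a planned seed term `s` as
#' `... left s right ...`. Multi-word related terms stay single
#' underscore-joined tokens. Only the original token positions are
#' scanned: inserted tokens never trigger further insertion, and deleting
#' all inserted tokens recovers the original corpus exactly.
#'
#' @param corpus A `tokenized_corpus`.
#' @param plans Named list of plans from [build_expansion_plans()].
#' @return A `tokenized_corpus` with rewritten documents, recomputed
#'   vocabulary and an `expansion_log` attribute (per-seed occurrence
#'   counts).
#' @export
expand_corpus <- function(corpus, plans) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  seeds <- names(plans)
  counts <- stats::setNames(integer(length(seeds)), seeds)
  if (length(seeds) == 0L) {
    attr(corpus, "expansion_log") <- counts
    return(corpus)
  }
  documents <- lapply(corpus$documents, function(toks) {
    hit <- toks %in% seeds
    if (!any(hit)) return(toks)
    pieces <- vector("list", length(toks))
    for (i in seq_along(toks)) {
      if (hit[i]) {
        p <- plans[[toks[i]]]
        pieces[[i]] <- c(p$left, toks[i], p$right)
      } else {
        pieces[[i]] <- toks[i]
      }
    }
    unlist(pieces, use.names = FALSE)
  })
  names(documents) <- names(corpus$documents)

  for (s in seeds) {
    counts[[s]] <- sum(vapply(corpus$documents,
                              function(t) sum(t == s), integer(1)))
  }

  all_tokens <- unlist(documents, use.names = FALSE)
  vocabulary <- if (length(all_tokens)) {
    tab <- table(all_tokens)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  out <- structure(
    list(documents = documents, vocabulary = vocabulary,
         min_token_len = corpus$min_token_len,
         stemmer_id = corpus$stemmer_id),
    class = "tokenized_corpus")
  attr(out, "expansion_log") <- counts
  out
}

#' Serialize / load expansion plans as JSON
#'
#' @param plans Named list of plans.
#' @param path Output (or input) path.
#' @return `path` invisibly; `read_expansion_plans()` returns the plan list.
#' @export
write_expansion_plans <- function(plans, path) {
  jsonlite::write_json(plans, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_expansion_plans
#' @export
read_expansion_plans <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(p) {
    list(seed_term = p$seed_term, kind = p$kind,
         left = as.character(unlist(p$left)),
         right = as.character(unlist(p$right)),
         cap = as.integer(p$cap))
  })
}
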