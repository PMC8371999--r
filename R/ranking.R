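# Candidate ranking: exhaustive cosine-similarity scan of the model
# vocabulary against a seed term's vector. Cosine can be negative for
# trained vectors; negative-scored candidates are kept and ranked rather
# than clipped, since the ordering is what matters downstream.

#' Cosine similarity between two vectors
#'
#' `dot(v1, v2) / (|v1| |v2|)`; symmetric; lies in `[-1, 1]`.
#'
#' @param v1,v2 Numeric vectors of equal, positive length and nonzero norm.
#' @return Scalar similarity.
#' @export
cosine_similarity <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    stop("vectors must have equal dimension", call. = FALSE)
  }
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    stop("cosine similarity undefined for zero-norm vectors", call. = FALSE)
  }
  sum(v1 * v2) / (n1 * n2)
}

#' Top-n candidate synonyms for a seed term
#'
#' Scans the whole model vocabulary (minus the seed itself and any
#' exclusions), scores every token by cosine similarity to the seed's
#' vector and returns the `n` best, ties broken lexicographically.
#' A seed term missing from the vocabulary yields `NULL` ("no list
#' generated"), which the evaluation layer counts against the generated
#' list total rather than treating as an error.
#'
#' @param model An `embedding_model`.
#' @param seed Seed token.
#' @param n Candidate list size (default 10).
#' @param exclusions Tokens to omit from the scan.
#' @param vectors Optional pre-computed vector matrix (rows =
#'   `model$vocab`), to amortize the export across many seeds.
#' @return A `candidate_list`: list with `seed_term`, `candidates`
#'   (data.frame `token`, `score` in non-increasing score order) and `n`;
#'   or `NULL` if the seed is out of vocabulary.
#' @export
top_candidates <- function(model, seed, n = 10L, exclusions = character(0),
                           vectors = NULL) {
  stopifnot(inherits(model, "embedding_model"), length(seed) == 1L)
  if (is.null(vectors)) vectors <- embedding_vectors(model)
  idx <- match(seed, model$vocab)
  if (is.na(idx)) return(NULL)
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative", call. = FALSE)

  sv <- vectors[idx, ]
  sn <- sqrt(sum(sv^2))
  norms <- sqrt(rowSums(vectors^2))
  scores <- as.numeric(vectors %*% sv) / (norms * sn)
  keep <- setdiff(seq_along(model$vocab), idx)
  if (length(exclusions)) {
    keep <- setdiff(keep, match(exclusions, model$vocab))
  }
  tokens <- model$vocab[keep]
  scores <- scores[keep]
  ord <- order(-scores, tokens)
  take <- ord[seq_len(min(n, length(ord)))]
  cand <- data.frame(token = tokens[take], score = unname(scores[take]),
                     stringsAsFactors = FALSE)
  rownames(cand) <- NULL
  structure(list(seed_term = seed, candidates = cand, n = n),
            class = "candidate_list")
}

#' @export
print.candidate_list <- function(x, ...) {
  cat("<candidate_list> seed '", x$seed_term, "', ", nrow(x$candidates),
      "/", x$n, " candidates\n", sep = "")
  invisible(x)
}

#' Rank candidates for every seed term of an assignment table
#'
#' @param model An `embedding_model`.
#' @param seeds Character vector of seed tokens.
#' @param n Candidate list size.
#' @return Named list of `candidate_list` objects (seeds out of
#'   vocabulary are dropped; compare `length()` against `length(seeds)`
#'   for the generated-list count).
#' @export
rank_all_seeds <- function(model, seeds, n = 10L) {
  vectors <- embedding_vectors(model)
  out <- list()
  for (s in seeds) {
    cl <- top_candidates(model, s, n = n, vectors = vectors)
    if (!is.null(cl)) out[[s]] <- cl
  }
  out
}

#' Write candidate lists as TSV
#'
#' Rows are `seed<TAB>rank<TAB>candidate<TAB>score`.
#'
#' @param lists Named list of `candidate_list` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_lists <- function(lists, path) {
  rows <- lapply(lists, function(cl) {
    if (nrow(cl$candidates) == 0L) return(NULL)
    data.frame(seed = cl$seed_term, rank = seq_len(nrow(cl$candidates)),
               candidate = cl$candidates$token,
               score = cl$candidates$score, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
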