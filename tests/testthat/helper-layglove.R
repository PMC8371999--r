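# Shared test helpers: in-code fixtures and independent oracles.

# Wrap a list of token vectors as a tokenized_corpus (bypassing
# preprocessing, for tests that construct token streams directly).
make_corpus <- function(token_docs) {
  all_tokens <- unlist(token_docs, use.names = FALSE)
  vocabulary <- if (length(all_tokens)) {
    tab <- table(all_tokens)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  names(token_docs) <- as.character(seq_along(token_docs))
  structure(list(documents = token_docs, vocabulary = vocabulary,
                 min_token_len = NA_integer_, stemmer_id = NA_character_),
            class = "tokenized_corpus")
}

# A read-only embedding model from a named row-matrix of vectors.
make_model <- function(vectors) {
  structure(list(vocab = rownames(vectors), vectors = vectors),
            class = "embedding_model")
}

# Independent co-occurrence oracle: per-distance vector shifts instead of
# the per-position window scan used by the implementation.
oracle_cooccurrence <- function(token_docs, vocab, window, weighting) {
  keys <- character(0)
  wts <- numeric(0)
  for (toks in token_docs) {
    n <- length(toks)
    if (n < 2) next
    ids <- match(toks, vocab)
    for (d in seq_len(min(window, n - 1))) {
      a <- ids[seq_len(n - d)]
      b <- ids[seq.int(1 + d, n)]
      keys <- c(keys, paste(pmin(a, b), pmax(a, b)))
      wts <- c(wts, rep(if (weighting == "flat") 1 else 1 / d, n - d))
    }
  }
  if (!length(keys)) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(wts, keys, sum)
  stats::setNames(as.numeric(out), names(out))
}

triplets_as_map <- function(mat) {
  stats::setNames(mat$triplets$x, paste(mat$triplets$i, mat$triplets$j))
}

# Random token documents over a small alphabet.
random_docs <- function(n_docs, len_range, vocab_size) {
  vocab <- sprintf("tok%03d", seq_len(vocab_size))
  lapply(seq_len(n_docs), function(i) {
    sample(vocab, sample(len_range[1]:len_range[2], 1), replace = TRUE)
  })
}

# Small in-code toy lexical resource: taxonomy root -> {m -> {a, b}, c},
# IC(m) = 2; each sense gets one-lemma surfaces suitable for relation
# queries (plus a multiword lemma on c).
toy_resource <- function() {
  load_lexical_resource(list(
    taxonomy = list(root = "", m = "root", a = "m", b = "m", c = "root"),
    ic = list(root = 0, m = 2.0, a = 3.5, b = 3.0, c = 1.0),
    lemmas = list(root = list("entity"), m = list("middle"),
                  a = list("alpha", "alephword"), b = list("betaword"),
                  c = list("gammaword", "dead_weight")),
    relations = list(
      root = list(hyponyms = list("m", "c"), hypernyms = list()),
      m = list(hyponyms = list("a", "b"), hypernyms = list("root")),
      a = list(hyponyms = list(), hypernyms = list("m")),
      b = list(hyponyms = list(), hypernyms = list("m")),
      c = list(hyponyms = list(), hypernyms = list("root")))),
    version_tag = "toy-test")
}

# The fully specified worked evaluation scenario: 25 concepts with four
# synonyms each (one seed + three held out); candidate lists of five are
# generated for 20 concepts; 15 of those lists contain exactly two true
# synonyms.
worked_example <- function() {
  cuis <- sprintf("K%02d", 1:25)
  terms <- lapply(1:25, function(k) sprintf("c%02dt%d", k, 1:4))
  assignments <- data.frame(cui = cuis,
                            seed_term = vapply(terms, `[`, character(1), 1),
                            stringsAsFactors = FALSE)
  assignments$held_out <- lapply(terms, function(ts) ts[2:4])
  lists <- list()
  for (k in 1:20) {
    hits <- if (k <= 15) terms[[k]][2:3] else character(0)
    fillers <- sprintf("c%02dfill%d", k, seq_len(5 - length(hits)))
    cand <- c(hits, fillers)
    lists[[assignments$seed_term[k]]] <- structure(
      list(seed_term = assignments$seed_term[k],
           candidates = data.frame(token = cand,
                                   score = seq(1, 0.1, length.out = 5),
                                   stringsAsFactors = FALSE),
           n = 5L),
      class = "candidate_list")
  }
  list(assignments = assignments, lists = lists)
}
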