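# Synthetic benchmark generator: a self-contained corpus + concept TSV +
# toy lexical resource with planted synonym groups. Each concept owns a
# multinomial of context tokens; its synonym tokens substitute for one
# another in identical context slots, which is the minimal generative
# process under which distributional synonymy is identifiable. Planted
# tokens are constructed to be stemmer fixed points so raw and
# preprocessed frequencies coincide.

#' Synthetic benchmark configuration
#'
#' @param n_concepts Number of planted concepts.
#' @param synonyms_per_concept Synonym tokens per concept (>= 2).
#' @param context_tokens_per_concept Topic tokens shared by a concept's
#'   synonyms.
#' @param background_vocab Number of background noise tokens.
#' @param docs Number of documents.
#' @param doc_length Tokens per document (before light punctuation /
#'   stopword noise is sprinkled in).
#' @param lexicon_coverage Fraction of each synonym group exposed through
#'   the toy lexical resource (so corpus-derived and lexicon-derived true
#'   positives stay distinguishable).
#' @param min_planted_freq Guaranteed minimum corpus frequency for every
#'   planted synonym; with the default 120 every planted synonym clears a
#'   strictly-greater-than-100 ground-truth filter.
#' @param rng_seed Integer seed; generation is fully deterministic.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_concepts = 20L, synonyms_per_concept = 3L,
                         context_tokens_per_concept = 8L,
                         background_vocab = 250L, docs = 1500L,
                         doc_length = 40L, lexicon_coverage = 0.6,
                         min_planted_freq = 120L, rng_seed = 13L) {
  stopifnot(n_concepts >= 1, synonyms_per_concept >= 2,
            context_tokens_per_concept >= 1, background_vocab >= 1,
            docs >= 1, doc_length >= 2,
            lexicon_coverage >= 0, lexicon_coverage <= 1,
            min_planted_freq >= 0)
  structure(list(n_concepts = as.integer(n_concepts),
                 synonyms_per_concept = as.integer(synonyms_per_concept),
                 context_tokens_per_concept =
                   as.integer(context_tokens_per_concept),
                 background_vocab = as.integer(background_vocab),
                 docs = as.integer(docs), doc_length = as.integer(doc_length),
                 lexicon_coverage = lexicon_coverage,
                 min_planted_freq = as.integer(min_planted_freq),
                 rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

# distinct pronounceable tokens that are Snowball fixed points
.synth_tokens <- function(n, taken = character(0)) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  fin <- c("b", "d", "f", "g", "k", "m", "p", "t", "z")
  out <- character(0)
  stop_set <- english_stopwords()
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 200000L) stop("token generation failed to converge")
    nsyl <- sample(2:3, 1L)
    w <- paste0(paste0(sample(cons, nsyl, replace = TRUE),
                       sample(vow, nsyl, replace = TRUE), collapse = ""),
                sample(fin, 1L))
    if (w %in% taken || w %in% out || w %in% stop_set) next
    if (snowball_stem(w) != w) next
    out <- c(out, w)
    taken <- c(taken, w)
  }
  out
}

#' Generate a synthetic benchmark
#'
#' Produces raw documents, a concept-to-term TSV and a toy lexical
#' resource, deterministically from `config$rng_seed`. Every planted
#' synonym is guaranteed a corpus frequency strictly greater than
#' `min_planted_freq` (booster documents are appended from the same RNG
#' stream if sampling left a synonym short).
#'
#' @param config A `synth_config`.
#' @return List with `documents` (data.frame `doc_id`, `text`),
#'   `mapping_lines` (character vector of TSV rows), `lexicon` (a
#'   `lexical_resource`), and `truth` (data.frame `cui`, `name`, `term`
#'   of the planted groups).
#' @export
generate_benchmark <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  need <- config$n_concepts * config$synonyms_per_concept *
    (config$min_planted_freq + 1L)
  budget <- config$docs * config$doc_length
  if (budget < need) {
    stop("infeasible frequency guarantee: docs * doc_length = ", budget,
         " < ", need, " required synonym occurrences", call. = FALSE)
  }

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$rng_seed)

  nc <- config$n_concepts
  spc <- config$synonyms_per_concept
  ctc <- config$context_tokens_per_concept

  names_tok <- .synth_tokens(nc)
  syn_tok <- .synth_tokens(nc * spc, taken = names_tok)
  ctx_tok <- .synth_tokens(nc * ctc, taken = c(names_tok, syn_tok))
  bg_tok <- .synth_tokens(config$background_vocab,
                          taken = c(names_tok, syn_tok, ctx_tok))

  cuis <- sprintf("C%07d", seq_len(nc))
  syn_groups <- split(syn_tok, rep(seq_len(nc), each = spc))
  ctx_groups <- split(ctx_tok, rep(seq_len(nc), each = ctc))
  # concept-specific multinomial over context tokens (geometric decay)
  ctx_probs <- 0.6^(seq_len(ctc) - 1L)
  ctx_probs <- ctx_probs / sum(ctx_probs)

  p_ctx <- 0.45
  p_syn <- 0.25
  noise_words <- c("the", "and", "was", "129", "4mg", "a")

  gen_doc <- function(concept) {
    L <- config$doc_length
    role <- sample(c("ctx", "syn", "bg"), L, replace = TRUE,
                   prob = c(p_ctx, p_syn, 1 - p_ctx - p_syn))
    toks <- character(L)
    n_ctx <- sum(role == "ctx")
    n_syn <- sum(role == "syn")
    n_bg <- L - n_ctx - n_syn
    toks[role == "ctx"] <- sample(ctx_groups[[concept]], n_ctx,
                                  replace = TRUE, prob = ctx_probs)
    toks[role == "syn"] <- sample(syn_groups[[concept]], n_syn,
                                  replace = TRUE)
    toks[role == "bg"] <- sample(bg_tok, n_bg, replace = TRUE)
    # light raw-text noise that preprocessing removes
    if (stats::runif(1) < 0.5) {
      pos <- sample.int(L, 1L)
      toks[pos] <- paste(sample(noise_words, 1L), toks[pos])
    }
    paste(toks, collapse = " ")
  }

  concepts_of_docs <- sample.int(nc, config$docs, replace = TRUE)
  texts <- vapply(concepts_of_docs, gen_doc, character(1))

  # frequency audit and deterministic top-up
  count_syn <- function(texts) {
    toks <- unlist(strsplit(texts, " ", fixed = TRUE), use.names = FALSE)
    tab <- table(factor(toks, levels = syn_tok))
    stats::setNames(as.integer(tab), syn_tok)
  }
  counts <- count_syn(texts)
  for (k in seq_len(nc)) {
    for (s in syn_groups[[k]]) {
      short <- config$min_planted_freq + 1L - counts[[s]]
      while (short > 0L) {
        per_doc <- min(short, config$doc_length %/% 2L)
        filler <- sample(ctx_groups[[k]], config$doc_length - per_doc,
                         replace = TRUE, prob = ctx_probs)
        doc <- sample(c(rep(s, per_doc), filler))
        texts <- c(texts, paste(doc, collapse = " "))
        short <- short - per_doc
      }
    }
  }

  documents <- data.frame(doc_id = sprintf("d%06d", seq_along(texts)),
                          text = texts, stringsAsFactors = FALSE)

  truth <- data.frame(
    cui = rep(cuis, each = spc),
    name = rep(names_tok, each = spc),
    term = syn_tok, stringsAsFactors = FALSE)
  mapping_lines <- paste(truth$cui, truth$name, truth$term, sep = "\t")

  lexicon <- .synth_lexicon(cuis, syn_groups, ctx_groups, bg_tok, config)

  list(documents = documents, mapping_lines = mapping_lines,
       lexicon = lexicon, truth = truth, config = config)
}

# Toy lexical resource over the planted groups: root -> branch senses ->
# concept senses (lemmas = the covered fraction of each synonym group)
# -> one narrow sense per concept (lemma = its dominant context token).
# Branch lemmas are background tokens, so hypernym insertion uses tokens
# the corpus already contains.
.synth_lexicon <- function(cuis, syn_groups, ctx_groups, bg_tok, config) {
  nc <- length(cuis)
  n_branch <- max(1L, ceiling(nc / 5))
  branch_of <- rep(seq_len(n_branch), length.out = nc)

  taxonomy <- list(root = "")
  ic <- list(root = 0)
  lemmas <- list(root = list("entiti"))
  relations <- list(root = list(hyponyms = as.list(paste0("b", seq_len(n_branch))),
                                hypernyms = list()))
  for (b in seq_len(n_branch)) {
    bs <- paste0("b", b)
    taxonomy[[bs]] <- "root"
    ic[[bs]] <- 1.5
    lemmas[[bs]] <- list(bg_tok[b])
    relations[[bs]] <- list(
      hyponyms = as.list(paste0("s_", cuis[branch_of == b])),
      hypernyms = list("root"))
  }
  for (k in seq_len(nc)) {
    cs <- paste0("s_", cuis[k])
    ns <- paste0("n_", cuis[k])
    n_cov <- round(config$lexicon_coverage * length(syn_groups[[k]]))
    covered <- syn_groups[[k]][seq_len(n_cov)]
    taxonomy[[cs]] <- paste0("b", branch_of[k])
    ic[[cs]] <- 4
    lemmas[[cs]] <- as.list(covered)
    relations[[cs]] <- list(hyponyms = list(ns),
                            hypernyms = list(paste0("b", branch_of[k])))
    taxonomy[[ns]] <- cs
    ic[[ns]] <- 6
    lemmas[[ns]] <- list(ctx_groups[[k]][1L])
    relations[[ns]] <- list(hyponyms = list(), hypernyms = list(cs))
  }
  load_lexical_resource(
    list(taxonomy = taxonomy, ic = ic, lemmas = lemmas,
         relations = relations),
    version_tag = paste0("synth-", config$rng_seed))
}

#' Write a generated benchmark to a directory
#'
#' Writes `corpus.txt` (one raw document per line), `mappings.tsv`
#' (`CUI<TAB>name<TAB>term`) and `lexicon.json`.
#'
#' @param benchmark Result of [generate_benchmark()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(benchmark$documents$text, file.path(dir, "corpus.txt"),
             useBytes = TRUE)
  writeLines(benchmark$mapping_lines, file.path(dir, "mappings.tsv"),
             useBytes = TRUE)
  lx <- benchmark$lexicon
  jsonlite::write_json(
    list(taxonomy = as.list(lx$taxonomy), ic = as.list(lx$ic),
         lemmas = lapply(lx$lemmas, as.list),
         relations = lx$relations),
    file.path(dir, "lexicon.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
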