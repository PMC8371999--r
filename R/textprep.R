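# Corpus preprocessing: raw lay-health documents -> stemmed, filtered token
# streams. The pipeline order is fixed:
#   lowercase -> strip punctuation -> drop digit tokens -> drop stopwords
#   (general + domain) -> stem -> drop tokens shorter than min_token_len
# Stemming before the length filter is what turns e.g. "fatigues" into the
# kept 6-character stem "fatigu".

#' Default general English stopwords
#'
#' The bundled Snowball-style English stopword list (lowercase, one word per
#' line, apostrophes removed so entries match the tokenizer's output).
#'
#' @return Character vector of stopwords.
#' @export
english_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "layglove")
  readLines(path, encoding = "UTF-8")
}

#' Default domain-specific stopwords
#'
#' Ubiquitous clinical-discussion words that carry almost no information in
#' a health forum corpus: "test", "doctor", "symptom", "physician". Users
#' can supply their own list instead.
#'
#' @return Character vector of four domain stopwords.
#' @export
domain_stopwords <- function() {
  c("test", "doctor", "symptom", "physician")
}

#' Preprocess a corpus of raw documents
#'
#' Normalizes raw text documents into the token streams the rest of the
#' pipeline consumes. Tokenization splits on any non-alphanumeric character
#' (so all punctuation, including apostrophes, is removed); any token
#' containing a digit is dropped entirely; stopword removal happens before
#' stemming (so stopwords are matched in their surface form); stemming uses
#' the Snowball English stemmer; finally tokens shorter than
#' `min_token_len` characters are dropped.
#'
#' @param docs Character vector of documents (one string per document), or a
#'   data.frame with columns `doc_id` and `text`.
#' @param stopwords Character vector of lowercase general stopwords.
#' @param domain_stop Character vector of lowercase domain stopwords.
#' @param min_token_len Minimum token length kept after stemming (default 3).
#' @param stemmer_id Stemmer identifier (default `"snowball-english"`).
#' @return A `tokenized_corpus` object: list with `documents` (list of
#'   character vectors of tokens, one per input document) and `vocabulary`
#'   (named integer vector, token -> corpus frequency).
#' @examples
#' tc <- preprocess_corpus("The doctor said: 2 headaches!!")
#' tc$documents[[1]]
#' @export
preprocess_corpus <- function(docs,
                              stopwords = english_stopwords(),
                              domain_stop = domain_stopwords(),
                              min_token_len = 3L,
                              stemmer_id = "snowball-english") {
  stem <- get_stemmer(stemmer_id)
  if (is.data.frame(docs)) {
    doc_ids <- as.character(docs$doc_id)
    texts <- as.character(docs$text)
    if (anyDuplicated(doc_ids)) stop("doc_id values must be unique")
  } else {
    texts <- as.character(docs)
    doc_ids <- as.character(seq_along(texts))
  }
  stopset <- c(stopwords, domain_stop)

  texts <- tolower(texts)
  token_lists <- strsplit(texts, "[^a-z0-9]+")
  documents <- lapply(token_lists, function(toks) {
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) return(character(0))
    toks <- toks[!grepl("[0-9]", toks)]
    toks <- toks[!(toks %in% stopset)]
    if (length(toks) == 0L) return(character(0))
    toks <- stem(toks)
    toks[nchar(toks) >= min_token_len]
  })
  names(documents) <- doc_ids

  all_tokens <- unlist(documents, use.names = FALSE)
  vocabulary <- if (length(all_tokens)) {
    tab <- table(all_tokens)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }

  structure(
    list(documents = documents, vocabulary = vocabulary,
         min_token_len = as.integer(min_token_len), stemmer_id = stemmer_id),
    class = "tokenized_corpus"
  )
}

#' @export
print.tokenized_corpus <- function(x, ...) {
  cat("<tokenized_corpus> ", length(x$documents), " documents, ",
      sum(x$vocabulary), " tokens, ", length(x$vocabulary),
      " vocabulary types\n", sep = "")
  invisible(x)
}

#' Corpus term frequencies
#'
#' @param corpus A `tokenized_corpus`.
#' @return Named integer vector, token -> count; sums to the total token
#'   count of the corpus.
#' @export
term_frequencies <- function(corpus) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  corpus$vocabulary
}

#' Read raw documents from a plain-text file
#'
#' One document per line, UTF-8. If `path` is a directory, every regular
#' file in it is read, one document per line across files.
#'
#' @param path File or directory path.
#' @return Data.frame with columns `doc_id`, `text`.
#' @export
read_raw_documents <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, full.names = TRUE)
  } else {
    if (!file.exists(path)) stop("input not found: ", path)
    path
  }
  lines <- unlist(lapply(files, readLines, encoding = "UTF-8"),
                  use.names = FALSE)
  data.frame(doc_id = as.character(seq_along(lines)), text = lines,
             stringsAsFactors = FALSE)
}

#' Write / read a tokenized corpus as plain text
#'
#' One space-joined document per line; the vocabulary can be written
#' alongside as a `token<TAB>count` TSV.
#'
#' @param corpus A `tokenized_corpus`.
#' @param path Output path for the corpus text.
#' @param vocab_path Optional output path for the vocabulary TSV.
#' @return `path`, invisibly.
#' @export
write_tokenized_corpus <- function(corpus, path, vocab_path = NULL) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  writeLines(vapply(corpus$documents, paste, character(1), collapse = " "),
             path, useBytes = TRUE)
  if (!is.null(vocab_path)) {
    utils::write.table(
      data.frame(token = names(corpus$vocabulary),
                 count = as.integer(corpus$vocabulary)),
      vocab_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_tokenized_corpus
#' @export
read_tokenized_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  documents <- strsplit(lines, " ", fixed = TRUE)
  documents <- lapply(documents, function(t) t[nzchar(t)])
  names(documents) <- as.character(seq_along(documents))
  all_tokens <- unlist(documents, use.names = FALSE)
  vocabulary <- if (length(all_tokens)) {
    tab <- table(all_tokens)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(list(documents = documents, vocabulary = vocabulary,
                 min_token_len = NA_integer_, stemmer_id = NA_character_),
            class = "tokenized_corpus")
}
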