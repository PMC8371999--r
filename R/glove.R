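# GloVe: a global word-word co-occurrence matrix built in one pass over
# the corpus, then a weighted least-squares log-bilinear fit
#   sum_{ij: X_ij > 0} f(X_ij) (w_i . w~_j + b_i + b~_j - log X_ij)^2
# with f(x) = (x / x_max)^alpha for x < x_max, else 1, minimized by
# AdaGrad over shuffled nonzero entries. Optimizer defaults (x_max 100,
# alpha 0.75, learning rate 0.05, symmetric window, export vector
# w + w~) follow the original GloVe formulation.

#' Build the global co-occurrence matrix
#'
#' Counts co-occurrences of token pairs at distance at most `window`
#' within each document (windows are symmetric around the pivot and never
#' cross document boundaries). Each unordered pair occurrence contributes
#' weight 1 (`"flat"`) or `1/d` for distance `d` (`"inverse-distance"`,
#' the default) to both `X_ij` and `X_ji`.
#'
#' @param corpus A `tokenized_corpus`.
#' @param window Window size (>= 1).
#' @param weighting `"inverse-distance"` or `"flat"`.
#' @return A `cooccurrence_matrix`: list with `vocab` (sorted character
#'   vector), `triplets` (data.frame `i`, `j`, `x` with `i <= j`, 1-based
#'   into `vocab`, representing a symmetric matrix), `window`, `weighting`.
#' @export
build_cooccurrence <- function(corpus, window,
                               weighting = c("inverse-distance", "flat")) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  weighting <- match.arg(weighting)
  if (!is.numeric(window) || window < 1) {
    stop("window must be an integer >= 1", call. = FALSE)
  }
  vocab <- sort(names(corpus$vocabulary))
  docs <- lapply(corpus$documents, function(toks) {
    match(toks, vocab) - 1L
  })
  tr <- .cpp_build_cooccurrence(docs, as.integer(window),
                                weighting == "inverse-distance")
  structure(
    list(vocab = vocab,
         triplets = data.frame(i = tr$i, j = tr$j, x = tr$x),
         window = as.integer(window), weighting = weighting),
    class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat("<cooccurrence_matrix> ", length(x$vocab), " types, ",
      nrow(x$triplets), " nonzero pairs, window ", x$window, " (",
      x$weighting, ")\n", sep = "")
  invisible(x)
}

#' Extract one token's co-occurrence row as a named vector
#'
#' @param matrix A `cooccurrence_matrix`.
#' @param token Token whose row to extract.
#' @return Named numeric vector over co-occurring tokens (nonzero entries
#'   only).
#' @export
cooccurrence_row <- function(matrix, token) {
  stopifnot(inherits(matrix, "cooccurrence_matrix"))
  idx <- match(token, matrix$vocab)
  if (is.na(idx)) return(stats::setNames(numeric(0), character(0)))
  tr <- matrix$triplets
  sel_i <- tr$i == idx
  sel_j <- tr$j == idx
  other <- c(tr$j[sel_i], tr$i[sel_j & !sel_i])
  vals <- c(tr$x[sel_i], tr$x[sel_j & !sel_i])
  stats::setNames(vals, matrix$vocab[other])
}

#' Training configuration for the embedding model
#'
#' @param dim Vector size (the corpus-scale experiments of the source
#'   method favored 400; smaller synthetic corpora train well at 50).
#' @param epochs Number of passes over the nonzero entries.
#' @param x_max,alpha Weighting-function parameters `f(x) = (x/x_max)^alpha`.
#' @param learning_rate AdaGrad initial step size.
#' @param rng_seed Integer seed controlling initialization and shuffling.
#' @return A `training_config` list.
#' @export
training_config <- function(dim = 400L, epochs = 25L, x_max = 100,
                            alpha = 0.75, learning_rate = 0.05,
                            rng_seed = 1L) {
  stopifnot(dim >= 1, epochs >= 0, alpha > 0, alpha <= 1, x_max > 0,
            learning_rate > 0)
  structure(list(dim = as.integer(dim), epochs = as.integer(epochs),
                 x_max = x_max, alpha = alpha,
                 learning_rate = learning_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "training_config")
}

#' Train GloVe-style embeddings from a co-occurrence matrix
#'
#' Fits the log-bilinear model by per-coordinate AdaGrad updates over the
#' shuffled nonzero entries of the full symmetric matrix. Deterministic
#' given `config$rng_seed`. An empty matrix yields seeded initial vectors
#' with a warning.
#'
#' @param matrix A `cooccurrence_matrix`.
#' @param config A `training_config`.
#' @return An `embedding_model`: `vocab`, `W` and `C` (vocab x dim main
#'   and context matrices), `b`, `b_ctx`, `epoch_loss`, `config`.
#' @export
train_embeddings <- function(matrix, config = training_config()) {
  stopifnot(inherits(matrix, "cooccurrence_matrix"),
            inherits(config, "training_config"))
  tr <- matrix$triplets
  n_vocab <- length(matrix$vocab)
  if (nrow(tr) == 0L) {
    warning("empty co-occurrence matrix; returning initialized vectors")
    fit <- .cpp_train_glove(integer(0), integer(0), numeric(0), n_vocab,
                            config$dim, 0L, config$x_max, config$alpha,
                            config$learning_rate, config$rng_seed)
    fit$epoch_loss <- numeric(0)
  } else {
    off <- tr$i != tr$j
    ti <- c(tr$i, tr$j[off])
    tj <- c(tr$j, tr$i[off])
    tx <- c(tr$x, tr$x[off])
    fit <- .cpp_train_glove(ti, tj, tx, n_vocab, config$dim, config$epochs,
                            config$x_max, config$alpha,
                            config$learning_rate, config$rng_seed)
  }
  rownames(fit$W) <- matrix$vocab
  rownames(fit$C) <- matrix$vocab
  structure(list(vocab = matrix$vocab, W = fit$W, C = fit$C, b = fit$b,
                 b_ctx = fit$b_ctx, epoch_loss = as.numeric(fit$epoch_loss),
                 config = config),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  d <- if (!is.null(x$W)) ncol(x$W) else ncol(x$vectors)
  cat("<embedding_model> ", length(x$vocab), " types, dim ", d, "\n",
      sep = "")
  invisible(x)
}

#' Export word vectors from a model
#'
#' The default export is the sum of the main and context vectors; the
#' main vectors alone are available via `which = "main"`.
#'
#' @param model An `embedding_model`.
#' @param which `"combined"` (default) or `"main"`.
#' @return Numeric matrix, one row per vocabulary token.
#' @export
embedding_vectors <- function(model, which = c("combined", "main")) {
  which <- match.arg(which)
  if (!is.null(model$vectors)) return(model$vectors)  # loaded from disk
  if (which == "combined") model$W + model$C else model$W
}

#' Save / load embeddings in word-per-line text format
#'
#' Each line is `token v1 ... vd`. Loading returns a read-only model
#' (export vectors only).
#'
#' @param model An `embedding_model`.
#' @param path File path.
#' @param which Which vectors to export (see [embedding_vectors()]).
#' @return `path` invisibly; `load_embeddings()` returns an
#'   `embedding_model` whose `vectors` field holds the loaded matrix.
#' @export
save_embeddings <- function(model, path, which = "combined") {
  vec <- embedding_vectors(model, which)
  lines <- vapply(seq_len(nrow(vec)), function(r) {
    paste(c(model$vocab[r], sprintf("%.10g", vec[r, ])), collapse = " ")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_embeddings
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(list(vocab = character(0),
                          vectors = matrix(numeric(0), 0, 0)),
                     class = "embedding_model"))
  }
  parts <- strsplit(lines, " ", fixed = TRUE)
  dims <- unique(lengths(parts))
  if (length(dims) != 1L) {
    stop("ragged embedding file: rows of differing dimension", call. = FALSE)
  }
  vocab <- vapply(parts, `[[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                  numeric(dims - 1L)))
  if (anyNA(vec)) stop("non-numeric vector entries in embedding file")
  rownames(vec) <- vocab
  structure(list(vocab = vocab, vectors = vec), class = "embedding_model")
}

#' Serialize / load a co-occurrence matrix
#'
#' Triplets go to `path` as TSV `i<TAB>j<TAB>weight`; vocabulary, window
#' and weighting go to a JSON header at `paste0(path, ".json")`.
#'
#' @param matrix A `cooccurrence_matrix`.
#' @param path Triplet TSV path.
#' @return `path` invisibly; `read_cooccurrence()` returns the matrix.
#' @export
write_cooccurrence <- function(matrix, path) {
  utils::write.table(matrix$triplets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(vocab = matrix$vocab, window = matrix$window,
         weighting = matrix$weighting),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cooccurrence
#' @export
read_cooccurrence <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tr <- utils::read.table(path, sep = "\t",
                          col.names = c("i", "j", "x"))
  structure(list(vocab = hdr$vocab, triplets = tr,
                 window = as.integer(hdr$window), weighting = hdr$weighting),
            class = "cooccurrence_matrix")
}
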