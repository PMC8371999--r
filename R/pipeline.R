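# End-to-end orchestration: preprocess -> ground truth -> (optional)
# lexical expansion -> co-occurrence -> training -> ranking -> evaluation,
# with every intermediate artifact and a provenance record written to the
# output directory. Identical configurations produce identical outputs.

#' Pipeline run configuration
#'
#' Defaults follow the method's best corpus-scale settings: window 30,
#' vector size 400, expansion cap 10, candidate list size 10, frequency
#' threshold 100. Smaller corpora (like the synthetic benchmark) train
#' well with smaller `dim`/`window`; pass them explicitly.
#'
#' @param corpus Path to raw corpus (one document per line) or a
#'   data.frame with `doc_id`, `text`.
#' @param mappings Path to the concept TSV (or character vector of rows).
#' @param lexicon Path to a lexical-resource JSON, a `lexical_resource`,
#'   or `NULL` (required when `relation != "none"`).
#' @param out_dir Output directory for artifacts.
#' @param relation `"none"` (basic baseline), `"synonym"`, `"hyponym"` or
#'   `"hypernym"`.
#' @param window,weighting Co-occurrence parameters.
#' @param dim,epochs,x_max,alpha,learning_rate,train_seed Training
#'   parameters (see [training_config()]).
#' @param cap,split_mode Expansion parameters (see [rank_and_split()]).
#' @param n Candidate list size.
#' @param min_freq,min_terms Ground-truth filters.
#' @param min_token_len,stemmer_id Preprocessing parameters.
#' @param seed_rng Seed for the random seed-term draw.
#' @return A `run_config` list.
#' @export
run_config <- function(corpus, mappings, lexicon = NULL, out_dir,
                       relation = c("none", "synonym", "hyponym",
                                    "hypernym"),
                       window = 30L, weighting = "inverse-distance",
                       dim = 400L, epochs = 25L, x_max = 100,
                       alpha = 0.75, learning_rate = 0.05,
                       train_seed = 1L, cap = 10L,
                       split_mode = "roundrobin", n = 10L,
                       min_freq = 100L, min_terms = 2L,
                       min_token_len = 3L,
                       stemmer_id = "snowball-english", seed_rng = 13L) {
  relation <- match.arg(relation)
  if (relation != "none" && is.null(lexicon)) {
    stop("a lexical resource is required for relation '", relation, "'",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full enrichment pipeline
#'
#' Executes every stage of the vocabulary-enrichment pipeline and writes
#' intermediate artifacts (tokenized and expanded corpora, vocabulary,
#' assignments, expansion plans, embeddings, candidate lists, evaluation
#' report, provenance JSON) under `config$out_dir`. Any stage error
#' aborts with the stage name.
#'
#' @param config A `run_config`.
#' @return The `evaluation_report`, with the artifact directory in
#'   attribute `"out_dir"` and the assignment table in attribute
#'   `"assignments"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  docs <- .stage("read-corpus", {
    if (is.data.frame(config$corpus)) config$corpus
    else read_raw_documents(config$corpus)
  })
  corpus <- .stage("preprocess", {
    tc <- preprocess_corpus(docs, min_token_len = config$min_token_len,
                            stemmer_id = config$stemmer_id)
    write_tokenized_corpus(tc, file.path(out, "corpus.tokens.txt"),
                           vocab_path = file.path(out, "vocab.tsv"))
    tc
  })
  gt <- .stage("ground-truth", {
    records <- load_concept_mappings(config$mappings)
    build_ground_truth(records, term_frequencies(corpus),
                       min_freq = config$min_freq,
                       min_terms = config$min_terms,
                       stemmer_id = config$stemmer_id)
  })
  assignments <- .stage("assign-seeds", {
    a <- assign_seeds(gt, rng_seed = config$seed_rng)
    write_assignments(a, file.path(out, "assignments.tsv"))
    utils::write.table(gt$terms, file.path(out, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(gt$stats, file.path(out, "ground_truth_stats.json"),
                         auto_unbox = TRUE)
    a
  })

  train_corpus <- corpus
  if (config$relation != "none") {
    train_corpus <- .stage("expand", {
      resource <- if (inherits(config$lexicon, "lexical_resource")) {
        config$lexicon
      } else {
        load_lexical_resource(config$lexicon,
                              stemmer_id = config$stemmer_id)
      }
      plans <- build_expansion_plans(assignments$seed_term,
                                     kind = config$relation,
                                     resource = resource,
                                     cap = config$cap,
                                     mode = config$split_mode)
      write_expansion_plans(plans, file.path(out, "plans.json"))
      ec <- expand_corpus(corpus, plans)
      write_tokenized_corpus(ec, file.path(out, "corpus.expanded.txt"))
      ec
    })
  }

  model <- .stage("train", {
    mat <- build_cooccurrence(train_corpus, window = config$window,
                              weighting = config$weighting)
    cfg <- training_config(dim = config$dim, epochs = config$epochs,
                           x_max = config$x_max, alpha = config$alpha,
                           learning_rate = config$learning_rate,
                           rng_seed = config$train_seed)
    m <- train_embeddings(mat, cfg)
    save_embeddings(m, file.path(out, "embeddings.txt"))
    m
  })

  lists <- .stage("rank", {
    l <- rank_all_seeds(model, assignments$seed_term, n = config$n)
    write_candidate_lists(l, file.path(out, "candidates.tsv"))
    l
  })

  report <- .stage("evaluate", {
    r <- evaluate_lists(lists, assignments, n = config$n,
                        dataset_size = nrow(assignments))
    write_report(r, file.path(out, "report.json"))
    r
  })

  .stage("provenance", {
    prov <- config
    prov$corpus <- if (is.character(config$corpus)) config$corpus
    else "<in-memory>"
    prov$mappings <- if (length(config$mappings) == 1L) config$mappings
    else "<in-memory>"
    prov$lexicon <- if (is.character(config$lexicon)) config$lexicon
    else if (is.null(config$lexicon)) NULL
    else config$lexicon$version_tag
    jsonlite::write_json(
      c(unclass(prov),
        list(package_version =
               as.character(utils::packageVersion("layglove")),
             r_version = R.version.string)),
      file.path(out, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  })

  attr(report, "out_dir") <- out
  attr(report, "assignments") <- assignments
  report
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
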