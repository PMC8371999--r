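# Evaluation of candidate lists against held-out synonyms.
#
# Two averaging views: the micro average counts retrieved synonym terms
# (each concept/synonym pair at most once), the macro average counts
# concepts with at least one retrieved synonym. Precision denominators
# run over generated candidate lists only; recall denominators run over
# the whole ground-truth dataset. NumCon is the number of concepts with
# at least one hit; MRR averages the reciprocal rank of the first hit
# over generated lists (misses contribute 0 by default).

.f_score <- function(p, r) {
  if ((p + r) == 0) 0 else 2 * p * r / (p + r)
}

#' Score candidate lists against seed assignments
#'
#' A candidate counts as a true synonym iff its (stemmed) surface equals
#' one of the held-out synonyms of the list's concept; each
#' concept/synonym pair is counted at most once, so duplicated candidates
#' cannot double-count a synonym.
#'
#' @param lists Named list of `candidate_list` objects (names = seed
#'   terms).
#' @param assignments Data.frame from [assign_seeds()].
#' @return Data.frame of per-concept match records: `cui`, `seed_term`,
#'   `n_candidates`, `tp` (distinct held-out synonyms retrieved),
#'   `first_hit_rank` (1-based, `NA` when no hit).
#' @export
score_lists <- function(lists, assignments) {
  seeds <- vapply(lists, `[[`, character(1), "seed_term")
  idx <- match(seeds, assignments$seed_term)
  if (anyNA(idx)) {
    stop("candidate list seed(s) without assignment: ",
         paste(seeds[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop("multiple candidate lists map to one assignment", call. = FALSE)
  }
  recs <- lapply(seq_along(lists), function(k) {
    cl <- lists[[k]]
    a <- assignments[idx[k], ]
    held <- a$held_out[[1L]]
    cand <- cl$candidates$token
    is_hit <- cand %in% held
    data.frame(cui = a$cui, seed_term = cl$seed_term,
               n_candidates = length(cand),
               tp = length(intersect(cand, held)),
               first_hit_rank = if (any(is_hit)) which(is_hit)[1L]
                                else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(cui = character(0), seed_term = character(0),
                      n_candidates = integer(0), tp = integer(0),
                      first_hit_rank = integer(0), stringsAsFactors = FALSE)
  }
  out
}

#' Micro-averaged precision, recall and F
#'
#' Precision divides retrieved true synonyms by the total candidate count
#' (generated lists times `n`); recall divides by the total number of
#' held-out synonyms in the ground-truth dataset.
#'
#' @param records Data.frame from [score_lists()].
#' @param assignments Full assignment table (recall denominator runs over
#'   all concepts, generated or not).
#' @param n Candidate list size.
#' @return List with `precision`, `recall`, `f_score`.
#' @export
micro_metrics <- function(records, assignments, n) {
  tp <- sum(records$tp)
  denom_p <- nrow(records) * n
  denom_r <- sum(lengths(assignments$held_out))
  p <- if (denom_p == 0) {
    warning("no candidate terms; micro precision reported as 0")
    0
  } else {
    tp / denom_p
  }
  r <- if (denom_r == 0) {
    warning("empty ground truth; micro recall reported as 0")
    0
  } else {
    tp / denom_r
  }
  list(precision = p, recall = r, f_score = .f_score(p, r))
}

#' Macro-averaged precision, recall and F
#'
#' Precision divides hit concepts by the number of generated candidate
#' lists; recall divides by the total number of concepts in the
#' ground-truth dataset.
#'
#' @param records Data.frame from [score_lists()].
#' @param dataset_size Number of concepts in the ground-truth dataset.
#' @return List with `precision`, `recall`, `f_score`.
#' @export
macro_metrics <- function(records, dataset_size) {
  hits <- sum(records$tp > 0)
  p <- if (nrow(records) == 0) {
    warning("no candidate lists; macro precision reported as 0")
    0
  } else {
    hits / nrow(records)
  }
  r <- if (dataset_size == 0) {
    warning("empty ground truth; macro recall reported as 0")
    0
  } else {
    hits / dataset_size
  }
  list(precision = p, recall = r, f_score = .f_score(p, r))
}

#' Mean reciprocal rank of the first true synonym
#'
#' @param records Data.frame from [score_lists()].
#' @param misses_as_zero Average over all generated lists with 0 for
#'   lists without a hit (default); `FALSE` averages over hit lists only.
#' @return MRR in `[0, 1]` (0 when there are no applicable lists).
#' @export
mean_reciprocal_rank <- function(records, misses_as_zero = TRUE) {
  rr <- ifelse(is.na(records$first_hit_rank), 0,
               1 / records$first_hit_rank)
  if (!misses_as_zero) rr <- rr[!is.na(records$first_hit_rank)]
  if (length(rr) == 0) return(0)
  mean(rr)
}

#' Full evaluation report for a set of candidate lists
#'
#' @param lists Named list of `candidate_list` objects.
#' @param assignments Data.frame from [assign_seeds()].
#' @param n Candidate list size used for ranking.
#' @param dataset_size Number of ground-truth concepts (defaults to
#'   `nrow(assignments)`).
#' @return An `evaluation_report`: `num_con`, `micro` and `macro`
#'   (`precision`, `recall`, `f_score` each), `mrr`, and bookkeeping
#'   counts (`lists_generated`, `total_candidates`, `total_truths`,
#'   `true_positive_count`).
#' @export
evaluate_lists <- function(lists, assignments, n,
                           dataset_size = nrow(assignments)) {
  records <- score_lists(lists, assignments)
  micro <- micro_metrics(records, assignments, n)
  macro <- macro_metrics(records, dataset_size)
  structure(
    list(num_con = sum(records$tp > 0),
         micro = micro, macro = macro,
         mrr = mean_reciprocal_rank(records),
         lists_generated = nrow(records),
         total_candidates = sum(records$n_candidates),
         total_truths = sum(lengths(assignments$held_out)),
         true_positive_count = sum(records$tp)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat("<evaluation_report>\n")
  cat("  lists generated: ", x$lists_generated, ", NumCon: ", x$num_con,
      "\n", sep = "")
  cat(sprintf("  micro P/R/F: %.*f / %.*f / %.*f\n", digits,
              x$micro$precision, digits, x$micro$recall, digits,
              x$micro$f_score))
  cat(sprintf("  macro P/R/F: %.*f / %.*f / %.*f\n", digits,
              x$macro$precision, digits, x$macro$recall, digits,
              x$macro$f_score))
  cat(sprintf("  MRR: %.*f\n", digits, x$mrr))
  invisible(x)
}

#' Sweep the candidate-list size
#'
#' Ranks each seed once at `max(n_values)` and evaluates every requested
#' prefix, so the sweep reuses a single ranked scan per seed.
#'
#' @param model An `embedding_model`.
#' @param assignments Data.frame from [assign_seeds()].
#' @param n_values Positive ascending integer vector of list sizes.
#' @param dataset_size Number of ground-truth concepts.
#' @return Data.frame with one row per `n`: micro precision/recall/F and
#'   `num_con`.
#' @export
sweep_candidate_size <- function(model, assignments, n_values,
                                 dataset_size = nrow(assignments)) {
  stopifnot(all(n_values >= 1), !is.unsorted(n_values))
  n_max <- max(n_values)
  full <- rank_all_seeds(model, assignments$seed_term, n = n_max)
  rows <- lapply(n_values, function(n) {
    pref <- lapply(full, function(cl) {
      cl$candidates <- cl$candidates[seq_len(min(n, nrow(cl$candidates))), ,
                                     drop = FALSE]
      cl$n <- as.integer(n)
      cl
    })
    rep <- evaluate_lists(pref, assignments, n, dataset_size)
    data.frame(n = n, micro_precision = rep$micro$precision,
               micro_recall = rep$micro$recall,
               micro_f = rep$micro$f_score, num_con = rep$num_con)
  })
  do.call(rbind, rows)
}

#' Relative F-score improvement between two algorithms
#'
#' `(f_b - f_a) / f_a`, reported as a percentage rounded to the nearest
#' integer. Inputs can be macro F values (any consistent scale),
#' `evaluation_report` objects, or lists of reports whose macro F values
#' are averaged first (the usual way results over two ground-truth
#' datasets are combined).
#'
#' @param report_a Baseline: number, report, or list of reports.
#' @param report_b Comparison algorithm, same forms.
#' @return List with `f_a`, `f_b`, `relative_improvement_pct` (integer,
#'   `NA` when `f_a` is 0 and the ratio is undefined).
#' @export
compare_algorithms <- function(report_a, report_b) {
  as_f <- function(x) {
    if (is.numeric(x)) return(mean(x))
    if (inherits(x, "evaluation_report")) return(x$macro$f_score)
    if (is.list(x)) {
      return(mean(vapply(x, function(r) as_f(r), numeric(1))))
    }
    stop("cannot extract a macro F value", call. = FALSE)
  }
  f_a <- as_f(report_a)
  f_b <- as_f(report_b)
  pct <- if (f_a == 0) NA_integer_ else as.integer(round(100 * (f_b - f_a) / f_a))
  list(f_a = f_a, f_b = f_b, relative_improvement_pct = pct)
}

#' Exact McNemar test on paired per-concept hit indicators
#'
#' Supplementary significance tooling (this package's own choice of
#' paired test, not part of the published evaluation framework): compares
#' two algorithms' per-concept hit/miss indicators over the same concepts
#' with an exact binomial test on the discordant pairs.
#'
#' @param records_a,records_b Data.frames from [score_lists()] over the
#'   same assignment table.
#' @return `htest`-like list with `b` (hits only in A), `c` (hits only in
#'   B) and the two-sided exact `p.value`.
#' @export
paired_hit_mcnemar <- function(records_a, records_b) {
  cuis <- intersect(records_a$cui, records_b$cui)
  ha <- records_a$tp[match(cuis, records_a$cui)] > 0
  hb <- records_b$tp[match(cuis, records_b$cui)] > 0
  b <- sum(ha & !hb)
  cc <- sum(!ha & hb)
  p <- if (b + cc == 0) 1 else stats::binom.test(b, b + cc, 0.5)$p.value
  list(b = b, c = cc, n_pairs = length(cuis), p.value = p)
}
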