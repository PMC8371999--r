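test_that("the fully specified worked scenario reproduces all four ratios", {
  wx <- worked_example()
  records <- score_lists(wx$lists, wx$assignments)
  micro <- micro_metrics(records, wx$assignments, n = 5)
  macro <- macro_metrics(records, dataset_size = 25)
  expect_identical(micro$precision, 30 / 100)
  expect_identical(micro$recall, 30 / 75)
  expect_identical(macro$precision, 15 / 20)
  expect_identical(macro$recall, 15 / 25)
})

test_that("match records count each concept/synonym pair at most once", {
  assignments <- data.frame(cui = "C1", seed_term = "seed",
                            stringsAsFactors = FALSE)
  assignments$held_out <- list(c("syn1", "syn2"))
  mk_list <- function(cand) {
    structure(list(seed_term = "seed",
                   candidates = data.frame(token = cand,
                                           score = seq(1, 0.1,
                                                       length.out =
                                                         length(cand)),
                                           stringsAsFactors = FALSE),
                   n = length(cand)), class = "candidate_list")
  }
  r <- score_lists(list(mk_list(c("syn1", "syn2", "x"))), assignments)
  expect_equal(r$tp, 2L)
  r <- score_lists(list(mk_list(c("x", "y"))), assignments)
  expect_equal(r$tp, 0L)
  expect_true(is.na(r$first_hit_rank))
  # a duplicated candidate matches one synonym only once
  r <- score_lists(list(mk_list(c("syn1", "syn1", "x"))), assignments)
  expect_equal(r$tp, 1L)
  expect_equal(r$first_hit_rank, 1L)

  orphan <- mk_list("x")
  orphan$seed_term <- "nobody"
  expect_error(score_lists(list(orphan), assignments), "without assignment")
})

test_that("macro metrics divide hits by generated lists and dataset size", {
  assignments <- data.frame(cui = c("C1", "C2"),
                            seed_term = c("s1", "s2"),
                            stringsAsFactors = FALSE)
  assignments$held_out <- list("h1", "h2")
  lists <- list(
    s1 = structure(list(seed_term = "s1",
                        candidates = data.frame(token = c("h1", "x"),
                                                score = c(1, 0.5)),
                        n = 2L), class = "candidate_list"),
    s2 = structure(list(seed_term = "s2",
                        candidates = data.frame(token = c("x", "y"),
                                                score = c(1, 0.5)),
                        n = 2L), class = "candidate_list"))
  records <- score_lists(lists, assignments)
  macro <- macro_metrics(records, dataset_size = 4)
  expect_equal(macro$precision, 0.5)
  expect_equal(macro$recall, 0.25)
})

test_that("mean reciprocal rank averages first-hit reciprocals", {
  recs <- data.frame(cui = "C1", seed_term = "s", n_candidates = 5,
                     tp = 1L, first_hit_rank = 1L)
  expect_equal(mean_reciprocal_rank(recs), 1.0)
  recs <- data.frame(cui = c("C1", "C2"), seed_term = c("s1", "s2"),
                     n_candidates = 5, tp = 1L,
                     first_hit_rank = c(2L, 4L))
  expect_equal(mean_reciprocal_rank(recs), 0.375)
  recs$first_hit_rank <- NA_integer_
  expect_equal(mean_reciprocal_rank(recs), 0)
  expect_equal(mean_reciprocal_rank(recs[0, ]), 0)
  # hits-only averaging variant
  recs$first_hit_rank <- c(2L, NA)
  expect_equal(mean_reciprocal_rank(recs, misses_as_zero = FALSE), 0.5)
})

test_that("degenerate inputs report zero metrics with a warning", {
  assignments <- data.frame(cui = "C1", seed_term = "s1",
                            stringsAsFactors = FALSE)
  assignments$held_out <- list("h1")
  warns <- capture_warnings(rep0 <- evaluate_lists(list(), assignments,
                                                   n = 5))
  expect_match(warns, "precision", all = TRUE)
  expect_equal(rep0$micro$recall, 0)
  expect_equal(rep0$macro$f_score, 0)
  expect_equal(rep0$num_con, 0L)
})

test_that("F is the harmonic mean, zero at zero, within its bounds", {
  expect_equal(layglove:::.f_score(0, 0), 0)
  set.seed(14)
  for (k in 1:50) {
    p <- stats::runif(1)
    r <- stats::runif(1)
    f <- layglove:::.f_score(p, r)
    expect_gte(f, 0)
    expect_lte(f, 1)
    lo <- min(p, r)
    hi <- max(p, r)
    expect_lte(f, lo * 2 / (1 + lo / hi) + 1e-12)
  }
})

test_that("relative improvement reproduces the printed averages", {
  cmp <- compare_algorithms(48.835, 61.08)
  expect_equal(cmp$relative_improvement_pct, 25L)
  expect_equal(compare_algorithms(10, 10)$relative_improvement_pct, 0L)
  expect_equal(compare_algorithms(50, 40)$relative_improvement_pct, -20L)
  expect_true(is.na(compare_algorithms(0, 40)$relative_improvement_pct))
  # averaging two per-dataset F values first
  cmp <- compare_algorithms(c(48.44, 49.23), c(57.87, 64.29))
  expect_equal(cmp$f_a, 48.835)
  expect_equal(cmp$f_b, 61.08)
  expect_equal(cmp$relative_improvement_pct, 25L)
})

test_that("candidate-size sweep finds the rank of the planted truth", {
  # 2-D model where the only true synonym sits at rank 3 for the seed
  model <- make_model(rbind(seedw = c(1, 0),
                            near1 = c(0.99, 0.01),
                            near2 = c(0.98, 0.02),
                            truth = c(0.97, 0.03),
                            far1 = c(0, 1), far2 = c(-1, 0)))
  assignments <- data.frame(cui = "C1", seed_term = "seedw",
                            stringsAsFactors = FALSE)
  assignments$held_out <- list("truth")
  sw <- sweep_candidate_size(model, assignments, n_values = 1:5)
  expect_equal(sw$num_con, c(0L, 0L, 1L, 1L, 1L))
  expect_true(all(diff(sw$micro_recall) >= 0))
  expect_true(all(diff(sw$num_con) >= 0))
})

test_that("micro recall and NumCon are non-decreasing in n generally", {
  set.seed(53)
  vocab <- sprintf("w%02d", 1:40)
  vec <- matrix(stats::rnorm(40 * 5), 40, 5, dimnames = list(vocab, NULL))
  model <- make_model(vec)
  assignments <- data.frame(cui = sprintf("C%d", 1:6),
                            seed_term = vocab[1:6],
                            stringsAsFactors = FALSE)
  assignments$held_out <- lapply(1:6, function(k) {
    sample(vocab[7:40], 3)
  })
  sw <- sweep_candidate_size(model, assignments, n_values = c(1:10, 20, 39))
  expect_true(all(diff(sw$micro_recall) >= 0))
  expect_true(all(diff(sw$num_con) >= 0))
})

test_that("macro precision dominates recall when lists <= dataset", {
  set.seed(54)
  wx <- worked_example()
  records <- score_lists(wx$lists, wx$assignments)
  macro <- macro_metrics(records, dataset_size = 25)
  expect_gte(macro$precision, macro$recall)
})

test_that("paired hit indicators feed an exact McNemar test", {
  ra <- data.frame(cui = sprintf("C%d", 1:10), tp = c(rep(1L, 8), 0L, 0L))
  rb <- data.frame(cui = sprintf("C%d", 1:10), tp = c(rep(1L, 2),
                                                      rep(0L, 8)))
  out <- paired_hit_mcnemar(ra, rb)
  expect_equal(out$b, 6L)
  expect_equal(out$c, 0L)
  expect_equal(out$p.value, stats::binom.test(6, 6, 0.5)$p.value)
  expect_equal(paired_hit_mcnemar(ra, ra)$p.value, 1)
})
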