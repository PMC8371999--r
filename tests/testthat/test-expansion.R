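syno_scored <- data.frame(
  surface = c("worry", "cephalalgia", "concern", "vexation"),
  score = c(4, 3, 2, 1), stringsAsFactors = FALSE)

test_that("halves split puts the top half left, contiguously", {
  sp <- rank_and_split(syno_scored, mode = "halves")
  expect_equal(sp$left, c("worry", "cephalalgia"))
  expect_equal(sp$right, c("concern", "vexation"))
})

test_that("round-robin split alternates in descending score order", {
  scored <- data.frame(surface = c("a", "b", "c", "d", "e"),
                       score = 5:1, stringsAsFactors = FALSE)
  sp <- rank_and_split(scored, mode = "roundrobin")
  expect_equal(sp$left, c("a", "c", "e"))
  expect_equal(sp$right, c("b", "d"))
})

test_that("cap truncates to the most similar items; ties break on surface", {
  scored <- data.frame(surface = sprintf("w%02d", 1:12),
                       score = c(rep(5, 3), 9:1),
                       stringsAsFactors = FALSE)
  sp <- rank_and_split(scored, cap = 10)
  expect_equal(length(sp$left) + length(sp$right), 10L)
  # score-5 trio w01 w02 w03 rank after the 9..6 block, ordered by surface
  interleaved <- character(10)
  interleaved[seq(1, 10, 2)] <- sp$left
  interleaved[seq(2, 10, 2)] <- sp$right
  expect_equal(interleaved[5:7], c("w01", "w02", "w03"))

  expect_equal(rank_and_split(scored[0, ]),
               list(left = character(0), right = character(0)))
  expect_error(rank_and_split(scored, cap = -1), "non-negative")
})

test_that("expansion surrounds each seed occurrence with the two subsets", {
  tc <- make_corpus(list(c("i", "had", "a", "headache")))
  plans <- list(headache = list(seed_term = "headache", kind = "synonym",
                                left = c("worry", "cephalalgia"),
                                right = c("concern", "vexation"),
                                cap = 10L))
  ec <- expand_corpus(tc, plans)
  expect_equal(ec$documents[[1]],
               c("i", "had", "a", "worry", "cephalalgia", "headache",
                 "concern", "vexation"))
  expect_equal(attr(ec, "expansion_log"), c(headache = 1L))
})

test_that("corpora without seed occurrences are untouched", {
  tc <- make_corpus(list(c("no", "seeds", "here")))
  plans <- list(headache = list(seed_term = "headache", kind = "synonym",
                                left = "x1", right = "x2", cap = 10L))
  ec <- expand_corpus(tc, plans)
  expect_equal(unname(ec$documents), unname(tc$documents))
  expect_equal(attr(ec, "expansion_log"), c(headache = 0L))
})

test_that("token counts grow by occurrences times inserted-set size", {
  tc <- make_corpus(list(c("pain", "x", "pain"), c("y", "pain")))
  plans <- list(pain = list(seed_term = "pain", kind = "synonym",
                            left = c("l1", "l2"), right = c("r1", "r2"),
                            cap = 10L))
  ec <- expand_corpus(tc, plans)
  expect_equal(sum(ec$vocabulary), sum(tc$vocabulary) + 3L * 4L)
})

test_that("count conservation and order preservation hold on random corpora", {
  set.seed(31)
  for (rep in 1:10) {
    docs <- random_docs(6, c(0, 40), 25)
    tc <- make_corpus(docs)
    seeds <- sample(sprintf("tok%03d", 1:25), 3)
    inserted_pool <- sprintf("ins%02d", 1:8)
    plans <- lapply(seeds, function(s) {
      k <- sample(0:4, 1)
      ins <- sample(inserted_pool, k)
      list(seed_term = s, kind = "synonym",
           left = utils::head(ins, ceiling(k / 2)),
           right = utils::tail(ins, floor(k / 2)), cap = 10L)
    })
    names(plans) <- seeds
    ec <- expand_corpus(tc, plans)
    log <- attr(ec, "expansion_log")
    expected_growth <- sum(vapply(seeds, function(s) {
      log[[s]] * (length(plans[[s]]$left) + length(plans[[s]]$right))
    }, numeric(1)))
    expect_equal(sum(ec$vocabulary), sum(tc$vocabulary) + expected_growth)
    # deleting inserted tokens recovers the original corpus
    recovered <- lapply(ec$documents, function(t) {
      t[!t %in% inserted_pool]
    })
    expect_equal(unname(recovered), unname(tc$documents))
  }
})

test_that("a seed's co-occurrence row gains exactly the inserted mass", {
  # flat weighting, window >= |X1| + |X2| + 1, inserted tokens appear
  # nowhere else, seed occurrences far apart: the expanded row equals the
  # original row plus occurrences(seed) at each inserted coordinate
  doc <- c("ctx1", "seedtok", "ctx2", rep("pad", 12),
           "ctx3", "seedtok", "ctx4", rep("pad", 12))
  tc <- make_corpus(list(doc))
  plans <- list(seedtok = list(seed_term = "seedtok", kind = "synonym",
                               left = c("insa", "insb"), right = "insc",
                               cap = 10L))
  ec <- expand_corpus(tc, plans)
  window <- 4  # >= 3 + 1
  before <- cooccurrence_row(build_cooccurrence(tc, window, "flat"),
                             "seedtok")
  after <- cooccurrence_row(build_cooccurrence(ec, window, "flat"),
                            "seedtok")
  occurrences <- 2
  for (x in c("insa", "insb", "insc")) {
    expect_equal(unname(after[x]), occurrences)
  }
  # pre-existing coordinates can only gain mass (here they are unchanged:
  # the insertions push no original token out of the seed's window reach
  # because context tokens sit adjacent to the seed)
  for (x in c("ctx1", "ctx2", "ctx3", "ctx4")) {
    expect_gte(after[x], 1)
  }
})

test_that("inserted tokens are never themselves expanded", {
  tc <- make_corpus(list(c("aseed", "bseed")))
  plans <- list(aseed = list(seed_term = "aseed", kind = "synonym",
                             left = "bseed", right = character(0),
                             cap = 10L),
                bseed = list(seed_term = "bseed", kind = "synonym",
                             left = "aseed", right = character(0),
                             cap = 10L))
  ec <- expand_corpus(tc, plans)
  expect_equal(ec$documents[[1]], c("bseed", "aseed", "aseed", "bseed"))
})

test_that("plans are built per distinct seed and survive JSON round trip", {
  res <- toy_resource()
  plans <- build_expansion_plans(c("alpha", "alpha", "nohit"), "synonym",
                                 res, cap = 10)
  expect_equal(names(plans), "alpha")
  expect_equal(plans$alpha$left, "alephword")
  path <- withr::local_tempfile(fileext = ".json")
  write_expansion_plans(plans, path)
  expect_equal(read_expansion_plans(path), plans)
})
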