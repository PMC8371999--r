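flu_rows <- c("C0021400\tinfluenza\tflu",
              "C0021400\tinfluenza\tinfluenza",
              "C0021400\tinfluenza\tgrippe")

test_that("concept mappings load, group and deduplicate", {
  recs <- load_concept_mappings(flu_rows)
  expect_equal(unique(recs$cui), "C0021400")
  expect_equal(sort(recs$term), c("flu", "grippe", "influenza"))

  expect_equal(nrow(load_concept_mappings(character(0))), 0L)
  expect_equal(nrow(load_concept_mappings(c(flu_rows, flu_rows))), 3L)

  # order-independent result
  expect_equal(load_concept_mappings(rev(flu_rows)),
               load_concept_mappings(flu_rows))

  expect_error(load_concept_mappings("C0021400\tinfluenza"),
               "line 1")
})

test_that("morphological variants collapse and small concepts drop out", {
  rows <- c("C0015672\ttiredness\tfatigue",
            "C0015672\ttiredness\tfatigues",
            "C0015672\ttiredness\tfatigued",
            "C0015672\ttiredness\tfatiguing")
  recs <- load_concept_mappings(rows)
  freqs <- c(fatigu = 500L)
  gt <- build_ground_truth(recs, freqs)
  # all four stem to "fatigu": one unique term, below min_terms = 2
  expect_equal(nrow(gt$concepts), 0L)
})

test_that("frequency filter is strictly greater-than", {
  rows <- c("C1\tname\ttermaa", "C1\tname\ttermbb")
  recs <- load_concept_mappings(rows)
  # stems are the terms themselves here
  gt <- build_ground_truth(recs,
                           c(termaa = 100L, termbb = 500L), min_freq = 100)
  expect_equal(nrow(gt$concepts), 0L)  # termaa at exactly 100 is dropped
  gt <- build_ground_truth(recs,
                           c(termaa = 101L, termbb = 500L), min_freq = 100)
  expect_equal(nrow(gt$concepts), 1L)
  expect_equal(sort(gt$terms$term), c("termaa", "termbb"))
})

test_that("multi-word names, multi-word terms and name-equal terms drop", {
  rows <- c("C1\theart attack\tthumper", "C1\theart attack\tticker",
            "C2\tcephalgia\thead ache", "C2\tcephalgia\tmigraine",
            "C2\tcephalgia\tcephalgias",
            "C2\tcephalgia\theadache")
  recs <- load_concept_mappings(rows)
  freqs <- c(thumper = 999L, ticker = 999L, migrain = 999L,
             headach = 999L, cephalgia = 999L)
  gt <- build_ground_truth(recs, freqs)
  expect_false("C1" %in% gt$concepts$cui)          # multiword name
  expect_true("C2" %in% gt$concepts$cui)
  terms2 <- gt$terms$term[gt$terms$cui == "C2"]
  expect_equal(sort(terms2), c("headach", "migrain"))  # no "head ache",
  # and "cephalgias" (stem == stemmed preferred name) removed
})

test_that("empty record set gives an empty dataset", {
  gt <- build_ground_truth(load_concept_mappings(character(0)),
                           c(x = 1000L))
  expect_equal(nrow(gt$concepts), 0L)
  expect_equal(nrow(gt$terms), 0L)
})

test_that("brute-force re-filter reproduces build_ground_truth", {
  set.seed(42)
  cuis <- sprintf("C%03d", 1:12)
  vocab <- sprintf("term%02db", 1:30)
  rows <- unlist(lapply(seq_along(cuis), function(k) {
    terms <- sample(vocab, sample(1:5, 1))
    name <- if (k %% 4 == 0) "two words" else sprintf("name%02d", k)
    paste(cuis[k], name, terms, sep = "\t")
  }))
  freqs <- stats::setNames(sample(c(50L, 100L, 101L, 500L), 30, TRUE),
                           snowball_stem(vocab))
  recs <- load_concept_mappings(rows)
  gt <- build_ground_truth(recs, freqs)

  # oracle: independent dplyr-free refilter
  df <- recs
  df <- df[!grepl(" ", df$preferred_name) & !grepl(" ", df$term), ]
  df$term <- snowball_stem(df$term)
  df <- df[df$term != snowball_stem(tolower(df$preferred_name)), ]
  df <- unique(df[, c("cui", "term")])
  df <- df[!is.na(freqs[df$term]) & freqs[df$term] > 100, ]
  keep <- names(which(table(df$cui) >= 2))
  df <- df[df$cui %in% keep, ]
  df <- df[order(df$cui, df$term), ]
  rownames(df) <- NULL
  expect_equal(gt$terms, df)
})

test_that("seed assignment partitions each concept's terms", {
  rows <- c(flu_rows, "C0043246\tlaceration\tlacer",
            "C0043246\tlaceration\ttorn", "C0043246\tlaceration\ttear")
  freqs <- stats::setNames(rep(999L, 6),
                           c("flu", "influenza", "gripp", "lacer",
                             "torn", "tear"))
  gt <- build_ground_truth(load_concept_mappings(rows), freqs)
  a <- assign_seeds(gt, rng_seed = 7)
  expect_equal(nrow(a), 2L)
  for (k in seq_len(nrow(a))) {
    terms <- sort(gt$terms$term[gt$terms$cui == a$cui[k]])
    expect_false(a$seed_term[k] %in% a$held_out[[k]])
    expect_equal(sort(c(a$seed_term[k], a$held_out[[k]])), terms)
  }
  # determinism and input-order independence
  expect_equal(assign_seeds(gt, rng_seed = 7), a)
  gt_rev <- gt
  gt_rev$terms <- gt_rev$terms[rev(seq_len(nrow(gt_rev$terms))), ]
  expect_equal(assign_seeds(gt_rev, rng_seed = 7), a)
  expect_false(identical(assign_seeds(gt, rng_seed = 8)$seed_term,
                         a$seed_term) &&
                 identical(assign_seeds(gt, rng_seed = 9)$seed_term,
                           a$seed_term) &&
                 identical(assign_seeds(gt, rng_seed = 10)$seed_term,
                           a$seed_term))
})

test_that("single-held-out concepts and contract violations behave", {
  rows <- c("C1\tname\ttermaa", "C1\tname\ttermbb")
  gt <- build_ground_truth(load_concept_mappings(rows),
                           c(termaa = 999L, termbb = 999L))
  a <- assign_seeds(gt, rng_seed = 1)
  expect_equal(lengths(a$held_out), 1L)

  broken <- gt
  broken$terms <- broken$terms[1L, , drop = FALSE]
  expect_error(assign_seeds(broken, 1), "fewer than 2")
})

test_that("assignments survive a TSV round trip", {
  rows <- c(flu_rows)
  gt <- build_ground_truth(load_concept_mappings(rows),
                           c(flu = 999L, influenza = 999L, gripp = 999L))
  a <- assign_seeds(gt, rng_seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assignments(a, path)
  b <- read_assignments(path)
  expect_equal(b$cui, a$cui)
  expect_equal(b$seed_term, a$seed_term)
  expect_equal(b$held_out, a$held_out)
})
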