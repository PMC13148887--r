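test_that("extract_content_words keeps nouns/adjectives and lemmatizes", {
  expect_identical(extract_content_words("They are kind and generous people."),
                   c("kind", "generous", "people"))
  # -ly adverbs are dropped; -ly adjectives on the allow-list survive
  expect_identical(extract_content_words("Running quickly toward the garden"),
                   "garden")
  expect_identical(extract_content_words("A friendly family with lovely traits"),
                   c("friendly", "family", "lovely", "trait"))
  # regular plurals are reduced to singular lemmas
  expect_identical(extract_content_words("Many stories about boxes and wishes"),
                   c("story", "box", "wish"))
  expect_error(extract_content_words(""), "non-empty")
  expect_error(extract_content_words("fine text", tagger = "statistical"),
               regexp = "rules", class = "scmaudit_tagger_error")
})

test_that("lemmatization guards -ss/-us/-is/-ous endings", {
  expect_identical(lemmatize_words(c("generous", "glass", "basis", "campus")),
                   c("generous", "glass", "basis", "campus"))
  expect_identical(lemmatize_words(c("traits", "hobbies", "walls")),
                   c("trait", "hobby", "wall"))
})

test_that("zipf_common_terms implements the cumulative prefix rule", {
  lemmas <- list(`10` = c(rep("a", 5), rep("b", 3), rep("c", 2)))
  expect_identical(zipf_common_terms(lemmas, 0.5)[["10"]], "a")
  expect_identical(zipf_common_terms(lemmas, 0.8)[["10"]], c("a", "b"))
  expect_setequal(zipf_common_terms(lemmas, 1.0)[["10"]], c("a", "b", "c"))
  # a single distinct word is always the whole set
  expect_identical(zipf_common_terms(list(`20` = rep("x", 7)), 0.1)[["20"]],
                   "x")
  # ties at the cut are all included (lexicographic order within the tie)
  tied <- list(`30` = c(rep("m", 2), rep("k", 2), rep("z", 2), "q"))
  expect_identical(zipf_common_terms(tied, 0.3)[["30"]], c("k", "m", "z"))
  expect_error(zipf_common_terms(list(`10` = character(0)), 0.5),
               "non-empty")
})

test_that("cross-age exclusion uses a strict threshold and reports removals", {
  sets <- c(lapply(1:7, function(i) c("common", paste0("u", i))),
            lapply(8:9, function(i) paste0("u", i)))
  names(sets) <- seq(10, 90, by = 10)
  res <- exclude_cross_age_common(sets, max_ages = 6L)
  expect_identical(res$report$word, "common")
  expect_equal(res$report$n_ages, 7L)
  expect_false("common" %in% unlist(res$retained))
  expect_true("u1" %in% res$retained[["10"]])

  # exactly max_ages appearances are retained (strictly-more-than rule)
  sets6 <- c(lapply(1:6, function(i) "edge"), lapply(7:9, function(i) "other"))
  names(sets6) <- seq(10, 90, by = 10)
  res6 <- exclude_cross_age_common(sets6, max_ages = 6L)
  expect_equal(nrow(res6$report), 0L)
  expect_true("edge" %in% res6$retained[["10"]])

  # empty common sets produce an empty report
  empty <- exclude_cross_age_common(stats::setNames(list(character(0)), "10"))
  expect_equal(nrow(empty$report), 0L)

  # exclusion applies to externally supplied full vocabularies
  vocab <- stats::setNames(lapply(names(sets), function(a)
    c("common", "rare")), names(sets))
  res_v <- exclude_cross_age_common(sets, 6L, vocabularies = vocab)
  expect_identical(res_v$retained[["10"]], "rare")
})

test_that("count_subdimensions tallies cells, polysemy and totals", {
  lex <- scm_lexicon(tibble::tibble(
    word = c("kind", "ambitious", "play", "play"),
    dimension = c("warmth", "competence", "warmth", "warmth"),
    subdimension = c("sociability", "assertiveness", "sociability",
                     "morality"),
    valence = c(1L, 1L, 1L, -1L)))
  lemmas <- list(`10` = c("kind", "kind", "ambitious"),
                 `20` = c("play", "garden"))
  tab <- count_subdimensions(lemmas, lexicon = lex,
                             total_word_counts = c(`10` = 30, `20` = 20))
  r10 <- tab[tab$age == 10, ]
  expect_equal(r10$sociability_positive, 2L)
  expect_equal(r10$assertiveness_positive, 1L)
  expect_equal(r10$total_word_count, 30L)
  # a polysemous lemma increments every matching cell
  r20 <- tab[tab$age == 20, ]
  expect_equal(r20$sociability_positive, 1L)
  expect_equal(r20$morality_negative, 1L)
  # canonical column order
  expect_identical(names(tab),
                   c("age", "total_word_count",
                     paste(rep(scm_subdimensions(), each = 2),
                           c("positive", "negative"), sep = "_")))

  # no lexicon matches: all eight cells zero, totals untouched
  none <- count_subdimensions(list(`10` = c("garden", "window")),
                              lexicon = lex,
                              total_word_counts = c(`10` = 9))
  expect_true(all(none[, -(1:2)] == 0))
  expect_equal(none$total_word_count, 9L)
})

test_that("removing a word from the retained vocabulary never raises counts", {
  set.seed(53)
  lex <- scm_seed_lexicon()
  lemmas <- list(`10` = sample(c(lex$word, default_filler_words()), 300,
                               replace = TRUE))
  full <- count_subdimensions(lemmas, retained_vocab = list(`10` = unique(lemmas[["10"]])),
                              lexicon = lex)
  for (drop in sample(unique(lemmas[["10"]]), 10)) {
    reduced_vocab <- list(`10` = setdiff(unique(lemmas[["10"]]), drop))
    reduced <- count_subdimensions(lemmas, retained_vocab = reduced_vocab,
                                   lexicon = lex)
    expect_true(all(as.matrix(reduced[, -(1:2)]) <=
                      as.matrix(full[, -(1:2)])))
  }
})

test_that("per-age cells match a brute-force full-corpus scan", {
  set.seed(59)
  lex <- scm_seed_lexicon()
  ages <- c("10", "20", "30")
  lemmas <- stats::setNames(lapply(ages, function(a) {
    sample(c(lex$word, default_filler_words()), 200, replace = TRUE)
  }), ages)
  vocab <- lapply(lemmas, unique)
  tab <- count_subdimensions(lemmas, retained_vocab = vocab, lexicon = lex)
  # independent scan: loop every (age, lemma, lexicon entry) triple
  for (a in ages) {
    for (i in seq_len(nrow(lex))) {
      cell <- paste(lex$subdimension[i],
                    ifelse(lex$valence[i] > 0, "positive", "negative"),
                    sep = "_")
      brute <- sum(lemmas[[a]] == lex$word[i])
      contrib <- tab[tab$age == as.integer(a), ][[cell]]
      same_cell <- lex[paste(lex$subdimension,
                             ifelse(lex$valence > 0, "positive", "negative"),
                             sep = "_") == cell, ]
      brute_cell <- sum(lemmas[[a]] %in% same_cell$word)
      expect_equal(contrib, brute_cell)
    }
  }
})

test_that("count table CSV export preserves the canonical schema", {
  tab <- count_subdimensions(list(`10` = c("kind", "garden")),
                             lexicon = scm_seed_lexicon())
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_table_csv(tab, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), names(tab))
})
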