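test_that("template sentences follow the label rule and pair combinatorics", {
  lex <- tiny_lexicon()
  tpl <- build_template_sentences(lex, pair_budget = 0L)
  expect_equal(nrow(tpl), 8L)
  warm_row <- tpl[vapply(tpl$adjectives, identical, logical(1), "kind"), ]
  expect_identical(warm_row$text, "These people are always kind.")
  expect_equal(warm_row$warmth_label, 1)
  expect_equal(warm_row$competence_label, 0)
  cold_row <- tpl[vapply(tpl$adjectives, identical, logical(1), "cold"), ]
  expect_equal(cold_row$warmth_label, -1)

  # 3 warmth-positive adjectives, generous budget -> exactly choose(3, 2) pairs
  lex3 <- scm_lexicon(tibble::tibble(
    word = c("kind", "warm", "friendly", "capable", "timid"),
    dimension = c("warmth", "warmth", "warmth", "competence", "competence"),
    subdimension = c("sociability", "sociability", "sociability",
                     "ability", "assertiveness"),
    valence = c(1L, 1L, 1L, 1L, -1L)))
  tpl3 <- build_template_sentences(lex3, pair_budget = 10L, seed = 2)
  pairs <- tpl3[tpl3$kind == "pair", ]
  expect_equal(nrow(pairs), choose(3, 2))
  expect_true(all(pairs$warmth_label == 1))
  expect_true(all(pairs$competence_label == 0))
  expect_true(all(grepl("^These people are always \\w+ and \\w+\\.$",
                        pairs$text)))

  # the pair budget caps sampling, seeded
  lexall <- scm_seed_lexicon()
  t1 <- build_template_sentences(lexall, pair_budget = 20L, seed = 3)
  t2 <- build_template_sentences(lexall, pair_budget = 20L, seed = 3)
  expect_identical(t1$text, t2$text)
  expect_equal(sum(t1$kind == "pair"), 20L)

  expect_error(build_template_sentences(
    scm_lexicon(tibble::tibble(word = "kind", dimension = "warmth",
                               subdimension = "sociability", valence = 1L))),
    "competence")
})

test_that("the PLS scorer exactly recovers noise-free separable axes", {
  lex <- scm_seed_lexicon()
  be <- noise_free_backend(lex)
  tpl <- build_template_sentences(lex, pair_budget = 0L)
  emb <- embed_sentences(be, tpl$text)
  model <- fit_scm_model(emb, tpl[, c("warmth_label", "competence_label")],
                         n_components = 4L)
  sc <- score_sentences(model, emb)
  expect_equal(sc$warmth, tpl$warmth_label, tolerance = 1e-6)
  expect_equal(sc$competence, tpl$competence_label, tolerance = 1e-6)
})

test_that("held-out adjectives score with the correct sign", {
  lex <- scm_seed_lexicon()
  be <- noise_free_backend(lex)
  tpl <- build_template_sentences(lex, pair_budget = 0L)
  emb <- embed_sentences(be, tpl$text)
  words <- vapply(tpl$adjectives, `[[`, character(1), 1)
  set.seed(31)
  for (w in sample(words, 10)) {
    hold <- which(words == w)
    model <- fit_scm_model(emb[-hold, ],
                           tpl[-hold, c("warmth_label", "competence_label")],
                           n_components = 4L)
    pred <- score_sentences(model, emb[hold, , drop = FALSE])
    entry <- scm_seed_lexicon()[scm_seed_lexicon()$word == w, ][1, ]
    got <- if (entry$dimension == "warmth") pred$warmth else pred$competence
    expect_equal(sign(got), entry$valence)
  }
})

test_that("degenerate training inputs are rejected", {
  lex <- scm_seed_lexicon()
  be <- noise_free_backend(lex)
  tpl <- build_template_sentences(lex, pair_budget = 0L)
  emb <- embed_sentences(be, tpl$text)
  same <- tpl
  same$warmth_label <- 1
  expect_error(fit_scm_model(emb, same[, c("warmth_label",
                                           "competence_label")], 4L),
               class = "scmaudit_degenerate_error")
  # rank-deficient: noise-free embeddings span only 4 coordinates
  expect_error(fit_scm_model(emb, tpl[, c("warmth_label",
                                          "competence_label")], 25L),
               regexp = "fewer components", class = "scmaudit_rank_error")
})

test_that("score_sentences clips, preserves order and checks dimensions", {
  lex <- scm_seed_lexicon()
  be <- noise_free_backend(lex)
  tpl <- build_template_sentences(lex, pair_budget = 0L)
  emb <- embed_sentences(be, tpl$text)
  model <- fit_scm_model(emb, tpl[, c("warmth_label", "competence_label")],
                         4L)
  # doubled signal predicts ~2 and is stored as 1
  strong <- embed_sentences(be, "They are kind kind people.")
  sc <- score_sentences(model, strong)
  expect_equal(sc$warmth, 1)
  expect_gt(attr(sc, "clipping_rate"), 0)

  # zero vector scores at the model intercept
  zero <- matrix(0, 1, 64)
  intercept <- score_sentences(model, zero)
  expect_true(abs(intercept$warmth) <= 1)

  expect_error(score_sentences(model, matrix(0, 1, 32)),
               regexp = "32.*64|64.*32", class = "scmaudit_dim_error")

  # no emitted score ever leaves [-1, 1]
  noisy <- synthetic_backend(
    synthetic_embedding_spec(noise_sd = 2, seed = 1), lex)
  nemb <- embed_sentences(noisy, sprintf("sentence number %d", 1:50))
  nsc <- score_sentences(model, nemb)
  expect_true(all(nsc$warmth >= -1 & nsc$warmth <= 1))
  expect_true(all(nsc$competence >= -1 & nsc$competence <= 1))
})

test_that("welch_anova matches the brute-force formula oracle", {
  set.seed(17)
  for (rep in 1:25) {
    k <- sample(2:9, 1)
    groups <- lapply(seq_len(k), function(i) {
      rnorm(sample(5:50, 1), mean = runif(1, -1, 1), sd = runif(1, 0.3, 3))
    })
    got <- welch_anova(groups)
    want <- welch_oracle(groups)
    expect_equal(got$F, want$F, tolerance = 1e-9)
    expect_equal(got$df1, want$df1)
    expect_equal(got$df2, want$df2, tolerance = 1e-9)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
  }
})

test_that("welch_anova obeys its invariances and degenerate contracts", {
  set.seed(23)
  groups <- lapply(1:4, function(i) rnorm(10 + i, mean = i, sd = i / 2))
  base <- welch_anova(groups)
  expect_equal(base$df1, 3L)

  # group reordering
  expect_equal(welch_anova(rev(groups))$F, base$F, tolerance = 1e-12)
  # location shift
  expect_equal(welch_anova(lapply(groups, `+`, 5))$F, base$F,
               tolerance = 1e-9)
  # positive scaling
  expect_equal(welch_anova(lapply(groups, `*`, 3.7))$F, base$F,
               tolerance = 1e-9)

  # identical means -> F = 0
  centred <- lapply(groups, function(g) g - mean(g))
  expect_lt(abs(welch_anova(centred)$F), 1e-12)

  # two groups: F equals the squared Welch t statistic
  two <- groups[1:2]
  t_stat <- stats::t.test(two[[1]], two[[2]], var.equal = FALSE)$statistic
  expect_equal(welch_anova(two)$F, unname(t_stat)^2, tolerance = 1e-9)

  expect_error(welch_anova(list(rnorm(5))),
               class = "scmaudit_degenerate_error")
  expect_error(welch_anova(list(a = rnorm(5), b = rep(1, 5))),
               regexp = "b", class = "scmaudit_degenerate_error")
  expect_error(welch_anova(list(rnorm(5), 3)),
               class = "scmaudit_degenerate_error")
})

test_that("equalized groups tie Welch's F to the classical F exactly", {
  # With equal group sizes and identical sample variances the Welch
  # numerator IS the classical F (MSB / pooled MSW); for two groups the
  # small-sample correction vanishes so the statistics coincide, while for
  # k > 2 they differ exactly by the correction factor
  # 1 + (2(k-2)/(k^2-1)) * sum((1 - w_i/W)^2 / (n_i - 1)),
  # which shrinks to 1 as n grows.
  set.seed(29)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    n <- sample(5:30, 1)
    template <- rnorm(n)
    template <- (template - mean(template)) / stats::sd(template)
    groups <- lapply(seq_len(k), function(i) i + template)
    got <- welch_anova(groups)$F
    classical <- unname(stats::oneway.test(
      values ~ g,
      data = data.frame(values = unlist(groups),
                        g = factor(rep(seq_len(k), each = n))),
      var.equal = TRUE)$statistic)
    correction <- 1 + (2 * (k - 2) / (k^2 - 1)) *
      sum(rep((1 - 1 / k)^2 / (n - 1), k))
    expect_equal(got * correction, classical, tolerance = 1e-9)
    if (k == 2) expect_equal(got, classical, tolerance = 1e-9)
  }
  # and the correction vanishes asymptotically: at large equal n the two
  # statistics agree to a loose tolerance even for k > 2
  big <- lapply(1:5, function(i) i / 10 + scale(rnorm(5000))[, 1])
  classical_big <- unname(stats::oneway.test(
    values ~ g, data = data.frame(values = unlist(big),
                                  g = factor(rep(1:5, each = 5000))),
    var.equal = TRUE)$statistic)
  expect_equal(welch_anova(big)$F, classical_big, tolerance = 1e-3)
})

test_that("summarize_scores_by_age reports moments, quartiles and Welch", {
  set.seed(37)
  n <- 40
  ages <- rep(c(10L, 20L, 30L), each = n)
  scores <- tibble::tibble(
    sentence_id = as.character(seq_along(ages)),
    warmth = rnorm(length(ages), mean = ages / 100),
    competence = rnorm(length(ages), mean = -ages / 100))
  summ <- summarize_scores_by_age(scores, ages)
  expect_equal(nrow(summ), 6L)
  expect_setequal(unique(summ$dimension), c("warmth", "competence"))
  w10 <- summ[summ$age == 10 & summ$dimension == "warmth", ]
  expect_equal(w10$n, n)
  expect_equal(w10$mean, mean(scores$warmth[ages == 10]))
  welch <- attr(summ, "welch")
  expect_s3_class(welch$warmth, "welch_result")
  expect_equal(welch$warmth$df1, 2L)

  # single sentence per age: sd is NA-flagged, Welch degenerates to an error
  tiny <- summarize_scores_by_age(scores[c(1, n + 1, 2 * n + 1), ],
                                  c(10L, 20L, 30L))
  expect_true(all(is.na(tiny$sd)))
  expect_true(!is.null(attr(tiny, "welch")$warmth$error))

  # constant scores: means equal the constant, Welch rejected as zero-variance
  const <- tibble::tibble(sentence_id = as.character(1:6),
                          warmth = 0.5, competence = 0.5)
  csum <- summarize_scores_by_age(const, rep(c(10L, 20L), each = 3))
  expect_true(all(csum$mean == 0.5))
  expect_match(attr(csum, "welch")$warmth$error, "zero-variance")
})
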