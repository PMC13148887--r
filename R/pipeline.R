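#' Pipeline configuration
#'
#' One configuration object governs every stage of the audit. Defaults mirror
#' the audited design: 9 ages (10-90 by 10), 100 responses per age,
#' temperature 1.0, top_p 1.0, 2,048-token cap, Zipf top fraction 0.8 and
#' cross-age exclusion threshold 6.
#'
#' @param seed Master seed for the whole run.
#' @param ages Prompted ages (must be covered by `profiles`).
#' @param responses_per_age Responses per age.
#' @param profiles Generator profiles (default [default_profiles()]).
#' @param lexicon Stereotype content lexicon.
#' @param embedding A [synthetic_embedding_spec()] for the synthetic backend;
#'   the default adds mild isotropic noise and a hashed bag-of-words signal
#'   so the corpus has realistic vocabulary-driven geometry.
#' @param backend Optional pre-built `embedding_backend`; overrides
#'   `embedding`.
#' @param pca_components Integer or variance fraction for [reduce_pca()].
#' @param pls_components PLS component count. `NULL` (default) matches the
#'   scorer's latent capacity to the backend: with the synthetic backend the
#'   signal rank is known (the number of distinct stereotype axes in
#'   `embedding`), so that count is used; with an external backend the
#'   [fit_scm_model()] default applies.
#' @param pair_budget Two-adjective template budget.
#' @param top_fraction Zipf cumulative-frequency threshold.
#' @param max_ages Cross-age exclusion threshold.
#' @param list_header_probability Generator list-header probability.
#' @param temperature,top_p,max_tokens Sampling parameters recorded in the
#'   manifest (and passed to live providers).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            ages = seq(10L, 90L, by = 10L),
                            responses_per_age = 100L,
                            profiles = default_profiles(),
                            lexicon = scm_seed_lexicon(),
                            embedding = synthetic_embedding_spec(
                              noise_sd = 0.05, token_hash_weight = 0.5,
                              seed = seed),
                            backend = NULL,
                            pca_components = 0.9,
                            pls_components = NULL,
                            pair_budget = 200L,
                            top_fraction = 0.8,
                            max_ages = 6L,
                            list_header_probability = 0.3,
                            temperature = 1.0, top_p = 1.0,
                            max_tokens = 2048L) {
  profile_ages <- vapply(profiles, function(p) p$age, integer(1))
  missing <- setdiff(as.integer(ages), profile_ages)
  if (length(missing) > 0) {
    rlang::abort(paste0("no generator profile for age(s): ",
                        paste(missing, collapse = ", ")))
  }
  structure(list(seed = as.integer(seed), ages = as.integer(ages),
                 responses_per_age = as.integer(responses_per_age),
                 profiles = profiles[profile_ages %in% as.integer(ages)],
                 lexicon = lexicon, embedding = embedding, backend = backend,
                 pca_components = pca_components,
                 pls_components = pls_components,
                 pair_budget = as.integer(pair_budget),
                 top_fraction = top_fraction, max_ages = as.integer(max_ages),
                 list_header_probability = list_header_probability,
                 temperature = temperature, top_p = top_p,
                 max_tokens = as.integer(max_tokens)),
            class = "pipeline_config")
}

#' Run the full audit pipeline
#'
#' Executes generate (or ingest) -> preprocess -> embed -> similarity ->
#' score -> ANOVA -> word count on one configuration and returns the
#' consolidated report. With the synthetic backend the whole run is a
#' deterministic function of `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param corpus Optional pre-collected corpus (`sample_id`, `age`,
#'   `raw_text`); when `NULL` a synthetic corpus is generated from the
#'   config's profiles.
#' @param verbose Emit per-stage progress messages?
#' @return List of class `scm_report` with elements `similarity`,
#'   `score_summary`, `welch`, `scores`, `count_table`, `exclusion_report`,
#'   `ground_truth` (when generated), `filter_log`, `clipping_rate`,
#'   `pca`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), corpus = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)), parent = e)
    })
  }

  say("stage: generate")
  generated <- is.null(corpus)
  if (generated) {
    gen_cfg <- generator_config(
      profiles = config$profiles,
      responses_per_age = config$responses_per_age,
      seed = config$seed,
      list_header_probability = config$list_header_probability)
    corpus <- stage("generate", generate_corpus(gen_cfg, config$lexicon))
  }

  say("stage: preprocess")
  sentences <- stage("preprocess", preprocess_corpus(corpus))
  if (nrow(sentences) == 0) {
    rlang::abort("pipeline stage 'preprocess' failed: no sentences survive filtering")
  }

  say("stage: embed")
  backend <- config$backend %||%
    synthetic_backend(config$embedding, config$lexicon)
  ids <- stats::setNames(sentences$text,
                         paste0(sentences$sample_id, ":",
                                sentences$position_index))
  emb <- stage("embed", embed_sentences(backend, ids))

  say("stage: similarity")
  reduced <- stage("similarity", reduce_pca(emb, config$pca_components))
  sample_means <- sample_mean_vectors(reduced, sentences$sample_id)
  age_of_sample <- corpus$age[match(rownames(sample_means),
                                    corpus$sample_id)]
  similarity <- stage("similarity",
                      age_similarity(sample_means, age_of_sample))

  say("stage: score")
  templates <- stage("score",
                     build_template_sentences(config$lexicon,
                                              config$pair_budget,
                                              seed = config$seed))
  template_emb <- stage("score", embed_sentences(backend, templates$text))
  pls_components <- config$pls_components
  if (is.null(pls_components) && is.null(config$backend)) {
    # Synthetic backend: the latent signal rank is known by construction —
    # one axis per stereotype subdimension group of the embedding spec.
    pls_components <- length(unique(config$embedding$axis_assignment$axis))
  }
  model <- stage("score",
                 fit_scm_model(template_emb,
                               templates[, c("warmth_label",
                                             "competence_label")],
                               pls_components))
  scores <- stage("score", score_sentences(model, emb))
  scores$sample_id <- sentences$sample_id
  scores$age <- sentences$age

  say("stage: anova")
  score_summary <- stage("anova",
                         summarize_scores_by_age(
                           scores[, c("sentence_id", "warmth", "competence")],
                           sentences$age))
  welch <- attr(score_summary, "welch")

  say("stage: wordcount")
  wordcount <- stage("wordcount", {
    by_age <- split(sentences$text, sentences$age)
    lemmas_by_age <- lapply(by_age, function(texts) {
      unlist(lapply(texts, extract_content_words), use.names = FALSE)
    })
    totals <- vapply(split(sentences$word_count, sentences$age), sum,
                     integer(1))
    common <- zipf_common_terms(lemmas_by_age, config$top_fraction)
    vocab <- lapply(lemmas_by_age, unique)
    excl <- exclude_cross_age_common(common, config$max_ages,
                                     vocabularies = vocab)
    table <- count_subdimensions(lemmas_by_age, excl$retained,
                                 config$lexicon, totals)
    list(table = table, exclusion_report = excl$report)
  })

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    backend_id = attr(emb, "backend_id"),
    package_version = as.character(utils::packageVersion("scmaudit")),
    n_samples = nrow(corpus),
    n_sentences = nrow(sentences),
    pls_components = model$n_components,
    pls_checksum = model$checksum,
    pca_components = attr(reduced, "n_components"),
    sampling = list(temperature = config$temperature, top_p = config$top_p,
                    max_tokens = config$max_tokens),
    timestamp = format(Sys.time(), tz = "UTC"))

  structure(list(
    similarity = similarity,
    score_summary = score_summary,
    welch = welch,
    scores = scores,
    count_table = wordcount$table,
    exclusion_report = wordcount$exclusion_report,
    ground_truth = if (generated) attr(corpus, "ground_truth") else NULL,
    filter_log = attr(sentences, "filter_log"),
    clipping_rate = attr(scores, "clipping_rate"),
    pca = list(n_components = attr(reduced, "n_components"),
               cumulative_variance = attr(reduced, "cumulative_variance")),
    manifest = manifest), class = "scm_report")
}

#' @export
print.scm_report <- function(x, ...) {
  cat("<scm_report>\n")
  cat("  samples:", x$manifest$n_samples,
      " sentences kept:", x$manifest$n_sentences, "\n")
  cat("  ages:", paste(x$similarity$ages, collapse = ", "), "\n")
  for (dimn in c("warmth", "competence")) {
    w <- x$welch[[dimn]]
    if (!is.null(w$F)) {
      cat(sprintf("  %s: Welch F(%d, %.1f) = %.2f, p = %.3g\n", dimn,
                  w$df1, w$df2, w$F, w$p_value))
    }
  }
  cat("  clipping rate:", signif(x$clipping_rate, 3), "\n")
  invisible(x)
}

#' Write the consolidated report to a directory
#'
#' Emits the similarity matrix, per-age score summary, per-sentence scores,
#' the subdimension count table and the exclusion report as CSV, plus the
#' Welch results and run manifest as JSON.
#'
#' @param report An `scm_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_similarity_csv(report$similarity, file.path(dir, "similarity.csv"))
  utils::write.csv(as.data.frame(report$score_summary),
                   file.path(dir, "score_summary.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$scores),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  write_count_table_csv(report$count_table,
                        file.path(dir, "count_table.csv"))
  utils::write.csv(as.data.frame(report$exclusion_report),
                   file.path(dir, "excluded_words.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(report$welch, unclass),
                       file.path(dir, "welch.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
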