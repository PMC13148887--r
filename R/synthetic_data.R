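#' Age profile for the synthetic corpus generator
#'
#' Describes the planted stereotype structure for one prompted age: per
#' content-word-slot sampling probabilities for the eight
#' (subdimension, valence) cells, the planted warmth/competence levels those
#' rates encode, sentence/slot count ranges and optional regime marker words
#' (vocabulary shared by neighbouring ages, giving the corpus its age-cluster
#' geometry).
#'
#' @param age Integer age in years.
#' @param subdim_rates Named numeric vector of 8 probabilities, names
#'   `subdimension_valence` (e.g. `sociability_positive`); remaining
#'   probability mass goes to filler/marker words.
#' @param warmth_level,competence_level Planted levels in \[-1, 1\].
#' @param sentences_per_response Integer range (min, max) of body sentences.
#' @param words_per_sentence Integer range (min, max) of content-word slots.
#' @param marker_words Character vector of regime marker words.
#' @param marker_rate Per-slot probability of a marker word.
#' @return List of class `age_profile`.
#' @export
age_profile <- function(age, subdim_rates, warmth_level, competence_level,
                        sentences_per_response = c(5L, 9L),
                        words_per_sentence = c(8L, 12L),
                        marker_words = character(0),
                        marker_rate = 0) {
  cell_names <- paste(rep(scm_subdimensions(), each = 2),
                      c("positive", "negative"), sep = "_")
  if (!setequal(names(subdim_rates), cell_names)) {
    rlang::abort("subdim_rates must be named by the 8 subdimension_valence cells")
  }
  subdim_rates <- subdim_rates[cell_names]
  if (any(subdim_rates < 0 | subdim_rates > 1)) {
    rlang::abort("subdim_rates must lie in [0, 1]")
  }
  if (sum(subdim_rates) + marker_rate > 1) {
    rlang::abort("cell rates plus marker_rate must sum to at most 1")
  }
  stopifnot(warmth_level >= -1, warmth_level <= 1,
            competence_level >= -1, competence_level <= 1,
            length(sentences_per_response) == 2L,
            sentences_per_response[1] <= sentences_per_response[2],
            sentences_per_response[1] >= 1L,
            length(words_per_sentence) == 2L,
            words_per_sentence[1] <= words_per_sentence[2],
            words_per_sentence[1] >= 1L,
            marker_rate >= 0)
  structure(list(age = as.integer(age), subdim_rates = subdim_rates,
                 warmth_level = warmth_level,
                 competence_level = competence_level,
                 sentences_per_response = as.integer(sentences_per_response),
                 words_per_sentence = as.integer(words_per_sentence),
                 marker_words = marker_words, marker_rate = marker_rate),
            class = "age_profile")
}

#' Default neutral filler vocabulary
#'
#' Sixty concrete nouns disjoint from the seed lexicon, the stopword list and
#' the regime markers, so every counted stereotype word in a generated corpus
#' is a planted one.
#'
#' @return Character vector.
#' @export
default_filler_words <- function() {
  c("garden", "window", "kitchen", "street", "river", "mountain", "village",
    "city", "book", "letter", "table", "chair", "lamp", "door", "road",
    "bridge", "field", "forest", "cloud", "stone", "paper", "bottle",
    "basket", "clock", "mirror", "carpet", "ceiling", "floor", "wall",
    "roof", "meadow", "harbor", "island", "valley", "market", "bakery",
    "museum", "library", "station", "airport", "engine", "wheel", "anchor",
    "candle", "pencil", "folder", "jacket", "pocket", "button", "ribbon",
    "blanket", "pillow", "curtain", "shelf", "drawer", "ladder", "bucket",
    "hammer", "shovel", "fence")
}

# Planted per-slot net stereotype rates for the nine default ages. Warmth
# rises to a mid-life peak at 40 and then declines gently; competence peaks
# at 30 and declines in older ages; positive assertiveness falls strictly
# with age. Adjacent-rank gaps of 0.012 net words per slot were sized (before
# any testing) so that per-age mean scores separate cleanly at 100 responses
# per age. Negative rates are small and constant, mirroring the rarity of
# negative stereotype terms in audited LLM text.
.default_rate_table <- function() {
  ages <- seq(10L, 90L, by = 10L)
  warmth_net <- c(0.003, 0.009, 0.015, 0.051, 0.045, 0.039, 0.033, 0.027,
                  0.021)
  competence_net <- c(0.023, 0.035, 0.053, 0.047, 0.041, 0.029, 0.017,
                      0.011, 0.005)
  assert_pos <- c(0.020, 0.018, 0.016, 0.014, 0.012, 0.010, 0.008, 0.006,
                  0.004)
  soc_neg <- 0.0025; mor_neg <- 0.0015; abil_neg <- 0.003; assert_neg <- 0.002
  warmth_pos <- warmth_net + soc_neg + mor_neg
  tibble::tibble(
    age = ages,
    sociability_positive = 0.6 * warmth_pos,
    sociability_negative = soc_neg,
    morality_positive = 0.4 * warmth_pos,
    morality_negative = mor_neg,
    ability_positive = competence_net - (assert_pos - assert_neg) + abil_neg,
    ability_negative = abil_neg,
    assertiveness_positive = assert_pos,
    assertiveness_negative = assert_neg,
    warmth_level = warmth_net / 0.06,
    competence_level = competence_net / 0.06)
}

#' Default age profiles with planted stereotype structure
#'
#' Nine profiles (ages 10-90): planted warmth rising to a mid-life peak then
#' plateauing with a gentle decline, competence peaking at age 30 and
#' declining from age 60, positive-assertiveness slot rate strictly
#' decreasing with age, and three vocabulary regimes (young 10-20, middle
#' 30-50, older 60-90) carried by regime marker words.
#'
#' @return List of nine [age_profile()] objects, named by age.
#' @export
default_profiles <- function() {
  tab <- .default_rate_table()
  markers <- list(
    young = c("school", "classmate", "homework", "playground"),
    middle = c("career", "workplace", "mortgage", "colleague"),
    older = c("retirement", "grandchild", "pension", "keepsake"))
  regime_of <- function(age) {
    if (age <= 20) "young" else if (age <= 50) "middle" else "older"
  }
  cell_names <- paste(rep(scm_subdimensions(), each = 2),
                      c("positive", "negative"), sep = "_")
  profiles <- lapply(seq_len(nrow(tab)), function(i) {
    rates <- unlist(tab[i, cell_names])
    age_profile(tab$age[i], rates,
                warmth_level = tab$warmth_level[i],
                competence_level = tab$competence_level[i],
                marker_words = markers[[regime_of(tab$age[i])]],
                marker_rate = 0.06)
  })
  names(profiles) <- tab$age
  profiles
}

#' Generator configuration
#'
#' @param profiles List of [age_profile()]s, one per age.
#' @param responses_per_age Positive integer (default 100).
#' @param seed Integer master seed; the corpus is a deterministic function of
#'   it.
#' @param boilerplate List with character vectors `openers` and `closers`
#'   (single full sentences) prepended/appended to every response.
#' @param list_header_probability Probability that a response contains a
#'   colon-ended list-header sentence.
#' @param filler_words Neutral filler vocabulary.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(profiles = default_profiles(),
                             responses_per_age = 100L,
                             seed = 1L,
                             boilerplate = default_boilerplate(),
                             list_header_probability = 0.3,
                             filler_words = default_filler_words()) {
  ages <- vapply(profiles, function(p) p$age, integer(1))
  if (anyDuplicated(ages)) rlang::abort("one profile per age required")
  stopifnot(responses_per_age >= 1L,
            list_header_probability >= 0, list_header_probability <= 1,
            length(filler_words) >= 1L,
            length(boilerplate$openers) >= 1L,
            length(boilerplate$closers) >= 1L)
  structure(list(profiles = profiles[order(ages)],
                 responses_per_age = as.integer(responses_per_age),
                 seed = as.integer(seed), boilerplate = boilerplate,
                 list_header_probability = list_header_probability,
                 filler_words = filler_words),
            class = "generator_config")
}

#' Default opener/closer boilerplate pools
#'
#' Single-sentence variability disclaimers of the kind LLMs put at the start
#' and end of personality descriptions; they exercise the first/last-sentence
#' filter realistically.
#'
#' @return List with `openers` and `closers`.
#' @export
default_boilerplate <- function() {
  list(
    openers = c(
      "It is important to remember that personality varies widely among individuals of any age.",
      "Personality differs greatly from person to person regardless of age.",
      "Every person is unique and the traits below are only broad tendencies."),
    closers = c(
      "Of course individual differences matter far more than any general description.",
      "Keep in mind that these are broad tendencies rather than fixed rules.",
      "Ultimately each person develops a personality shaped by unique circumstances."))
}

.body_templates <- c(
  "They are often %s in everyday life.",
  "Many of them seem %s to the people around them.",
  "People of this age can be %s at times.",
  "In general they tend to be %s with others.")

.list_header <- "Here are some common characteristics:"

# Uniform integer draw on [lo, hi] that is safe when lo == hi (sample() on a
# numeric scalar would otherwise draw from 1..lo).
sample_range <- function(lo, hi) {
  if (lo == hi) lo else sample(seq(lo, hi), 1L)
}

# Generate one response for one profile; returns list(text, labels) where
# labels records every planted stereotype draw (sentence position, cell,
# word).
generate_response <- function(profile, lexicon, config, resp_seed) {
  pools <- split(lexicon$word,
                 paste(lexicon$subdimension,
                       ifelse(lexicon$valence > 0, "positive", "negative"),
                       sep = "_"))
  rates <- profile$subdim_rates
  withr::with_seed(resp_seed, {
    opener <- sample(config$boilerplate$openers, 1L)
    closer <- sample(config$boilerplate$closers, 1L)
    has_header <- stats::runif(1) < config$list_header_probability
    n_body <- sample_range(profile$sentences_per_response[1],
                           profile$sentences_per_response[2])
    sentences <- opener
    if (has_header) sentences <- c(sentences, .list_header)
    labels <- list()
    n_slots <- vapply(seq_len(n_body), function(b) {
      sample_range(profile$words_per_sentence[1],
                   profile$words_per_sentence[2])
    }, integer(1))
    total_slots <- sum(n_slots)
    # Stratified planting: each cell gets floor(rate * slots) words plus a
    # Bernoulli remainder, so realized per-response cell counts match the
    # profile's rates in expectation with far less variance than iid slot
    # draws — the planted age profile is what an audit should recover, not a
    # noisy realization of it.
    cell_rates <- c(rates, marker = profile$marker_rate)
    target <- cell_rates * total_slots
    cell_counts <- floor(target) +
      (stats::runif(length(target)) < (target - floor(target)))
    cell_counts <- pmin(cell_counts, total_slots)
    while (sum(cell_counts) > total_slots) {   # degenerate high-rate guard
      i <- which.max(cell_counts)
      cell_counts[i] <- cell_counts[i] - 1L
    }
    assignment <- c(rep(names(cell_rates), cell_counts),
                    rep("filler", total_slots - sum(cell_counts)))
    assignment <- sample(assignment, total_slots)
    slot_sentence <- rep(seq_len(n_body), n_slots)
    words <- character(total_slots)
    offset <- length(sentences)  # body sentence b sits at position offset+b-1
    for (s in seq_len(total_slots)) {
      cell <- assignment[s]
      if (cell == "filler") {
        words[s] <- sample(config$filler_words, 1L)
      } else if (cell == "marker") {
        words[s] <- if (length(profile$marker_words) == 0L) {
          sample(config$filler_words, 1L)
        } else if (length(profile$marker_words) == 1L) {
          profile$marker_words
        } else sample(profile$marker_words, 1L)
      } else {
        pool <- pools[[cell]]
        if (is.null(pool) || length(pool) == 0) {
          words[s] <- sample(config$filler_words, 1L)
        } else {
          words[s] <- if (length(pool) == 1L) pool else sample(pool, 1L)
          labels[[length(labels) + 1L]] <- list(
            sentence_position = offset + slot_sentence[s] - 1L, cell = cell,
            word = words[s])
        }
      }
    }
    for (b in seq_len(n_body)) {
      template <- sample(.body_templates, 1L)
      sentences <- c(sentences,
                     sprintf(template,
                             paste(words[slot_sentence == b],
                                   collapse = " ")))
    }
    sentences <- c(sentences, closer)
    lab <- if (length(labels) > 0) {
      tibble::tibble(
        sentence_position = vapply(labels, `[[`, integer(1),
                                   "sentence_position"),
        cell = vapply(labels, `[[`, character(1), "cell"),
        word = vapply(labels, `[[`, character(1), "word"))
    } else {
      tibble::tibble(sentence_position = integer(0), cell = character(0),
                     word = character(0))
    }
    list(text = paste(sentences, collapse = "\n"), labels = lab)
  })
}

response_seed <- function(seed, age, rep) {
  as.integer((as.numeric(seed) * 10007 + age * 101 + rep) %% 2147483647)
}

#' Generate a synthetic age-conditioned corpus with planted structure
#'
#' Each response is one opener, an optional colon-ended list header, 5-9 body
#' sentences whose content-word slots are filled from the lexicon according
#' to the profile's cell rates (with regime markers and neutral filler
#' otherwise), and one closer. Fully deterministic given `config$seed`. The
#' planted draws are attached as the `ground_truth` attribute (one row per
#' planted stereotype word) and can also be exported as a JSON-Lines sidecar.
#'
#' @param config A [generator_config()].
#' @param lexicon An [scm_lexicon()].
#' @return An `scm_corpus` tibble (`sample_id`, `age`, `raw_text`) with
#'   attribute `ground_truth`: tibble (`sample_id`, `age`,
#'   `sentence_position`, `subdimension`, `valence`, `word`).
#' @export
generate_corpus <- function(config = generator_config(),
                            lexicon = scm_seed_lexicon()) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(lexicon) == 0) rlang::abort("lexicon must be non-empty")
  rows <- list(); truths <- list()
  for (profile in config$profiles) {
    for (rep in seq_len(config$responses_per_age)) {
      res <- generate_response(profile, lexicon, config,
                               response_seed(config$seed, profile$age, rep))
      sid <- sprintf("age%02d_r%03d", profile$age, rep)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, age = profile$age, raw_text = res$text)
      if (nrow(res$labels) > 0) {
        truths[[length(truths) + 1L]] <- tibble::tibble(
          sample_id = sid, age = profile$age,
          sentence_position = res$labels$sentence_position,
          subdimension = sub("_(positive|negative)$", "", res$labels$cell),
          valence = ifelse(grepl("positive$", res$labels$cell), 1L, -1L),
          word = res$labels$word)
      }
    }
  }
  corpus <- dplyr::bind_rows(rows)
  attr(corpus, "ground_truth") <- dplyr::bind_rows(truths)
  class(corpus) <- c("scm_corpus", class(corpus))
  corpus
}

#' Synchronous text provider backed by the synthetic generator
#'
#' Wraps the generator in the provider contract used by [collect_corpus()]:
#' `provider(prompt, temperature, top_p, max_tokens)`. The prompted age is
#' parsed from the rendered prompt; replicate indices count up per age, so a
#' fixed seed reproduces the corpus bit-for-bit. Ground-truth labels are
#' discarded (a live provider would not supply them).
#'
#' @param config A [generator_config()].
#' @param lexicon An [scm_lexicon()].
#' @return A provider function.
#' @export
synthetic_provider <- function(config = generator_config(),
                               lexicon = scm_seed_lexicon()) {
  counters <- new.env(parent = emptyenv())
  ages <- vapply(config$profiles, function(p) p$age, integer(1))
  function(prompt, temperature, top_p, max_tokens) {
    m <- regmatches(prompt, regexpr("[0-9]+(?=-year-old)", prompt,
                                    perl = TRUE))
    if (length(m) == 0) stop("prompt does not name an age")
    age <- as.integer(m)
    if (!age %in% ages) stop("no profile for age ", age)
    key <- as.character(age)
    rep <- (get0(key, envir = counters, ifnotfound = 0L)) + 1L
    assign(key, rep, envir = counters)
    profile <- config$profiles[[which(ages == age)]]
    generate_response(profile, lexicon, config,
                      response_seed(config$seed, age, rep))$text
  }
}

#' Exact subdimension counts from generator ground truth
#'
#' Tallies the planted stereotype draws per age and
#' (subdimension, valence) cell — the oracle against which the lexicon
#' counting pipeline is checked. Totals are the raw token counts of each
#' age's sentence-filtered text, the same totals definition the pipeline
#' uses.
#'
#' @param corpus Corpus from [generate_corpus()] (must carry the
#'   `ground_truth` attribute).
#' @return A `subdimension_counts` tibble.
#' @export
ground_truth_counts <- function(corpus) {
  truth <- attr(corpus, "ground_truth")
  if (is.null(truth)) {
    rlang::abort("corpus carries no ground_truth labels (not generated by generate_corpus?)")
  }
  ages <- sort(unique(corpus$age))
  sentences <- preprocess_corpus(corpus)
  totals <- vapply(ages, function(a) {
    sum(sentences$word_count[sentences$age == a])
  }, integer(1))
  names(totals) <- ages
  cell_names <- paste(rep(scm_subdimensions(), each = 2),
                      c("positive", "negative"), sep = "_")
  rows <- lapply(ages, function(a) {
    tr <- truth[truth$age == a, , drop = FALSE]
    counts <- stats::setNames(integer(length(cell_names)), cell_names)
    if (nrow(tr) > 0) {
      key <- paste(tr$subdimension,
                   ifelse(tr$valence > 0, "positive", "negative"), sep = "_")
      tab <- table(key)
      counts[names(tab)] <- as.integer(tab)
    }
    tibble::tibble(age = as.integer(a),
                   total_word_count = as.integer(totals[[as.character(a)]]),
                   !!!as.list(counts))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(age = integer(0), total_word_count = integer(0),
                          !!!stats::setNames(as.list(rep(0L, 8)), cell_names))
  }
  class(out) <- c("subdimension_counts", class(out))
  out
}

#' Write generator ground truth as JSON-Lines
#'
#' One object per planted draw with keys `sample_id`, `age`,
#' `sentence_position`, `subdimension`, `valence`, `word`.
#'
#' @param corpus Corpus from [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_jsonl <- function(corpus, path) {
  truth <- attr(corpus, "ground_truth")
  if (is.null(truth)) rlang::abort("corpus carries no ground_truth labels")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(truth))) {
    writeLines(jsonlite::toJSON(as.list(truth[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
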