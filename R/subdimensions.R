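# Closed-class / function words and high-frequency verbs excluded from
# content-word extraction. Deliberately conservative: extraction keeps
# anything not clearly a function word, adverb or common verb, which is the
# behaviour wanted for noun/adjective counting over descriptive text.
.stopwords <- c(
  # pronouns / determiners
  "i", "me", "my", "mine", "myself", "we", "us", "our", "ours", "ourselves",
  "you", "your", "yours", "yourself", "he", "him", "his", "she", "her",
  "hers", "it", "its", "itself", "they", "them", "their", "theirs",
  "themselves", "this", "that", "these", "those", "a", "an", "the", "some",
  "any", "each", "every", "no", "none", "both", "few", "many", "much",
  "more", "most", "other", "others", "another", "such", "what", "which",
  "who", "whom", "whose", "all", "several", "certain", "own", "same",
  # prepositions / conjunctions / particles
  "in", "on", "at", "by", "for", "with", "about", "against", "between",
  "into", "through", "during", "before", "after", "above", "below", "to",
  "from", "up", "down", "out", "off", "over", "under", "again", "further",
  "then", "once", "here", "there", "when", "where", "why", "how", "and",
  "but", "or", "nor", "so", "than", "too", "very", "not", "only", "just",
  "also", "as", "if", "because", "while", "of", "per", "via", "within",
  "without", "toward", "towards", "among", "across", "around", "like",
  "unlike", "regardless", "rather", "instead", "whether", "either",
  "neither", "yet", "still", "even", "ever", "never", "now",
  # auxiliaries / modals / common light verbs
  "am", "is", "are", "was", "were", "be", "been", "being", "have", "has",
  "had", "having", "do", "does", "did", "doing", "will", "would", "shall",
  "should", "can", "could", "may", "might", "must", "get", "gets", "got",
  "make", "makes", "made", "take", "takes", "took", "become", "becomes",
  "became", "seem", "seems", "seemed", "tend", "tends", "tended", "keep",
  "keeps", "kept", "let", "lets", "go", "goes", "went", "come", "comes",
  "came", "show", "shows", "showed", "find", "finds", "found", "know",
  "knows", "knew", "think", "thinks", "thought", "want", "wants", "wanted",
  "need", "needs", "needed", "use", "uses", "used", "often", "sometimes",
  "usually", "always", "frequently", "generally", "typically", "perhaps",
  "maybe", "quite", "really", "somewhat", "well", "however", "therefore",
  "thus", "overall", "moreover", "furthermore", "meanwhile", "indeed",
  "though", "although", "despite", "due", "etc")

# Adjectives/nouns ending in -ly that must not be dropped by the adverb rule.
.ly_keep <- c("family", "friendly", "unfriendly", "lively", "lonely",
              "lovely", "elderly", "silly", "jolly", "ugly", "early",
              "likely", "unlikely", "orderly", "costly", "deadly", "daily")

# Words ending in -ing that are adjectives/nouns, not gerund verb forms.
.ing_keep <- c("caring", "loving", "outgoing", "easygoing", "charming",
               "thing", "something", "anything", "everything", "nothing",
               "morning", "evening", "feeling", "being", "wellbeing",
               "understanding", "upbringing", "learning")

#' Rule-based lemmatization to base forms
#'
#' Reduces regular English plurals to their singular lemma (`stories` ->
#' `story`, `boxes` -> `box`, `traits` -> `trait`). Words ending in `ss`,
#' `us`, `is` or `ous` are left alone, as are short words, so adjectives such
#' as `generous` survive unchanged. Irregular forms are not handled.
#'
#' @param words Character vector of lowercase tokens.
#' @return Character vector of lemmas, same length.
#' @export
lemmatize_words <- function(words) {
  out <- words
  ies <- grepl("ies$", out) & nchar(out) > 4L
  out[ies] <- sub("ies$", "y", out[ies])
  es <- !ies & grepl("(x|s|z|ch|sh)es$", out) & nchar(out) > 4L
  out[es] <- sub("es$", "", out[es])
  s <- !ies & !es & grepl("s$", out) & nchar(out) > 3L &
    !grepl("(ss|us|is|ous)$", out)
  out[s] <- sub("s$", "", out[s])
  out
}

#' Extract lowercase content-word lemmas (nouns and adjectives)
#'
#' The built-in rule-based tagger keeps tokens that are not function words,
#' not `-ly` adverbs (with an allow-list for `-ly` adjectives such as
#' `friendly`) and not gerund `-ing` verb forms (with an allow-list for
#' `-ing` adjectives/nouns such as `caring`), then lemmatizes with
#' [lemmatize_words()]. Tokens containing no letters are dropped. Order of
#' occurrence is preserved.
#'
#' @param text Non-empty character scalar.
#' @param tagger Tagger to use; only `"rules"` (the built-in rule-based
#'   tagger) is available. Any other value is an error naming the flag.
#' @return Character vector of lemmas in order of occurrence.
#' @export
extract_content_words <- function(text, tagger = "rules") {
  if (!identical(tagger, "rules")) {
    rlang::abort(paste0("tagger '", tagger, "' is not available; use ",
                        "tagger = \"rules\" (the built-in rule-based tagger)"),
                 class = "scmaudit_tagger_error")
  }
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    rlang::abort("text must be a non-empty string")
  }
  toks <- tokenize_words(text)
  toks <- toks[grepl("[a-z]", toks)]
  toks <- toks[!toks %in% .stopwords]
  toks <- toks[!(grepl("ly$", toks) & !toks %in% .ly_keep)]
  toks <- toks[!(grepl("ing$", toks) & !toks %in% .ing_keep)]
  lemmatize_words(toks)
}

#' Common terms per age by cumulative rank frequency
#'
#' Formalizes the "Zipf's law of common terms" extraction as a
#' cumulative-frequency prefix rule: within each age, lemmas are ranked by
#' frequency (ties broken lexicographically) and the common set is the
#' shortest rank prefix whose cumulative frequency reaches `top_fraction` of
#' the age's tokens, extended to include every word tied at the cut
#' frequency.
#'
#' @param lemmas_by_age Named list, one character vector (lemma multiset) per
#'   age.
#' @param top_fraction Fraction of cumulative token mass, in (0, 1].
#' @return Named list of character vectors (one common-word set per age).
#' @export
zipf_common_terms <- function(lemmas_by_age, top_fraction = 0.8) {
  stopifnot(is.list(lemmas_by_age), top_fraction > 0, top_fraction <= 1)
  lapply(lemmas_by_age, function(lemmas) {
    if (length(lemmas) == 0) {
      rlang::abort("each age's lemma multiset must be non-empty")
    }
    tab <- table(lemmas)
    ord <- order(-as.vector(tab), names(tab))
    freq <- as.vector(tab)[ord]
    words <- names(tab)[ord]
    k <- which(cumsum(freq) >= top_fraction * length(lemmas))[1]
    k_ext <- max(which(freq == freq[k]))
    words[seq_len(k_ext)]
  })
}

#' Exclude words common across too many ages
#'
#' A word present in the common sets of strictly more than `max_ages` ages is
#' judged model boilerplate rather than stereotype content and is removed
#' from every age's vocabulary.
#'
#' @param common_sets Named list of common-word sets from
#'   [zipf_common_terms()].
#' @param max_ages Words in more than this many common sets are excluded
#'   (default 6).
#' @param vocabularies Named list of vocabularies to filter; defaults to
#'   `common_sets`. The full pipeline passes each age's complete lemma
#'   vocabulary so that rare stereotype words are kept for counting.
#' @return List with `retained` (filtered vocabularies per age) and `report`,
#'   a tibble (`word`, `n_ages`) of excluded words with attribute
#'   `threshold_ages`.
#' @export
exclude_cross_age_common <- function(common_sets, max_ages = 6L,
                                     vocabularies = common_sets) {
  stopifnot(max_ages >= 0L)
  flat <- unlist(lapply(common_sets, unique), use.names = FALSE)
  counts <- table(if (is.null(flat)) character(0) else flat)
  excluded <- names(counts)[as.vector(counts) > max_ages]
  report <- tibble::tibble(
    word = as.character(excluded),
    n_ages = as.integer(counts[excluded]))
  report <- dplyr::arrange(report, dplyr::desc(.data$n_ages), .data$word)
  attr(report, "threshold_ages") <- as.integer(max_ages)
  retained <- lapply(vocabularies, function(v) setdiff(unique(v), excluded))
  list(retained = retained, report = report)
}

#' Count stereotype subdimension words per age
#'
#' For each age, every occurrence of a retained lemma matching a lexicon
#' entry increments that entry's (subdimension, valence) cell; a lemma with
#' several lexicon entries increments every matching cell. Totals are the
#' ages' raw token counts (all tokens of the sentence-filtered text, before
#' any vocabulary filtering), supplied via `total_word_counts`.
#'
#' @param lemmas_by_age Named list of lemma multisets per age.
#' @param retained_vocab Named list of retained vocabularies per age (from
#'   [exclude_cross_age_common()]); `NULL` retains everything.
#' @param lexicon An [scm_lexicon()].
#' @param total_word_counts Named numeric vector of raw token totals per age;
#'   defaults to the lemma multiset sizes if not supplied.
#' @return Tibble of class `subdimension_counts` in the canonical column
#'   order: `age`, `total_word_count`, then
#'   `{sociability,morality,ability,assertiveness}_{positive,negative}`.
#' @export
count_subdimensions <- function(lemmas_by_age, retained_vocab = NULL,
                                lexicon = scm_seed_lexicon(),
                                total_word_counts = NULL) {
  ages <- names(lemmas_by_age)
  if (is.null(ages)) rlang::abort("lemmas_by_age must be named by age")
  if (!is.null(retained_vocab) &&
      !setequal(names(retained_vocab), ages)) {
    rlang::abort("retained_vocab must be keyed by the same ages as lemmas_by_age")
  }
  if (is.null(total_word_counts)) {
    total_word_counts <- lengths(lemmas_by_age)
    names(total_word_counts) <- ages
  }
  cells <- expand.grid(subdimension = scm_subdimensions(),
                       valence = c("positive", "negative"),
                       stringsAsFactors = FALSE)
  cell_names <- paste(cells$subdimension, cells$valence, sep = "_")
  rows <- lapply(ages, function(a) {
    lemmas <- lemmas_by_age[[a]]
    if (!is.null(retained_vocab)) {
      lemmas <- lemmas[lemmas %in% retained_vocab[[a]]]
    }
    counts <- stats::setNames(integer(length(cell_names)), cell_names)
    if (length(lemmas) > 0) {
      occ <- table(lemmas)
      hits <- lexicon[lexicon$word %in% names(occ), , drop = FALSE]
      if (nrow(hits) > 0) {
        key <- paste(hits$subdimension,
                     ifelse(hits$valence > 0, "positive", "negative"),
                     sep = "_")
        add <- tapply(as.integer(occ[hits$word]), key, sum)
        counts[names(add)] <- counts[names(add)] + as.integer(add)
      }
    }
    tibble::tibble(age = as.integer(a),
                   total_word_count = as.integer(total_word_counts[[a]]),
                   !!!as.list(counts))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$age)
  out <- out[, c("age", "total_word_count",
                 paste(rep(scm_subdimensions(), each = 2),
                       c("positive", "negative"), sep = "_"))]
  class(out) <- c("subdimension_counts", class(out))
  out
}

#' Export the subdimension count table as CSV
#'
#' Column order: age, total word count, then positive/negative counts for
#' sociability, morality, ability, assertiveness.
#'
#' @param counts A `subdimension_counts` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table_csv <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}
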