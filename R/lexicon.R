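#' Stereotype content lexicon
#'
#' A stereotype content lexicon maps lowercase word lemmas to a Stereotype
#' Content Model dimension (`warmth` or `competence`), a subdimension
#' (`sociability`/`morality` under warmth, `ability`/`assertiveness` under
#' competence) and a valence (`+1` or `-1`). A word may carry several entries
#' (e.g. a word that is positive sociability under one sense and negative
#' morality under another), but a `(word, subdimension, valence)` triple may
#' appear at most once.
#'
#' @param entries A data frame with columns `word`, `dimension`,
#'   `subdimension`, `valence`.
#' @return A tibble of class `scm_lexicon`.
#' @seealso [scm_seed_lexicon()], [read_scm_lexicon()]
#' @export
scm_lexicon <- function(entries) {
  entries <- tibble::as_tibble(entries)
  required <- c("word", "dimension", "subdimension", "valence")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0) {
    rlang::abort(paste0("lexicon is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  entries$word <- tolower(trimws(entries$word))
  entries$valence <- as.integer(entries$valence)
  if (nrow(entries) == 0) rlang::abort("lexicon has no entries")
  if (!all(entries$dimension %in% c("warmth", "competence"))) {
    rlang::abort("dimension must be 'warmth' or 'competence'")
  }
  if (!all(entries$subdimension %in% scm_subdimensions())) {
    rlang::abort(paste0("subdimension must be one of: ",
                        paste(scm_subdimensions(), collapse = ", ")))
  }
  if (!all(entries$valence %in% c(-1L, 1L))) {
    rlang::abort("valence must be +1 or -1")
  }
  expected_dim <- subdimension_parent(entries$subdimension)
  bad <- which(expected_dim != entries$dimension)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "subdimension/dimension mismatch for word(s): ",
      paste(unique(entries$word[bad]), collapse = ", "),
      " (sociability/morality belong to warmth; ability/assertiveness to competence)"
    ))
  }
  key <- paste(entries$word, entries$subdimension, entries$valence)
  if (anyDuplicated(key)) {
    rlang::abort(paste0("duplicated (word, subdimension, valence) entries: ",
                        paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  entries <- entries[, required]
  class(entries) <- c("scm_lexicon", class(entries))
  entries
}

#' @export
print.scm_lexicon <- function(x, ...) {
  cat("<scm_lexicon> ", nrow(x), " entries, ",
      length(unique(x$word)), " distinct words\n", sep = "")
  tab <- table(x$subdimension, ifelse(x$valence > 0, "positive", "negative"))
  print(tab)
  invisible(x)
}

#' The four SCM subdimensions, in canonical order
#' @return Character vector.
#' @export
scm_subdimensions <- function() {
  c("sociability", "morality", "ability", "assertiveness")
}

# Parent dimension of each subdimension.
subdimension_parent <- function(subdimension) {
  ifelse(subdimension %in% c("sociability", "morality"), "warmth", "competence")
}

#' Read a stereotype content lexicon from delimited text
#'
#' Expects a header with columns `word`, `dimension`, `subdimension`,
#' `valence` (tab- or comma-separated, sniffed from the header line).
#'
#' @param path Path to the file.
#' @return An [scm_lexicon()].
#' @export
read_scm_lexicon <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  scm_lexicon(df)
}

#' Write a stereotype content lexicon to tab-separated text
#' @param lexicon An [scm_lexicon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scm_lexicon <- function(lexicon, path) {
  utils::write.table(as.data.frame(lexicon), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Built-in seed lexicon
#'
#' A small built-in set of stereotype content seed adjectives covering all
#' four subdimensions in both valences, in the spirit of published stereotype
#' content dictionaries. It is intentionally compact: real audits should read
#' a full dictionary with [read_scm_lexicon()]. Every entry is a lemma (base
#' form) so that the rule-based lemmatizer maps corpus occurrences back onto
#' the lexicon exactly.
#'
#' @return An [scm_lexicon()].
#' @export
scm_seed_lexicon <- function() {
  e <- function(words, dimension, subdimension, valence) {
    tibble::tibble(word = words, dimension = dimension,
                   subdimension = subdimension, valence = valence)
  }
  scm_lexicon(dplyr::bind_rows(
    e(c("warm", "kind", "friendly", "sociable", "caring", "outgoing",
        "cheerful", "playful", "gentle", "affectionate"),
      "warmth", "sociability", 1L),
    e(c("cold", "distant", "unfriendly", "aloof", "hostile", "grumpy",
        "withdrawn", "irritable"),
      "warmth", "sociability", -1L),
    e(c("honest", "trustworthy", "sincere", "loyal", "fair", "moral",
        "dependable", "genuine", "humble", "responsible"),
      "warmth", "morality", 1L),
    e(c("dishonest", "deceitful", "unfair", "selfish", "cruel", "immoral",
        "untrustworthy", "corrupt"),
      "warmth", "morality", -1L),
    e(c("intelligent", "competent", "capable", "skillful", "wise",
        "knowledgeable", "clever", "efficient", "experienced", "smart"),
      "competence", "ability", 1L),
    e(c("incompetent", "foolish", "clumsy", "ignorant", "incapable", "inept",
        "unskilled", "forgetful"),
      "competence", "ability", -1L),
    e(c("confident", "ambitious", "assertive", "energetic", "determined",
        "independent", "bold", "driven", "proactive", "adventurous"),
      "competence", "assertiveness", 1L),
    e(c("timid", "passive", "submissive", "hesitant", "insecure", "dependent",
        "meek", "indecisive"),
      "competence", "assertiveness", -1L)
  ))
}
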