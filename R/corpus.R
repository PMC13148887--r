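#' Default prompt template
#'
#' The age-neutral prompt used to elicit personality descriptions, with a
#' single `[AGE]` placeholder.
#'
#' @return Character scalar.
#' @export
default_prompt_template <- function() {
  "Describe the personality of a [AGE]-year-old person."
}

#' Collection configuration
#'
#' Bundles the prompt template, the prompted ages, the number of responses per
#' age and the text-generation sampling parameters. Defaults mirror a
#' 9-age x 100-response design with temperature 1.0, top_p 1.0 and a
#' 2,048-token output cap.
#'
#' @param prompt_template Prompt with exactly one `[AGE]` placeholder.
#' @param ages Strictly increasing integer vector of prompted ages (years).
#' @param responses_per_age Positive integer.
#' @param temperature Sampling temperature, >= 0.
#' @param top_p Nucleus-sampling mass, in (0, 1].
#' @param max_tokens Positive integer output cap.
#' @param seed Integer seed driving any seeded provider.
#' @return A list of class `collection_config`.
#' @export
collection_config <- function(prompt_template = default_prompt_template(),
                              ages = seq(10L, 90L, by = 10L),
                              responses_per_age = 100L,
                              temperature = 1.0,
                              top_p = 1.0,
                              max_tokens = 2048L,
                              seed = 1L) {
  n_placeholder <- lengths(regmatches(prompt_template,
                                      gregexpr("[AGE]", prompt_template,
                                               fixed = TRUE)))
  if (n_placeholder != 1L) {
    rlang::abort(paste0("prompt_template must contain the [AGE] placeholder ",
                        "exactly once (found ", n_placeholder, ")"),
                 class = "scmaudit_config_error")
  }
  ages <- as.integer(ages)
  if (length(ages) < 1L || any(diff(ages) <= 0)) {
    rlang::abort("ages must be a strictly increasing integer vector",
                 class = "scmaudit_config_error")
  }
  if (responses_per_age < 1L) {
    rlang::abort("responses_per_age must be >= 1",
                 class = "scmaudit_config_error")
  }
  if (temperature < 0) {
    rlang::abort("temperature must be >= 0", class = "scmaudit_config_error")
  }
  if (top_p <= 0 || top_p > 1) {
    rlang::abort("top_p must be in (0, 1]", class = "scmaudit_config_error")
  }
  if (max_tokens < 1L) {
    rlang::abort("max_tokens must be positive",
                 class = "scmaudit_config_error")
  }
  structure(list(prompt_template = prompt_template, ages = ages,
                 responses_per_age = as.integer(responses_per_age),
                 temperature = temperature, top_p = top_p,
                 max_tokens = as.integer(max_tokens), seed = as.integer(seed)),
            class = "collection_config")
}

#' Render the prompt for one age
#'
#' @param template Prompt template with exactly one `[AGE]` placeholder.
#' @param age Positive integer age in years.
#' @return The prompt with the placeholder replaced by the decimal age.
#' @examples
#' render_prompt(default_prompt_template(), 40)
#' @export
render_prompt <- function(template, age) {
  n_placeholder <- lengths(regmatches(template,
                                      gregexpr("[AGE]", template,
                                               fixed = TRUE)))
  if (n_placeholder != 1L) {
    rlang::abort(paste0("template must contain the [AGE] placeholder exactly ",
                        "once (found ", n_placeholder, ")"),
                 class = "scmaudit_config_error")
  }
  if (!is.numeric(age) || length(age) != 1L || age <= 0 || age != round(age)) {
    rlang::abort("age must be a single positive integer",
                 class = "scmaudit_config_error")
  }
  sub("[AGE]", format(as.integer(age)), template, fixed = TRUE)
}

# Abbreviations that do not end a sentence.
.abbreviations <- c("mr", "mrs", "ms", "dr", "prof", "st", "e.g", "i.e",
                    "etc", "vs", "approx", "no")

#' Split raw response text into sentences
#'
#' Rule-based splitter: terminal punctuation (`.` `!` `?`) followed by
#' whitespace ends a sentence, with a small abbreviation guard list; newlines
#' (list items) are always treated as sentence boundaries, so colon-ended list
#' headers become their own sentences. Each sentence records its 0-based
#' position, first/last flags, whether it ends with a colon, and its word
#' count under the package tokenizer ([tokenize_words()]).
#'
#' @param raw_text Character scalar (a full response).
#' @return A tibble with columns `text`, `position_index`, `word_count`,
#'   `is_first`, `is_last`, `ends_with_colon`. Empty input yields zero rows.
#' @export
split_sentences <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  empty <- tibble::tibble(text = character(0), position_index = integer(0),
                          word_count = integer(0), is_first = logical(0),
                          is_last = logical(0), ends_with_colon = logical(0))
  if (is.na(raw_text) || !nzchar(trimws(raw_text))) return(empty)

  lines <- strsplit(raw_text, "\n+")[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  split_line <- function(line) {
    # Split after . ! ? followed by whitespace, unless the token before the
    # period is a known abbreviation or a single initial.
    pieces <- character(0)
    rest <- line
    repeat {
      m <- regexpr("[.!?]+(?=\\s)", rest, perl = TRUE)
      if (m == -1) {
        pieces <- c(pieces, rest)
        break
      }
      cut <- m + attr(m, "match.length") - 1L
      head_txt <- substr(rest, 1L, cut)
      last_word <- sub("^.*?([^\\s]+)[.!?]+$", "\\1", head_txt, perl = TRUE)
      last_word <- tolower(gsub("[.!?]+$", "", last_word))
      if (grepl("\\.$", substr(rest, cut, cut)) &&
          (last_word %in% .abbreviations ||
           (nchar(last_word) == 1L && grepl("^[a-z]$", last_word)))) {
        # Abbreviation: do not split here; find the next boundary.
        nxt <- regexpr("[.!?]+(?=\\s)", substr(rest, cut + 1L, nchar(rest)),
                       perl = TRUE)
        if (nxt == -1) {
          pieces <- c(pieces, rest)
          break
        }
        # Re-run with the remainder glued on; simplest correct approach is to
        # scan forward from the character after this boundary.
        cut2 <- cut + nxt + attr(nxt, "match.length") - 1L
        pieces <- c(pieces, substr(rest, 1L, cut2))
        rest <- trimws(substr(rest, cut2 + 1L, nchar(rest)))
      } else {
        pieces <- c(pieces, head_txt)
        rest <- trimws(substr(rest, cut + 1L, nchar(rest)))
      }
      if (!nzchar(rest)) break
    }
    trimws(pieces[nzchar(trimws(pieces))])
  }

  sents <- unlist(lapply(lines, split_line), use.names = FALSE)
  if (length(sents) == 0) return(empty)
  n <- length(sents)
  tibble::tibble(
    text = sents,
    position_index = seq_len(n) - 1L,
    word_count = vapply(sents, function(s) length(tokenize_words(s)),
                        integer(1), USE.NAMES = FALSE),
    is_first = seq_len(n) == 1L,
    is_last = seq_len(n) == n,
    ends_with_colon = grepl(":\\s*$", sents)
  )
}

#' Apply the sentence-level filters of the audit
#'
#' Given the sentences of a single response (as returned by
#' [split_sentences()]), excludes, in order: (i) the first and last sentence
#' of the response (boilerplate openers/closers), (ii) sentences of three
#' words or fewer (short sentences embed poorly), and (iii) sentences ending
#' with a colon (list headers). Relative order is preserved and sentence text
#' is never altered; position flags are not recomputed.
#'
#' @param sentences Tibble from [split_sentences()] for one response.
#' @return The surviving rows, original columns intact.
#' @export
filter_sentences <- function(sentences) {
  stopifnot(is.data.frame(sentences))
  if (nrow(sentences) == 0) return(sentences)
  kept <- sentences[!(sentences$is_first | sentences$is_last), , drop = FALSE]
  kept <- kept[kept$word_count > 3L, , drop = FALSE]
  kept <- kept[!kept$ends_with_colon, , drop = FALSE]
  kept
}

#' Collect a corpus from a text provider
#'
#' Iterates over `config$ages` (outer) and replicates (inner), rendering the
#' prompt for each age and calling
#' `provider(prompt, temperature, top_p, max_tokens)`. Provider text is stored
#' unmodified. Any provider failure aborts the whole collection (no partial
#' corpus is returned), naming the failing age and replicate.
#'
#' @param provider A function `(prompt, temperature, top_p, max_tokens)`
#'   returning a character scalar. See [synthetic_provider()].
#' @param config A [collection_config()].
#' @return A tibble with columns `sample_id`, `age`, `raw_text` (one row per
#'   response), of class `scm_corpus`.
#' @export
collect_corpus <- function(provider, config) {
  stopifnot(is.function(provider), inherits(config, "collection_config"))
  rows <- vector("list", length(config$ages) * config$responses_per_age)
  k <- 0L
  for (age in config$ages) {
    prompt <- render_prompt(config$prompt_template, age)
    for (rep in seq_len(config$responses_per_age)) {
      txt <- tryCatch(
        provider(prompt, config$temperature, config$top_p, config$max_tokens),
        error = function(e) {
          rlang::abort(paste0("provider failed for age ", age, ", replicate ",
                              rep, ": ", conditionMessage(e)),
                       class = "scmaudit_collection_error")
        })
      if (!is.character(txt) || length(txt) != 1L) {
        rlang::abort(paste0("provider returned a non-string for age ", age,
                            ", replicate ", rep),
                     class = "scmaudit_collection_error")
      }
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        sample_id = sprintf("age%02d_r%03d", age, rep),
        age = as.integer(age), raw_text = txt)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scm_corpus", class(out))
  out
}

#' Split and filter every response of a corpus
#'
#' Applies [split_sentences()] and [filter_sentences()] per response and
#' returns the surviving sentences keyed by sample. Responses whose sentences
#' are all filtered out simply contribute no rows.
#'
#' @param corpus Tibble with `sample_id`, `age`, `raw_text`.
#' @param filter Apply [filter_sentences()]? Default `TRUE`.
#' @return Tibble with columns `sample_id`, `age`, `position_index`, `text`,
#'   `word_count`. The attribute `filter_log` records how many sentences each
#'   rule removed.
#' @export
preprocess_corpus <- function(corpus, filter = TRUE) {
  stopifnot(all(c("sample_id", "age", "raw_text") %in% names(corpus)))
  if (anyDuplicated(corpus$sample_id)) {
    rlang::abort("sample_id must be unique within a corpus")
  }
  log <- c(total = 0L, first_last = 0L, short = 0L, colon = 0L, kept = 0L)
  out <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    sents <- split_sentences(corpus$raw_text[i])
    log["total"] <- log["total"] + nrow(sents)
    if (filter) {
      s1 <- sents[!(sents$is_first | sents$is_last), , drop = FALSE]
      log["first_last"] <- log["first_last"] + nrow(sents) - nrow(s1)
      s2 <- s1[s1$word_count > 3L, , drop = FALSE]
      log["short"] <- log["short"] + nrow(s1) - nrow(s2)
      s3 <- s2[!s2$ends_with_colon, , drop = FALSE]
      log["colon"] <- log["colon"] + nrow(s2) - nrow(s3)
      sents <- s3
    }
    if (nrow(sents) > 0) {
      out[[i]] <- tibble::tibble(sample_id = corpus$sample_id[i],
                                 age = corpus$age[i],
                                 position_index = sents$position_index,
                                 text = sents$text,
                                 word_count = sents$word_count)
    }
  }
  log["kept"] <- log["total"] - log["first_last"] - log["short"] - log["colon"]
  res <- dplyr::bind_rows(out)
  attr(res, "filter_log") <- log
  res
}

#' Write / read a corpus as JSON-Lines
#'
#' One JSON object per line with keys `sample_id`, `age`, `raw_text`.
#'
#' @param corpus Tibble with those columns.
#' @param path File path.
#' @return `path` (write) or the corpus tibble (read).
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(list(sample_id = corpus$sample_id[i],
                                     age = corpus$age[i],
                                     raw_text = corpus$raw_text[i]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rows <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    tibble::tibble(sample_id = obj$sample_id, age = as.integer(obj$age),
                   raw_text = obj$raw_text)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scm_corpus", class(out))
  out
}

#' Write filtered sentences as JSON-Lines
#'
#' One object per line with keys `sample_id`, `age`, `position_index`, `text`.
#'
#' @param sentences Tibble from [preprocess_corpus()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sentences_jsonl <- function(sentences, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(sentences))) {
    writeLines(jsonlite::toJSON(list(sample_id = sentences$sample_id[i],
                                     age = sentences$age[i],
                                     position_index = sentences$position_index[i],
                                     text = sentences$text[i]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}
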