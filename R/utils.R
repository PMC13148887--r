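#' Tokenize a piece of text into whitespace-delimited words
#'
#' Tokens are split on whitespace; leading and trailing punctuation is stripped
#' from every token (so `"kind,"` and `"(kind"` both yield `"kind"`), and
#' hyphenated forms count as one token. This single tokenizer underlies the
#' sentence word-count rule, the synthetic embedding backend, and the total
#' word counts of the subdimension count table, so the three stages agree on
#' what a "word" is.
#'
#' @param text Character scalar.
#' @param lowercase Lowercase the tokens? Default `TRUE`.
#' @return Character vector of tokens (empty tokens dropped).
#' @export
tokenize_words <- function(text, lowercase = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks <- toks[nzchar(toks)]
  if (lowercase) toks <- tolower(toks)
  toks
}

# Deterministic 31-adic string hash, platform independent (pure integer
# arithmetic below 2^31). Used to seed per-sentence noise and to place
# non-lexicon tokens on hashed coordinates.
string_hash <- function(x) {
  h <- 0
  for (cp in utf8ToInt(enc2utf8(x))) {
    h <- (h * 31 + cp) %% 1000003
  }
  as.integer(h)
}

# Clip a numeric vector into [lo, hi].
clip <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
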