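#' Synthetic embedding specification
#'
#' Defines the geometry of the deterministic synthetic embedding backend.
#' Each Stereotype Content Model subdimension owns one dedicated coordinate
#' (distinct across subdimensions); a lexicon word found in a sentence adds
#' `valence * signal_weight` on its subdimension's axis, so a positive and a
#' negative word of the same subdimension cancel. Optionally, non-lexicon
#' tokens contribute `token_hash_weight` on a coordinate chosen by a
#' deterministic string hash over the non-axis coordinates, giving sentences a
#' vocabulary-driven geometry (off by default). Isotropic Gaussian noise with
#' standard deviation `noise_sd` is seeded per sentence from `(seed, text)`,
#' so identical sentences always embed identically.
#'
#' @param dim Embedding dimension (default 64).
#' @param axis_assignment Data frame with columns `subdimension`, `valence`,
#'   `axis` (1-based coordinate). Default: one shared axis per subdimension on
#'   coordinates 1-4 for both valences.
#' @param signal_weight Positive signal magnitude per lexicon word.
#' @param noise_sd Noise standard deviation, >= 0.
#' @param seed Integer noise seed.
#' @param token_hash_weight Weight of the hashed bag-of-words signal for
#'   non-lexicon tokens; 0 disables it.
#' @return A list of class `synthetic_embedding_spec`.
#' @export
synthetic_embedding_spec <- function(dim = 64L,
                                     axis_assignment = NULL,
                                     signal_weight = 1,
                                     noise_sd = 0,
                                     seed = 42L,
                                     token_hash_weight = 0) {
  dim <- as.integer(dim)
  stopifnot(dim >= 1L, signal_weight > 0, noise_sd >= 0,
            token_hash_weight >= 0)
  if (is.null(axis_assignment)) {
    axis_assignment <- tibble::tibble(
      subdimension = rep(scm_subdimensions(), each = 2L),
      valence = rep(c(1L, -1L), times = 4L),
      axis = rep(1:4, each = 2L))
  }
  axis_assignment <- tibble::as_tibble(axis_assignment)
  stopifnot(all(c("subdimension", "valence", "axis") %in%
                  names(axis_assignment)))
  if (any(axis_assignment$axis < 1L | axis_assignment$axis > dim)) {
    rlang::abort("axis indices must lie in 1..dim")
  }
  # Axes must be distinct across subdimensions (the two valences of one
  # subdimension may share an axis, which is what makes opposite-valence
  # words cancel).
  per_sub <- unique(axis_assignment[, c("subdimension", "axis")])
  if (anyDuplicated(per_sub$axis)) {
    rlang::abort("axis indices must be distinct across subdimensions")
  }
  structure(list(dim = dim, axis_assignment = axis_assignment,
                 signal_weight = signal_weight, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 token_hash_weight = token_hash_weight),
            class = "synthetic_embedding_spec")
}

# Map a non-axis token to its hashed coordinate.
hash_coordinate <- function(token, spec) {
  axes <- sort(unique(spec$axis_assignment$axis))
  free <- setdiff(seq_len(spec$dim), axes)
  if (length(free) == 0) rlang::abort("no free coordinates for token hashing")
  free[(string_hash(token) %% length(free)) + 1L]
}

#' Embed one sentence with the synthetic backend
#'
#' The embedding is the sum, over lexicon entries whose word occurs as a
#' (case-insensitive, exactly tokenized) token of the sentence, of
#' `valence * signal_weight` on the entry's assigned axis — each occurrence
#' counts — plus the optional hashed signal for non-lexicon tokens, plus
#' seeded isotropic noise. Deterministic given `(spec$seed, sentence)`.
#'
#' @param spec A [synthetic_embedding_spec()].
#' @param sentence Character scalar.
#' @param lexicon An [scm_lexicon()].
#' @return Numeric vector of length `spec$dim`.
#' @export
synthetic_embed <- function(spec, sentence, lexicon) {
  stopifnot(inherits(spec, "synthetic_embedding_spec"))
  v <- numeric(spec$dim)
  toks <- tokenize_words(sentence)
  if (length(toks) > 0) {
    amap <- spec$axis_assignment
    in_lex <- toks %in% lexicon$word
    for (tok in toks[in_lex]) {
      entries <- lexicon[lexicon$word == tok, , drop = FALSE]
      for (j in seq_len(nrow(entries))) {
        ax <- amap$axis[amap$subdimension == entries$subdimension[j] &
                          amap$valence == entries$valence[j]]
        if (length(ax) != 1L) {
          rlang::abort(paste0("no axis assigned for (",
                              entries$subdimension[j], ", ",
                              entries$valence[j], ")"))
        }
        v[ax] <- v[ax] + entries$valence[j] * spec$signal_weight
      }
    }
    if (spec$token_hash_weight > 0) {
      for (tok in toks[!in_lex]) {
        co <- hash_coordinate(tok, spec)
        v[co] <- v[co] + spec$token_hash_weight
      }
    }
  }
  if (spec$noise_sd > 0) {
    noise_seed <- (spec$seed + string_hash(sentence)) %% 2147483647L
    v <- v + withr::with_seed(noise_seed,
                              stats::rnorm(spec$dim, sd = spec$noise_sd))
  }
  v
}

#' Embedding backends
#'
#' A backend is a list with elements `id` (string recorded in metadata),
#' `dim`, and `embed_fn(texts)` returning a numeric matrix with one row per
#' text. `synthetic_backend()` wraps [synthetic_embed()];
#' `function_backend()` adapts any user-supplied sentence encoder (e.g. a
#' transformer model driven from another process), recording its checkpoint
#' identifier rather than assuming one.
#'
#' @param spec A [synthetic_embedding_spec()].
#' @param lexicon An [scm_lexicon()].
#' @return An object of class `embedding_backend`.
#' @export
synthetic_backend <- function(spec = synthetic_embedding_spec(),
                              lexicon = scm_seed_lexicon()) {
  structure(list(
    id = sprintf("synthetic(dim=%d,seed=%d,noise_sd=%g)", spec$dim,
                 spec$seed, spec$noise_sd),
    dim = spec$dim,
    embed_fn = function(texts) {
      t(vapply(texts, function(s) synthetic_embed(spec, s, lexicon),
               numeric(spec$dim), USE.NAMES = FALSE))
    }), class = "embedding_backend")
}

#' @rdname synthetic_backend
#' @param fn Function mapping a character vector to an `n x dim` matrix.
#' @param dim Output dimension of `fn` (a typical large sentence transformer
#'   emits 1,024-dimensional embeddings).
#' @param checkpoint Identifier of the encoder checkpoint, kept in `id`.
#' @export
function_backend <- function(fn, dim, checkpoint = "user-supplied") {
  stopifnot(is.function(fn), dim >= 1)
  structure(list(id = paste0("function(", checkpoint, ")"),
                 dim = as.integer(dim),
                 embed_fn = function(texts) {
                   m <- fn(texts)
                   if (!is.matrix(m) || nrow(m) != length(texts) ||
                       ncol(m) != dim) {
                     rlang::abort(paste0(
                       "backend '", checkpoint, "' returned a ",
                       paste(dim(m), collapse = "x"),
                       " object; expected ", length(texts), "x", dim),
                       class = "scmaudit_backend_error")
                   }
                   m
                 }), class = "embedding_backend")
}

#' Embed a vector of sentences
#'
#' @param backend An `embedding_backend`.
#' @param sentences Character vector of non-empty sentence texts; names (or
#'   positions) become row ids.
#' @return Numeric matrix, one row per sentence in input order, with row
#'   names as ids and attribute `backend_id`. An empty input yields a 0-row
#'   matrix with the backend's declared dimension.
#' @export
embed_sentences <- function(backend, sentences) {
  if (!inherits(backend, "embedding_backend")) {
    rlang::abort("backend must be an embedding_backend",
                 class = "scmaudit_backend_error")
  }
  ids <- names(sentences) %||% as.character(seq_along(sentences))
  if (length(sentences) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = backend$dim)
    attr(m, "backend_id") <- backend$id
    return(m)
  }
  if (any(is.na(sentences)) || any(!nzchar(sentences))) {
    rlang::abort("sentences must be non-empty strings")
  }
  m <- backend$embed_fn(as.character(sentences))
  if (any(!is.finite(m))) {
    rlang::abort("backend produced non-finite embedding entries",
                 class = "scmaudit_backend_error")
  }
  rownames(m) <- ids
  attr(m, "backend_id") <- backend$id
  m
}
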