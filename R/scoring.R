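#' Build labelled template sentences from a lexicon
#'
#' Generates supervised training sentences for the warmth/competence scorer.
#' Every distinct lexicon adjective yields one single-adjective sentence,
#' "These people are always \[ADJECTIVE\].". Up to `pair_budget`
#' two-adjective sentences, "These people are always \[ADJECTIVE 1\] and
#' \[ADJECTIVE 2\].", are sampled (seeded, without replacement) from the
#' unordered pairs of adjectives sharing both dimension and valence, keeping
#' the labels unambiguous.
#'
#' Label rule: each adjective contributes its valence on its own dimension
#' and 0 on the other; a sentence's labels are the mean of its adjectives'
#' contributions. A word with several lexicon entries contributes the mean of
#' its entries.
#'
#' @param lexicon An [scm_lexicon()].
#' @param pair_budget Maximum number of two-adjective sentences (0 = singles
#'   only).
#' @param seed Integer seed for pair sampling.
#' @return Tibble with columns `text`, `warmth_label`, `competence_label`,
#'   `adjectives` (list-column), `kind` ("single"/"pair").
#' @export
build_template_sentences <- function(lexicon, pair_budget = 200L, seed = 1L) {
  if (!inherits(lexicon, "scm_lexicon")) lexicon <- scm_lexicon(lexicon)
  has_w <- any(lexicon$dimension == "warmth")
  has_c <- any(lexicon$dimension == "competence")
  if (!has_w || !has_c) {
    rlang::abort("lexicon must contain at least one warmth and one competence entry")
  }
  contribution <- function(word) {
    entries <- lexicon[lexicon$word == word, , drop = FALSE]
    w <- mean(ifelse(entries$dimension == "warmth", entries$valence, 0))
    co <- mean(ifelse(entries$dimension == "competence", entries$valence, 0))
    c(w, co)
  }
  words <- unique(lexicon$word)
  contribs <- vapply(words, contribution, numeric(2))
  singles <- tibble::tibble(
    text = sprintf("These people are always %s.", words),
    warmth_label = unname(contribs[1, ]),
    competence_label = unname(contribs[2, ]),
    adjectives = lapply(words, identity),
    kind = "single")

  # Candidate pairs: unordered, within a (dimension, valence) class, over
  # words whose entries all agree on that class (ambiguous words excluded
  # from pairing).
  pure <- lexicon |>
    dplyr::distinct(.data$word, .data$dimension, .data$valence) |>
    dplyr::group_by(.data$word) |>
    dplyr::filter(dplyr::n() == 1L) |>
    dplyr::ungroup()
  pair_rows <- list()
  for (cls in split(pure, paste(pure$dimension, pure$valence))) {
    ws <- sort(unique(cls$word))
    if (length(ws) >= 2L) {
      idx <- utils::combn(length(ws), 2L)
      pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
        w1 = ws[idx[1, ]], w2 = ws[idx[2, ]],
        dimension = cls$dimension[1], valence = cls$valence[1])
    }
  }
  pairs <- dplyr::bind_rows(pair_rows)
  if (nrow(pairs) > 0 && pair_budget > 0) {
    if (nrow(pairs) > pair_budget) {
      keep <- withr::with_seed(seed,
                               sample.int(nrow(pairs), pair_budget))
      pairs <- pairs[sort(keep), , drop = FALSE]
    }
    pair_sentences <- tibble::tibble(
      text = sprintf("These people are always %s and %s.",
                     pairs$w1, pairs$w2),
      warmth_label = ifelse(pairs$dimension == "warmth", pairs$valence, 0),
      competence_label = ifelse(pairs$dimension == "competence",
                                pairs$valence, 0),
      adjectives = Map(c, pairs$w1, pairs$w2),
      kind = "pair")
  } else {
    pair_sentences <- singles[0, ]
  }
  dplyr::bind_rows(singles, pair_sentences)
}

#' Fit the warmth/competence scoring model
#'
#' Fits a two-response partial least squares regression from sentence
#' embeddings of labelled template sentences to (warmth, competence) labels.
#' The fitted map is linear; predictions are clipped to \[-1, 1\] at scoring
#' time, not here.
#'
#' @param train Numeric matrix of template-sentence embeddings (rows =
#'   sentences).
#' @param labels Data frame or matrix with columns/cols `warmth_label` and
#'   `competence_label` (or two unnamed columns in that order).
#' @param n_components Number of PLS components. `NULL` (default) uses
#'   `min(25, rank of the centred training matrix)`; an explicit value larger
#'   than the rank is an error.
#' @return Object of class `scm_model` with elements `fit`, `n_components`,
#'   `dim`, `checksum`.
#' @export
fit_scm_model <- function(train, labels, n_components = NULL) {
  stopifnot(is.matrix(train))
  labels <- as.data.frame(labels)
  if (!all(c("warmth_label", "competence_label") %in% names(labels))) {
    if (ncol(labels) == 2L) names(labels) <- c("warmth_label",
                                               "competence_label")
    else rlang::abort("labels must have warmth_label and competence_label")
  }
  if (nrow(train) != nrow(labels)) {
    rlang::abort("train and labels must have the same number of rows")
  }
  Y <- cbind(warmth = labels$warmth_label, competence = labels$competence_label)
  for (j in 1:2) {
    if (stats::var(Y[, j]) == 0) {
      rlang::abort(paste0("no variance on the ", colnames(Y)[j],
                          " labels; training requires both positive and ",
                          "negative examples"),
                   class = "scmaudit_degenerate_error")
    }
    if (!any(Y[, j] > 0) || !any(Y[, j] < 0)) {
      rlang::abort(paste0("labels must contain both positive and negative ",
                          "examples on the ", colnames(Y)[j], " dimension"),
                   class = "scmaudit_degenerate_error")
    }
  }
  rk <- qr(scale(train, center = TRUE, scale = FALSE))$rank
  if (is.null(n_components)) {
    n_components <- min(25L, rk)
  }
  n_components <- as.integer(n_components)
  if (nrow(train) < n_components + 1L) {
    rlang::abort("need at least n_components + 1 training sentences")
  }
  if (rk < n_components) {
    rlang::abort(paste0("training matrix has rank ", rk, " < n_components = ",
                        n_components, "; use fewer components"),
                 class = "scmaudit_rank_error")
  }
  X <- train
  colnames(X) <- paste0("E", seq_len(ncol(X)))
  fit <- tryCatch(
    suppressWarnings(
      mixOmics::pls(X, Y, ncomp = n_components, scale = FALSE,
                    mode = "regression")),
    error = function(e) {
      rlang::abort(paste0("PLS fit failed on degenerate training geometry (",
                          conditionMessage(e),
                          "); try fewer components"),
                   class = "scmaudit_rank_error")
    })
  structure(list(fit = fit, n_components = n_components, dim = ncol(train),
                 checksum = rlang::hash(list(unname(train), unname(Y),
                                             n_components))),
            class = "scm_model")
}

#' @export
print.scm_model <- function(x, ...) {
  cat("<scm_model> PLS scorer: dim =", x$dim, ", components =",
      x$n_components, "\n  training checksum:", x$checksum, "\n")
  invisible(x)
}

#' Score sentences on warmth and competence
#'
#' Applies the fitted linear map and clips each predicted score into
#' \[-1, 1\]. The fraction of predictions that needed clipping is attached as
#' the `clipping_rate` attribute.
#'
#' @param model An `scm_model`.
#' @param embeddings Numeric matrix of sentence embeddings with the model's
#'   training dimension.
#' @return Tibble with columns `sentence_id`, `warmth`, `competence`, rows in
#'   input order.
#' @export
score_sentences <- function(model, embeddings) {
  stopifnot(inherits(model, "scm_model"), is.matrix(embeddings))
  if (ncol(embeddings) != model$dim) {
    rlang::abort(paste0("embedding dim ", ncol(embeddings),
                        " does not match model training dim ", model$dim),
                 class = "scmaudit_dim_error")
  }
  ids <- rownames(embeddings) %||% as.character(seq_len(nrow(embeddings)))
  if (nrow(embeddings) == 0) {
    return(tibble::tibble(sentence_id = character(0), warmth = numeric(0),
                          competence = numeric(0)))
  }
  X <- embeddings
  colnames(X) <- paste0("E", seq_len(ncol(X)))
  raw <- suppressWarnings(
    predict(model$fit, X)$predict[, , model$n_components, drop = FALSE])
  raw <- matrix(raw, nrow = nrow(X), ncol = 2)
  clipped <- clip(raw, -1, 1)
  out <- tibble::tibble(sentence_id = ids, warmth = clipped[, 1],
                        competence = clipped[, 2])
  attr(out, "clipping_rate") <- mean(raw != clipped)
  out
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Tests equality of group means without assuming equal variances, via the
#' Welch F statistic with Welch-Satterthwaite denominator degrees of freedom.
#'
#' @param groups List of numeric vectors, one per group (e.g. one per age);
#'   names, if present, are used in error messages.
#' @return List of class `welch_result`: `F`, `df1` (= groups - 1), `df2`,
#'   `p_value`.
#' @export
welch_anova <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) {
    rlang::abort("need at least 2 groups", class = "scmaudit_degenerate_error")
  }
  nm <- names(groups) %||% as.character(seq_along(groups))
  n <- lengths(groups)
  if (any(n < 2L)) {
    rlang::abort(paste0("group(s) with fewer than 2 observations: ",
                        paste(nm[n < 2L], collapse = ", ")),
                 class = "scmaudit_degenerate_error")
  }
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) {
    rlang::abort(paste0("zero-variance group(s): ",
                        paste(nm[v == 0], collapse = ", ")),
                 class = "scmaudit_degenerate_error")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), times = n))
  ow <- stats::oneway.test(values ~ g, var.equal = FALSE)
  structure(list(F = unname(ow$statistic),
                 df1 = as.integer(unname(ow$parameter["num df"])),
                 df2 = unname(ow$parameter["denom df"]),
                 p_value = unname(ow$p.value)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch's ANOVA: F(%d, %.1f) = %.2f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p_value))
  invisible(x)
}

#' Per-age summary of warmth/competence scores
#'
#' For each age: n, mean, standard deviation and quartiles of both score
#' dimensions, plus Welch's ANOVA across ages for each dimension (attached as
#' the `welch` attribute; a dimension whose groups are degenerate — e.g. all
#' scores equal, or single-sentence groups — records the error message
#' instead of a result).
#'
#' @param scores Tibble from [score_sentences()].
#' @param ages Integer vector, one age per scored sentence.
#' @return Tibble with one row per (age, dimension), columns `age`,
#'   `dimension`, `n`, `mean`, `sd`, `q25`, `median`, `q75`.
#' @export
summarize_scores_by_age <- function(scores, ages) {
  stopifnot(nrow(scores) == length(ages))
  df <- dplyr::bind_cols(scores, tibble::tibble(age = as.integer(ages)))
  long <- tidyr::pivot_longer(df, c("warmth", "competence"),
                              names_to = "dimension", values_to = "score")
  summ <- long |>
    dplyr::group_by(.data$age, .data$dimension) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$score),
                     sd = stats::sd(.data$score),
                     q25 = unname(stats::quantile(.data$score, 0.25)),
                     median = stats::median(.data$score),
                     q75 = unname(stats::quantile(.data$score, 0.75)),
                     .groups = "drop") |>
    dplyr::arrange(.data$dimension, .data$age)
  welch <- lapply(c(warmth = "warmth", competence = "competence"),
                  function(dimn) {
                    grp <- split(df[[dimn]], df$age)
                    tryCatch(welch_anova(grp), error = function(e) {
                      list(error = conditionMessage(e))
                    })
                  })
  attr(summ, "welch") <- welch
  summ
}
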