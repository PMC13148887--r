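#' Principal-component reduction of sentence embeddings
#'
#' Fits PCA (mean-centred, unscaled) on the full sentence-level embedding
#' matrix of the corpus jointly, and returns the component scores. The number
#' of retained components is either a fixed integer or, when given as a
#' fraction in (0, 1), the smallest count whose cumulative explained-variance
#' fraction reaches that value (default 0.9).
#'
#' @param matrix Numeric matrix, rows = sentences.
#' @param n_components Positive integer, or a variance fraction in (0, 1).
#' @return Score matrix (rows preserved, with row names) with attributes
#'   `explained_variance` (fraction per retained component, of total
#'   variance), `cumulative_variance`, and `n_components`.
#' @export
reduce_pca <- function(matrix, n_components = 0.9) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2L)
  p <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  total <- sum(ev)
  if (total <= .Machine$double.eps * ncol(matrix)) {
    rlang::abort("cannot reduce: input has zero total variance (all rows identical)",
                 class = "scmaudit_degenerate_error")
  }
  frac <- ev / total
  if (n_components > 0 && n_components < 1) {
    k <- which(cumsum(frac) >= n_components)[1]
  } else {
    k <- as.integer(n_components)
    if (k < 1L || k > min(nrow(matrix), ncol(matrix))) {
      rlang::abort("n_components must be in 1..min(rows, dim)")
    }
  }
  scores <- p$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(matrix)
  attr(scores, "explained_variance") <- frac[seq_len(k)]
  attr(scores, "cumulative_variance") <- cumsum(frac)[k]
  attr(scores, "all_variance_fractions") <- frac
  attr(scores, "n_components") <- k
  scores
}

#' Per-sample mean vectors
#'
#' Averages the (reduced) sentence vectors of each text sample. Samples are
#' taken from `sample_ids`, one id per row of `reduced`; a sample with no
#' surviving sentences simply does not appear (it cannot be represented by a
#' zero row).
#'
#' @param reduced Numeric matrix of sentence vectors.
#' @param sample_ids Character vector assigning each row to a sample.
#' @return Matrix with one row per distinct sample (row names = sample ids,
#'   in first-appearance order).
#' @export
sample_mean_vectors <- function(reduced, sample_ids) {
  stopifnot(is.matrix(reduced), length(sample_ids) == nrow(reduced))
  ids <- factor(sample_ids, levels = unique(sample_ids))
  sums <- rowsum(reduced, ids)
  counts <- as.vector(table(ids))
  means <- sums / counts
  rownames(means) <- levels(ids)
  means
}

#' Age-by-age cosine similarity of group mean vectors
#'
#' The group vector of an age is the unweighted mean of that age's per-sample
#' mean vectors; entry (i, j) is the cosine of group vectors i and j. Because
#' the vectors live in a mean-centred principal-component space, negative
#' similarities are expected and meaningful (groups on opposite sides of the
#' corpus centroid).
#'
#' @param sample_means Matrix from [sample_mean_vectors()].
#' @param ages Integer vector assigning each row of `sample_means` to an age.
#' @return An object of class `age_similarity`: list with `ages` (sorted
#'   unique ages) and `values` (symmetric matrix, unit diagonal, entries in
#'   \[-1, 1\], dimnames = ages).
#' @export
age_similarity <- function(sample_means, ages) {
  stopifnot(is.matrix(sample_means), length(ages) == nrow(sample_means))
  uages <- sort(unique(as.integer(ages)))
  group <- rowsum(sample_means, factor(as.integer(ages), levels = uages))
  group <- group / as.vector(table(factor(as.integer(ages), levels = uages)))
  norms <- sqrt(rowSums(group^2))
  if (any(norms == 0)) {
    rlang::abort(paste0("zero-norm group vector for age(s): ",
                        paste(uages[norms == 0], collapse = ", ")),
                 class = "scmaudit_degenerate_error")
  }
  unit <- group / norms
  vals <- tcrossprod(unit)
  vals <- clip(vals, -1, 1)        # guard 1e-16 overshoot
  diag(vals) <- 1
  vals <- (vals + t(vals)) / 2     # enforce exact symmetry
  dimnames(vals) <- list(uages, uages)
  structure(list(ages = uages, values = vals), class = "age_similarity")
}

#' @export
print.age_similarity <- function(x, ...) {
  cat("<age_similarity> ", length(x$ages), " age groups\n", sep = "")
  print(round(x$values, 2))
  invisible(x)
}

#' @export
as.matrix.age_similarity <- function(x, ...) x$values

#' Export an age similarity matrix as CSV
#'
#' Age-labelled rows and columns, matching the heatmap layout of the report.
#'
#' @param similarity An `age_similarity` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(similarity, path) {
  df <- as.data.frame(similarity$values)
  df <- cbind(age = similarity$ages, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
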