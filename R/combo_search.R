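#' Enumerate all non-empty feature subsets
#'
#' For n effective features there are 2^n - 1 non-empty combinations;
#' they are returned in canonical bitmask-ascending order (mask m selects
#' feature i when bit i of m is set), deterministically.
#'
#' @param features Ordered character vector, 1 <= length <= 20.
#' @return List of character vectors, one per non-empty subset.
#' @export
enumerate_combinations <- function(features) {
  n <- length(features)
  if (n < 1L) stop("empty feature list")
  if (n > 20L) stop("refusing exhaustive enumeration for n > 20 features")
  lapply(seq_len(2^n - 1L), function(mask) {
    features[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
  })
}

# deterministic tie-break key independent of input ordering:
# smaller subsets first, then lexicographic on the joined feature names
subset_key <- function(subset) {
  sprintf("%02d|%s", length(subset), paste(subset, collapse = "+"))
}

#' Evaluate every feature combination with paired negative samples
#'
#' Runs [evaluate_feature_set()] for each subset using one shared round
#' plan (the same per-round balanced negative draw and fold assignment
#' for every subset), so the ranking of combinations is a paired
#' comparison not confounded by resampling noise. Reproducible from
#' `seed`.
#'
#' @inheritParams evaluate_feature_set
#' @param subsets List of feature-name vectors, e.g. from
#'   [enumerate_combinations()].
#' @return List of `combo_result` objects (`subset`, `metrics`, `score` =
#'   TPR - FPR, `rank` by descending score).
#' @export
evaluate_combinations <- function(matrix, partition, subsets,
                                  n_rounds = 1000L, cv_folds = 10L,
                                  classifier = svm_config(), seed = 1L) {
  if (length(subsets) == 0L) stop("no subsets to evaluate")
  rounds <- make_round_plan(partition$positive$members,
                            partition$negative$members, n_rounds, seed)
  res <- lapply(subsets, function(s) {
    m <- evaluate_feature_set(matrix, partition, s,
                              cv_folds = cv_folds, classifier = classifier,
                              rounds = rounds)
    structure(list(subset = s, metrics = m, score = m$tpr - m$fpr,
                   rank = NA_integer_),
              class = "combo_result")
  })
  ord <- order(-vapply(res, `[[`, numeric(1L), "score"),
               vapply(res, function(r) subset_key(r$subset), character(1L)))
  for (i in seq_along(ord)) res[[ord[i]]]$rank <- i
  res
}

#' @export
print.combo_result <- function(x, ...) {
  cat(sprintf("<combo_result #%s [%s]: score=%.3f precision=%.3f tpr=%.3f fpr=%.3f>\n",
              x$rank, paste(x$subset, collapse = "+"), x$score,
              x$metrics$precision, x$metrics$tpr, x$metrics$fpr))
  invisible(x)
}

#' Select the optimal combined feature set
#'
#' `"youden"` (default) maximizes TPR - FPR, breaking ties by higher
#' precision, then smaller subset, then canonical feature order.
#' `"precision_first"` maximizes precision, breaking ties by TPR - FPR,
#' then smaller subset. The winner is invariant to permutation of the
#' input list.
#'
#' @param results List of `combo_result` from [evaluate_combinations()].
#' @param rule `"youden"` or `"precision_first"`.
#' @return The winning `combo_result`.
#' @export
select_optima <- function(results, rule = c("youden", "precision_first")) {
  rule <- match.arg(rule)
  if (length(results) == 0L) stop("empty results")
  score <- vapply(results, `[[`, numeric(1L), "score")
  prec <- vapply(results, function(r) r$metrics$precision, numeric(1L))
  key <- vapply(results, function(r) subset_key(r$subset), character(1L))
  ord <- if (rule == "youden") order(-score, -prec, key)
         else order(-prec, -score, key)
  results[[ord[1L]]]
}

#' Write the combination report as TSV
#' @param results List of `combo_result`.
#' @param path File path.
#' @export
write_combo_report <- function(results, path) {
  df <- data.frame(
    subset = vapply(results, function(r) paste(r$subset, collapse = "+"),
                    character(1L)),
    precision = vapply(results, function(r) r$metrics$precision, numeric(1L)),
    tpr = vapply(results, function(r) r$metrics$tpr, numeric(1L)),
    fpr = vapply(results, function(r) r$metrics$fpr, numeric(1L)),
    score = vapply(results, `[[`, numeric(1L), "score"),
    rank = vapply(results, `[[`, integer(1L), "rank"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df[order(df$rank), ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
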