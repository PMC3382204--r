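#' Call candidate disease genes by intersecting randomized predictions
#'
#' Repeats, for `n_rounds` randomizations: draw a fresh balanced negative
#' sample (same size as the positive set), z-score the selected features
#' on that round's training data, train the configured SVM on positives
#' versus the sampled negatives, and classify every test gene. The
#' fraction of rounds in which each test gene is called positive is
#' accumulated; candidates are the test genes whose call fraction reaches
#' `agreement`. The default `agreement = 1` is the strict intersection of
#' all predictions (the method's original rule, performed for 10,000
#' randomizations); lower values relax it. Reproducible from `seed`.
#'
#' @inheritParams evaluate_feature_set
#' @param subset Feature names of the optimal combined feature set.
#' @param agreement Call-fraction threshold in `[0, 1]`.
#' @return A `candidate_result`: list with `candidates` ([gene_set()]),
#'   `call_fraction` (named numeric over all test genes), `n_rounds`,
#'   `subset_used`, `agreement`.
#' @export
predict_candidates <- function(matrix, partition, subset,
                               n_rounds = 10000L,
                               classifier = svm_config(),
                               agreement = 1.0, seed = 1L) {
  stopifnot(inherits(partition, "gene_partition"))
  if (n_rounds < 1L) stop("n_rounds must be >= 1")
  if (agreement < 0 || agreement > 1) stop("agreement must be in [0, 1]")
  test <- partition$test$members
  if (length(test) == 0L) stop("test set is empty; nothing to predict")
  feats <- attr(matrix, "features")
  if (!all(subset %in% feats))
    stop("subset contains features absent from the matrix")
  pos <- partition$positive$members
  neg <- partition$negative$members
  need <- c(pos, neg, test)
  if (!all(need %in% matrix$gene))
    stop("feature matrix does not cover all partition genes")

  rounds <- make_round_plan(pos, neg, n_rounds, seed)
  Xpos <- feature_submatrix(matrix, pos, subset)
  Xneg_all <- feature_submatrix(matrix, neg, subset)
  Xtest <- feature_submatrix(matrix, test, subset)

  calls <- stats::setNames(numeric(length(test)), test)
  for (r in seq_len(n_rounds)) {
    Xn <- Xneg_all[rounds[[r]]$neg, , drop = FALSE]
    xtr <- rbind(Xpos, Xn)
    ytr <- c(rep(1, nrow(Xpos)), rep(-1, nrow(Xn)))
    zs <- zscore_fit(xtr)
    model <- svm_fit(zscore_apply(xtr, zs), ytr, classifier)
    pr <- predict(model, zscore_apply(Xtest, zs))
    calls <- calls + (pr == 1)
  }
  frac <- calls / n_rounds
  structure(list(candidates = gene_set(test[frac >= agreement], "candidates"),
                 call_fraction = frac,
                 n_rounds = n_rounds,
                 subset_used = subset,
                 agreement = agreement),
            class = "candidate_result")
}

#' @export
print.candidate_result <- function(x, ...) {
  cat(sprintf("<candidate_result: %d candidate(s) of %d test genes at agreement %.2f over %d rounds [%s]>\n",
              length(x$candidates), length(x$call_fraction), x$agreement,
              x$n_rounds, paste(x$subset_used, collapse = "+")))
  invisible(x)
}

#' Re-threshold an existing prediction at a different agreement level
#'
#' Uses the stored call fractions, so no retraining happens; the
#' candidate set is non-increasing in `agreement`.
#'
#' @param result A `candidate_result`.
#' @param agreement New threshold in `[0, 1]`.
#' @return A `candidate_result` with the new threshold applied.
#' @export
rethreshold_candidates <- function(result, agreement) {
  stopifnot(inherits(result, "candidate_result"))
  if (agreement < 0 || agreement > 1) stop("agreement must be in [0, 1]")
  result$agreement <- agreement
  result$candidates <- gene_set(
    names(result$call_fraction)[result$call_fraction >= agreement],
    "candidates")
  result
}

#' Write the prediction report as TSV
#'
#' One row per test gene: gene, call_fraction, candidate(Y/N); the
#' feature subset, agreement, round count and seed-independent config
#' checksum go into `#` header lines.
#'
#' @param result A `candidate_result`.
#' @param path File path.
#' @export
write_prediction_report <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# subset=%s", paste(result$subset_used, collapse = "+")),
    sprintf("# n_rounds=%d", result$n_rounds),
    sprintf("# agreement=%g", result$agreement)
  ), con)
  df <- data.frame(gene = names(result$call_fraction),
                   call_fraction = unname(result$call_fraction),
                   candidate = ifelse(names(result$call_fraction) %in%
                                        result$candidates$members, "Y", "N"),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$call_fraction, df$gene), ]
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
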