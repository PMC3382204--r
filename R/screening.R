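#' Wilcoxon rank-sum disparity of one feature between gene sets
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction and continuity correction) of a feature's values in the
#' positive versus the negative gene set.
#'
#' @param pos_values,neg_values Non-empty numeric vectors.
#' @param alpha Significance threshold (default 0.05).
#' @param feature Optional feature name carried into the result.
#' @return A `disparity_result`: list with `feature`, `statistic`,
#'   `p_value`, `significant` (`p_value < alpha`) and `alpha`.
#' @export
wilcoxon_disparity <- function(pos_values, neg_values, alpha = 0.05,
                               feature = NA_character_) {
  if (length(pos_values) == 0L || length(neg_values) == 0L)
    stop("both value vectors must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(pos_values, neg_values, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)
  )
  structure(list(feature = feature,
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 significant = wt$p.value < alpha,
                 alpha = alpha),
            class = "disparity_result")
}

# One plan entry per round: the balanced negative draw and a fold seed.
# A single master seed drives the whole sequence, so plans are shared
# across feature subsets for paired comparisons.
make_round_plan <- function(positive, negative, n_rounds, seed) {
  n_pos <- length(positive)
  if (length(negative) < n_pos)
    stop("fewer negative genes (", length(negative),
         ") than positive genes (", n_pos, ")")
  set.seed(seed)
  lapply(seq_len(n_rounds), function(i) {
    list(neg = sample(negative, n_pos),
         fold_seed = sample.int(2147483646L, 1L))
  })
}

# stratified fold ids: each class split as evenly as possible across folds
stratified_folds <- function(n_pos, n_neg, k, fold_seed) {
  set.seed(fold_seed)
  list(pos = sample(rep_len(seq_len(k), n_pos)),
       neg = sample(rep_len(seq_len(k), n_neg)))
}

# One balanced round of k-fold CV; returns the round's confusion counts
# accumulated over held-out folds. Positives are +1, negatives -1.
cv_round <- function(Xpos, Xneg, cv_folds, fold_seed, classifier) {
  folds <- stratified_folds(nrow(Xpos), nrow(Xneg), cv_folds, fold_seed)
  tp <- fp <- tn <- fn <- 0L
  for (f in seq_len(cv_folds)) {
    trp <- Xpos[folds$pos != f, , drop = FALSE]
    trn <- Xneg[folds$neg != f, , drop = FALSE]
    tep <- Xpos[folds$pos == f, , drop = FALSE]
    ten <- Xneg[folds$neg == f, , drop = FALSE]
    if (nrow(tep) + nrow(ten) == 0L) next
    xtr <- rbind(trp, trn)
    ytr <- c(rep(1, nrow(trp)), rep(-1, nrow(trn)))
    zs <- zscore_fit(xtr)
    model <- svm_fit(zscore_apply(xtr, zs), ytr, classifier)
    if (nrow(tep) > 0L) {
      pr <- predict(model, zscore_apply(tep, zs))
      tp <- tp + sum(pr == 1)
      fn <- fn + sum(pr == -1)
    }
    if (nrow(ten) > 0L) {
      pr <- predict(model, zscore_apply(ten, zs))
      fp <- fp + sum(pr == 1)
      tn <- tn + sum(pr == -1)
    }
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

ratio0 <- function(num, den) if (den == 0) 0 else num / den

# feature submatrix keyed by gene name
feature_submatrix <- function(matrix, genes, subset) {
  m <- as.matrix(matrix[match(genes, matrix$gene), subset, drop = FALSE])
  rownames(m) <- genes
  storage.mode(m) <- "double"
  m
}

#' Evaluate a feature subset by repeated balanced SVM cross-validation
#'
#' Each round draws, without replacement, as many negative genes as there
#' are positives (balanced resampling against class imbalance), z-scores
#' the features on each training split, runs stratified k-fold
#' cross-validation of the configured SVM, and accumulates the confusion
#' counts over held-out folds. Precision, TPR and FPR are averaged over
#' rounds; their standard deviation across rounds is reported as the
#' dispersion. Fully reproducible from `seed`.
#'
#' @param matrix A [build_feature_matrix()] result covering all genes in
#'   the partition's positive and negative sets.
#' @param partition A [build_partition()] result.
#' @param subset Ordered feature names to use (subset of the matrix's
#'   features).
#' @param n_rounds Number of randomized rounds (method default 1000).
#' @param cv_folds Folds of the cross-validation (method default 10).
#' @param classifier An [svm_config()].
#' @param seed Master seed for the round plan.
#' @param rounds Optional precomputed plan from the same partition (used
#'   internally for paired comparisons across subsets).
#' @return An `eval_metrics`: list with `feature_subset`, `precision`,
#'   `tpr`, `fpr`, `n_rounds`, `dispersion` (named sd vector).
#' @export
evaluate_feature_set <- function(matrix, partition, subset,
                                 n_rounds = 1000L, cv_folds = 10L,
                                 classifier = svm_config(), seed = 1L,
                                 rounds = NULL) {
  stopifnot(inherits(partition, "gene_partition"))
  feats <- attr(matrix, "features")
  if (!all(subset %in% feats))
    stop("subset contains features absent from the matrix: ",
         paste(setdiff(subset, feats), collapse = ", "))
  pos <- partition$positive$members
  neg <- partition$negative$members
  if (!all(c(pos, neg) %in% matrix$gene))
    stop("feature matrix does not cover all positive/negative genes")
  if (length(pos) < cv_folds)
    stop("need at least cv_folds (", cv_folds, ") positive genes")
  if (is.null(rounds))
    rounds <- make_round_plan(pos, neg, n_rounds, seed)
  n_rounds <- length(rounds)

  Xpos <- feature_submatrix(matrix, pos, subset)
  Xneg_all <- feature_submatrix(matrix, neg, subset)
  const <- apply(rbind(Xpos, Xneg_all), 2L, stats::sd) == 0
  if (any(const))
    message("constant feature column(s) retained: ",
            paste(subset[const], collapse = ", "))

  per_round <- base::matrix(NA_real_, n_rounds, 3L,
                      dimnames = list(NULL, c("precision", "tpr", "fpr")))
  for (r in seq_len(n_rounds)) {
    cm <- cv_round(Xpos, Xneg_all[rounds[[r]]$neg, , drop = FALSE],
                   cv_folds, rounds[[r]]$fold_seed, classifier)
    per_round[r, ] <- c(ratio0(cm["tp"], cm["tp"] + cm["fp"]),
                        ratio0(cm["tp"], cm["tp"] + cm["fn"]),
                        ratio0(cm["fp"], cm["fp"] + cm["tn"]))
  }
  structure(list(feature_subset = subset,
                 precision = mean(per_round[, "precision"]),
                 tpr = mean(per_round[, "tpr"]),
                 fpr = mean(per_round[, "fpr"]),
                 n_rounds = n_rounds,
                 dispersion = apply(per_round, 2L, stats::sd)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics [%s]: precision=%.3f tpr=%.3f fpr=%.3f over %d rounds>\n",
              paste(x$feature_subset, collapse = "+"),
              x$precision, x$tpr, x$fpr, x$n_rounds))
  invisible(x)
}

#' Retain effective features
#'
#' A feature is retained when (i) its positive/negative disparity is
#' significant and (ii) it satisfies the effectiveness rule. The default
#' `"threshold"` rule requires precision >= `p_min`, TPR >= `t_min` and
#' FPR <= `f_max` (defaults 0.55 / 0.55 / 0.45). The alternative
#' `"drop_worst_k"` rule keeps all significant features except the `k`
#' with the lowest TPR - FPR. A per-feature decision trace is attached as
#' the `"trace"` attribute (a data frame).
#'
#' @param results Named list: feature -> [evaluate_feature_set()] result.
#' @param disparity Named list: feature -> [wilcoxon_disparity()] result.
#' @param rule_config List with `mode` (`"threshold"` or
#'   `"drop_worst_k"`), `p_min`, `t_min`, `f_max`, `k`.
#' @return Ordered character vector of retained feature names (input
#'   order preserved), with the decision trace attached.
#' @export
select_effective_features <- function(results, disparity,
                                      rule_config = list()) {
  rc <- utils::modifyList(list(mode = "threshold", p_min = 0.55,
                               t_min = 0.55, f_max = 0.45, k = 1L),
                          rule_config)
  feats <- names(results)
  if (is.null(feats) || !setequal(feats, names(disparity)))
    stop("results and disparity must be named by the same features")
  trace <- data.frame(
    feature = feats,
    p_value = vapply(disparity[feats], `[[`, numeric(1L), "p_value"),
    significant = vapply(disparity[feats], `[[`, logical(1L), "significant"),
    precision = vapply(results[feats], `[[`, numeric(1L), "precision"),
    tpr = vapply(results[feats], `[[`, numeric(1L), "tpr"),
    fpr = vapply(results[feats], `[[`, numeric(1L), "fpr"),
    stringsAsFactors = FALSE
  )
  if (rc$mode == "threshold") {
    trace$retained <- trace$significant &
      trace$precision >= rc$p_min & trace$tpr >= rc$t_min &
      trace$fpr <= rc$f_max
  } else if (rc$mode == "drop_worst_k") {
    youden <- trace$tpr - trace$fpr
    youden[!trace$significant] <- -Inf
    worst <- order(youden)[seq_len(min(rc$k, sum(trace$significant)))]
    trace$retained <- trace$significant
    trace$retained[worst] <- FALSE
  } else stop("unknown rule mode: ", rc$mode)
  retained <- trace$feature[trace$retained]
  if (length(retained) == 0L)
    stop("no feature passed the effectiveness rule; consider relaxing ",
         "p_min/t_min/f_max or alpha")
  structure(retained, trace = trace)
}
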