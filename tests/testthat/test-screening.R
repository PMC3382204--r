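test_that("wilcoxon_disparity reproduces rank-sum statistics and symmetry", {
  # identical multisets: no disparity
  d <- wilcoxon_disparity(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(d$p_value, 1, tolerance = 1e-12)
  expect_false(d$significant)

  # fully separated samples (normal approximation at n = 10 per group)
  d2 <- wilcoxon_disparity(1:10, 101:110)
  expect_lt(d2$p_value, 0.001)
  expect_true(d2$significant)

  # tie-corrected statistic by hand: pooled ranks of {1,1,2,2,3,3} are
  # 1.5,1.5,3.5,3.5,5.5,5.5 so W = 10.5 - 3*4/2 = 4.5
  d3 <- wilcoxon_disparity(c(1, 2, 3), c(1, 2, 3))
  expect_equal(d3$statistic, 4.5)
  expect_equal(d3$p_value, 1, tolerance = 1e-12)

  # two-sided p is invariant under swapping the two groups
  set.seed(4)
  a <- rnorm(15); b <- rnorm(15, 0.8)
  expect_equal(wilcoxon_disparity(a, b)$p_value,
               wilcoxon_disparity(b, a)$p_value, tolerance = 1e-12)

  expect_error(wilcoxon_disparity(numeric(), 1:3), "non-empty")
})

test_that("evaluate_feature_set nails separable data and is reproducible", {
  fx <- separable_fixture()
  m <- evaluate_feature_set(fx$matrix, fx$partition, "S",
                            n_rounds = 20L, cv_folds = 5L, seed = 7L)
  expect_gte(m$precision, 0.95)
  expect_gte(m$tpr, 0.95)
  expect_lte(m$fpr, 0.05)

  m2 <- evaluate_feature_set(fx$matrix, fx$partition, "S",
                             n_rounds = 1L, cv_folds = 5L, seed = 3L)
  m3 <- evaluate_feature_set(fx$matrix, fx$partition, "S",
                             n_rounds = 1L, cv_folds = 5L, seed = 3L)
  expect_identical(m2[c("precision", "tpr", "fpr")],
                   m3[c("precision", "tpr", "fpr")])
})

test_that("metrics are invariant to row order and affine feature rescaling", {
  fx <- separable_fixture(extra_features = "T")
  base <- evaluate_feature_set(fx$matrix, fx$partition, c("S", "T"),
                               n_rounds = 5L, cv_folds = 5L, seed = 11L)
  shuf <- fx$matrix[sample(nrow(fx$matrix)), ]
  m_shuf <- evaluate_feature_set(shuf, fx$partition, c("S", "T"),
                                 n_rounds = 5L, cv_folds = 5L, seed = 11L)
  expect_equal(m_shuf[c("precision", "tpr", "fpr")],
               base[c("precision", "tpr", "fpr")], tolerance = 1e-12)

  resc <- fx$matrix
  resc$S <- 1000 * resc$S - 77
  m_resc <- evaluate_feature_set(resc, fx$partition, c("S", "T"),
                                 n_rounds = 5L, cv_folds = 5L, seed = 11L)
  expect_equal(m_resc[c("precision", "tpr", "fpr")],
               base[c("precision", "tpr", "fpr")], tolerance = 1e-10)
})

test_that("no-signal features yield chance-level discrimination", {
  fx <- null_fixture()
  m <- evaluate_feature_set(fx$matrix, fx$partition, c("F1", "F2"),
                            n_rounds = 60L, cv_folds = 5L, seed = 13L)
  expect_lt(abs(m$tpr - m$fpr), 0.12)
})

test_that("evaluate_feature_set enforces its preconditions", {
  fx <- separable_fixture(n_pos = 10L, n_neg = 5L)
  expect_error(evaluate_feature_set(fx$matrix, fx$partition, "S",
                                    n_rounds = 1L, cv_folds = 5L),
               "fewer negative")
  fx2 <- separable_fixture(n_pos = 3L, n_neg = 10L)
  expect_error(evaluate_feature_set(fx2$matrix, fx2$partition, "S",
                                    n_rounds = 1L, cv_folds = 5L),
               "cv_folds")
  fx3 <- separable_fixture()
  expect_error(evaluate_feature_set(fx3$matrix, fx3$partition, "nope",
                                    n_rounds = 1L),
               "absent")
  # constant columns are retained with a message, not dropped
  fx3$matrix$K <- 1
  attr(fx3$matrix, "features") <- c("S", "K")
  expect_message(evaluate_feature_set(fx3$matrix, fx3$partition, c("S", "K"),
                                      n_rounds = 2L, cv_folds = 5L, seed = 1L),
                 "constant feature")
})

test_that("select_effective_features applies disparity and threshold rules", {
  mk_metrics <- function(f, prec, tpr, fpr)
    structure(list(feature_subset = f, precision = prec, tpr = tpr,
                   fpr = fpr, n_rounds = 10L,
                   dispersion = c(precision = 0, tpr = 0, fpr = 0)),
              class = "eval_metrics")
  mk_disp <- function(f, p)
    structure(list(feature = f, statistic = 0, p_value = p,
                   significant = p < 0.05, alpha = 0.05),
              class = "disparity_result")
  feats <- c("D", "N", "R", "B", "C")
  results <- list(D = mk_metrics("D", 0.7, 0.7, 0.3),
                  N = mk_metrics("N", 0.8, 0.6, 0.2),
                  R = mk_metrics("R", 0.75, 0.65, 0.25),
                  B = mk_metrics("B", 0.5, 0.5, 0.9),   # high FPR: out
                  C = mk_metrics("C", 0.6, 0.6, 0.4))
  disparity <- lapply(stats::setNames(nm = feats), mk_disp, p = 0.001)

  sel <- select_effective_features(results, disparity)
  expect_setequal(as.character(sel), c("D", "N", "R", "C"))
  expect_false("B" %in% sel)
  expect_s3_class(attr(sel, "trace"), "data.frame")

  # vacuous thresholds retain every significant feature
  sel2 <- select_effective_features(results, disparity,
                                    list(p_min = 0, t_min = 0, f_max = 1))
  expect_setequal(as.character(sel2), feats)

  # non-significant features are excluded regardless of metrics
  disparity$D <- mk_disp("D", 0.5)
  sel3 <- select_effective_features(results, disparity,
                                    list(p_min = 0, t_min = 0, f_max = 1))
  expect_false("D" %in% sel3)

  # drop-worst-k removes the weakest significant feature (B here)
  disparity$D <- mk_disp("D", 0.001)
  sel4 <- select_effective_features(results, disparity,
                                    list(mode = "drop_worst_k", k = 1L))
  expect_setequal(as.character(sel4), c("D", "N", "R", "C"))

  # all features identical and above thresholds: all retained
  same <- lapply(stats::setNames(nm = feats), mk_metrics,
                 prec = 0.7, tpr = 0.7, fpr = 0.3)
  same <- lapply(feats, function(f) { s <- same[[f]]; s$feature_subset <- f; s })
  names(same) <- feats
  sel5 <- select_effective_features(same, disparity)
  expect_setequal(as.character(sel5), feats)

  bad <- list(D = mk_metrics("D", 0.1, 0.1, 0.9))
  expect_error(select_effective_features(bad, disparity["D"]),
               "relaxing")
})

test_that("disease-relative features gain discrimination with module density", {
  dens <- c(0.06, 0.15, 0.35)
  margins <- sapply(seq_along(dens), function(i) {
    w <- small_planted_world(seed = 31L, n_background = 250L,
                             n_disease = 20L, n_hidden = 10L,
                             module_p = dens[i], cross_p = 0.01)
    sapply(c("N", "R", "M"), function(f) {
      m <- evaluate_feature_set(w$matrix, w$partition, f, n_rounds = 25L,
                                cv_folds = 5L, seed = 17L)
      m$tpr - m$fpr
    })
  })
  # positive margin everywhere, growing from sparsest to densest module
  expect_true(all(margins > 0))
  expect_true(all(margins[, 3] > margins[, 1]))
})
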