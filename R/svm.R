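#' Support-vector classifier configuration
#'
#' Settings for the soft-margin C-SVM used throughout the screening,
#' combination-search and prediction stages. The default mirrors the
#' pipeline-wide choice: an RBF kernel with `C = 1` and, when `gamma` is
#' `NULL`, the data-driven scale `1 / (n_features * mean feature variance)`
#' computed on each training split after z-scoring.
#'
#' @param kernel `"rbf"` or `"linear"`.
#' @param C Soft-margin cost, positive.
#' @param gamma RBF width, positive, or `NULL` for the data-driven scale.
#' @param tol KKT tolerance of the SMO solver.
#' @param max_steps Cap on successful SMO working-set updates.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(kernel = c("rbf", "linear"), C = 1, gamma = NULL,
                       tol = 1e-3, max_steps = 20000L) {
  kernel <- match.arg(kernel)
  stopifnot(is.numeric(C), length(C) == 1L, C > 0)
  if (!is.null(gamma)) stopifnot(is.numeric(gamma), gamma > 0)
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 tol = tol, max_steps = as.integer(max_steps)),
            class = "svm_config")
}

resolve_gamma <- function(x, config) {
  if (!is.null(config$gamma)) return(config$gamma)
  v <- mean(apply(x, 2L, stats::var))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(x) * v)
}

#' Fit a two-class support-vector machine
#'
#' Trains a soft-margin C-SVM by sequential minimal optimization. The
#' solver is deterministic (no random number use), so fits are exactly
#' reproducible.
#'
#' @param x Numeric feature matrix, one row per sample.
#' @param y Labels in `{-1, +1}` (numeric) or a logical vector
#'   (`TRUE` = positive class).
#' @param config An [svm_config()].
#' @return An object of class `svm_model`.
#' @export
svm_fit <- function(x, y, config = svm_config()) {
  x <- as.matrix(x)
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2L) stop("svm_fit needs both classes present")
  gamma <- resolve_gamma(x, config)
  kern <- if (config$kernel == "linear") 0L else 1L
  K <- .kernel_matrix(x, x, kern, gamma)
  fit <- .smo_train(K, y, config$C, config$tol, config$max_steps)
  keep <- fit$alpha > 1e-8
  structure(list(sv = x[keep, , drop = FALSE],
                 coef = fit$alpha[keep] * y[keep],
                 b = fit$b, gamma = gamma, kernel = kern,
                 config = config),
            class = "svm_model")
}

#' @rdname svm_fit
#' @param object A fitted `svm_model`.
#' @param newdata Matrix of samples to classify.
#' @param type `"class"` for labels in `{-1, +1}`, `"decision"` for raw
#'   decision values.
#' @param ... Unused.
#' @export
predict.svm_model <- function(object, newdata, type = c("class", "decision"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (nrow(object$sv) == 0L) {
    dec <- rep(object$b, nrow(newdata))
  } else {
    K <- .kernel_matrix(newdata, object$sv, object$kernel, object$gamma)
    dec <- drop(K %*% object$coef) + object$b
  }
  if (type == "decision") dec else ifelse(dec >= 0, 1, -1)
}

# z-score columns using training statistics; zero-variance columns are
# retained but mapped to all-zeros so they cannot dominate the kernel.
zscore_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- Inf
  list(mu = mu, sd = sd)
}

zscore_apply <- function(x, zs) {
  sweep(sweep(x, 2L, zs$mu, "-"), 2L, zs$sd, "/")
}
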