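#' Expression profiles
#'
#' Container for a genes-by-samples log-intensity matrix with case /
#' control group labels. Requires at least two samples per group;
#' duplicate gene rows are collapsed by their mean (with a reported
#' count).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids).
#' @param groups Character/factor of length `ncol(values)` with levels
#'   `case` and `control`.
#' @param name Optional profile label.
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(values, groups, name = "profile") {
  values <- as.matrix(values)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(values))
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (sum(groups == "case") < 2L || sum(groups == "control") < 2L)
    stop("need at least 2 samples per group")
  if (is.null(rownames(values))) stop("values must have gene rownames")
  if (anyDuplicated(rownames(values))) {
    n <- sum(duplicated(rownames(values)))
    message(n, " duplicate gene row(s) collapsed by mean")
    values <- do.call(rbind, lapply(split.data.frame(values, rownames(values)),
                                    colMeans))
  }
  structure(list(values = values, groups = groups, name = name),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile '%s': %d genes x %d samples (%d case / %d control)>\n",
              x$name, nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' Read / write an expression profile TSV
#'
#' Format: first header line `gene<TAB>sample ids...`, second line
#' `group<TAB>case/control labels...`, then one row per gene.
#'
#' @param path File path.
#' @param name Profile label.
#' @export
read_expression <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 3L) stop("expression file too short: ", path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  grp <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (!identical(grp[1L], "group"))
    stop("second header line must start with 'group'")
  body <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                            stringsAsFactors = FALSE)
  if (ncol(body) != length(hdr))
    stop("column count mismatch between header and body")
  vals <- as.matrix(body[, -1L, drop = FALSE])
  rownames(vals) <- body[[1L]]
  colnames(vals) <- hdr[-1L]
  expression_profile(vals, grp[-1L], name = name)
}

#' @rdname read_expression
#' @param profile An `expression_profile`.
#' @export
write_expression <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(colnames(profile$values)))
    colnames(profile$values) <- sprintf("S%02d", seq_len(ncol(profile$values)))
  writeLines(paste(c("gene", colnames(profile$values)), collapse = "\t"), con)
  writeLines(paste(c("group", profile$groups), collapse = "\t"), con)
  utils::write.table(cbind(gene = rownames(profile$values),
                           as.data.frame(profile$values)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Global median normalization
#'
#' Shifts every sample column so that its median equals the global median
#' of all values before the shift. Idempotent.
#'
#' @param profile An `expression_profile`.
#' @return The normalized profile.
#' @export
median_normalize <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  v <- profile$values
  if (length(v) == 0L) stop("empty expression matrix")
  gm <- stats::median(v)
  shift <- gm - apply(v, 2L, stats::median)
  profile$values <- sweep(v, 2L, shift, "+")
  profile
}

#' Differential-expression screen by per-gene t-test
#'
#' Two-sided two-sample t-test per gene between case and control columns
#' (Welch unequal-variance by default; pooled-variance selectable).
#' Returns genes with p below `alpha`; no multiple-testing correction is
#' applied. A gene with zero variance in both groups and equal means is
#' assigned p = 1 (not an error); zero variance with different means
#' yields p = 0.
#'
#' @param profile An `expression_profile` (>= 2 samples per group).
#' @param alpha P-value cutoff (default 0.05).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A [gene_set()] of the passing genes, with the full per-gene
#'   report (gene, t, p, passed) attached as attribute `"report"`.
#' @export
differential_expression <- function(profile, alpha = 0.05,
                                    var_equal = FALSE) {
  stopifnot(inherits(profile, "expression_profile"))
  ca <- profile$values[, profile$groups == "case", drop = FALSE]
  co <- profile$values[, profile$groups == "control", drop = FALSE]
  n1 <- ncol(ca); n2 <- ncol(co)
  m1 <- rowMeans(ca); m2 <- rowMeans(co)
  v1 <- apply(ca, 1L, stats::var); v2 <- apply(co, 1L, stats::var)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate rows: zero variance in both groups
  degen <- se == 0
  p[degen & m1 == m2] <- 1
  p[degen & m1 != m2] <- 0
  tt[degen & m1 == m2] <- 0
  passed <- p < alpha
  report <- data.frame(gene = rownames(profile$values), t = tt, p = p,
                       passed = ifelse(passed, "Y", "N"),
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(gene_set(rownames(profile$values)[passed],
                     paste0("DE_", profile$name)),
            report = report)
}

#' Intersect differential-expression calls across profiles
#'
#' @param de_sets Non-empty list of [gene_set()] (or character vectors).
#' @return A [gene_set()] of the genes present in every set; a warning is
#'   emitted when the intersection is empty.
#' @export
intersect_profiles <- function(de_sets) {
  if (length(de_sets) < 1L) stop("need at least one DE gene set")
  common <- Reduce(intersect, lapply(de_sets, as_members))
  if (length(common) == 0L)
    warning("intersection of differential-expression calls is empty")
  gene_set(common, "DE_common")
}
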