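#' Read an undirected interaction network from an edge list
#'
#' Parses a two-column tab-separated edge list (or a SIF file:
#' `node <TAB> relation <TAB> node ...`) into a simple undirected
#' [igraph][igraph::graph] over gene identifiers. Identifier case is
#' preserved verbatim; self-loops and duplicate edges are dropped and
#' their counts reported via `message()`. Lines starting with `#` and
#' blank lines are ignored.
#'
#' @param source File path or connection.
#' @param dialect `"tsv2col"` (two tab-separated identifiers per line) or
#'   `"sif"`.
#' @return An undirected simple `igraph` graph whose vertex names are the
#'   gene identifiers.
#' @export
load_network <- function(source, dialect = c("tsv2col", "sif")) {
  dialect <- match.arg(dialect)
  lines <- readLines(source, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty network input: no edge lines found")
  pairs <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (dialect == "tsv2col") {
      if (length(f) != 2L)
        stop(sprintf("malformed edge line %d: expected 2 tab-separated fields, got %d",
                     idx[k], length(f)))
      pairs[[k]] <- matrix(f, ncol = 2L)
    } else {
      if (length(f) < 3L)
        stop(sprintf("malformed SIF line %d: expected node, relation, node(s)",
                     idx[k]))
      pairs[[k]] <- cbind(f[1L], f[3:length(f)])
    }
  }
  el <- do.call(rbind, pairs)
  loops <- el[, 1L] == el[, 2L]
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  el <- el[!loops, , drop = FALSE]
  if (nrow(el) == 0L) stop("no edges remain after dropping self-loops")
  # canonical unordered orientation, then dedup
  key <- ifelse(el[, 1L] <= el[, 2L],
                paste(el[, 1L], el[, 2L], sep = "\r"),
                paste(el[, 2L], el[, 1L], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) message(sum(dup), " duplicate edge(s) dropped")
  el <- el[!dup, , drop = FALSE]
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Write a network as a two-column tab-separated edge list
#'
#' Inverse of [load_network()] for the `tsv2col` dialect; edges are
#' written once in canonical orientation.
#'
#' @param network An `igraph` graph with named vertices.
#' @param path Output file path.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  swap <- el[, 1L] > el[, 2L]
  el[swap, ] <- el[swap, c(2L, 1L)]
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Gene sets
#'
#' A `gene_set` is a named, de-duplicated collection of gene identifiers
#' (opaque strings; no symbol/ID mapping is attempted).
#'
#' @param members Character vector of identifiers.
#' @param name Label for the set.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(members, name = "genes") {
  members <- unique(as.character(members))
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes>\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

# accept gene_set or bare character vector
as_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else unique(as.character(x))
}

#' Read a gene set from a one-identifier-per-line file
#'
#' `#` comments and blank lines are allowed; duplicates are removed with
#' a reported count. An input that is empty after parsing is an error.
#'
#' @param source File path or connection.
#' @param name Label for the resulting set.
#' @return A [gene_set()].
#' @export
load_gene_set <- function(source, name = "genes") {
  lines <- readLines(source, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("gene set '", name, "' is empty after parsing")
  ndup <- sum(duplicated(lines))
  if (ndup > 0L) message(ndup, " duplicate identifier(s) removed from '", name, "'")
  gene_set(lines, name = name)
}

#' Write a gene set, one identifier per line
#' @param x A [gene_set()] or character vector.
#' @param path Output file path.
#' @export
write_gene_set <- function(x, path) {
  writeLines(as_members(x), path)
  invisible(path)
}

#' Partition network genes into positive, negative and test sets
#'
#' Implements the label construction used for the classifier ensemble:
#' positives are the known disease genes present in the network; the test
#' set is the intersection of the differentially-expressed genes with the
#' disease-locus genes (restricted to the network, minus positives);
#' negatives are all remaining network genes excluding positives and all
#' differentially-expressed genes. Differentially-expressed genes outside
#' every locus belong to none of the three sets (they are unlabeled).
#'
#' @param network An `igraph` network.
#' @param positive Known disease genes ([gene_set()] or character).
#' @param de_genes Differentially-expressed genes.
#' @param loci_genes Genes located in disease loci (already resolved to
#'   identifiers; coordinate arithmetic is out of scope).
#' @return A `gene_partition`: list with `gene_set` elements `positive`,
#'   `negative`, `test`.
#' @export
build_partition <- function(network, positive, de_genes = character(),
                            loci_genes = character()) {
  nodes <- igraph::V(network)$name
  pos_in <- intersect(as_members(positive), nodes)
  de <- as_members(de_genes)
  loci <- as_members(loci_genes)
  n_pos_dropped <- length(as_members(positive)) - length(pos_in)
  if (n_pos_dropped > 0L)
    message(n_pos_dropped, " positive gene(s) absent from the network dropped")
  if (length(pos_in) == 0L)
    stop("no positive genes present in the network")
  de_in <- intersect(de, nodes)
  if (length(de) > length(de_in))
    message(length(de) - length(de_in),
            " differentially-expressed gene(s) absent from the network dropped")
  test <- setdiff(intersect(de_in, loci), pos_in)
  negative <- setdiff(nodes, union(pos_in, de_in))
  if (length(test) == 0L)
    warning("test set is empty (no differentially-expressed locus genes)")
  structure(list(positive = gene_set(pos_in, "positive"),
                 negative = gene_set(negative, "negative"),
                 test = gene_set(test, "test")),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("<gene_partition: %d positive, %d negative, %d test>\n",
              length(x$positive), length(x$negative), length(x$test)))
  invisible(x)
}
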