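#' Per-gene topological measurements relative to a disease gene set
#'
#' Six measurements are computed for a gene \eqn{g} on an undirected,
#' unweighted interaction network:
#' \describe{
#'   \item{D}{degree: number of adjacent links.}
#'   \item{N}{number of neighboring disease genes among the neighbors.}
#'   \item{R}{ratio N/D of disease neighbors to all neighbors (0 when
#'     D = 0).}
#'   \item{B}{betweenness centrality: unnormalized Brandes betweenness
#'     over unordered pairs, with fractional credit
#'     \eqn{\sigma_{st}(v)/\sigma_{st}} when multiple shortest paths
#'     exist.}
#'   \item{C}{local clustering coefficient: realized edges among
#'     neighbors over \eqn{D(D-1)/2} (0 when D < 2).}
#'   \item{M}{mean shortest-path length (hop count) from the gene to the
#'     reachable disease genes; `NA` when none is reachable.}
#' }
#'
#' @name topo_features
NULL

check_gene <- function(network, gene) {
  if (!gene %in% igraph::V(network)$name)
    stop("unknown gene: ", gene)
}

#' @describeIn topo_features Degree of one gene.
#' @param network An `igraph` network with named vertices.
#' @param gene A gene identifier present in the network.
#' @export
degree_of <- function(network, gene) {
  check_gene(network, gene)
  as.integer(igraph::degree(network, v = gene))
}

disease_prime <- function(gene, disease, exclude_self) {
  d <- as_members(disease)
  if (exclude_self) setdiff(d, gene) else d
}

#' @describeIn topo_features Count of disease genes among the neighbors.
#' @param disease Disease gene set ([gene_set()] or character).
#' @param exclude_self Drop the gene itself from the disease set first
#'   (leave-one-out for genes that are themselves disease genes).
#' @export
disease_neighbor_count <- function(network, gene, disease,
                                   exclude_self = TRUE) {
  check_gene(network, gene)
  nb <- names(igraph::neighbors(network, gene))
  length(intersect(nb, disease_prime(gene, disease, exclude_self)))
}

#' @describeIn topo_features Fraction of neighbors that are disease genes.
#' @export
disease_neighbor_ratio <- function(network, gene, disease,
                                   exclude_self = TRUE) {
  check_gene(network, gene)
  d <- degree_of(network, gene)
  if (d == 0L) return(0)
  disease_neighbor_count(network, gene, disease, exclude_self) / d
}

#' @describeIn topo_features Unnormalized fractional betweenness for every
#'   node (named numeric vector). Pairs in different components contribute
#'   zero.
#' @export
betweenness_all <- function(network) {
  if (igraph::vcount(network) == 0L) stop("empty network")
  igraph::betweenness(network, directed = FALSE, normalized = FALSE)
}

#' @describeIn topo_features Local clustering coefficient of one gene.
#' @export
clustering_coefficient <- function(network, gene) {
  check_gene(network, gene)
  cc <- unname(igraph::transitivity(network, type = "local", vids = gene))
  if (is.nan(cc) || is.na(cc)) 0 else cc
}

#' @describeIn topo_features Mean hop distance from `gene` to the
#'   reachable disease genes; `NA` if none reachable. Errors when the
#'   disease set (after self-exclusion) is empty.
#' @export
mean_shortest_path_to_disease <- function(network, gene, disease,
                                          exclude_self = TRUE) {
  check_gene(network, gene)
  dset <- disease_prime(gene, disease, exclude_self)
  dset <- intersect(dset, igraph::V(network)$name)
  if (length(dset) == 0L) stop("disease set empty after self-exclusion")
  d <- igraph::distances(network, v = gene, to = dset)
  d <- d[is.finite(d)]
  if (length(d) == 0L) return(NA_real_)
  mean(d)
}

#' Build the per-gene feature matrix
#'
#' Computes the requested topological features for a list of genes
#' relative to a disease gene set and returns them as a data frame with
#' one row per gene. With `leave_one_out = TRUE` (default) the
#' disease-relative features N, R and M of a gene that is itself in the
#' disease set are computed against the disease set minus that gene, so
#' training labels do not leak into the features. Genes that cannot reach
#' any disease gene get `M` imputed as (max finite M) + 1; the imputation
#' count is reported and recorded in the `n_imputed` attribute.
#'
#' @param network An `igraph` network with named vertices.
#' @param genes Character vector of genes (subset of the network nodes).
#' @param disease Disease gene set.
#' @param features Ordered subset of `c("D","N","R","B","C","M")`.
#' @param leave_one_out See description.
#' @return A `feature_matrix`: data frame with a `gene` column followed by
#'   one column per feature, plus attributes `features`, `leave_one_out`,
#'   `disease_checksum`, `n_imputed`.
#' @export
build_feature_matrix <- function(network, genes, disease,
                                 features = c("D", "N", "R", "B", "C", "M"),
                                 leave_one_out = TRUE) {
  features <- match.arg(features, c("D", "N", "R", "B", "C", "M"),
                        several.ok = TRUE)
  genes <- as.character(genes)
  nodes <- igraph::V(network)$name
  if (!all(genes %in% nodes))
    stop("genes not in network: ",
         paste(utils::head(setdiff(genes, nodes), 5L), collapse = ", "))
  if (anyDuplicated(genes)) stop("duplicate genes in feature matrix request")
  dset <- intersect(as_members(disease), nodes)
  if (length(dset) == 0L) stop("disease set is empty (after restriction to network)")

  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  deg <- igraph::degree(network)[genes]
  if ("D" %in% features) out$D <- as.numeric(deg)

  need_nr <- any(c("N", "R") %in% features)
  if (need_nr) {
    nb <- igraph::adjacent_vertices(network, genes)
    nn <- vapply(seq_along(genes), function(i) {
      d <- dset
      if (leave_one_out) d <- setdiff(d, genes[i])
      length(intersect(names(nb[[i]]), d))
    }, integer(1L))
    if ("N" %in% features) out$N <- as.numeric(nn)
    if ("R" %in% features) out$R <- ifelse(deg > 0, nn / deg, 0)
  }

  if ("B" %in% features) out$B <- as.numeric(betweenness_all(network)[genes])

  if ("C" %in% features) {
    cc <- igraph::transitivity(network, type = "local", vids = genes)
    cc[is.na(cc) | is.nan(cc)] <- 0
    out$C <- cc
  }

  n_imputed <- 0L
  if ("M" %in% features) {
    dm <- igraph::distances(network, v = genes, to = dset)
    m <- vapply(seq_along(genes), function(i) {
      row <- dm[i, ]
      if (leave_one_out && genes[i] %in% dset)
        row <- row[colnames(dm) != genes[i]]
      row <- row[is.finite(row)]
      if (length(row) == 0L) NA_real_ else mean(row)
    }, numeric(1L))
    miss <- is.na(m)
    n_imputed <- sum(miss)
    if (n_imputed > 0L) {
      if (all(miss)) stop("no gene can reach any disease gene; M undefined")
      m[miss] <- max(m, na.rm = TRUE) + 1
      message(n_imputed, " unreachable gene(s): M imputed as max finite M + 1")
    }
    out$M <- m
  }

  structure(out,
            features = features,
            leave_one_out = leave_one_out,
            disease_checksum = str_checksum(paste(sort(dset), collapse = ",")),
            n_imputed = n_imputed,
            class = c("feature_matrix", "data.frame"))
}

#' Serialize / read a feature matrix as TSV
#'
#' Missing values are written as `NA`; the leave-one-out flag and a
#' checksum of the disease set used go into `#` header lines.
#'
#' @param x A `feature_matrix`.
#' @param path File path.
#' @export
write_feature_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# leave_one_out=%s", attr(x, "leave_one_out")),
    sprintf("# disease_checksum=%s", attr(x, "disease_checksum")),
    sprintf("# n_imputed=%d", attr(x, "n_imputed"))
  ), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, "="), "", grep(paste0("^# ", key, "="), hdr, value = TRUE))
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  structure(df,
            features = setdiff(names(df), "gene"),
            leave_one_out = identical(get("leave_one_out"), "TRUE"),
            disease_checksum = get("disease_checksum"),
            n_imputed = as.integer(get("n_imputed")),
            class = c("feature_matrix", "data.frame"))
}

# tiny polynomial string hash (hex, mod 2^31-1); used for config and
# gene-set checksums so reports are self-describing without a digest
# dependency. Not cryptographic.
str_checksum <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
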