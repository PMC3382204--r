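#' Generate a scale-free network with a planted disease module
#'
#' Builds a preferential-attachment (scale-free) background of
#' `n_background` genes and plants a disease module of
#' `n_disease + n_hidden` genes on top of it: module genes are wired to
#' each other with probability `module_p` and to uniformly chosen
#' background genes with probability `cross_p` (per module-background
#' pair). This emulates the empirical regularities of disease genes on
#' interaction networks — they are hub-like, mutually adjacent, and their
#' neighborhoods are densely interconnected. `n_disease` module genes are
#' designated the seed (known) disease genes handed to the pipeline as
#' positives; the remaining `n_hidden` are withheld as the planted truth
#' the pipeline is expected to recover. Bit-reproducible from `seed`.
#'
#' @param n_background Background genes (>= 1).
#' @param n_disease Seed disease genes (>= 1).
#' @param n_hidden Withheld planted disease genes (>= 0).
#' @param attach_m Edges added per node in the preferential-attachment
#'   background.
#' @param module_p Within-module edge probability; must exceed `cross_p`.
#' @param cross_p Module-to-background edge probability.
#' @param seed RNG seed.
#' @return List with `network` (igraph) and `truth` (`planted_truth`:
#'   gene_sets `seed_disease`, `hidden_disease`, `background`, plus
#'   `params`).
#' @export
generate_network <- function(n_background = 2000L, n_disease = 60L,
                             n_hidden = 40L, attach_m = 3L,
                             module_p = 0.15, cross_p = 0.005,
                             seed = 1L) {
  if (n_background < 1L || n_disease < 1L || attach_m < 1L)
    stop("n_background, n_disease and attach_m must be >= 1")
  if (n_hidden < 0L) stop("n_hidden must be >= 0")
  if (!(module_p > 0 && module_p <= 1) || !(cross_p > 0 && cross_p <= 1))
    stop("module_p and cross_p must be in (0, 1]")
  if (module_p <= cross_p) stop("module_p must exceed cross_p")
  n_mod <- n_disease + n_hidden
  ids <- sprintf("g%05d", seq_len(n_background + n_mod))
  bg_ids <- ids[seq_len(n_background)]
  mod_ids <- ids[n_background + seq_len(n_mod)]

  set.seed(seed)
  bg <- igraph::sample_pa(n_background, m = attach_m, directed = FALSE)
  el <- igraph::as_edgelist(bg, names = FALSE)
  edges <- cbind(bg_ids[el[, 1L]], bg_ids[el[, 2L]])

  if (n_mod > 1L) {
    pr <- utils::combn(n_mod, 2L)
    hit <- stats::runif(ncol(pr)) < module_p
    if (any(hit))
      edges <- rbind(edges, cbind(mod_ids[pr[1L, hit]], mod_ids[pr[2L, hit]]))
  }
  cross <- base::matrix(stats::runif(n_mod * n_background) < cross_p,
                        nrow = n_mod)
  ci <- which(cross, arr.ind = TRUE)
  if (nrow(ci) > 0L)
    edges <- rbind(edges, cbind(mod_ids[ci[, 1L]], bg_ids[ci[, 2L]]))

  g <- igraph::simplify(
    igraph::graph_from_edgelist(edges, directed = FALSE))
  missing <- setdiff(ids, igraph::V(g)$name)
  if (length(missing) > 0L) g <- igraph::add_vertices(g, length(missing),
                                                      name = missing)
  seed_genes <- sample(mod_ids, n_disease)
  hidden <- setdiff(mod_ids, seed_genes)
  comp <- igraph::components(g)
  message(sprintf("synthetic network: %d nodes, %d edges; giant component %.1f%%",
                  igraph::vcount(g), igraph::ecount(g),
                  100 * max(comp$csize) / igraph::vcount(g)))
  truth <- structure(list(seed_disease = gene_set(seed_genes, "seed_disease"),
                          hidden_disease = gene_set(hidden, "hidden_disease"),
                          background = gene_set(bg_ids, "background"),
                          params = list(n_background = n_background,
                                        n_disease = n_disease,
                                        n_hidden = n_hidden,
                                        attach_m = attach_m,
                                        module_p = module_p,
                                        cross_p = cross_p, seed = seed)),
                     class = "planted_truth")
  list(network = g, truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth: %d seed, %d hidden, %d background genes>\n",
              length(x$seed_disease), length(x$hidden_disease),
              length(x$background)))
  invisible(x)
}

#' Generate expression profiles with planted differential expression
#'
#' Every profile is an independent genes-by-samples Gaussian
#' log-intensity matrix (per-gene baseline drawn once around 8, noise sd
#' `sigma`); the `de_genes` are shifted upward by `effect` in the case
#' samples of every profile. Emulates a small set of case/control
#' microarray studies of the same disease.
#'
#' @param genes Character vector of gene identifiers.
#' @param de_genes Genes to plant as differentially expressed (subset of
#'   `genes`).
#' @param n_case,n_control Samples per group (>= 2 each).
#' @param effect Case-group shift for planted genes (>= 0, in sd units
#'   when `sigma = 1`).
#' @param sigma Noise standard deviation (> 0).
#' @param n_profiles Number of independent profiles.
#' @param seed RNG seed.
#' @return List of [expression_profile()] objects.
#' @export
generate_expression <- function(genes, de_genes, n_case = 8L,
                                n_control = 8L, effect = 2, sigma = 1,
                                n_profiles = 3L, seed = 1L) {
  genes <- as.character(genes)
  de <- as_members(de_genes)
  if (!all(de %in% genes)) stop("de_genes must be a subset of genes")
  if (effect < 0) stop("effect must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (n_case < 2L || n_control < 2L) stop("need >= 2 samples per group")
  if (n_profiles < 1L) stop("n_profiles must be >= 1")
  set.seed(seed)
  baseline <- stats::rnorm(length(genes), mean = 8, sd = 1)
  groups <- c(rep("case", n_case), rep("control", n_control))
  lapply(seq_len(n_profiles), function(p) {
    v <- baseline +
      base::matrix(stats::rnorm(length(genes) * (n_case + n_control),
                                sd = sigma),
                   nrow = length(genes))
    v[genes %in% de, seq_len(n_case)] <-
      v[genes %in% de, seq_len(n_case)] + effect
    rownames(v) <- genes
    colnames(v) <- sprintf("P%d_S%02d", p, seq_along(groups))
    expression_profile(v, groups, name = sprintf("synthetic_profile_%d", p))
  })
}

#' Generate the full synthetic benchmark world
#'
#' One call that stands in for the method's real inputs: the planted
#' network ([generate_network()]), a disease-locus gene list, and
#' case/control expression profiles ([generate_expression()]). The locus
#' list contains every hidden disease gene plus `n_loci_background`
#' random background genes; the planted differentially-expressed set is
#' the hidden disease genes plus `n_decoy_de` decoy background genes
#' drawn from the locus list (differentially expressed but not disease),
#' so the downstream test set contains both true candidates and
#' topologically unremarkable background genes.
#'
#' @param seed Master seed; sub-seeds for network and expression are
#'   derived from it.
#' @param network_params Overrides for [generate_network()] arguments.
#' @param n_loci_background Background genes included in the locus list.
#' @param n_decoy_de Locus background genes also planted as DE decoys.
#' @param expression_params Overrides for [generate_expression()]
#'   arguments (other than `genes`, `de_genes`, `seed`).
#' @return List: `network`, `truth`, `loci` (gene_set), `decoy_de`
#'   (gene_set), `profiles` (list of expression profiles).
#' @export
synthetic_fixture <- function(seed = 1L, network_params = list(),
                              n_loci_background = 300L, n_decoy_de = 150L,
                              expression_params = list()) {
  if (n_decoy_de > n_loci_background)
    stop("n_decoy_de cannot exceed n_loci_background")
  set.seed(seed)
  sub <- sample.int(2147483646L, 3L)
  net <- do.call(generate_network,
                 utils::modifyList(list(seed = sub[1L]), network_params))
  set.seed(sub[3L])
  loci_bg <- sample(net$truth$background$members, n_loci_background)
  decoy <- sample(loci_bg, n_decoy_de)
  loci <- gene_set(c(net$truth$hidden_disease$members, loci_bg), "loci")
  de_planted <- c(net$truth$hidden_disease$members, decoy)
  profiles <- do.call(generate_expression,
                      utils::modifyList(
                        list(genes = igraph::V(net$network)$name,
                             de_genes = de_planted, seed = sub[2L]),
                        expression_params))
  list(network = net$network, truth = net$truth, loci = loci,
       decoy_de = gene_set(decoy, "decoy_de"), profiles = profiles)
}

#' Write the planted truth as JSON
#' @param truth A `planted_truth`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(seed_disease = truth$seed_disease$members,
                            hidden_disease = truth$hidden_disease$members,
                            background = truth$background$members,
                            params = truth$params),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
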