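# Hand-built classifier fixtures: a feature matrix + partition pair
# where the class structure is known by construction.

# Perfectly separable one-feature world: positives at 10 +- 0.1,
# negatives at 0 +- 0.1 (extra features, if any, are pure noise).
separable_fixture <- function(n_pos = 20L, n_neg = 60L, seed = 99L,
                              extra_features = character()) {
  set.seed(seed)
  pos <- sprintf("pos%02d", seq_len(n_pos))
  neg <- sprintf("neg%02d", seq_len(n_neg))
  df <- data.frame(gene = c(pos, neg),
                   S = c(stats::rnorm(n_pos, 10, 0.1),
                         stats::rnorm(n_neg, 0, 0.1)),
                   stringsAsFactors = FALSE)
  for (f in extra_features) df[[f]] <- stats::rnorm(n_pos + n_neg)
  mat <- structure(df, features = setdiff(names(df), "gene"),
                   leave_one_out = FALSE, disease_checksum = "test",
                   n_imputed = 0L,
                   class = c("feature_matrix", "data.frame"))
  part <- structure(list(positive = gene_set(pos, "positive"),
                         negative = gene_set(neg, "negative"),
                         test = gene_set(character(), "test")),
                    class = "gene_partition")
  list(matrix = mat, partition = part)
}

# No-signal world: every feature is iid noise for both classes
null_fixture <- function(n_pos = 20L, n_neg = 60L,
                         features = c("F1", "F2"), seed = 100L) {
  set.seed(seed)
  pos <- sprintf("pos%02d", seq_len(n_pos))
  neg <- sprintf("neg%02d", seq_len(n_neg))
  df <- data.frame(gene = c(pos, neg), stringsAsFactors = FALSE)
  for (f in features) df[[f]] <- stats::rnorm(n_pos + n_neg)
  mat <- structure(df, features = features, leave_one_out = FALSE,
                   disease_checksum = "test", n_imputed = 0L,
                   class = c("feature_matrix", "data.frame"))
  part <- structure(list(positive = gene_set(pos, "positive"),
                         negative = gene_set(neg, "negative"),
                         test = gene_set(character(), "test")),
                    class = "gene_partition")
  list(matrix = mat, partition = part)
}

# Relabel a partition with a random label permutation over pos+neg,
# destroying any feature/label association while keeping set sizes.
permute_labels <- function(partition, seed) {
  set.seed(seed)
  all_genes <- c(partition$positive$members, partition$negative$members)
  n_pos <- length(partition$positive$members)
  pos <- sample(all_genes, n_pos)
  structure(list(positive = gene_set(pos, "positive"),
                 negative = gene_set(setdiff(all_genes, pos), "negative"),
                 test = partition$test),
            class = "gene_partition")
}

# Small planted world shared by slower classifier tests: modest sizes so
# the suite stays fast. Returns network, truth, matrix, partition.
small_planted_world <- function(seed = 11L, n_background = 400L,
                                n_disease = 30L, n_hidden = 20L,
                                module_p = 0.2, cross_p = 0.01,
                                n_test_background = 60L) {
  net <- suppressMessages(generate_network(
    n_background = n_background, n_disease = n_disease,
    n_hidden = n_hidden, attach_m = 3L, module_p = module_p,
    cross_p = cross_p, seed = seed))
  set.seed(seed + 1L)
  test_bg <- sample(net$truth$background$members, n_test_background)
  test <- c(net$truth$hidden_disease$members, test_bg)
  pos <- net$truth$seed_disease$members
  neg <- setdiff(igraph::V(net$network)$name, c(pos, test))
  part <- structure(list(positive = gene_set(pos, "positive"),
                         negative = gene_set(neg, "negative"),
                         test = gene_set(test, "test")),
                    class = "gene_partition")
  mat <- suppressMessages(build_feature_matrix(
    net$network, igraph::V(net$network)$name, pos))
  list(network = net$network, truth = net$truth,
       matrix = mat, partition = part)
}
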