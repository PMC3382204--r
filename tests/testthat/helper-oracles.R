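# Independent brute-force oracles for the graph metrics. Deliberately
# avoids igraph for all metric computation: graphs are handled as plain
# adjacency lists and all quantities come from hand-rolled BFS /
# enumeration, so these can certify the package implementations.

# adjacency list (named list of character vectors) from an edge matrix
oracle_adj <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character()
  if (nrow(edges) > 0L) for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

# BFS from s: hop distances and shortest-path counts to every node
oracle_bfs <- function(adj, s) {
  nodes <- names(adj)
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  sigma <- stats::setNames(rep(0, length(nodes)), nodes)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- character()
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# unnormalized fractional betweenness over unordered pairs via the
# pair-combination identity: B(v) = sum over s<t, s!=v!=t with
# d(s,v)+d(v,t)=d(s,t) of sigma_sv * sigma_vt / sigma_st
oracle_betweenness <- function(adj) {
  nodes <- names(adj)
  bfs <- lapply(stats::setNames(nm = nodes), function(s) oracle_bfs(adj, s))
  B <- stats::setNames(rep(0, length(nodes)), nodes)
  n <- length(nodes)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- nodes[i]; t <- nodes[j]
    dst <- bfs[[s]]$dist[t]
    if (is.infinite(dst)) next
    for (v in nodes) {
      if (v == s || v == t) next
      if (bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == dst)
        B[v] <- B[v] + bfs[[s]]$sigma[v] * bfs[[t]]$sigma[v] / bfs[[s]]$sigma[t]
    }
  }
  B
}

oracle_clustering <- function(adj, v) {
  nb <- adj[[v]]
  d <- length(nb)
  if (d < 2L) return(0)
  links <- 0L
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d)
    if (nb[j] %in% adj[[nb[i]]]) links <- links + 1L
  2 * links / (d * (d - 1))
}

oracle_mean_sp <- function(adj, v, disease) {
  dd <- oracle_bfs(adj, v)$dist[setdiff(disease, v)]
  dd <- dd[is.finite(dd)]
  if (length(dd) == 0L) NA_real_ else mean(unname(dd))
}

# Erdos-Renyi-ish random simple graph as (nodes, edge matrix, igraph)
random_test_graph <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2L))
  hit <- stats::runif(nrow(pairs)) < p
  edges <- cbind(nodes[pairs[hit, 1L]], nodes[pairs[hit, 2L]])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                            name = setdiff(nodes, igraph::V(g)$name))
  list(nodes = nodes, edges = edges, graph = g,
       adj = oracle_adj(nodes, edges))
}

# small named graph from an edge specification like c("A-B", "B-C")
graph_from_spec <- function(edge_spec, extra_nodes = character()) {
  edges <- do.call(rbind, strsplit(edge_spec, "-", fixed = TRUE))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (length(extra_nodes) > 0L)
    g <- igraph::add_vertices(g, length(extra_nodes), name = extra_nodes)
  g
}
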