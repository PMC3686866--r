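# Graph builders and independent oracles used across the suite.

edge_mat <- function(...) do.call(rbind, list(...))

path_net <- function(labels) {
  network_from_edges(cbind(labels[-length(labels)], labels[-1]))
}

cycle_net <- function(labels) {
  network_from_edges(rbind(cbind(labels[-length(labels)], labels[-1]),
                           c(labels[length(labels)], labels[1])))
}

complete_net <- function(labels) {
  network_from_edges(t(utils::combn(labels, 2)))
}

triangle_net <- function(labels = c("a", "b", "c")) complete_net(labels)

two_triangles <- function() {
  network_from_edges(rbind(c("a","b"), c("b","c"), c("a","c"),
                           c("d","e"), c("e","f"), c("d","f")))
}

# triangles a,b,c and c,d,e sharing node c
bowtie_net <- function() {
  network_from_edges(rbind(c("a","b"), c("b","c"), c("a","c"),
                           c("c","d"), c("d","e"), c("c","e")))
}

# the worked link-similarity example graph: hub a with two branches b and c
fig_example_net <- function() {
  network_from_edges(rbind(c("a","b"), c("a","c"), c("b","d"), c("b","e"),
                           c("b","f"), c("c","e"), c("c","f"), c("c","g")))
}

# Erdos-Renyi graph with at least one edge, labels x01, x02, ...
random_net <- function(n, p = 0.35) {
  labels <- sprintf("x%02d", seq_len(n))
  repeat {
    pairs <- t(utils::combn(labels, 2))
    keep <- stats::runif(nrow(pairs)) < p
    if (any(keep)) return(network_from_edges(pairs[keep, , drop = FALSE],
                                             nodes = labels))
  }
}

as_igraph_test <- function(net) {
  igraph::graph_from_data_frame(links(net)[, c("from", "to")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

# --- independent oracles -------------------------------------------------

# EQ by explicit triple loop over ordered node pairs (incl. i = j).
eq_bruteforce <- function(net, communities) {
  n <- n_nodes(net)
  M <- n_links(net)
  A <- matrix(0, n, n)
  A[cbind(net$ei, net$ej)] <- 1
  A <- A + t(A)
  k <- rowSums(A)
  comms <- lapply(communities, function(h) match(h, net$nodes))
  O <- integer(n)
  for (h in comms) O[h] <- O[h] + 1L
  tot <- 0
  for (h in comms)
    for (i in h) for (j in h)
      tot <- tot + (A[i, j] - k[i] * k[j] / (2 * M)) / (O[i] * O[j])
  tot / (2 * M)
}

# flat single-linkage clusters at a similarity threshold: connected
# components of the graph on links with an edge wherever S >= thr
threshold_components <- function(S, thr) {
  M <- nrow(S)
  A <- (S >= thr)
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "max")
  memb <- igraph::components(g)$membership
  canonical_clusters(split(seq_len(M), memb))
}

canonical_clusters <- function(cl) {
  cl <- lapply(cl, function(x) sort.int(as.integer(x)))
  names(cl) <- NULL
  cl[order(vapply(cl, `[[`, integer(1L), 1L))]
}

# flat clusters of a dendrogram at threshold thr: apply all merges with
# similarity >= thr (merge similarities are non-increasing)
dendrogram_cut <- function(dend, thr) {
  canonical_clusters(elclust:::clusters_at(dend, sum(dend$similarity >= thr)))
}

# random symmetric sparse similarity matrix on M links
random_similarity <- function(M, density = 0.3) {
  S <- matrix(0, M, M)
  up <- which(upper.tri(S))
  sel <- up[stats::runif(length(up)) < density]
  S[sel] <- round(stats::runif(length(sel)), 3)
  S <- S + t(S)
  diag(S) <- 1
  as_similarity_matrix(S)
}
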