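# Quality functions on link partitions and overlapping node covers:
# partition density (PD), extended modularity (EQ), in-group proportion
# (IGP) and coverage statistics.

#' Overlapping node communities from a cover
#'
#' Wraps a list of node sets as an `elc_communities` object. Identical
#' communities are merged (two link clusters or two input lines describing
#' the same node set are one community), and each node's membership count
#' O_i — the number of communities containing it — is recomputed from the
#' deduplicated list. Use this for externally produced covers; covers
#' induced from link partitions are built by [induce_node_communities()].
#'
#' @param communities list of character vectors of node labels.
#' @param net optional `elc_network`; when given, members are validated
#'   against its node set and memberships are tallied over all its nodes.
#' @return An `elc_communities`: list with `communities` (each sorted,
#'   deduplicated) and `memberships` (named integer vector of O_i, 0 for
#'   uncovered nodes).
#' @export
node_communities <- function(communities, net = NULL) {
  if (!is.list(communities)) stop("`communities` must be a list of label vectors")
  comms <- lapply(communities, function(h) {
    h <- unique(as.character(h))
    if (!length(h)) stop("empty community")
    h[order(h, method = "radix")]
  })
  keys <- vapply(comms, paste, character(1L), collapse = "\r")
  comms <- comms[!duplicated(keys)]
  all_nodes <- if (is.null(net)) {
    u <- unique(unlist(comms))
    u[order(u, method = "radix")]
  } else net$nodes
  miss <- setdiff(unlist(comms), all_nodes)
  if (length(miss))
    stop("community members not in network: ", paste(miss, collapse = ", "))
  O <- table(factor(unlist(comms), levels = all_nodes))
  structure(list(communities = comms,
                 memberships = stats::setNames(as.integer(O), all_nodes)),
            class = "elc_communities")
}

#' Node communities induced by a link partition
#'
#' Each link cluster induces the node community formed by the endpoints of
#' its links; a node whose links fall in several clusters belongs to several
#' communities, which is how overlap arises. Clusters inducing identical
#' node sets are merged (deduplicated), and isolated nodes of the network
#' are appended as singleton communities so that every node is covered.
#'
#' @param net an `elc_network`.
#' @param partition an `elc_partition` covering all links of `net`.
#' @return An `elc_communities` (see [node_communities()]).
#' @export
induce_node_communities <- function(net, partition) {
  stopifnot(inherits(net, "elc_network"), inherits(partition, "elc_partition"))
  if (sum(partition$m) != n_links(net))
    stop("partition does not cover all links of the network")
  ei <- net$ei; ej <- net$ej
  comms <- lapply(partition$clusters, function(ix) {
    h <- net$nodes[unique(c(ei[ix], ej[ix]))]
    h[order(h, method = "radix")]
  })
  keys <- vapply(comms, paste, character(1L), collapse = "\r")
  comms <- comms[!duplicated(keys)]
  iso <- net$nodes[lengths(net$adj) == 0L]
  comms <- c(comms, as.list(iso))
  O <- table(factor(unlist(comms), levels = net$nodes))
  structure(list(communities = comms,
                 memberships = stats::setNames(as.integer(O), net$nodes)),
            class = "elc_communities")
}

#' @export
print.elc_communities <- function(x, ...) {
  sz <- lengths(x$communities)
  cat(sprintf("<elc_communities> %d communities, sizes %s; %d node(s) overlap\n",
              length(sz),
              paste(utils::head(sort(sz, decreasing = TRUE), 8L), collapse = " "),
              sum(x$memberships > 1L)))
  invisible(x)
}

#' Density of a single link community
#'
#' For a cluster of `m_c` links touching `n_c` nodes the density is
#' `(m_c - (n_c - 1)) / (n_c (n_c - 1) / 2 - (n_c - 1))`: 0 for a tree,
#' 1 for a clique. The degenerate two-node cluster (denominator zero) is
#' assigned density 0 by convention.
#'
#' @param m_c link count(s), >= 1.
#' @param n_c node count(s), >= 2. Vectorized over both.
#' @return density value(s) in `[0, 1]` for connected clusters.
#' @export
community_density <- function(m_c, n_c) {
  if (any(m_c < 1L) || any(n_c < 2L))
    stop("community density needs m_c >= 1 and n_c >= 2")
  if (any(m_c > n_c * (n_c - 1) / 2))
    stop("inconsistent cluster: more links than node pairs")
  d <- ifelse(n_c == 2L, 0,
              (m_c - (n_c - 1)) / (n_c * (n_c - 1) / 2 - (n_c - 1)))
  as.numeric(d)
}

#' Partition density of a link partition
#'
#' The link-count-weighted mean of per-cluster densities,
#' `PD = (1/|M|) * sum_c m_c D_c`. All-singleton partitions and partitions
#' whose clusters are trees score 0; a partition into cliques scores 1.
#'
#' @param net an `elc_network`.
#' @param partition an `elc_partition` covering all links of `net`.
#' @return partition density in `[0, 1]`.
#' @export
partition_density <- function(net, partition) {
  stopifnot(inherits(net, "elc_network"), inherits(partition, "elc_partition"))
  M <- n_links(net)
  if (sum(partition$m) != M)
    stop("partition does not cover all links of the network")
  sum(partition$m * community_density(partition$m, partition$n_nodes)) / M
}

# EQ core on integer node indices; internal.
# ei/ej: link endpoints; deg: degrees; comms: list of integer node-index
# vectors; O: membership count per node (length n).
eq_core <- function(ei, ej, deg, comms, O, n) {
  M <- length(ei)
  twoM <- 2 * M
  w <- ifelse(O > 0L, 1 / O, 0)
  tot <- 0
  inh <- logical(n)
  for (h in comms) {
    wk <- sum(w[h] * deg[h])
    inh[h] <- TRUE
    sel <- inh[ei] & inh[ej]
    sA <- 2 * sum(w[ei[sel]] * w[ej[sel]])
    inh[h] <- FALSE
    tot <- tot + sA - wk * wk / twoM
  }
  tot / twoM
}

#' Extended modularity (EQ) of an overlapping cover
#'
#' Generalizes Newman's modularity to overlapping covers by down-weighting
#' every node pair by the product of membership counts:
#' `EQ = (1/2|M|) * sum_l sum_{i,j in H_l} (A_ij - k_i k_j / 2|M|) / (O_i O_j)`,
#' the double sum running over all ordered pairs including `i = j`. For a
#' disjoint cover (all `O_i = 1`) EQ reduces exactly to Newman's Q, and the
#' trivial one-community cover of a connected network scores exactly 0.
#'
#' @param net an `elc_network`.
#' @param communities an `elc_communities`, or a list of character vectors
#'   (memberships are then recomputed from the list).
#' @return the EQ value (dimensionless; higher means a more plausible
#'   overlapping division).
#' @export
extended_modularity <- function(net, communities) {
  stopifnot(inherits(net, "elc_network"))
  if (!inherits(communities, "elc_communities"))
    communities <- node_communities(communities, net)
  comms <- lapply(communities$communities, function(h) {
    ix <- match(h, net$nodes)
    if (anyNA(ix)) stop("community member not in network: ",
                        paste(h[is.na(ix)], collapse = ", "))
    ix
  })
  O <- integer(n_nodes(net))
  pos <- match(names(communities$memberships), net$nodes)
  ok <- !is.na(pos)
  O[pos[ok]] <- communities$memberships[ok]
  if (any(O[unlist(comms)] == 0L))
    stop("community references a node with membership count 0")
  eq_core(net$ei, net$ej, lengths(net$adj), comms, O, n_nodes(net))
}

#' Nearest neighbor of a node
#'
#' The adjacent node maximizing the node-level Jaccard similarity of
#' inclusive neighborhoods, `|n+(i) n n+(j)| / |n+(i) u n+(j)|`; ties are
#' broken by smallest node label. This is the proximity used by the
#' in-group proportion.
#'
#' @param net an `elc_network`.
#' @param i a node label with degree >= 1.
#' @return the neighbor's label.
#' @export
nearest_neighbor <- function(net, i) {
  stopifnot(inherits(net, "elc_network"))
  k <- match(i, net$nodes)
  if (is.na(k)) stop("unknown node: ", i)
  nb <- net$adj[[k]]
  if (!length(nb)) stop("node has no neighbors: ", i)
  ni <- c(k, nb)
  jac <- vapply(nb, function(j) {
    nj <- c(j, net$adj[[j]])
    length(intersect(ni, nj)) / length(union(ni, nj))
  }, numeric(1L))
  best <- net$nodes[nb[jac == max(jac)]]
  best[order(best, method = "radix")][1L]
}

#' In-group proportion (IGP) of a cover
#'
#' Per community, the fraction of its nodes whose nearest neighbor (see
#' [nearest_neighbor()]) lies in the same community; isolated nodes count
#' as non-matching. The aggregate is the membership-weighted mean of the
#' per-community values (equivalently the fraction of all node-memberships
#' whose nearest neighbor co-occurs); `weighting = "equal"` gives the plain
#' mean instead.
#'
#' @param net an `elc_network`.
#' @param communities an `elc_communities` or list of label vectors.
#' @param weighting `"membership"` (default) or `"equal"`.
#' @return list with `igp` (aggregate, in `[0, 1]`) and `per_community`
#'   (numeric vector in community order).
#' @export
in_group_proportion <- function(net, communities,
                                weighting = c("membership", "equal")) {
  stopifnot(inherits(net, "elc_network"))
  weighting <- match.arg(weighting)
  if (!inherits(communities, "elc_communities"))
    communities <- node_communities(communities, net)
  comms <- communities$communities
  if (!length(comms)) stop("empty community list")
  covered <- unique(unlist(comms))
  deg <- degree_sequence(net)
  nn <- stats::setNames(rep(NA_character_, length(covered)), covered)
  for (v in covered) if (deg[[v]] > 0L) nn[[v]] <- nearest_neighbor(net, v)
  per <- vapply(comms, function(h) {
    mean(!is.na(nn[h]) & nn[h] %in% h)
  }, numeric(1L))
  sz <- lengths(comms)
  agg <- if (weighting == "membership") sum(sz * per) / sum(sz) else mean(per)
  list(igp = agg, per_community = per)
}

#' Cover rate and uncovered-node count
#'
#' @param net an `elc_network`.
#' @param communities an `elc_communities` or list of label vectors.
#' @return list with `cr` (covered nodes / all nodes, in `[0, 1]`) and `un`
#'   (number of nodes in no community).
#' @export
coverage_stats <- function(net, communities) {
  stopifnot(inherits(net, "elc_network"))
  if (inherits(communities, "elc_communities"))
    communities <- communities$communities
  covered <- length(intersect(unique(unlist(communities)), net$nodes))
  list(cr = covered / n_nodes(net), un = n_nodes(net) - covered)
}

#' Read / write community files
#'
#' One community per line, whitespace-separated node labels; `#` comment
#' lines and blank lines are ignored on read.
#'
#' @param path file path.
#' @return `read_communities()` returns a list of character vectors.
#' @export
read_communities <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lapply(strsplit(trimws(lines), "\\s+"), as.character)
}

#' @rdname read_communities
#' @param communities an `elc_communities` or list of label vectors.
#' @export
write_communities <- function(communities, path) {
  if (inherits(communities, "elc_communities"))
    communities <- communities$communities
  writeLines(vapply(communities, paste, character(1L), collapse = " "), path)
  invisible(path)
}
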