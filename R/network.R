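# Network representation: simple undirected, unweighted graphs with opaque
# string node labels and a canonical (lexicographic) link ordering that fixes
# matrix row order and all downstream tie-breaking.

# C-locale lexicographic ranks of a character vector (locale-independent).
lex_rank <- function(x) {
  r <- integer(length(x))
  r[order(x, method = "radix")] <- seq_along(x)
  r
}

#' Build a network from an edge table
#'
#' Constructs an undirected, unweighted network from pairs of node labels.
#' Self-loops are dropped with a warning and parallel edges collapse to a
#' single edge. Node order is the order of first appearance (or the order of
#' `nodes` when given); links are stored in canonical lexicographic order on
#' `(min-label, max-label)`, which fixes link indices for all downstream
#' computation.
#'
#' @param edges two-column matrix or data frame of node labels, one edge per
#'   row. May have zero rows only when `nodes` is supplied.
#' @param nodes optional character vector of node labels fixing the node set
#'   and its order; must contain every label appearing in `edges`. Use it to
#'   include isolated nodes.
#' @return An object of class `elc_network` with components `nodes`
#'   (character), `ei`/`ej` (integer endpoint indices of each link, canonical
#'   order) and `adj` (adjacency list of integer neighbor indices).
#' @examples
#' net <- network_from_edges(rbind(c("a", "b"), c("b", "c")))
#' n_links(net)
#' @export
network_from_edges <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) < 2L)
    stop("`edges` must have two columns of node labels")
  u <- as.character(edges[, 1L])
  v <- as.character(edges[, 2L])
  loops <- u == v
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    u <- u[!loops]
    v <- v[!loops]
  }
  if (is.null(nodes)) {
    if (!length(u)) stop("empty edge set")
    # first-appearance order across the edge list
    nodes <- unique(as.vector(rbind(u, v)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate labels in `nodes`")
    miss <- setdiff(unique(c(u, v)), nodes)
    if (length(miss))
      stop("edge labels not in `nodes`: ", paste(miss, collapse = ", "))
  }
  n <- length(nodes)
  ei <- match(u, nodes)
  ej <- match(v, nodes)
  lexr <- lex_rank(nodes)
  # canonical per-edge orientation: endpoint with the smaller label first
  swap <- lexr[ei] > lexr[ej]
  tmp <- ei[swap]; ei[swap] <- ej[swap]; ej[swap] <- tmp
  # collapse parallel edges
  key <- (ei - 1) * n + ej
  keep <- !duplicated(key)
  ei <- ei[keep]; ej <- ej[keep]
  # canonical link order: lexicographic on (min-label, max-label)
  o <- order(lexr[ei], lexr[ej])
  ei <- ei[o]; ej <- ej[o]
  fac <- factor(c(ei, ej), levels = seq_len(n))
  adj <- lapply(split(c(ej, ei), fac), function(x) sort.int(unique(x)))
  names(adj) <- NULL
  structure(list(nodes = nodes, ei = ei, ej = ej, adj = adj, lexr = lexr),
            class = "elc_network")
}

#' Read a network from an edge-list or GML file
#'
#' Edge-list files hold one edge per line as two whitespace-separated node
#' labels; lines starting with `#` and blank lines are ignored, extra tokens
#' on a line (e.g. weights) are discarded. GML files are parsed with
#' \pkg{igraph}; node labels are taken from the `label` attribute if present,
#' else from `id`. In both formats self-loops are dropped with a warning and
#' duplicate edges are collapsed.
#'
#' @param path path to the input file.
#' @param fmt `"tsv"` (whitespace-separated edge list, the default) or
#'   `"gml"`.
#' @return An [`elc_network`][network_from_edges] object.
#' @export
read_edge_list <- function(path, fmt = c("tsv", "gml")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "tsv") {
    lines <- readLines(path)
    idx <- which(!grepl("^\\s*(#|$)", lines))
    if (!length(idx)) stop("empty edge set in ", path)
    toks <- strsplit(trimws(lines[idx]), "\\s+")
    bad <- which(lengths(toks) < 2L)
    if (length(bad))
      stop(sprintf("malformed edge line %d in %s (need >= 2 tokens)",
                   idx[bad[1L]], path))
    u <- vapply(toks, `[[`, character(1L), 1L)
    v <- vapply(toks, `[[`, character(1L), 2L)
    net <- network_from_edges(cbind(u, v))
  } else {
    g <- igraph::read_graph(path, format = "gml")
    labs <- igraph::vertex_attr(g, "label")
    if (is.null(labs)) labs <- igraph::vertex_attr(g, "id")
    if (is.null(labs)) labs <- seq_len(igraph::vcount(g))
    labs <- as.character(labs)
    el <- igraph::as_edgelist(g, names = FALSE)
    if (!nrow(el)) stop("empty edge set in ", path)
    net <- network_from_edges(cbind(labs[el[, 1L]], labs[el[, 2L]]),
                              nodes = labs)
  }
  if (!n_links(net)) stop("empty edge set in ", path)
  net
}

#' Write a network as a plain-text edge list
#'
#' Links are written in canonical order, one `from to` pair per line, so
#' that writing and re-reading reproduces an identical network.
#'
#' @param net an `elc_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "elc_network"))
  writeLines(paste(net$nodes[net$ei], net$nodes[net$ej]), path)
  invisible(path)
}

#' Number of nodes / links in a network
#' @param net an `elc_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_links <- function(net) length(net$ei)

#' Link table of a network
#'
#' @param net an `elc_network`.
#' @return data frame with columns `index`, `from`, `to` in canonical link
#'   order (`from` is the lexicographically smaller endpoint).
#' @export
links <- function(net) {
  data.frame(index = seq_along(net$ei),
             from = net$nodes[net$ei],
             to = net$nodes[net$ej],
             stringsAsFactors = FALSE)
}

#' Inclusive neighborhood of a node
#'
#' The inclusive neighborhood n+(i) contains node `i` itself together with
#' all of its neighbors (every node at shortest-path distance at most 1).
#' It is the primitive from which both link-similarity kernels are built.
#'
#' @param net an `elc_network`.
#' @param i a node label present in `net`.
#' @return character vector of node labels, sorted lexicographically.
#' @export
inclusive_neighborhood <- function(net, i) {
  stopifnot(inherits(net, "elc_network"))
  k <- match(i, net$nodes)
  if (is.na(k)) stop("unknown node: ", i)
  labs <- net$nodes[c(k, net$adj[[k]])]
  labs[order(labs, method = "radix")]
}

#' Degree of every node
#'
#' @param net an `elc_network`.
#' @return named integer vector of degrees in node order; the degrees sum to
#'   twice the number of links.
#' @export
degree_sequence <- function(net) {
  stopifnot(inherits(net, "elc_network"))
  stats::setNames(lengths(net$adj), net$nodes)
}

# igraph view of a network (vertex names = labels); internal.
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    links(net)[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' Connected components of a network
#'
#' @param net an `elc_network`.
#' @return list of character vectors (node labels, each sorted), one per
#'   component, ordered by smallest member label.
#' @export
network_components <- function(net) {
  stopifnot(inherits(net, "elc_network"))
  memb <- igraph::components(as_igraph(net))$membership
  comps <- split(net$nodes, memb[net$nodes])
  comps <- lapply(comps, function(x) x[order(x, method = "radix")])
  names(comps) <- NULL
  comps[order(vapply(comps, `[[`, character(1L), 1L), method = "radix")]
}

#' @export
print.elc_network <- function(x, ...) {
  cat(sprintf("<elc_network> %d nodes, %d links\n", n_nodes(x), n_links(x)))
  invisible(x)
}
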