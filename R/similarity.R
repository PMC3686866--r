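# Link-similarity kernels and the link x link transform matrix.
#
# Both kernels are functions of inclusive neighborhoods n+(x) = {x} u N(x):
#  - LS (Jaccard): defined for two links sharing exactly one node; Jaccard
#    index of the inclusive neighborhoods of the two non-shared endpoints.
#  - ELS: defined for any pair of links (i,j), (k,l); the sum over all four
#    endpoint pairings of |n+(x) n n+(y)| divided by the corresponding sum
#    of |n+(x) u n+(y)|. Non-neighbor links within two steps of each other
#    get a positive score; links in different components score 0.

# Pairwise inclusive-neighborhood overlap counts P[x, y] = |n+(x) n n+(y)|
# and sizes s[x] = |n+(x)| = degree + 1; internal.
incl_overlap <- function(net) {
  n <- n_nodes(net)
  B <- Matrix::sparseMatrix(i = c(net$ei, net$ej, seq_len(n)),
                            j = c(net$ej, net$ei, seq_len(n)),
                            x = 1, dims = c(n, n))
  list(P = as.matrix(Matrix::crossprod(B)), s = lengths(net$adj) + 1L)
}

# Resolve a length-2 label vector to integer endpoints of an existing link.
resolve_link <- function(net, e) {
  if (length(e) != 2L) stop("a link is a pair of node labels")
  idx <- match(as.character(e), net$nodes)
  if (anyNA(idx)) stop("unknown node in link: ", paste(e, collapse = "-"))
  if (idx[1L] == idx[2L]) stop("link endpoints must be distinct")
  if (!(idx[2L] %in% net$adj[[idx[1L]]]))
    stop("no such link in network: ", paste(e, collapse = "-"))
  idx
}

#' Jaccard similarity of two neighbor links
#'
#' For links e1 = (i, k) and e2 = (j, k) sharing exactly the node k, the
#' link similarity is the Jaccard index of the inclusive neighborhoods of
#' the non-shared endpoints, `|n+(i) n n+(j)| / |n+(i) u n+(j)|`.
#'
#' @param net an `elc_network`.
#' @param e1,e2 links given as length-2 character vectors of node labels;
#'   both must be edges of `net` and share exactly one endpoint.
#' @return similarity in `[0, 1]`.
#' @examples
#' net <- network_from_edges(rbind(c("a","b"), c("b","c")))
#' jaccard_link_similarity(net, c("a","b"), c("b","c"))  # 1/3
#' @export
jaccard_link_similarity <- function(net, e1, e2) {
  p <- resolve_link(net, e1)
  q <- resolve_link(net, e2)
  shared <- intersect(p, q)
  if (length(shared) != 1L)
    stop("links must share exactly one node for the Jaccard link similarity")
  a <- setdiff(p, shared)
  b <- setdiff(q, shared)
  na <- c(a, net$adj[[a]])
  nb <- c(b, net$adj[[b]])
  length(intersect(na, nb)) / length(union(na, nb))
}

#' Extended link similarity (ELS) of any two links
#'
#' For links e1 = (i, j) and e2 = (k, l), ELS is the ratio of the summed
#' inclusive-neighborhood intersection sizes to the summed union sizes over
#' all four endpoint pairings (i,k), (i,l), (j,k), (j,l). Unlike the Jaccard
#' link similarity it is defined for non-neighbor links and is positive
#' whenever some endpoint of one link shares an inclusive neighbor with some
#' endpoint of the other (the links lie within two steps of each other); it
#' is 0 for links in different connected components.
#'
#' @inheritParams jaccard_link_similarity
#' @return similarity in `[0, 1]`.
#' @examples
#' cyc <- network_from_edges(rbind(c("a","b"), c("b","c"),
#'                                 c("c","d"), c("a","d")))
#' extended_link_similarity(cyc, c("a","b"), c("c","d"))  # 0.5
#' @export
extended_link_similarity <- function(net, e1, e2) {
  p <- resolve_link(net, e1)
  q <- resolve_link(net, e2)
  nb <- lapply(c(p, q), function(x) c(x, net$adj[[x]]))
  inter <- 0L
  uni <- 0L
  for (x in 1:2) for (y in 3:4) {
    inter <- inter + length(intersect(nb[[x]], nb[[y]]))
    uni <- uni + length(union(nb[[x]], nb[[y]]))
  }
  if (inter == 0L) return(0)
  inter / uni
}

#' Build the link x link transform matrix
#'
#' In `"LC"` mode entry (p, q) is the Jaccard link similarity for link pairs
#' sharing a node and 0 otherwise; in `"ELC"` mode it is the extended link
#' similarity for every pair. Only nonzero off-diagonal entries are stored
#' (sparse, absent = 0); the diagonal is set to 1 by convention and is never
#' consulted by the clustering.
#'
#' @param net an `elc_network` with at least one link.
#' @param mode `"ELC"` (extended link similarity, the default) or `"LC"`
#'   (Jaccard similarity of neighbor links).
#' @return An `elc_similarity` object wrapping a symmetric sparse matrix `S`
#'   of dimension `n_links(net)` with the link table and mode attached.
#' @export
build_similarity_matrix <- function(net, mode = c("ELC", "LC")) {
  stopifnot(inherits(net, "elc_network"))
  mode <- match.arg(mode)
  M <- n_links(net)
  if (M < 1L) stop("network has no links")
  ov <- incl_overlap(net)
  P <- ov$P
  s <- ov$s
  ei <- net$ei
  ej <- net$ej
  if (mode == "ELC") {
    I4 <- P[ei, ei, drop = FALSE] + P[ei, ej, drop = FALSE] +
          P[ej, ei, drop = FALSE] + P[ej, ej, drop = FALSE]
    sz2 <- 2 * (s[ei] + s[ej])
    U4 <- outer(sz2, rep(1, M)) + outer(rep(1, M), sz2) - I4
    S <- I4 / U4
    S[I4 == 0] <- 0
    diag(S) <- 1
    S <- Matrix::drop0(methods::as(S, "sparseMatrix"))
  } else {
    fac <- factor(c(ei, ej), levels = seq_len(n_nodes(net)))
    inc <- split(rep.int(seq_len(M), 2L), fac)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (k in seq_along(inc)) {
      lk <- inc[[k]]
      if (length(lk) < 2L) next
      pr <- utils::combn(lk, 2L)
      # non-shared endpoint of each link relative to the shared node k
      oa <- ei[pr[1L, ]] + ej[pr[1L, ]] - k
      ob <- ei[pr[2L, ]] + ej[pr[2L, ]] - k
      pov <- P[cbind(oa, ob)]
      ii <- c(ii, pr[1L, ]); jj <- c(jj, pr[2L, ])
      xx <- c(xx, pov / (s[oa] + s[ob] - pov))
    }
    S <- Matrix::sparseMatrix(i = c(ii, jj, seq_len(M)),
                              j = c(jj, ii, seq_len(M)),
                              x = c(xx, xx, rep(1, M)),
                              dims = c(M, M))
  }
  structure(list(S = S, mode = mode, links = links(net), n_links = M),
            class = "elc_similarity")
}

#' Wrap a plain similarity matrix for link clustering
#'
#' Accepts any symmetric nonnegative matrix of pairwise link similarities
#' (dense or sparse) so that [single_linkage()] can be applied to custom
#' kernels. Absent/zero entries mean similarity 0.
#'
#' @param S square symmetric numeric matrix with values in `[0, 1]`.
#' @param mode label recorded on the object (default `"custom"`).
#' @param links optional link table (`index`, `from`, `to`) matching the
#'   matrix rows; required downstream only for node-level bookkeeping.
#' @return An `elc_similarity` object.
#' @export
as_similarity_matrix <- function(S, mode = "custom", links = NULL) {
  m <- as.matrix(S)
  if (nrow(m) != ncol(m)) stop("similarity matrix must be square")
  if (!isSymmetric(unname(m))) stop("similarity matrix must be symmetric")
  if (any(m < 0)) stop("similarities must be nonnegative")
  nz <- which(m != 0, arr.ind = TRUE)
  sp <- Matrix::sparseMatrix(i = nz[, 1L], j = nz[, 2L], x = m[nz],
                             dims = dim(m))
  structure(list(S = sp, mode = mode, links = links, n_links = nrow(m)),
            class = "elc_similarity")
}

#' Count stored nonzero off-diagonal link pairs
#'
#' One way to quantify how much denser the ELS transform matrix is than the
#' Jaccard one: the number of unordered link pairs with positive similarity.
#'
#' @param sim an `elc_similarity`.
#' @return integer count of unordered pairs with nonzero similarity.
#' @export
n_similar_pairs <- function(sim) {
  stopifnot(inherits(sim, "elc_similarity"))
  tr <- Matrix::summary(sim$S)
  sum(tr$i < tr$j & tr$x != 0)
}

#' Dump a similarity matrix as a 3-column text file
#'
#' Writes one `link-index link-index value` triple per stored off-diagonal
#' entry (upper triangle), and the link index/endpoint map alongside.
#'
#' @param sim an `elc_similarity` with a link table.
#' @param path output path for the triples.
#' @param map_path output path for the link map (default `path` +
#'   `".links"`).
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path,
                                    map_path = paste0(path, ".links")) {
  stopifnot(inherits(sim, "elc_similarity"))
  tr <- Matrix::summary(sim$S)
  tr <- tr[tr$i < tr$j & tr$x != 0, , drop = FALSE]
  utils::write.table(tr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(sim$links))
    utils::write.table(sim$links, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.elc_similarity <- function(x, ...) {
  cat(sprintf("<elc_similarity> mode=%s, %d links, %d nonzero pairs\n",
              x$mode, x$n_links, n_similar_pairs(x)))
  invisible(x)
}
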