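# Single-linkage hierarchical clustering of links.
#
# The similarity of two clusters is the maximum pairwise link similarity
# across them; absent matrix entries count as 0. At each step the pair of
# clusters with maximal similarity is merged; among ties, the pair whose
# smallest contained link index is lowest wins (then the second-smallest),
# so dendrograms are fully reproducible. Zero-similarity merges are
# performed last, continuing until all links form one cluster.

#' Single-linkage clustering of a link similarity matrix
#'
#' @param sim an `elc_similarity` (see [build_similarity_matrix()] or
#'   [as_similarity_matrix()]).
#' @return An `elc_dendrogram`: a data frame of merge records with columns
#'   `id_a`, `id_b` (cluster ids; leaves are `1..M`, new clusters are
#'   numbered `M+1, M+2, ...` in merge order), `similarity` (non-increasing)
#'   and `new_id`. The link table, when available, travels along as an
#'   attribute for node-level bookkeeping downstream.
#' @export
single_linkage <- function(sim) {
  stopifnot(inherits(sim, "elc_similarity"))
  M <- sim$n_links
  C <- as.matrix(sim$S)
  C <- (C + t(C)) / 2    # guard against floating asymmetry in custom kernels
  diag(C) <- -Inf
  minidx <- seq_len(M)       # smallest link index in each active cluster slot
  dendid <- seq_len(M)       # dendrogram id of each active cluster slot
  nm <- max(M - 1L, 0L)
  id_a <- integer(nm); id_b <- integer(nm); simv <- numeric(nm)
  for (step in seq_len(nm)) {
    m <- max(C)
    cand <- which(C == m, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    u <- pmin(minidx[cand[, 1L]], minidx[cand[, 2L]])
    v <- pmax(minidx[cand[, 1L]], minidx[cand[, 2L]])
    k <- order(u, v)[1L]
    a <- cand[k, 1L]
    b <- cand[k, 2L]
    ia <- dendid[a]; ib <- dendid[b]
    id_a[step] <- min(ia, ib)
    id_b[step] <- max(ia, ib)
    simv[step] <- m
    newrow <- pmax(C[a, ], C[b, ])
    newrow[a] <- -Inf
    C[a, ] <- newrow
    C[, a] <- newrow
    C[b, ] <- -Inf
    C[, b] <- -Inf
    minidx[a] <- min(minidx[a], minidx[b])
    dendid[a] <- M + step
  }
  d <- data.frame(id_a = id_a, id_b = id_b, similarity = simv,
                  new_id = M + seq_len(nm))
  structure(d, class = c("elc_dendrogram", "data.frame"),
            n_links = M, links = sim$links)
}

#' @export
print.elc_dendrogram <- function(x, ...) {
  cat(sprintf("<elc_dendrogram> %d links, %d merges\n",
              attr(x, "n_links"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

# Link clusters after the first `level` merges, as a list of sorted integer
# link-index vectors ordered by smallest member; internal.
clusters_at <- function(dend, level) {
  M <- attr(dend, "n_links")
  if (level < 0L || level > nrow(dend))
    stop(sprintf("level must be in 0..%d", nrow(dend)))
  members <- c(as.list(seq_len(M)), vector("list", level))
  alive <- c(rep(TRUE, M), rep(FALSE, level))
  for (s in seq_len(level)) {
    ia <- dend$id_a[s]; ib <- dend$id_b[s]; nid <- dend$new_id[s]
    members[[nid]] <- c(members[[ia]], members[[ib]])
    alive[ia] <- FALSE; alive[ib] <- FALSE; alive[nid] <- TRUE
  }
  cl <- lapply(members[alive], sort.int)
  cl[order(vapply(cl, `[[`, integer(1L), 1L))]
}

#' Link partition at a dendrogram level
#'
#' Level `t` is the partition of links after the first `t` merges: level 0
#' is all singletons, the final level a single cluster. Each cluster carries
#' its link count `m` and the count `n_nodes` of distinct nodes touched by
#' its links (when the dendrogram knows its link table).
#'
#' @param dend an `elc_dendrogram`.
#' @param level integer number of merges applied, `0..nrow(dend)`.
#' @return An `elc_partition`: list with `clusters` (list of link-index
#'   vectors), `m`, `n_nodes`, `level` and the link table.
#' @export
partition_at <- function(dend, level) {
  stopifnot(inherits(dend, "elc_dendrogram"))
  cl <- clusters_at(dend, level)
  lk <- attr(dend, "links")
  n_nodes <- if (is.null(lk)) rep(NA_integer_, length(cl)) else
    vapply(cl, function(ix)
      length(unique(c(lk$from[ix], lk$to[ix]))), integer(1L))
  structure(list(clusters = cl, m = lengths(cl), n_nodes = n_nodes,
                 level = level, links = lk),
            class = "elc_partition")
}

#' All link partitions of a dendrogram
#'
#' @param dend an `elc_dendrogram`.
#' @return list of [partition_at()] results for levels `0..nrow(dend)`, in
#'   level order.
#' @export
partition_sequence <- function(dend) {
  lapply(0:nrow(dend), function(l) partition_at(dend, l))
}

#' @export
print.elc_partition <- function(x, ...) {
  cat(sprintf("<elc_partition> level %d: %d link cluster(s), sizes %s\n",
              x$level, length(x$clusters),
              paste(utils::head(sort(x$m, decreasing = TRUE), 8L),
                    collapse = " ")))
  invisible(x)
}

#' Write a dendrogram as a 4-column text file
#'
#' Columns: `id_a`, `id_b`, `similarity`, `new_id`, one merge per line.
#'
#' @param dend an `elc_dendrogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(dend, path) {
  stopifnot(inherits(dend, "elc_dendrogram"))
  utils::write.table(as.data.frame(dend), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
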