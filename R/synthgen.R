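# Planted-community benchmark generator: equal-sized disjoint blocks, a
# prescribed total link budget L = round(n * avg_degree / 2), an inside
# quota L_in = round(p_inside * L) split as evenly as possible across
# blocks (remainder to lowest-index blocks), a uniform random spanning
# tree per block guaranteeing connectivity, extra uniform within-block
# links up to quota, and the remaining L - L_in links placed uniformly
# across block boundaries.

round_half_up <- function(x) floor(x + 0.5)

#' Configuration for the planted-community generator
#'
#' Defaults reproduce the benchmark conditions of the study design: 128
#' nodes in 4 blocks of 32, 10 replicates per condition, with the average
#' degree and the within-block link proportion as the condition knobs.
#'
#' @param n_nodes total node count; must be divisible by `n_blocks`.
#' @param n_blocks number of planted blocks.
#' @param avg_degree target mean degree k̄ (e.g. 4, 8, 12); the total link
#'   count is `round(n_nodes * avg_degree / 2)`.
#' @param p_inside proportion of links placed within blocks, in `(0, 1]`;
#'   `1 - p_inside` of the links run between blocks.
#' @param seed integer base seed; replicate `r` is generated from seed
#'   `seed + r`.
#' @param replicates number of replicate networks per condition.
#' @return A validated `elc_synth_config` list, with the derived quantities
#'   `n_links` (L), `n_inside` (L_in) and `block_quota` attached.
#' @export
synthetic_config <- function(n_nodes = 128L, n_blocks = 4L, avg_degree = 4,
                             p_inside = 0.9, seed = 1L, replicates = 10L) {
  if (n_nodes %% n_blocks != 0L)
    stop("n_nodes must be divisible by n_blocks")
  if (p_inside <= 0 || p_inside > 1)
    stop("p_inside must be in (0, 1]")
  if (replicates < 1L) stop("replicates must be >= 1")
  size <- n_nodes %/% n_blocks
  L <- round_half_up(n_nodes * avg_degree / 2)
  L_in <- round_half_up(p_inside * L)
  quota <- rep(L_in %/% n_blocks, n_blocks)
  rem <- L_in %% n_blocks
  if (rem > 0L) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L
  max_in <- size * (size - 1) / 2
  if (any(quota < size - 1L))
    stop(sprintf(
      "inside-link quota %d is below the spanning-tree minimum %d for a block of %d nodes",
      min(quota), size - 1L, size))
  if (any(quota > max_in))
    stop(sprintf(
      "inside-link quota %d exceeds the %d node pairs available in a block of %d nodes",
      max(quota), max_in, size))
  structure(list(n_nodes = as.integer(n_nodes), n_blocks = as.integer(n_blocks),
                 block_size = as.integer(size), avg_degree = avg_degree,
                 p_inside = p_inside, seed = as.integer(seed),
                 replicates = as.integer(replicates),
                 n_links = as.integer(L), n_inside = as.integer(L_in),
                 block_quota = as.integer(quota)),
            class = "elc_synth_config")
}

# Uniform random labeled tree on s nodes via a random Pruefer sequence;
# returns a (s-1) x 2 matrix of local node indices.
random_spanning_tree <- function(s) {
  if (s == 1L) return(matrix(integer(0), 0L, 2L))
  if (s == 2L) return(matrix(c(1L, 2L), 1L, 2L))
  code <- sample.int(s, s - 2L, replace = TRUE)
  deg <- rep(1L, s) + tabulate(code, nbins = s)
  edges <- matrix(integer(0), s - 1L, 2L)
  for (t in seq_len(s - 2L)) {
    leaf <- which(deg == 1L)[1L]
    edges[t, ] <- c(leaf, code[t])
    deg[leaf] <- 0L
    deg[code[t]] <- deg[code[t]] - 1L
  }
  edges[s - 1L, ] <- which(deg == 1L)
  edges
}

# Sample k elements from x without replacement, robust to length-1 x.
sample_exact <- function(x, k) x[sample.int(length(x), k)]

#' Generate one planted-community network
#'
#' Draws a network under the configured condition: per block, a uniform
#' random spanning tree (so every block's internal subgraph is connected)
#' plus additional distinct within-block links up to the block's quota;
#' then the remaining links are placed uniformly over all between-block
#' node pairs. No self-loops or duplicate links are produced. The RNG seed
#' is set to `config$seed + replicate_index`, so every network is
#' reproducible from the configuration alone.
#'
#' @param config an [`elc_synth_config`][synthetic_config].
#' @param replicate_index positive integer replicate number.
#' @return list with `network` (an `elc_network` whose nodes are labelled
#'   `v001, v002, ...` in block order) and `blocks` (named integer vector:
#'   planted block of every node).
#' @export
generate_network <- function(config, replicate_index = 1L) {
  stopifnot(inherits(config, "elc_synth_config"))
  set.seed(config$seed + as.integer(replicate_index))
  n <- config$n_nodes
  B <- config$n_blocks
  s <- config$block_size
  width <- max(3L, nchar(as.character(n)))
  labels <- sprintf(paste0("v%0", width, "d"), seq_len(n))
  block_of <- rep(seq_len(B), each = s)
  ein <- integer(0); ejn <- integer(0)
  for (b in seq_len(B)) {
    off <- (b - 1L) * s
    tree <- random_spanning_tree(s)
    ta <- pmin(tree[, 1L], tree[, 2L]) + off
    tb <- pmax(tree[, 1L], tree[, 2L]) + off
    extra <- config$block_quota[b] - (s - 1L)
    if (extra > 0L) {
      pairs <- utils::combn(s, 2L)
      ka <- pairs[1L, ] + off
      kb <- pairs[2L, ] + off
      key <- (ka - 1) * n + kb
      free <- which(!(key %in% ((ta - 1) * n + tb)))
      pick <- sample_exact(free, extra)
      ta <- c(ta, ka[pick]); tb <- c(tb, kb[pick])
    }
    ein <- c(ein, ta); ejn <- c(ejn, tb)
  }
  L_out <- config$n_links - config$n_inside
  if (L_out > 0L) {
    ut <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    cross <- ut[block_of[ut[, 1L]] != block_of[ut[, 2L]], , drop = FALSE]
    pick <- sample_exact(seq_len(nrow(cross)), L_out)
    ein <- c(ein, cross[pick, 1L]); ejn <- c(ejn, cross[pick, 2L])
  }
  net <- network_from_edges(cbind(labels[ein], labels[ejn]), nodes = labels)
  list(network = net, blocks = stats::setNames(block_of, labels))
}

#' Generate a batch of replicate networks
#'
#' @param config an [`elc_synth_config`][synthetic_config].
#' @return list of [generate_network()] results for replicates
#'   `1..config$replicates`; identical configurations give identical
#'   batches.
#' @export
generate_batch <- function(config) {
  stopifnot(inherits(config, "elc_synth_config"))
  lapply(seq_len(config$replicates), function(r) generate_network(config, r))
}

#' Run a method over a batch and average the quality metrics
#'
#' @param batch a [generate_batch()] result (or any list of elements with a
#'   `network` field).
#' @param method,cut passed to [elc_run()].
#' @return list with `per_replicate` (data frame of `eq`, `pd`, `igp`,
#'   `cn`, `cr`, `un`, one row per network) and `mean` (named numeric
#'   vector of column means — the condition-level summary).
#' @export
evaluate_batch <- function(batch, method = c("ELC", "LC"), cut = NULL) {
  method <- match.arg(method)
  reports <- lapply(batch, function(x) elc_run(x$network, method, cut)$report)
  df <- compare_reports(reports, labels = seq_along(reports))[, -1L]
  list(per_replicate = df, mean = colMeans(df))
}
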