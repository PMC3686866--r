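# End-to-end runners: similarity -> single-linkage dendrogram -> cut
# selection -> induced overlapping node communities -> quality report.
#
# ELC pairs the extended link similarity with a maximal-EQ cut; the
# baseline LC pairs the Jaccard neighbor-link similarity with a
# maximal-partition-density cut. Either kernel can be combined with either
# cut criterion.

# Criterion value (and community count) at every dendrogram level,
# computed incrementally along the merge sequence; internal workhorse.
profile_core <- function(dend, net, criterion) {
  M <- attr(dend, "n_links")
  if (M != n_links(net))
    stop("dendrogram and network disagree on the number of links")
  L <- nrow(dend)
  ei <- net$ei; ej <- net$ej
  n <- n_nodes(net)
  deg <- lengths(net$adj)
  iso <- which(deg == 0L)
  # cluster state keyed by dendrogram id
  members <- c(as.list(seq_len(M)), vector("list", L))
  nodeset <- c(lapply(seq_len(M), function(p) unique(c(ei[p], ej[p]))),
               vector("list", L))
  alive <- c(rep(TRUE, M), rep(FALSE, L))
  value <- numeric(L + 1L)
  cn <- integer(L + 1L)
  eval_level <- function(lv) {
    act <- which(alive)
    if (criterion == "PD") {
      m_c <- lengths(members[act])
      n_c <- lengths(nodeset[act])
      value[lv] <<- sum(m_c * community_density(m_c, n_c)) / M
    }
    # induced node communities: deduplicated endpoint sets + isolated nodes
    comms <- nodeset[act]
    keys <- vapply(comms, paste, character(1L), collapse = ",")
    comms <- comms[!duplicated(keys)]
    cn[lv] <<- length(comms) + length(iso)
    if (criterion == "EQ") {
      allc <- c(comms, as.list(iso))
      O <- tabulate(unlist(allc), nbins = n)
      value[lv] <<- eq_core(ei, ej, deg, allc, O, n)
    }
  }
  eval_level(1L)
  for (s in seq_len(L)) {
    ia <- dend$id_a[s]; ib <- dend$id_b[s]; nid <- dend$new_id[s]
    members[[nid]] <- c(members[[ia]], members[[ib]])
    nodeset[[nid]] <- unique(c(nodeset[[ia]], nodeset[[ib]]))
    alive[ia] <- FALSE; alive[ib] <- FALSE; alive[nid] <- TRUE
    eval_level(s + 1L)
  }
  data.frame(level = 0:L, value = value, cn = cn)
}

#' Criterion profile along a dendrogram
#'
#' Evaluates the chosen cut criterion — extended modularity (`"EQ"`) of the
#' induced node communities, or partition density (`"PD"`) of the link
#' partition — at every merge level of the dendrogram. The selected cut of
#' a run is the level maximizing this profile.
#'
#' @param dend an `elc_dendrogram` produced from `net`'s links.
#' @param net the `elc_network` the dendrogram was built on.
#' @param criterion `"EQ"` or `"PD"`.
#' @return data frame with columns `level` (0..number of merges), `value`
#'   (criterion value) and `cn` (induced node-community count, used for
#'   tie-breaking).
#' @export
criterion_profile <- function(dend, net, criterion = c("EQ", "PD")) {
  stopifnot(inherits(dend, "elc_dendrogram"), inherits(net, "elc_network"))
  criterion <- match.arg(criterion)
  profile_core(dend, net, criterion)
}

# Best level of a profile: maximal value, ties -> fewest node communities,
# remaining ties -> lowest level; internal.
select_cut <- function(profile) {
  best <- profile$value == max(profile$value)
  cand <- profile[best, , drop = FALSE]
  cand <- cand[cand$cn == min(cand$cn), , drop = FALSE]
  cand$level[1L]
}

#' Run link clustering end to end
#'
#' Builds the link similarity matrix in the configured mode, clusters the
#' links by single linkage, evaluates the cut criterion at every dendrogram
#' level, cuts at the level of maximal criterion value (ties: fewest node
#' communities, then lowest level), induces the overlapping node
#' communities and scores them.
#'
#' @param net an `elc_network` with at least one link.
#' @param method `"ELC"` (extended link similarity, default cut `"EQ"`) or
#'   `"LC"` (Jaccard neighbor-link similarity, default cut `"PD"`).
#' @param cut optional cut criterion `"EQ"` or `"PD"`, overriding the
#'   method's default pairing.
#' @param igp_weighting passed to [in_group_proportion()].
#' @return An `elc_result`: list with `communities`, `partition`, `report`
#'   (class `elc_report` with fields `eq`, `pd`, `igp`, `cn`, `cr`, `un`,
#'   `per_community_igp` plus `method`, `criterion`, `level`,
#'   `criterion_value`), `dendrogram`, `profile` and `similarity`.
#' @examples
#' net <- network_from_edges(rbind(c("a","b"), c("b","c"), c("a","c"),
#'                                 c("d","e"), c("e","f"), c("d","f")))
#' res <- elc_run(net, method = "ELC")
#' res$report$cn  # 2 communities
#' @export
elc_run <- function(net, method = c("ELC", "LC"), cut = NULL,
                    igp_weighting = c("membership", "equal")) {
  stopifnot(inherits(net, "elc_network"))
  method <- match.arg(method)
  if (n_links(net) < 1L) stop("network has no links")
  criterion <- if (is.null(cut)) {
    if (method == "ELC") "EQ" else "PD"
  } else match.arg(cut, c("EQ", "PD"))
  sim <- build_similarity_matrix(net, mode = method)
  dend <- single_linkage(sim)
  profile <- criterion_profile(dend, net, criterion)
  level <- select_cut(profile)
  partition <- partition_at(dend, level)
  communities <- induce_node_communities(net, partition)
  igp <- in_group_proportion(net, communities, weighting = igp_weighting)
  cov <- coverage_stats(net, communities)
  report <- structure(list(
    eq = extended_modularity(net, communities),
    pd = partition_density(net, partition),
    igp = igp$igp,
    cn = length(communities$communities),
    cr = cov$cr,
    un = cov$un,
    per_community_igp = igp$per_community,
    method = method,
    criterion = criterion,
    level = level,
    criterion_value = profile$value[profile$level == level]
  ), class = "elc_report")
  structure(list(communities = communities, partition = partition,
                 report = report, dendrogram = dend, profile = profile,
                 similarity = sim),
            class = "elc_result")
}

#' Score an externally produced cover
#'
#' Computes the node-level quality metrics (EQ, IGP, coverage) for a cover
#' obtained by any method, e.g. clique percolation, on a given network.
#'
#' @param net an `elc_network`.
#' @param communities an `elc_communities` or list of label vectors.
#' @param igp_weighting passed to [in_group_proportion()].
#' @return An `elc_report` (without `pd`, which needs a link partition;
#'   its value is `NA`).
#' @export
evaluate_cover <- function(net, communities,
                           igp_weighting = c("membership", "equal")) {
  if (!inherits(communities, "elc_communities"))
    communities <- node_communities(communities, net)
  igp <- in_group_proportion(net, communities, weighting = igp_weighting)
  cov <- coverage_stats(net, communities)
  structure(list(
    eq = extended_modularity(net, communities),
    pd = NA_real_,
    igp = igp$igp,
    cn = length(communities$communities),
    cr = cov$cr,
    un = cov$un,
    per_community_igp = igp$per_community,
    method = "external",
    criterion = NA_character_,
    level = NA_integer_,
    criterion_value = NA_real_
  ), class = "elc_report")
}

#' @export
print.elc_report <- function(x, ...) {
  cat(sprintf(
    "<elc_report> %s%s  EQ=%.4f  PD=%s  IGP=%.4f  CN=%d  CR=%.1f%%  UN=%d\n",
    x$method,
    if (is.na(x$criterion)) "" else sprintf("/max_%s@level %d", x$criterion, x$level),
    x$eq, if (is.na(x$pd)) "NA" else sprintf("%.4f", x$pd),
    x$igp, x$cn, 100 * x$cr, x$un))
  invisible(x)
}

#' @export
print.elc_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Tabulate quality reports
#'
#' @param reports list of `elc_report` objects.
#' @param labels character vector of row labels, same length as `reports`.
#' @return data frame with one row per report and columns `label`, `eq`,
#'   `pd`, `igp`, `cn`, `cr`, `un`.
#' @export
compare_reports <- function(reports, labels) {
  if (length(reports) != length(labels))
    stop("`reports` and `labels` must have the same length")
  rows <- lapply(reports, function(r)
    data.frame(eq = r$eq, pd = r$pd, igp = r$igp, cn = r$cn,
               cr = r$cr, un = r$un))
  cbind(data.frame(label = as.character(labels), stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

#' Serialize a quality report as JSON
#'
#' Writes the fixed keys `eq`, `pd`, `igp`, `cn`, `cr`, `un`,
#' `per_community_igp` plus a `meta` object (`method`, `criterion`,
#' `level`).
#'
#' @param report an `elc_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "elc_report"))
  out <- list(eq = report$eq, pd = report$pd, igp = report$igp,
              cn = report$cn, cr = report$cr, un = report$un,
              per_community_igp = as.list(report$per_community_igp),
              meta = list(method = report$method,
                          criterion = report$criterion,
                          level = report$level))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
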