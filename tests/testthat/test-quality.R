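test_that("community density covers clique, degenerate and worked cases", {
  expect_equal(community_density(3, 3), 1)
  expect_equal(community_density(1, 2), 0)
  expect_equal(community_density(4, 4), 1 / 3)
  expect_error(community_density(7, 4), "more links")
  expect_error(community_density(0, 3), "m_c >= 1")
})

test_that("partition density scores cliques, trees and singletons", {
  tt <- two_triangles()
  d <- single_linkage(build_similarity_matrix(tt, "ELC"))
  # level 4: the two triangles (positive merges done, before the 0-union)
  p <- partition_at(d, 4)
  expect_length(p$clusters, 2L)
  expect_equal(partition_density(tt, p), 1)
  expect_equal(partition_density(tt, partition_at(d, 0)), 0)

  tree <- path_net(letters[1:6])
  dt <- single_linkage(build_similarity_matrix(tree, "ELC"))
  expect_equal(partition_density(tree, partition_at(dt, nrow(dt))), 0)
  expect_equal(partition_density(tree, partition_at(dt, 0)), 0)
})

test_that("induced communities overlap exactly at shared nodes", {
  tt <- two_triangles()
  d <- single_linkage(build_similarity_matrix(tt, "ELC"))
  cm <- induce_node_communities(tt, partition_at(d, 4))
  expect_length(cm$communities, 2L)
  expect_true(all(lengths(cm$communities) == 3L))
  expect_true(all(cm$memberships == 1L))

  bt <- bowtie_net()
  db <- single_linkage(build_similarity_matrix(bt, "ELC"))
  # find the level whose partition is the two triangles
  lv <- which(vapply(partition_sequence(db), function(p)
    length(p$clusters) == 2L && all(p$m == 3L), logical(1))) - 1L
  cm2 <- induce_node_communities(bt, partition_at(db, lv[1]))
  expect_setequal(lapply(cm2$communities, paste, collapse = ""),
                  list("abc", "cde"))
  expect_equal(cm2$memberships[["c"]], 2L)
})

test_that("isolated nodes become singleton communities with full coverage", {
  net <- network_from_edges(rbind(c("a","b"), c("b","c"), c("a","c")),
                            nodes = c("a", "b", "c", "z"))
  d <- single_linkage(build_similarity_matrix(net, "ELC"))
  cm <- induce_node_communities(net, partition_at(d, nrow(d)))
  expect_true(list("z") %in% cm$communities)
  cov <- coverage_stats(net, cm)
  expect_equal(cov$cr, 1)
  expect_equal(cov$un, 0L)
})

test_that("EQ of the whole-network community is exactly zero", {
  set.seed(71)
  for (rep in 1:100) {
    net <- random_net(sample(4:14, 1))
    expect_identical(extended_modularity(net, list(net$nodes)), 0)
  }
})

test_that("EQ equals brute force on overlapping covers", {
  bt <- bowtie_net()
  cover <- list(c("a","b","c"), c("c","d","e"))
  expect_equal(extended_modularity(bt, cover), 1 / 6)
  expect_equal(extended_modularity(bt, cover), eq_bruteforce(bt, cover))
  set.seed(83)
  for (rep in 1:25) {
    net <- random_net(sample(5:10, 1))
    k <- sample(2:3, 1)
    cover <- lapply(1:k, function(i)
      sample(net$nodes, sample(2:max(2, n_nodes(net) - 1), 1)))
    cover <- unique(lapply(cover, function(h) sort(unique(h))))
    expect_equal(extended_modularity(net, cover),
                 eq_bruteforce(net, cover), tolerance = 1e-12)
  }
})

test_that("EQ reduces to Newman modularity for disjoint covers", {
  set.seed(89)
  for (rep in 1:200) {
    net <- random_net(sample(5:20, 1))
    k <- sample(2:4, 1)
    memb <- sample(k, n_nodes(net), replace = TRUE)
    cover <- unname(split(net$nodes, memb))
    cover <- cover[lengths(cover) > 0]
    q_igraph <- igraph::modularity(as_igraph_test(net), memb)
    expect_equal(extended_modularity(net, cover), q_igraph,
                 tolerance = 1e-12)
  }
})

test_that("duplicated communities collapse and leave EQ unchanged", {
  bt <- bowtie_net()
  cover <- list(c("a","b","c"), c("c","d","e"))
  doubled <- node_communities(c(cover, cover), bt)
  expect_length(doubled$communities, 2L)
  expect_equal(extended_modularity(bt, doubled),
               extended_modularity(bt, cover))
})

test_that("nearest neighbor maximizes inclusive-neighborhood Jaccard", {
  only <- network_from_edges(rbind(c("a", "b")))
  expect_equal(nearest_neighbor(only, "a"), "b")
  p <- path_net(c("a", "b", "c"))
  expect_equal(nearest_neighbor(p, "b"), "a")  # tie at 2/3, label order
  pend <- network_from_edges(rbind(c("a","b"), c("b","c"), c("a","c"),
                                   c("c","d")))
  expect_equal(nearest_neighbor(pend, "a"), "b")
  iso <- network_from_edges(rbind(c("a","b")), nodes = c("a","b","z"))
  expect_error(nearest_neighbor(iso, "z"), "no neighbors")
})

test_that("IGP weights communities by size and skips isolated nodes", {
  net1 <- network_from_edges(rbind(c("a","b"), c("c","d")))
  r1 <- in_group_proportion(net1, list(c("a","b"), c("c","d")))
  expect_equal(r1$igp, 1)

  whole <- random_net(8)
  expect_equal(in_group_proportion(whole, list(whole$nodes))$igp, 1)

  p <- path_net(c("a", "b", "c"))
  r <- in_group_proportion(p, list(c("a", "b"), "c"))
  expect_equal(r$per_community, c(1, 0))
  expect_equal(r$igp, 2 / 3)
  expect_equal(in_group_proportion(p, list(c("a","b"), "c"),
                                   weighting = "equal")$igp, 1 / 2)
  expect_error(in_group_proportion(p, list()), "empty community")
})

test_that("coverage tracks uncovered nodes one for one", {
  net <- network_from_edges(rbind(c("a","b"), c("b","c"), c("c","d")))
  full <- coverage_stats(net, list(c("a","b"), c("c","d")))
  expect_equal(full$cr, 1); expect_equal(full$un, 0L)
  part <- coverage_stats(net, list(c("a","b","c")))
  expect_equal(part$cr, 3 / 4); expect_equal(part$un, 1L)
  none <- coverage_stats(net, list())
  expect_equal(none$cr, 0); expect_equal(none$un, 4L)
  # adding an uncovered node drops CR and bumps UN by exactly one
  net2 <- network_from_edges(rbind(c("a","b"), c("b","c"), c("c","d")),
                             nodes = c("a","b","c","d","e"))
  part2 <- coverage_stats(net2, list(c("a","b","c")))
  expect_lt(part2$cr, part$cr)
  expect_equal(part2$un, part$un + 1L)
})

test_that("community files round-trip", {
  cover <- list(c("a", "b", "c"), c("c", "d"))
  f <- withr::local_tempfile()
  write_communities(cover, f)
  expect_equal(read_communities(f), cover)
})
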