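test_that("Jaccard link similarity matches the worked hub example", {
  net <- fig_example_net()
  # n+(b) = {a,b,d,e,f}, n+(c) = {a,c,e,f,g}: intersection 3, union 7
  expect_equal(jaccard_link_similarity(net, c("a","b"), c("a","c")), 3 / 7)
})

test_that("Jaccard link similarity on forced small cases", {
  tri <- triangle_net()
  expect_equal(jaccard_link_similarity(tri, c("a","b"), c("a","c")), 1)
  p <- path_net(c("a", "b", "c"))
  expect_equal(jaccard_link_similarity(p, c("a","b"), c("b","c")), 1 / 3)
  sq <- cycle_net(c("a","b","c","d"))
  expect_error(jaccard_link_similarity(sq, c("a","b"), c("c","d")),
               "share exactly one node")
  expect_error(jaccard_link_similarity(tri, c("a","b"), c("a","z")),
               "unknown node")
})

test_that("extended link similarity reproduces the quadrangle family", {
  cyc <- cycle_net(c("a","b","c","d"))
  expect_equal(extended_link_similarity(cyc, c("a","b"), c("c","d")), 0.5)
  chord <- network_from_edges(rbind(c("a","b"), c("b","c"), c("c","d"),
                                    c("a","d"), c("b","d")))
  expect_equal(extended_link_similarity(chord, c("a","b"), c("c","d")), 0.75)
  k4 <- complete_net(c("a","b","c","d"))
  expect_equal(extended_link_similarity(k4, c("a","b"), c("c","d")), 1)
})

test_that("extended link similarity is zero across components", {
  tt <- two_triangles()
  expect_equal(extended_link_similarity(tt, c("a","b"), c("d","e")), 0)
})

test_that("both kernels are symmetric and bounded on random graphs", {
  set.seed(23)
  for (rep in 1:20) {
    net <- random_net(sample(5:9, 1))
    lk <- links(net)
    M <- n_links(net)
    for (draw in 1:5) {
      pq <- sample.int(M, 2, replace = TRUE)
      e1 <- c(lk$from[pq[1]], lk$to[pq[1]])
      e2 <- c(lk$from[pq[2]], lk$to[pq[2]])
      v1 <- extended_link_similarity(net, e1, e2)
      expect_identical(v1, extended_link_similarity(net, e2, e1))
      expect_gte(v1, 0); expect_lte(v1, 1)
      shared <- intersect(e1, e2)
      if (length(shared) == 1L) {
        j <- jaccard_link_similarity(net, e1, e2)
        expect_identical(j, jaccard_link_similarity(net, e2, e1))
        expect_gte(j, 0); expect_lte(j, 1)
      }
    }
  }
})

test_that("ELS is positive exactly for link pairs within two steps", {
  set.seed(31)
  for (rep in 1:10) {
    net <- random_net(7, p = 0.3)
    lk <- links(net)
    M <- n_links(net)
    nbs <- lapply(net$nodes, function(v) inclusive_neighborhood(net, v))
    names(nbs) <- net$nodes
    for (p in seq_len(min(M, 4))) for (q in seq_len(M)) {
      e1 <- c(lk$from[p], lk$to[p]); e2 <- c(lk$from[q], lk$to[q])
      couples <- any(vapply(e1, function(x) any(vapply(e2, function(y)
        length(intersect(nbs[[x]], nbs[[y]])) > 0, logical(1))), logical(1)))
      expect_identical(extended_link_similarity(net, e1, e2) > 0, couples)
    }
  }
})

test_that("transform matrices agree with the kernels entry by entry", {
  net <- fig_example_net()
  lk <- links(net)
  M <- n_links(net)
  selc <- build_similarity_matrix(net, "ELC")
  Selc <- as.matrix(selc$S)
  for (p in 1:M) for (q in 1:M) {
    e1 <- c(lk$from[p], lk$to[p]); e2 <- c(lk$from[q], lk$to[q])
    want <- if (p == q) 1 else extended_link_similarity(net, e1, e2)
    expect_equal(Selc[p, q], want)
  }
  slc <- build_similarity_matrix(net, "LC")
  Slc <- as.matrix(slc$S)
  for (p in 1:M) for (q in 1:M) {
    if (p == q) { expect_equal(Slc[p, q], 1); next }
    e1 <- c(lk$from[p], lk$to[p]); e2 <- c(lk$from[q], lk$to[q])
    want <- if (length(intersect(e1, e2)) == 1L)
      jaccard_link_similarity(net, e1, e2) else 0
    expect_equal(Slc[p, q], want)
  }
})

test_that("LC matrix of a path has the single expected off-diagonal pair", {
  p <- path_net(c("a", "b", "c"))
  S <- as.matrix(build_similarity_matrix(p, "LC")$S)
  expect_equal(S, matrix(c(1, 1/3, 1/3, 1), 2, 2))
})

test_that("ELC matrix is block-diagonal across components", {
  tt <- two_triangles()
  S <- as.matrix(build_similarity_matrix(tt, "ELC")$S)
  # canonical order puts the a,b,c triangle links first
  expect_true(all(S[1:3, 4:6] == 0))
  expect_true(all(S[1:3, 1:3] > 0))
})

test_that("the ELS matrix is at least as dense as the Jaccard matrix", {
  set.seed(53)
  nets <- c(list(fig_example_net(), two_triangles(),
                 cycle_net(letters[1:6])),
            lapply(1:10, function(i) random_net(sample(5:10, 1))))
  for (net in nets) {
    expect_gte(n_similar_pairs(build_similarity_matrix(net, "ELC")),
               n_similar_pairs(build_similarity_matrix(net, "LC")))
  }
})

test_that("similarity dump writes triples plus the link map", {
  net <- triangle_net()
  sim <- build_similarity_matrix(net, "ELC")
  f <- withr::local_tempfile()
  write_similarity_matrix(sim, f)
  tr <- utils::read.table(f)
  expect_equal(nrow(tr), n_similar_pairs(sim))
  expect_true(file.exists(paste0(f, ".links")))
})
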