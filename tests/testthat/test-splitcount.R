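test_that("split counts match hand-checkable trees and the min-cut oracle", {
  q <- quartet_tree()
  expect_equal(count_splits(q, prefix_map(q))$s, 1L)

  ct <- caterpillar_tree()
  mct <- prefix_map(ct)
  oracle <- min_cut_bruteforce(ct, mct)
  expect_equal(oracle, 2L)
  expect_equal(count_splits(ct, mct)$s, oracle)

  # one domain empty: s = 0, no split edges
  all_a <- domain_map(data.frame(leaf = q$tip.label, domain = "A"))
  r0 <- count_splits(q, all_a)
  expect_equal(r0$s, 0L)
  expect_equal(nrow(r0$splits), 0)
  expect_equal(min_cut_bruteforce(q, all_a), 0L)
})

test_that("split edges are located at domain-subtree LCAs with parent p", {
  q <- quartet_tree()
  loc <- locate_split_nodes(q, prefix_map(q))
  expect_equal(nrow(loc), 1)
  # the one split edge hangs off the root; its lca is one of the cherries
  expect_equal(loc$parent_node, ape::Ntip(q) + 1L)

  t3 <- read_newick("((b1,(a1,b2)),b3);")
  loc3 <- locate_split_nodes(t3, prefix_map(t3))
  expect_equal(nrow(loc3), 1)
  expect_equal(loc3$lca_label, "a1")  # single archaeal leaf is its own lca
  # p is the (a1,b2) node: parent of both a1 and b2
  edge <- t3$edge
  a1 <- match("a1", t3$tip.label)
  b2 <- match("b2", t3$tip.label)
  expect_equal(loc3$parent_node, edge[edge[, 2] == a1, 1])
  expect_equal(loc3$parent_node, edge[edge[, 2] == b2, 1])

  ct <- caterpillar_tree()
  expect_equal(nrow(locate_split_nodes(ct, prefix_map(ct))),
               count_splits(ct, prefix_map(ct))$s)
})

test_that("support is read at p and averaged across splits", {
  tr <- read_newick("((a1,a2)0.93,(b1,b2)0.93)0.5;")
  res <- count_splits(tr, prefix_map(tr))
  expect_equal(res$s, 1L)
  # p = root here, support 0.5; per-split values come from p, not the lca
  expect_equal(res$mean_support, 0.5)

  loc <- locate_split_nodes(tr, prefix_map(tr))
  sup <- split_support(tr, loc)
  expect_equal(sup$mean, 0.5)

  # two B islands in an A matrix: two splits, parent supports 0.8 and 0.6
  tr2 <- read_newick("((b1,(a1,a2)0.5)0.8,(b2,(a3,a4)0.5)0.6);")
  m2 <- prefix_map(tr2)
  res2 <- count_splits(tr2, m2)
  expect_equal(res2$s, 2L)
  expect_equal(min_cut_bruteforce(tr2, m2), 2L)
  expect_setequal(res2$splits$support, c(0.8, 0.6))
  expect_equal(res2$mean_support, 0.7)

  # unannotated root as p: undefined support, flagged as NA
  bare <- quartet_tree()
  resb <- count_splits(bare, prefix_map(bare))
  expect_true(is.na(resb$splits$support))
  expect_true(is.na(resb$mean_support))
})

test_that("s is invariant under label swap and ignores branch lengths", {
  set.seed(11)
  for (i in 1:25) {
    tr <- rand_tree(sample(4:12, 1))
    m <- rand_map(tr)
    swapped <- m
    swapped$domain <- ifelse(m$domain == "A", "B", "A")
    s1 <- count_splits(tr, m)$s
    expect_identical(s1, count_splits(tr, swapped)$s)
    # zero / absent lengths are legal: s is purely topological
    no_len <- tr
    no_len$edge.length <- NULL
    expect_identical(count_splits(no_len, m)$s, s1)
    zero_len <- tr
    zero_len$edge.length <- rep(0, nrow(tr$edge))
    expect_identical(count_splits(zero_len, m)$s, s1)
  }
})

test_that("multifurcations are scored exactly, not by naive state-set union", {
  # 4-way polytomy with two A and two B children: two changes are needed
  # (a union/intersection Fitch generalization would report one)
  tp <- read_newick("((a1,a2,b1,b2),(a3,b3));")
  m <- prefix_map(tp)
  expect_equal(count_splits(tp, m)$s, min_cut_bruteforce(tp, m))
  expect_equal(count_splits(tp, m)$s, 3L)

  # random polytomous trees vs the oracle
  set.seed(23)
  for (i in 1:15) {
    tr <- ape::di2multi(ape::rtree(sample(5:9, 1), rooted = TRUE), tol = 0.4)
    tr$edge.length <- NULL
    tr$tip.label <- paste0("t", seq_len(ape::Ntip(tr)))
    m <- rand_map(tr)
    expect_equal(count_splits(tr, m)$s, min_cut_bruteforce(tr, m))
  }
})

test_that("parsimony agrees with an independent Sankoff implementation", {
  skip_if_not_installed("phangorn")
  set.seed(37)
  for (i in 1:40) {
    tr <- rand_tree(sample(5:40, 1))
    m <- rand_map(tr)
    states <- setNames(m$domain, m$leaf)[tr$tip.label]
    pd <- phangorn::phyDat(matrix(states, ncol = 1,
                                  dimnames = list(tr$tip.label, NULL)),
                           type = "USER", levels = c("A", "B"))
    expect_equal(count_splits(tr, m)$s,
                 as.integer(phangorn::parsimony(tr, pd, method = "sankoff")))
  }
})

test_that("planting one transfer into a clean tree raises s by exactly 1", {
  set.seed(53)
  for (k in 0:4) {
    sim_k <- simulate_tree(n_A = 8, n_B = 8, stem_length = 1,
                           within_rate = 0.2, n_transfers = k)
    sim_k1 <- simulate_tree(n_A = 8, n_B = 8, stem_length = 1,
                            within_rate = 0.2, n_transfers = k + 1)
    expect_equal(count_splits(sim_k1$tree, sim_k1$map)$s,
                 count_splits(sim_k$tree, sim_k$map)$s + 1L)
  }
})

test_that("count_splits rejects unmapped leaves; oracle refuses big trees", {
  q <- quartet_tree()
  part <- domain_map(data.frame(leaf = c("a1", "a2", "b1"),
                                domain = c("A", "A", "B")))
  expect_error(count_splits(q, part), "unmapped")
  big <- rand_tree(30)
  expect_error(min_cut_bruteforce(big, rand_map(big)), "22 edges")
})

test_that("split_result tidiers expose splits and the one-row summary", {
  ct <- caterpillar_tree()
  res <- count_splits(ct, prefix_map(ct))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), res$s)
  gl <- glance(res)
  expect_equal(gl$s, 2L)
  expect_equal(gl$n_A, 3)
  expect_equal(gl$n_B, 2)
})
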