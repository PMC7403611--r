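test_that("newick parsing keeps lengths, supports, and topology", {
  tr <- read_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(sort(tr$tip.label), c("a1", "a2", "b1", "b2"))
  expect_true(all(tr$edge.length == 1))

  sup_only <- read_newick("((a1,a2)0.93,(b1,b2)0.93);")
  expect_null(sup_only$edge.length)
  expect_equal(support_values(sup_only), c(NA, 0.93, 0.93))

  # round trip: read -> serialize -> read
  rt <- read_newick(write_newick(tr))
  expect_equal(ape::cophenetic.phylo(rt), ape::cophenetic.phylo(tr))
  rt2 <- read_newick(write_newick(sup_only))
  expect_equal(support_values(rt2), support_values(sup_only))
})

test_that("newick validation rejects duplicates and junk", {
  expect_error(read_newick("((a1:1,a1:1):1,(b1:1,b2:1):1);"), "duplicate")
  expect_error(read_newick("not a tree at all"), "cannot read tree")
})

test_that("support normalization rescales only an unambiguous 0-100 scale", {
  tr <- read_newick("((a1,a2)93,(b1,b2)68);")
  expect_equal(support_values(tr), c(NA, 93, 68))
  expect_equal(support_values(tr, normalize = TRUE), c(NA, 0.93, 0.68))
  # mixed/0-1 scale: never rescaled
  tr2 <- read_newick("((a1,a2)0.93,(b1,b2)0.68);")
  expect_equal(support_values(tr2, normalize = TRUE), c(NA, 0.93, 0.68))
})

test_that("domain maps parse from tables, files, and pattern rules", {
  q <- quartet_tree()
  tab <- data.frame(leaf = c("a1", "a2", "b1", "b2"),
                    domain = c("A", "A", "B", "B"))
  m1 <- domain_map(tab)
  m2 <- domain_map(list(A = "^a", B = "^b"), tree = q)
  expect_equal(dplyr::arrange(m1, leaf), dplyr::arrange(m2, leaf))
  expect_equal(sum(m1$domain == "A"), 2)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expect_equal(dplyr::arrange(domain_map(tsv), leaf), dplyr::arrange(m1, leaf))
})

test_that("domain map contradictions and extra labels are errors", {
  expect_error(
    domain_map(data.frame(leaf = c("a1", "a1"), domain = c("A", "B"))),
    "two different domains"
  )
  expect_error(
    domain_map(data.frame(leaf = c("a1", "b1", "e1"),
                          domain = c("A", "B", "E"))),
    "more than two"
  )
  # duplicate consistent rows are fine
  expect_equal(nrow(domain_map(data.frame(leaf = c("a1", "a1"),
                                          domain = c("A", "A")))), 1)
})

test_that("validate_pair flags eligibility for s and for the ratios", {
  q <- quartet_tree()
  v <- validate_pair(q, prefix_map(q))
  expect_true(v$eligible_splits)
  expect_true(v$eligible_ratios)
  expect_equal(v$n_A + v$n_B + v$n_unmapped, ape::Ntip(q))

  # one domain absent: unusable altogether (inclusion rule)
  all_b <- domain_map(data.frame(leaf = q$tip.label, domain = "B"))
  v2 <- validate_pair(q, all_b)
  expect_false(v2$eligible_splits)
  expect_false(v2$eligible_ratios)

  # a single A leaf: s is fine, ratios are not
  one_a <- domain_map(data.frame(leaf = q$tip.label,
                                 domain = c("A", "B", "B", "B")))
  v3 <- validate_pair(q, one_a)
  expect_true(v3$eligible_splits)
  expect_false(v3$eligible_ratios)

  # unmapped leaves are listed, never dropped silently
  part <- domain_map(data.frame(leaf = c("a1", "a2", "b1"),
                                domain = c("A", "A", "B")))
  v4 <- validate_pair(q, part)
  expect_equal(v4$n_unmapped, 1)
  expect_equal(v4$unmapped[[1]], "b2")
  expect_false(v4$eligible_splits)
})

test_that("pruning preserves pairwise path lengths among kept leaves", {
  q <- quartet_tree()
  p <- prune_leaves(q, c("a1", "a2", "b1"))
  expect_equal(ape::Ntip(p), 3)
  expect_equal(pairwise_distance_bruteforce(p, "a1", "a2"), 2)

  expect_identical(prune_leaves(q, q$tip.label), q)

  ct <- caterpillar_tree()
  ct$edge.length <- seq_len(nrow(ct$edge)) / 10
  before <- pairwise_distance_bruteforce(ct, "a1", "b1")
  two <- prune_leaves(ct, c("a1", "b1"))
  expect_equal(ape::Ntip(two), 2)
  expect_equal(sum(two$edge.length), before)

  # property: random trees, random kept subsets, all pairwise distances kept
  set.seed(71)
  for (i in 1:20) {
    tr <- rand_tree(sample(6:15, 1))
    keep <- sample(tr$tip.label, sample(3:ape::Ntip(tr), 1))
    pr <- prune_leaves(tr, keep)
    for (pair in list(sample(keep, 2), sample(keep, 2))) {
      expect_equal(pairwise_distance_bruteforce(pr, pair[1], pair[2]),
                   pairwise_distance_bruteforce(tr, pair[1], pair[2]),
                   tolerance = 1e-12)
    }
  }
  expect_error(prune_leaves(q, "a1"), "at least 2")
  expect_error(prune_leaves(q, c("a1", "zz")), "not in tree")
})

test_that("report writing is deterministic, NA-explicit, header-stable", {
  q <- quartet_tree()
  br <- run_batch(q, prefix_map(q))
  dest <- withr::local_tempfile(fileext = ".tsv")
  write_report(br$report, dest)
  lines <- readLines(dest)
  expect_length(lines, 2)
  expect_equal(strsplit(lines[1], "\t")[[1]],
               c("tree_id", "n_A", "n_B", "s", "mean_support",
                 "per_split_supports", "d_AA", "d_BB", "d_AB",
                 "D_bar", "D_min", "flags"))

  # degenerate record: undefined statistics serialize as the string NA
  rec <- tibble::tibble(tree_id = "deg", n_A = 1, n_B = 3, s = 1,
                        d_AA = NA_real_, D_bar = NA_real_)
  write_report(rec, dest)
  cells <- strsplit(readLines(dest)[2], "\t")[[1]]
  expect_equal(cells[7], "NA")   # d_AA
  expect_equal(cells[10], "NA")  # D_bar

  # empty record list: header only
  write_report(tibble::tibble(), dest)
  expect_length(readLines(dest), 1)

  # floats at 6 significant digits
  write_report(tibble::tibble(tree_id = "x", d_AA = 1.23456789), dest)
  expect_match(readLines(dest)[2], "1\\.23457")
})
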