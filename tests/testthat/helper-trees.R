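# Fixture builders shared across test files. Everything is generated in
# code; no stored tree files.

quartet_tree <- function() {
  read_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
}

long_stem_tree <- function() {
  read_newick("((a1:0.1,a2:0.1):5,(b1:0.1,b2:0.1):5);")
}

# interleaved caterpillar: minimal separation needs 2 edges
caterpillar_tree <- function() {
  read_newick("(a1,(b1,(a2,(b2,a3))));")
}

prefix_map <- function(tree) {
  domain_map(list(A = "^a", B = "^b"), tree = tree)
}

# random rooted binary tree with exponential branch lengths, labels t1..tn
rand_tree <- function(n, mean_len = 0.5) {
  tr <- ape::rtree(n, rooted = TRUE, br = NULL)
  tr$tip.label <- paste0("t", seq_len(n))
  tr$edge.length <- rexp(nrow(tr$edge), rate = 1 / mean_len)
  tr
}

# random 2-domain labeling with both domains non-empty
rand_map <- function(tree) {
  n <- ape::Ntip(tree)
  repeat {
    dom <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(dom)) == 2) break
  }
  tibble::tibble(leaf = tree$tip.label, domain = dom)
}

# All rooted binary tree shapes (unlabeled) with n leaves, as newick shape
# strings with "x" leaf placeholders, deduplicated by canonical ordering.
all_shapes <- function(n) {
  memo <- new.env(parent = emptyenv())
  shapes <- function(k) {
    key <- as.character(k)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- if (k == 1) "x" else {
      res <- character(0)
      for (i in seq_len(k %/% 2)) {
        for (l in shapes(i)) for (r in shapes(k - i)) {
          pair <- sort(c(l, r))
          res <- c(res, paste0("(", pair[1], ",", pair[2], ")"))
        }
      }
      unique(res)
    }
    memo[[key]] <- out
    out
  }
  shapes(n)
}

# Instantiate a shape string as a phylo with leaves L1..Ln
shape_to_tree <- function(shape) {
  n <- lengths(regmatches(shape, gregexpr("x", shape)))
  for (i in seq_len(n)) shape <- sub("x", paste0("L", i), shape, fixed = TRUE)
  read_newick(paste0(shape, ";"))
}

# All 2-domain labelings of n leaves with both domains present:
# matrix of "A"/"B", one row per labeling
all_labelings <- function(n) {
  g <- as.matrix(expand.grid(rep(list(c("A", "B")), n),
                             stringsAsFactors = FALSE))
  keep <- apply(g, 1, function(r) length(unique(r)) == 2)
  g[keep, , drop = FALSE]
}

# Independent O(n^2) distance means via ape's cophenetic matrix
cophenetic_means <- function(tree, map) {
  dmat <- ape::cophenetic.phylo(tree)
  dom <- setNames(map$domain, map$leaf)[rownames(dmat)]
  a <- which(dom == "A")
  b <- which(dom == "B")
  d_aa <- if (length(a) >= 2) mean(dmat[a, a][upper.tri(dmat[a, a])]) else NA_real_
  d_bb <- if (length(b) >= 2) mean(dmat[b, b][upper.tri(dmat[b, b])]) else NA_real_
  d_ab <- if (length(a) >= 1 && length(b) >= 1) mean(dmat[a, b, drop = FALSE]) else NA_real_
  list(d_AA = d_aa, d_BB = d_bb, d_AB = d_ab)
}
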