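# Synthetic trees with planted domain structure.
#
# A simulated family starts as two independent random subtrees (one per
# domain, random topology, i.i.d. exponential edge lengths) joined by an
# interdomain stem. With no transfers the tree has exactly one
# archaea:bacteria branch (the stem), so the planted split count is 1;
# each guarded cross-domain leaf regraft adds exactly one more. Guarded
# placement attaches each transferred B leaf onto the pendant edge of a
# distinct A leaf, so every transferred leaf forms its own single-leaf
# "island" whose separation needs exactly one extra cut -- giving provable
# ground truth s = 1 + n_transfers. The stem length tunes the strength of
# the domain signal: D_bar decreases toward 0 as the stem grows relative
# to within-domain depth.

# Random rooted subtree with exponential edge lengths (mean within_rate)
# and tips labeled prefix1..prefixN. Uses the current RNG state.
random_subtree <- function(n, prefix, within_rate) {
  stopifnot(n >= 2)
  tr <- ape::rtree(n, rooted = TRUE, br = NULL)
  tr$tip.label <- paste0(prefix, seq_len(n))
  tr$edge.length <- rexp(nrow(tr$edge), rate = 1 / within_rate)
  tr
}

# Join two rooted subtrees by a stem: each subtree hangs from the new root
# by an edge of stem/2.
join_by_stem <- function(tree_a, tree_b, stem_length) {
  half <- stem_length / 2
  na <- sub(";$", "", ape::write.tree(tree_a))
  nb <- sub(";$", "", ape::write.tree(tree_b))
  ape::read.tree(text = paste0("(", na, ":", format(half, digits = 17),
                               ",", nb, ":", format(half, digits = 17), ");"))
}

# Attach a new leaf onto edge `edge_index` of `tree` at `position` from the
# parent end, with a pendant edge of `pendant_length`. Pure edge-matrix
# surgery; node labels are dropped (synthetic trees carry none).
attach_leaf <- function(tree, edge_index, label, position, pendant_length) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  stopifnot(edge_index >= 1, edge_index <= nrow(tree$edge))
  len <- tree$edge.length[edge_index]
  stopifnot(position >= 0, position <= len)
  # renumber: old tips keep 1..nt, new tip = nt+1, old internals shift by 1,
  # new internal node appended last
  remap <- function(v) ifelse(v > nt, v + 1L, v)
  new_tip <- nt + 1L
  new_internal <- nt + 1L + nn + 1L
  edge <- apply(tree$edge, 2, remap)
  p <- edge[edge_index, 1]
  ch <- edge[edge_index, 2]
  edge <- edge[-edge_index, , drop = FALSE]
  lens <- tree$edge.length[-edge_index]
  edge <- rbind(edge,
                c(p, new_internal),
                c(new_internal, ch),
                c(new_internal, new_tip))
  lens <- c(lens, position, len - position, pendant_length)
  out <- list(edge = edge, edge.length = lens,
              tip.label = c(tree$tip.label, label),
              Nnode = nn + 1L)
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  out
}

#' Simulate a tree with planted domain structure
#'
#' Builds a gene-family tree with known ground truth: two independent
#' random subtrees (domains A and B; `n_A` and `n_B` leaves named
#' `a1..an`, `b1..bm`; exponential edge lengths with mean `within_rate`)
#' joined by an interdomain stem of length `stem_length`, followed by
#' `n_transfers` guarded cross-domain leaf regrafts (B leaves moved onto
#' pendant edges of distinct A leaves), emulating interdomain gene
#' transfer. Guarded placement guarantees a planted split count of
#' `1 + n_transfers`. For `n_transfers = 0` the realized `D_bar` is also
#' recorded, computed from the realized branch lengths by an independent
#' path-sum route ([ape::cophenetic.phylo()]).
#'
#' @param n_A,n_B Leaves per domain (each >= 2).
#' @param stem_length Interdomain stem length (>= 0), substitutions/site.
#' @param within_rate Mean intradomain edge length (> 0).
#' @param n_transfers Number of planted transfers, at most
#'   `min(n_A, n_B) - 1`: each transfer needs its own A-leaf host, and both
#'   the B clade and the untouched part of the A clade must stay non-empty
#'   or a cheaper cut than the planted one exists (isolating every A leaf
#'   costs only `n_A` edges).
#' @param seed Optional integer; when given, seeds the RNG for a fully
#'   reproducible tree.
#' @return List with `tree` (`phylo`), `map` (domain map tibble) and
#'   `truth` (one-row tibble: `n_A`, `n_B`, `stem_length`, `within_rate`,
#'   `n_transfers`, `planted_s`, `true_D_bar` -- `NA` when transfers were
#'   planted).
#' @examples
#' sim <- simulate_tree(n_A = 8, n_B = 8, stem_length = 2,
#'                      within_rate = 0.2, seed = 7)
#' count_splits(sim$tree, sim$map)$s  # recovers the planted s = 1
#' @export
simulate_tree <- function(n_A, n_B, stem_length = 1, within_rate = 0.1,
                          n_transfers = 0, seed = NULL) {
  stopifnot(n_A >= 2, n_B >= 2, stem_length >= 0, within_rate > 0,
            n_transfers >= 0)
  if (n_transfers > min(n_A, n_B) - 1) {
    abort("n_transfers must be <= min(n_A, n_B) - 1 for guarded placement")
  }
  if (!is.null(seed)) set.seed(seed)
  tree_a <- random_subtree(n_A, "a", within_rate)
  tree_b <- random_subtree(n_B, "b", within_rate)
  tree <- join_by_stem(tree_a, tree_b, stem_length)
  if (n_transfers > 0) {
    moved <- sample(paste0("b", seq_len(n_B)), n_transfers)
    hosts <- sample(paste0("a", seq_len(n_A)), n_transfers)
    for (i in seq_len(n_transfers)) {
      tree <- ape::drop.tip(tree, moved[i])
      host_tip <- match(hosts[i], tree$tip.label)
      host_edge <- which(tree$edge[, 2] == host_tip)
      tree <- attach_leaf(tree, host_edge, moved[i],
                          position = tree$edge.length[host_edge] / 2,
                          pendant_length = rexp(1, rate = 1 / within_rate))
    }
  }
  map <- tibble(leaf = tree$tip.label,
                domain = ifelse(grepl("^a", tree$tip.label), "A", "B"))
  true_d_bar <- NA_real_
  if (n_transfers == 0) {
    dmat <- ape::cophenetic.phylo(tree)
    a_ix <- grep("^a", rownames(dmat))
    b_ix <- grep("^b", rownames(dmat))
    d_aa <- mean(dmat[a_ix, a_ix][upper.tri(dmat[a_ix, a_ix])])
    d_bb <- mean(dmat[b_ix, b_ix][upper.tri(dmat[b_ix, b_ix])])
    d_ab <- mean(dmat[a_ix, b_ix])
    if (d_ab > 0) true_d_bar <- (d_aa + d_bb) / (2 * d_ab)
  }
  list(
    tree = tree,
    map = map,
    truth = tibble(n_A = n_A, n_B = n_B, stem_length = stem_length,
                   within_rate = within_rate, n_transfers = n_transfers,
                   planted_s = 1L + as.integer(n_transfers),
                   true_D_bar = true_d_bar)
  )
}

#' Simulate a batch of trees to disk
#'
#' Runs [simulate_tree()] for every row of `specs` and writes, per tree, a
#' newick file (`<name>.nwk`) and a domain-map TSV (`<name>.map.tsv`),
#' plus a single `truth.tsv` with the planted ground truth. Deterministic
#' given the per-row seeds.
#'
#' @param specs Tibble/data frame with columns `name`, `n_A`, `n_B`,
#'   `stem_length`, `within_rate`, `n_transfers`, `seed`.
#' @param dest Output directory (created if needed).
#' @return The truth table, invisibly (one row per tree, with `name`).
#' @export
simulate_batch <- function(specs, dest) {
  specs <- as_tibble(specs)
  need <- c("name", "n_A", "n_B", "stem_length", "within_rate",
            "n_transfers", "seed")
  missing <- setdiff(need, names(specs))
  if (length(missing) > 0) {
    abort(paste0("specs is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(specs$name)) {
    abort(paste0("duplicate output names: ",
                 paste(unique(specs$name[duplicated(specs$name)]),
                       collapse = ", ")))
  }
  dir.create(dest, showWarnings = FALSE, recursive = TRUE)
  truths <- purrr::pmap(specs[need], function(name, n_A, n_B, stem_length,
                                              within_rate, n_transfers, seed) {
    sim <- simulate_tree(n_A, n_B, stem_length, within_rate, n_transfers,
                         seed = seed)
    write_newick(sim$tree, file.path(dest, paste0(name, ".nwk")))
    utils::write.table(sim$map, file.path(dest, paste0(name, ".map.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    dplyr::bind_cols(tibble(name = name), sim$truth)
  })
  truth <- dplyr::bind_rows(truths)
  utils::write.table(truth, file.path(dest, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(truth)
}
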