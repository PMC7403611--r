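# Patristic distance ratio statistics.
#
# For a tree t with archaeal leaf set A (size n) and bacterial set B
# (size m), the mean pairwise patristic distances are
#   d_AA = sum_{i,j} d(a_i, a_j) / (n (n-1))   (ordered pairs; equals the
#   mean over unordered distinct pairs), d_BB analogously, and
#   d_AB = sum_i sum_j d(a_i, b_j) / (n m).
# The ratio statistics are
#   D_bar = (d_AA + d_BB) / (2 d_AB)    and    D_min = min(d_AA, d_BB) / d_AB
# (also written Dav and Dmin). Low D_bar means within-domain diversity is
# small relative to the interdomain distance -- a long interdomain branch.
#
# Rather than summing over all pairs, each edge's contribution is counted
# once: an edge of length l that separates (n1A, n1B) leaves below from
# (n2A, n2B) above lies on n1A*n2A A-A paths, n1B*n2B B-B paths and
# n1A*n2B + n1B*n2A A-B paths. This gives all three sums in one O(edges)
# pass and is checked against brute-force path sums in the tests.

# Per-node leaf counts below each node (tips count themselves).
leaf_counts_below <- function(tree, dom) {
  nt <- ape::Ntip(tree)
  n_nodes <- nt + tree$Nnode
  below_a <- below_b <- numeric(n_nodes)
  below_a[seq_len(nt)] <- as.numeric(dom == "A")
  below_b[seq_len(nt)] <- as.numeric(dom == "B")
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]
    ch <- eo[k, 2]
    below_a[p] <- below_a[p] + below_a[ch]
    below_b[p] <- below_b[p] + below_b[ch]
  }
  list(A = below_a, B = below_b)
}

#' Mean intra- and inter-domain patristic distances
#'
#' Computes the mean pairwise patristic distance (sum of branch lengths on
#' the leaf-to-leaf path) within domain A (`d_AA`), within domain B
#' (`d_BB`) and between domains (`d_AB`), using the edge-contribution
#' algorithm (single pass over edges). `d_AA` is defined only when
#' `n >= 2`, `d_BB` when `m >= 2`, `d_AB` when both domains are non-empty;
#' undefined means are `NA` and recorded in `flags`.
#'
#' @param tree A `phylo` object with complete non-negative branch lengths.
#' @param map A domain map covering every leaf, see [domain_map()].
#' @return One-row tibble of class `distance_summary` columns: `n`, `m`,
#'   `d_AA`, `d_BB`, `d_AB`, `D_bar`, `D_min` (ratios `NA` until
#'   [compute_ratios()]), `flags`.
#' @examples
#' tr <- read_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
#' dm <- domain_map(list(A = "^a", B = "^b"), tree = tr)
#' mean_pairwise_distances(tr, dm)
#' @export
mean_pairwise_distances <- function(tree, map) {
  dom <- domain_vector(tree, map)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    abort(paste0("missing branch length on edge ",
                 which(is.na(tree$edge.length))[1]))
  }
  if (any(tree$edge.length < 0)) {
    abort(paste0("negative branch length on edge ",
                 which(tree$edge.length < 0)[1]))
  }
  n <- sum(dom == "A")
  m <- sum(dom == "B")
  below <- leaf_counts_below(tree, dom)
  ch <- tree$edge[, 2]
  len <- tree$edge.length
  b_a <- below$A[ch]
  b_b <- below$B[ch]
  o_a <- n - b_a   # leaves on the rootward side of each edge
  o_b <- m - b_b
  sum_aa <- sum(len * b_a * o_a)               # unordered A-A path sum
  sum_bb <- sum(len * b_b * o_b)
  sum_ab <- sum(len * (b_a * o_b + b_b * o_a))
  flags <- character(0)
  d_aa <- if (n >= 2) sum_aa / (n * (n - 1) / 2) else { flags <- c(flags, "d_AA_undefined"); NA_real_ }
  d_bb <- if (m >= 2) sum_bb / (m * (m - 1) / 2) else { flags <- c(flags, "d_BB_undefined"); NA_real_ }
  d_ab <- if (n >= 1 && m >= 1) sum_ab / (n * m) else { flags <- c(flags, "d_AB_undefined"); NA_real_ }
  out <- tibble(n = n, m = m, d_AA = d_aa, d_BB = d_bb, d_AB = d_ab,
                D_bar = NA_real_, D_min = NA_real_,
                flags = paste(flags, collapse = ";"))
  class(out) <- c("distance_summary", class(out))
  out
}

#' Fill in the distance ratio statistics
#'
#' Adds `D_bar = (d_AA + d_BB) / (2 d_AB)` (alias Dav) and
#' `D_min = min(d_AA, d_BB) / d_AB` (alias Dmin) to a distance summary.
#' Ratios are undefined (`NA`, with an explanatory flag) when any required
#' mean is undefined or when `d_AB = 0` (a tree with no interdomain distance
#' signal carries no ratio, not an infinity). `D_min <= D_bar` always holds
#' when both are defined, since a minimum never exceeds a mean.
#'
#' @param summary A `distance_summary` tibble from
#'   [mean_pairwise_distances()] (or any tibble with `d_AA`, `d_BB`,
#'   `d_AB`, `flags`). Vectorized over rows.
#' @return The summary with `D_bar`, `D_min` and `flags` updated.
#' @export
compute_ratios <- function(summary) {
  need <- c("d_AA", "d_BB", "d_AB")
  stopifnot(all(need %in% names(summary)))
  if (!"flags" %in% names(summary)) summary$flags <- ""
  defined <- !is.na(summary$d_AA) & !is.na(summary$d_BB) & !is.na(summary$d_AB)
  zero_ab <- defined & summary$d_AB == 0
  ok <- defined & !zero_ab
  summary$D_bar <- ifelse(ok, (summary$d_AA + summary$d_BB) / (2 * summary$d_AB),
                          NA_real_)
  summary$D_min <- ifelse(ok, pmin(summary$d_AA, summary$d_BB) / summary$d_AB,
                          NA_real_)
  add_flag <- function(flags, add, where) {
    ifelse(where, ifelse(flags == "", add, paste(flags, add, sep = ";")), flags)
  }
  summary$flags <- add_flag(summary$flags, "d_AB_zero", zero_ab)
  summary$flags <- add_flag(summary$flags, "ratios_undefined", !ok)
  if (!inherits(summary, "distance_summary")) {
    class(summary) <- c("distance_summary", class(summary))
  }
  summary
}

#' Distance summary for one tree: means plus ratios
#'
#' Convenience composition of [mean_pairwise_distances()] and
#' [compute_ratios()].
#'
#' @inheritParams mean_pairwise_distances
#' @return One-row `distance_summary` tibble with all fields filled.
#' @examples
#' tr <- read_newick("((a1:0.1,a2:0.1):5,(b1:0.1,b2:0.1):5);")
#' dm <- domain_map(list(A = "^a", B = "^b"), tree = tr)
#' domain_distances(tr, dm)  # D_bar ~ 0.0196: long interdomain stem
#' @export
domain_distances <- function(tree, map) {
  compute_ratios(mean_pairwise_distances(tree, map))
}

#' Patristic distance between two leaves by explicit path walking
#'
#' Independent brute-force oracle: walks each leaf's ancestor chain to the
#' root and sums branch lengths over the symmetric difference of the two
#' chains (the unique simple path between the leaves).
#'
#' @param tree A `phylo` object with branch lengths.
#' @param leaf1,leaf2 Leaf labels.
#' @return The path length (0 for a leaf with itself).
#' @export
pairwise_distance_bruteforce <- function(tree, leaf1, leaf2) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  i <- match(leaf1, tree$tip.label)
  j <- match(leaf2, tree$tip.label)
  if (is.na(i)) abort(paste0("unknown leaf: ", leaf1))
  if (is.na(j)) abort(paste0("unknown leaf: ", leaf2))
  if (i == j) return(0)
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  n_nodes <- nt + tree$Nnode
  parent_of <- integer(n_nodes)
  edge_len <- numeric(n_nodes)   # length of edge above each node
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_len[tree$edge[, 2]] <- tree$edge.length
  chain <- function(v) {
    out <- integer(0)
    while (v != root) { out <- c(out, v); v <- parent_of[v] }
    out
  }
  ci <- chain(i)
  cj <- chain(j)
  on_path <- c(setdiff(ci, cj), setdiff(cj, ci))
  sum(edge_len[on_path])
}
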