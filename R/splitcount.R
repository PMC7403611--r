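# Interdomain split counting.
#
# The split count s of a tree with leaves labeled A/B is the minimum number
# of edges whose removal disconnects every A leaf from every B leaf. On a
# tree this equals the parsimony score of the two-state leaf character:
# any most-parsimonious assignment of states to internal nodes has exactly s
# state-change edges, and those edges form a minimal separating set. We
# compute it with an exact two-state Sankoff-style dynamic program
# (identical to Fitch on binary trees, exact on multifurcations, where the
# naive union/intersection generalization of Fitch can undercount).
# Branch lengths play no role; s is purely topological and invariant under
# rerooting.

# Postorder cost DP. Returns list(cost = N x 2 matrix of minimal change
# counts with node forced to state A (col 1) or B (col 2), root).
split_cost_dp <- function(tree, dom) {
  nt <- ape::Ntip(tree)
  n_nodes <- nt + tree$Nnode
  cost <- matrix(0, nrow = n_nodes, ncol = 2)
  cost[seq_len(nt), 1] <- ifelse(dom == "A", 0, Inf)
  cost[seq_len(nt), 2] <- ifelse(dom == "B", 0, Inf)
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]
    ch <- eo[k, 2]
    cost[p, 1] <- cost[p, 1] + min(cost[ch, 1], cost[ch, 2] + 1)
    cost[p, 2] <- cost[p, 2] + min(cost[ch, 2], cost[ch, 1] + 1)
  }
  list(cost = cost, root = nt + 1L)
}

# Deterministic traceback: root tie resolved toward A; on a tie at a child
# the parent's state is kept (DELTRAN), pushing changes leafward.
split_state_assignment <- function(tree, dp) {
  cost <- dp$cost
  root <- dp$root
  n_nodes <- nrow(cost)
  state <- integer(n_nodes)
  state[root] <- if (cost[root, 1] <= cost[root, 2]) 1L else 2L
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in rev(seq_len(nrow(eo)))) {  # preorder: parents before children
    p <- eo[k, 1]
    ch <- eo[k, 2]
    sp <- state[p]
    v <- c(cost[ch, 1] + (sp != 1L), cost[ch, 2] + (sp != 2L))
    state[ch] <- if (v[1] < v[2]) 1L else if (v[2] < v[1]) 2L else sp
  }
  state
}

#' Count interdomain splits
#'
#' Computes the split count `s`: the minimal number of archaea:bacteria
#' branches, i.e. the minimum number of edges whose removal disconnects
#' every A leaf from every B leaf (equivalently the parsimony score of the
#' two-state leaf character). Locates one minimal set of split edges by a
#' deterministic traceback, records for each split the lowest common
#' ancestor node of the separated subtree and its parent node `p`, and
#' aggregates the support values found at those parents.
#'
#' `s = 0` iff one domain is empty; `s >= 1` otherwise. The count is
#' invariant under rerooting and under swapping the two domain labels; the
#' *located* edges (and hence which node is `p`) depend on the rooting as
#' given, since "parent" is only meaningful in a rooted tree.
#'
#' @param tree A `phylo` object (branch lengths ignored; multifurcations
#'   handled natively).
#' @param map A domain map covering every leaf, see [domain_map()].
#' @param normalize_support Passed to [support_values()].
#' @return An object of class `split_result`: list with elements `s`,
#'   `splits` (tibble: `lca_node`, `lca_label`, `parent_node`, `support`),
#'   `mean_support` (`NA` when no split parent carries a support),
#'   `n_A`, `n_B`.
#' @examples
#' tr <- read_newick("((a1,a2)0.9,(b1,b2)0.8);")
#' dm <- domain_map(list(A = "^a", B = "^b"), tree = tr)
#' count_splits(tr, dm)
#' @export
count_splits <- function(tree, map, normalize_support = FALSE) {
  dom <- domain_vector(tree, map)
  if (length(dom) == 0) abort("empty tree")
  nt <- ape::Ntip(tree)
  n_a <- sum(dom == "A")
  n_b <- sum(dom == "B")
  if (n_a == 0 || n_b == 0) {
    res <- list(s = 0L,
                splits = tibble(lca_node = integer(), lca_label = character(),
                                parent_node = integer(), support = double()),
                mean_support = NA_real_, n_A = n_a, n_B = n_b)
    class(res) <- "split_result"
    return(res)
  }
  dp <- split_cost_dp(tree, dom)
  s <- as.integer(min(dp$cost[dp$root, ]))
  state <- split_state_assignment(tree, dp)
  change <- state[tree$edge[, 1]] != state[tree$edge[, 2]]
  lca <- tree$edge[change, 2]
  parent <- tree$edge[change, 1]
  sup <- support_values(tree, normalize = normalize_support)
  labels <- c(tree$tip.label,
              if (is.null(tree$node.label)) rep("", tree$Nnode) else tree$node.label)
  splits <- tibble(
    lca_node = as.integer(lca),
    lca_label = labels[lca],
    parent_node = as.integer(parent),
    support = sup[parent - nt]
  )
  splits <- splits[order(splits$lca_node), , drop = FALSE]
  stopifnot(nrow(splits) == s)  # traceback realizes the minimal count
  mean_sup <- if (all(is.na(splits$support))) NA_real_ else
    mean(splits$support, na.rm = TRUE)
  res <- list(s = s, splits = splits, mean_support = mean_sup,
              n_A = n_a, n_B = n_b)
  class(res) <- "split_result"
  res
}

#' @export
print.split_result <- function(x, ...) {
  cat("Interdomain split count\n")
  cat("  s =", x$s, " (n_A =", x$n_A, ", n_B =", x$n_B, ")\n")
  if (!is.na(x$mean_support)) cat("  mean split support:", x$mean_support, "\n")
  if (nrow(x$splits) > 0) print(x$splits, ...)
  invisible(x)
}

#' @describeIn count_splits Tidy the located splits: one row per split edge.
#' @param x A `split_result`.
#' @param ... Unused.
#' @method tidy split_result
#' @export
tidy.split_result <- function(x, ...) x$splits

#' @describeIn count_splits One-row summary: `s`, `n_A`, `n_B`, `mean_support`.
#' @method glance split_result
#' @export
glance.split_result <- function(x, ...) {
  tibble(s = x$s, n_A = x$n_A, n_B = x$n_B, mean_support = x$mean_support)
}

#' Locate split nodes
#'
#' Returns, for one minimal reconstruction, the lowest common ancestor node
#' of each separated same-domain subtree together with its parent node `p`
#' (the node whose support value annotates the split). The edge above each
#' returned lca is a member of the minimal separating edge set.
#'
#' @inheritParams count_splits
#' @return Tibble with columns `lca_node`, `lca_label`, `parent_node`;
#'   empty when one domain is empty.
#' @export
locate_split_nodes <- function(tree, map) {
  count_splits(tree, map)$splits[c("lca_node", "lca_label", "parent_node")]
}

#' Aggregate support values at split parents
#'
#' Reads the support value at the parent node `p` of each located split and
#' averages the defined ones. A split whose parent carries no numeric
#' support (e.g. an unannotated root) contributes `NA`; the mean is `NA`
#' when no split parent is annotated.
#'
#' @param tree A `phylo` object.
#' @param located Tibble from [locate_split_nodes()] (column `parent_node`).
#' @param normalize Passed to [support_values()].
#' @return List with `per_split` (numeric vector) and `mean`.
#' @export
split_support <- function(tree, located, normalize = FALSE) {
  validate_phylo(tree)
  nt <- ape::Ntip(tree)
  sup <- support_values(tree, normalize = normalize)
  per <- sup[located$parent_node - nt]
  list(per_split = per,
       mean = if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE))
}

#' Exhaustive minimum edge cut (test oracle)
#'
#' Exact minimum number of edges whose removal leaves no connected component
#' containing both an A leaf and a B leaf, found by enumerating edge subsets
#' in increasing size. Exponential: refuses trees with more than 22 edges
#' (a 12-leaf binary tree).
#' Intended as an independent oracle for [count_splits()] on small trees.
#'
#' @inheritParams count_splits
#' @return Integer minimum cut size (0 when one domain is empty).
#' @export
min_cut_bruteforce <- function(tree, map) {
  dom <- domain_vector(tree, map)
  n_edge <- nrow(tree$edge)
  if (n_edge > 22) abort("min_cut_bruteforce refuses trees with > 22 edges")
  if (sum(dom == "A") == 0 || sum(dom == "B") == 0) return(0L)
  nt <- ape::Ntip(tree)
  # edge row index by child node
  edge_of <- integer(nt + tree$Nnode)
  edge_of[tree$edge[, 2]] <- seq_len(n_edge)
  parent_of <- integer(nt + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- nt + 1L
  path_edges <- function(i, j) {
    anc <- function(v) {
      out <- integer(0)
      while (v != root) { out <- c(out, edge_of[v]); v <- parent_of[v] }
      out
    }
    ei <- anc(i); ej <- anc(j)
    c(setdiff(ei, ej), setdiff(ej, ei))
  }
  a_tips <- which(dom == "A")
  b_tips <- which(dom == "B")
  pairs <- expand.grid(a = a_tips, b = b_tips)
  # cover[e, p]: TRUE if edge e lies on the path of A-B pair p
  cover <- matrix(FALSE, nrow = n_edge, ncol = nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    cover[path_edges(pairs$a[p], pairs$b[p]), p] <- TRUE
  }
  # a subset separates A from B iff it hits every A-B path
  for (size in seq_len(n_edge)) {
    subsets <- combn(n_edge, size)
    for (col in seq_len(ncol(subsets))) {
      if (all(colSums(cover[subsets[, col], , drop = FALSE]) > 0)) {
        return(size)
      }
    }
  }
  n_edge  # unreachable: cutting all edges always separates
}
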