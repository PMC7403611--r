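# Leaf-label permutation null model.
#
# Reference distributions of s and D_bar are built by keeping each tree's
# topology and branch lengths fixed and reassigning domain labels to leaves
# at controlled proportions (e.g. 30% A / 70% B, 50/50, 90/10). Exact-count
# shuffling is used: each replicate labels exactly k = round(p * L) leaves
# A (clamped to [1, L-1] so both groups are always non-empty), drawn
# uniformly without replacement.

# 32-bit FNV-1a hash of a string, reduced to a valid set.seed() value.
# Used to derive per-replicate seeds from (master seed, tree_id,
# proportion, replicate) so records are identical regardless of execution
# order.
fnv1a_seed <- function(...) {
  s <- paste(..., sep = "\r")
  h <- 2166136261
  m <- 16777619
  for (b in utf8ToInt(s)) {
    # xor only touches the low byte (b < 256)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # multiply mod 2^32 in two 16-bit halves to stay within double precision
    hi16 <- h %/% 65536
    lo16 <- h %% 65536
    h <- (((hi16 * m) %% 65536) * 65536 + lo16 * m) %% 4294967296
  }
  as.integer(h %% (2^31 - 1))
}

#' Shuffle domain labels on a tree at a fixed proportion
#'
#' Draws a random domain map for the leaves of `tree` with exactly
#' `k = round(proportion * L)` A leaves (clamped to `[1, L-1]` so both
#' groups are non-empty), chosen uniformly without replacement. Topology
#' and branch lengths are untouched. Uses the current RNG state, so a
#' preceding `set.seed()` makes the draw reproducible.
#'
#' @param tree A `phylo` object with `L >= 2` leaves.
#' @param proportion A-fraction, strictly between 0 and 1.
#' @return A domain map tibble (`leaf`, `domain`).
#' @export
shuffle_labels <- function(tree, proportion) {
  validate_phylo(tree)
  if (!(proportion > 0 && proportion < 1)) {
    abort("proportion must be strictly between 0 and 1")
  }
  leaves <- tree$tip.label
  l <- length(leaves)
  if (l < 2) abort("shuffle_labels needs at least 2 leaves")
  k <- round(proportion * l)
  k <- min(max(k, 1L), l - 1L)
  a_leaves <- sample(leaves, k)
  tibble(leaf = leaves,
         domain = ifelse(leaves %in% a_leaves, "A", "B"))
}

#' Null distributions of s and D_bar over label shuffles
#'
#' For every (tree, proportion, replicate) triple, shuffles leaf labels
#' with [shuffle_labels()] and records the split count `s` and, when branch
#' lengths are available, the distance ratio `D_bar` (undefined values are
#' `NA`). Each replicate's RNG stream is derived from
#' `(seed, tree_id, proportion, replicate)`, so results are reproducible
#' and independent of execution order.
#'
#' @param trees A `phylo`, a `multiPhylo`, or a (preferably named) list of
#'   `phylo` objects. Unnamed trees are called `tree_1`, `tree_2`, ...
#' @param proportions Numeric vector of A-fractions in (0, 1).
#' @param replicates Replicates per tree and proportion.
#' @param seed Master seed (integer).
#' @return Object of class `null_result`: list with `records` (tibble:
#'   `tree_id`, `proportion`, `replicate`, `n_A`, `n_B`, `s`, `D_bar`) and
#'   `config`.
#' @examples
#' tr <- read_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
#' nd <- null_distribution(tr, proportions = 0.5, replicates = 50, seed = 1)
#' table(nd$records$s)
#' @export
null_distribution <- function(trees, proportions = c(0.3, 0.5, 0.9),
                              replicates = 100, seed = 1) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1, replicates >= 1,
            all(proportions > 0 & proportions < 1))
  ids <- names(trees)
  if (is.null(ids) || any(ids == "")) {
    ids <- paste0("tree_", seq_along(trees))
  }
  grid <- tidyr::expand_grid(
    tree_id = ids,
    proportion = proportions,
    replicate = seq_len(replicates)
  )
  recs <- purrr::pmap(grid, function(tree_id, proportion, replicate) {
    tree <- trees[[match(tree_id, ids)]]
    sub_seed <- fnv1a_seed(seed, tree_id, format(proportion, digits = 12),
                           replicate)
    shuffled <- local({
      set.seed(sub_seed)
      shuffle_labels(tree, proportion)
    })
    sres <- count_splits(tree, shuffled)
    d_bar <- NA_real_
    if (!is.null(tree$edge.length) && !anyNA(tree$edge.length)) {
      d_bar <- domain_distances(tree, shuffled)$D_bar
    }
    tibble(tree_id = tree_id, proportion = proportion,
           replicate = as.integer(replicate),
           n_A = sres$n_A, n_B = sres$n_B, s = sres$s, D_bar = d_bar)
  })
  out <- list(records = dplyr::bind_rows(recs),
              config = list(proportions = proportions,
                            replicates = replicates, seed = seed))
  class(out) <- "null_result"
  out
}

#' @export
print.null_result <- function(x, ...) {
  cat("Label-shuffle null distribution:",
      nrow(x$records), "records,",
      length(unique(x$records$tree_id)), "tree(s), proportions",
      paste(x$config$proportions, collapse = "/"),
      "seed", x$config$seed, "\n")
  print(summarize_null(x), ...)
  invisible(x)
}

#' @describeIn null_distribution Tidy the per-replicate records.
#' @param x A `null_result`.
#' @param ... Unused.
#' @method tidy null_result
#' @export
tidy.null_result <- function(x, ...) x$records

#' @describeIn null_distribution Per-proportion summary (all sizes pooled).
#' @method glance null_result
#' @export
glance.null_result <- function(x, ...) {
  summarize_null(x, size_classes = numeric(0))
}

#' Summarize a null distribution by proportion and tree-size class
#'
#' Groups replicates by proportion and by minimum per-domain group size
#' (cut at `size_classes`, default: fewer than 10 per group vs at least
#' 10). Reports the minimum split count, the split-count histogram, and
#' the minimum/quartiles of `D_bar` restricted to single-split (`s = 1`)
#' replicates -- the tail that mimics a clean domain separation by chance.
#'
#' @param result A `null_result`.
#' @param size_classes Cut points for `min(n_A, n_B)`; empty for no size
#'   stratification.
#' @return Tibble with one row per proportion x size class: `proportion`,
#'   `size_class`, `n_records`, `min_s`, `s_histogram` (string
#'   `"s:count,..."`), `n_single_split`, `min_D_bar_s1`, `q25_D_bar_s1`,
#'   `median_D_bar_s1`, `q75_D_bar_s1`.
#' @export
summarize_null <- function(result, size_classes = 10) {
  stopifnot(inherits(result, "null_result"))
  rec <- result$records
  if (nrow(rec) == 0) abort("empty null result")
  rec$group_min <- pmin(rec$n_A, rec$n_B)
  if (length(size_classes) > 0) {
    brk <- c(-Inf, size_classes, Inf)
    lab <- character(length(brk) - 1)
    for (i in seq_along(lab)) {
      lab[i] <- if (is.infinite(brk[i + 1])) paste0(">=", brk[i])
                else paste0("<", brk[i + 1])
    }
    rec$size_class <- as.character(cut(rec$group_min, breaks = brk,
                                       labels = lab, right = FALSE))
  } else {
    rec$size_class <- "all"
  }
  hist_str <- function(s) {
    tb <- table(s)
    paste(paste0(names(tb), ":", as.integer(tb)), collapse = ",")
  }
  q_or_na <- function(x, p) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else unname(quantile(x, p))
  }
  rec |>
    dplyr::group_by(.data$proportion, .data$size_class) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      min_s = min(.data$s),
      s_histogram = hist_str(.data$s),
      n_single_split = sum(.data$s == 1),
      min_D_bar_s1 = q_or_na(.data$D_bar[.data$s == 1], 0),
      q25_D_bar_s1 = q_or_na(.data$D_bar[.data$s == 1], 0.25),
      median_D_bar_s1 = q_or_na(.data$D_bar[.data$s == 1], 0.5),
      q75_D_bar_s1 = q_or_na(.data$D_bar[.data$s == 1], 0.75),
      .groups = "drop"
    )
}
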