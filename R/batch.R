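# Batch orchestration over tree collections.

# Resolve a tree collection argument into a named list of phylo objects.
collect_trees <- function(trees) {
  if (inherits(trees, "phylo")) return(list(tree_1 = trees))
  if (inherits(trees, "multiPhylo")) {
    trees <- unclass(trees)
  }
  if (is.character(trees) && length(trees) == 1 && dir.exists(trees)) {
    files <- sort(list.files(trees, pattern = "\\.(nwk|newick|tree|tre)$",
                             full.names = TRUE))
    if (length(files) == 0) abort(paste0("no tree files in ", trees))
    out <- lapply(files, read_newick)
    names(out) <- sub("\\.[^.]+$", "", basename(files))
    return(out)
  }
  if (is.list(trees)) {
    if (!all(vapply(trees, inherits, logical(1), "phylo"))) {
      abort("tree list must contain phylo objects")
    }
    if (is.null(names(trees)) || any(names(trees) == "")) {
      names(trees) <- paste0("tree_", seq_along(trees))
    }
    return(trees)
  }
  abort("unsupported tree collection: give a phylo, multiPhylo, list, or directory")
}

# Resolve a map argument (tibble/path/pattern list) per tree.
resolve_map <- function(map, tree) {
  if (is.list(map) && !is.data.frame(map) &&
      all(names(map) %in% c("A", "B"))) {
    return(domain_map(map, tree = tree))
  }
  if (is.data.frame(map)) return(domain_map(map))
  if (is.character(map) && length(map) == 1) return(domain_map(map))
  abort("unsupported domain map source")
}

#' Run all domain-separation statistics over a tree collection
#'
#' For every tree: validates the domain map, computes the split count `s`
#' with split-node supports, and (when branch lengths are complete) the
#' distance summary with `D_bar`/`D_min`. Trees in which one domain is
#' empty are excluded with reason `"single-domain"` (a family must contain
#' both archaeal and bacterial sequences to be informative about the
#' interdomain split). Trees with unmapped leaves abort the run by
#' default; set `on_unmapped` to `"prune"` to drop them or `"exclude"` to
#' skip those trees.
#'
#' @param trees A `phylo`, `multiPhylo`, named list of `phylo`, or a
#'   directory of newick files (`.nwk`, `.newick`, `.tree`, `.tre`).
#' @param map Domain map source: tibble, TSV path, or pattern list
#'   `list(A = ..., B = ...)` (see [domain_map()]); applied to each tree.
#' @param min_per_domain Per-domain leaf threshold `T` for the headline
#'   tally of well-sampled single-split trees (default 10).
#' @param on_unmapped `"abort"` (default), `"prune"`, or `"exclude"`.
#' @param normalize_support Passed to [support_values()].
#' @return Object of class `batch_result`: list with `report` (tibble in
#'   the [write_report()] schema), `excluded` (tibble: `tree_id`,
#'   `reason`), and `min_per_domain`.
#' @export
run_batch <- function(trees, map, min_per_domain = 10,
                      on_unmapped = c("abort", "prune", "exclude"),
                      normalize_support = FALSE) {
  on_unmapped <- match.arg(on_unmapped)
  trees <- collect_trees(trees)
  rows <- list()
  excluded <- list()
  for (id in names(trees)) {
    tree <- trees[[id]]
    dm <- resolve_map(map, tree)
    check <- validate_pair(tree, dm)
    if (check$n_unmapped > 0) {
      if (on_unmapped == "abort") {
        abort(paste0("tree ", id, " has unmapped leaves: ",
                     paste(check$unmapped[[1]], collapse = ", "),
                     " (set on_unmapped = \"prune\" or \"exclude\")"))
      }
      if (on_unmapped == "exclude") {
        excluded[[id]] <- tibble(tree_id = id, reason = "unmapped-leaves")
        next
      }
      keep <- setdiff(tree$tip.label, check$unmapped[[1]])
      if (length(keep) < 2) {
        excluded[[id]] <- tibble(tree_id = id, reason = "unmapped-leaves")
        next
      }
      tree <- prune_leaves(tree, keep)
      check <- validate_pair(tree, dm)
    }
    if (check$n_A == 0 || check$n_B == 0) {
      excluded[[id]] <- tibble(tree_id = id, reason = "single-domain")
      next
    }
    sres <- count_splits(tree, dm, normalize_support = normalize_support)
    flags <- character(0)
    if (check$has_lengths) {
      dres <- domain_distances(tree, dm)
      if (nzchar(dres$flags)) flags <- c(flags, dres$flags)
    } else {
      dres <- tibble(d_AA = NA_real_, d_BB = NA_real_, d_AB = NA_real_,
                     D_bar = NA_real_, D_min = NA_real_)
      flags <- c(flags, "no_branch_lengths")
    }
    per_split <- if (nrow(sres$splits) > 0) {
      paste(ifelse(is.na(sres$splits$support), "NA",
                   formatC(sres$splits$support, format = "g", digits = 6)),
            collapse = ",")
    } else NA_character_
    rows[[id]] <- tibble(
      tree_id = id, n_A = check$n_A, n_B = check$n_B, s = sres$s,
      mean_support = sres$mean_support, per_split_supports = per_split,
      d_AA = dres$d_AA, d_BB = dres$d_BB, d_AB = dres$d_AB,
      D_bar = dres$D_bar, D_min = dres$D_min,
      flags = paste(flags, collapse = ";")
    )
  }
  report <- dplyr::bind_rows(rows)
  if (nrow(report) == 0) abort("no valid trees to analyze")
  out <- list(report = report,
              excluded = dplyr::bind_rows(excluded),
              min_per_domain = min_per_domain)
  class(out) <- "batch_result"
  out
}

#' @export
print.batch_result <- function(x, ...) {
  g <- glance(x)
  cat("Domain-separation batch:", g$n_analyzed, "trees analyzed,",
      g$n_excluded, "excluded\n")
  cat("  single-split trees:", g$n_single_split,
      paste0("(", g$n_single_split_min_domain, " with >= ",
             x$min_per_domain, " leaves per domain)"), "\n")
  if (!is.na(g$median_D_bar)) {
    cat("  median D_bar:", signif(g$median_D_bar, 4),
        "| median D_bar among single-split:",
        signif(g$median_D_bar_s1, 4), "\n")
  }
  invisible(x)
}

#' @describeIn run_batch Tidy the per-tree report rows.
#' @param x A `batch_result`.
#' @param ... Unused.
#' @method tidy batch_result
#' @export
tidy.batch_result <- function(x, ...) x$report

#' @describeIn run_batch One-row batch summary: totals, exclusions,
#'   single-split tallies (overall and with at least `min_per_domain`
#'   leaves per domain), and `D_bar` medians.
#' @method glance batch_result
#' @export
glance.batch_result <- function(x, ...) {
  r <- x$report
  well_sampled <- r$n_A >= x$min_per_domain & r$n_B >= x$min_per_domain
  med <- function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  tibble(
    n_input = nrow(r) + nrow(x$excluded),
    n_analyzed = nrow(r),
    n_excluded = nrow(x$excluded),
    n_single_split = sum(r$s == 1),
    n_single_split_min_domain = sum(r$s == 1 & well_sampled),
    min_per_domain = x$min_per_domain,
    median_D_bar = med(r$D_bar),
    median_D_bar_s1 = med(r$D_bar[r$s == 1])
  )
}

#' Extract the (s, D_bar) scatter table
#'
#' Machine-readable pairs for plotting split counts against distance
#' ratios. Rows with undefined `D_bar` are omitted and counted in the
#' `n_omitted` attribute.
#'
#' @param report A `batch_result` or its report tibble.
#' @return Tibble (`tree_id`, `s`, `D_bar`) with attribute `n_omitted`.
#' @export
scatter_table <- function(report) {
  if (inherits(report, "batch_result")) report <- report$report
  if (nrow(report) == 0) {
    out <- tibble(tree_id = character(), s = integer(), D_bar = double())
    attr(out, "n_omitted") <- 0L
    return(out)
  }
  keep <- !is.na(report$s) & !is.na(report$D_bar)
  out <- tibble(tree_id = report$tree_id[keep], s = report$s[keep],
                D_bar = report$D_bar[keep])
  attr(out, "n_omitted") <- sum(!keep)
  out
}
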