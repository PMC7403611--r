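# Tree and domain-map input/output.
#
# Trees are ape "phylo" objects throughout: tips 1..Ntip, internal nodes
# Ntip+1..Ntip+Nnode, edge matrix (parent, child), optional edge.length and
# node.label. Internal-node labels that parse as numbers are treated as
# support values (bootstrap proportions or similar) and passed through on
# their original scale.

#' Read a newick tree (or trees) with branch lengths and support values
#'
#' Thin wrapper around [ape::read.tree()] that adds validation: duplicate
#' leaf labels and negative branch lengths are rejected, and parse failures
#' are reported with the offending source. Internal-node labels are kept
#' verbatim in `node.label`; use [support_values()] to interpret them as
#' numeric supports.
#'
#' @param source Path to a newick file, or a newick string (recognised by the
#'   presence of parentheses and a terminating semicolon). A file may contain
#'   several trees, one per line.
#' @return A `phylo` object, or a `multiPhylo` list when the source holds
#'   more than one tree.
#' @examples
#' tr <- read_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
#' ape::Ntip(tr)
#' @export
read_newick <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  is_text <- grepl("\\(", source) && grepl(";", source)
  if (!is_text && !file.exists(source)) {
    abort(paste0("cannot read tree: no such file and not newick text: ", source))
  }
  tr <- tryCatch(
    if (is_text) ape::read.tree(text = source) else ape::read.tree(source),
    error = function(e) {
      abort(paste0("malformed newick in ", if (is_text) "input text" else source,
                   ": ", conditionMessage(e)))
    }
  )
  if (is.null(tr)) {
    abort(paste0("malformed newick: no tree could be parsed from ",
                 if (is_text) "input text" else source))
  }
  if (inherits(tr, "multiPhylo")) {
    for (i in seq_along(tr)) validate_phylo(tr[[i]], where = paste0("tree ", i))
    return(tr)
  }
  validate_phylo(tr, where = if (is_text) "input text" else source)
  tr
}

# Structural checks shared by every entry point that accepts a tree.
validate_phylo <- function(tree, where = "tree") {
  if (!inherits(tree, "phylo")) abort(paste0(where, ": not a phylo object"))
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0) {
    abort(paste0(where, ": duplicate leaf labels: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    bad <- which(tree$edge.length < 0)[1]
    abort(paste0(where, ": negative branch length on edge ", bad))
  }
  invisible(tree)
}

#' Serialize a tree back to newick
#'
#' Inverse of [read_newick()]; support values stored in `node.label` are
#' written as internal-node labels so that a read/write round trip preserves
#' topology, branch lengths (to serialization precision) and supports.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @return The newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylo(tree)
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Numeric support values at internal nodes
#'
#' Interprets internal-node labels as support values. Labels that do not
#' parse as numbers (including empty labels) become `NA`. Supports are passed
#' through on their original scale; set `normalize = TRUE` to divide by 100
#' when every defined support exceeds 1 (i.e. a 0-100 bootstrap scale),
#' never rescaling silently otherwise.
#'
#' @param tree A `phylo` object.
#' @param normalize Rescale 0-100 supports to 0-1 when unambiguous.
#' @return Numeric vector of length `tree$Nnode`, indexed by internal node
#'   number minus `Ntip(tree)`.
#' @export
support_values <- function(tree, normalize = FALSE) {
  validate_phylo(tree)
  n_node <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n_node))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  if (normalize && any(!is.na(sup)) && all(sup[!is.na(sup)] > 1)) {
    sup <- sup / 100
  }
  sup
}

#' Build or parse a leaf-to-domain mapping
#'
#' A domain map assigns every leaf to one of two groups, conventionally
#' `"A"` (archaea) and `"B"` (bacteria). Input may be a two-column data
#' frame (leaf, domain), a path to a headerless two-column TSV, or a named
#' list of regular expressions `list(A = "^a", B = "^b")` matched against
#' the labels of `tree`.
#'
#' @param source Data frame, TSV path, or named pattern list.
#' @param tree Required when `source` is a pattern list; leaves of `tree`
#'   are classified by first match.
#' @param domains The two admissible group labels.
#' @return A tibble with columns `leaf` and `domain`.
#' @examples
#' tr <- read_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
#' domain_map(list(A = "^a", B = "^b"), tree = tr)
#' @export
domain_map <- function(source, tree = NULL, domains = c("A", "B")) {
  stopifnot(length(domains) == 2L, !anyDuplicated(domains))
  if (is.character(source) && length(source) == 1L && !is.list(source)) {
    df <- utils::read.table(source, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("leaf", "domain"),
                            colClasses = "character")
  } else if (is.data.frame(source)) {
    if (ncol(source) < 2) abort("domain map needs two columns: leaf, domain")
    df <- data.frame(leaf = as.character(source[[1]]),
                     domain = as.character(source[[2]]),
                     stringsAsFactors = FALSE)
  } else if (is.list(source)) {
    if (is.null(tree)) abort("a pattern-rule domain map needs `tree`")
    validate_phylo(tree)
    if (!all(names(source) %in% domains) || length(source) == 0) {
      abort(paste0("pattern rules must be named with the domain labels: ",
                   paste(domains, collapse = ", ")))
    }
    leaves <- tree$tip.label
    dom <- rep(NA_character_, length(leaves))
    for (d in names(source)) {
      hit <- grepl(source[[d]], leaves)
      clash <- hit & !is.na(dom) & dom != d
      if (any(clash)) {
        abort(paste0("leaf matches patterns for two domains: ",
                     paste(leaves[clash], collapse = ", ")))
      }
      dom[hit] <- d
    }
    df <- data.frame(leaf = leaves[!is.na(dom)], domain = dom[!is.na(dom)],
                     stringsAsFactors = FALSE)
  } else {
    abort("unsupported domain map source")
  }
  extra <- setdiff(unique(df$domain), domains)
  if (length(extra) > 0) {
    abort(paste0("more than two domain labels: unexpected ",
                 paste(extra, collapse = ", ")))
  }
  n_dom <- tapply(df$domain, df$leaf, function(d) length(unique(d)))
  if (any(n_dom > 1)) {
    abort(paste0("leaf mapped to two different domains: ",
                 paste(names(n_dom)[n_dom > 1], collapse = ", ")))
  }
  df <- df[!duplicated(df$leaf), , drop = FALSE]
  tibble(leaf = df$leaf, domain = df$domain)
}

# Leaf-ordered domain vector for a tree; errors on unmapped leaves unless
# allow_unmapped, in which case NA entries are returned.
domain_vector <- function(tree, map, allow_unmapped = FALSE) {
  validate_phylo(tree)
  idx <- match(tree$tip.label, map$leaf)
  if (!allow_unmapped && anyNA(idx)) {
    abort(paste0("unmapped leaves: ",
                 paste(tree$tip.label[is.na(idx)], collapse = ", ")))
  }
  dom <- map$domain[idx]
  names(dom) <- tree$tip.label
  dom
}

#' Check a tree/domain-map pair for analysis eligibility
#'
#' Reports group sizes, unmapped leaves, and whether the pair supports the
#' split count `s` (both domains non-empty) and the distance ratios
#' `D_bar`/`D_min` (at least two leaves per domain and complete branch
#' lengths). Mirrors the inclusion rule that a family must contain both
#' archaeal and bacterial sequences to be analysed at all.
#'
#' @param tree A `phylo` object.
#' @param map A domain map, see [domain_map()].
#' @return One-row tibble: `n_A`, `n_B`, `n_unmapped`, `unmapped`
#'   (list-column of leaf labels), `has_lengths`, `has_supports`,
#'   `eligible_splits`, `eligible_ratios`.
#' @export
validate_pair <- function(tree, map) {
  dom <- domain_vector(tree, map, allow_unmapped = TRUE)
  n_a <- sum(dom == "A", na.rm = TRUE)
  n_b <- sum(dom == "B", na.rm = TRUE)
  unmapped <- names(dom)[is.na(dom)]
  has_len <- !is.null(tree$edge.length) && !anyNA(tree$edge.length)
  sup <- support_values(tree)
  all_mapped <- length(unmapped) == 0
  ok_splits <- n_a > 0 && n_b > 0 && all_mapped
  ok_ratios <- n_a >= 2 && n_b >= 2 && all_mapped && has_len
  tibble(
    n_A = n_a,
    n_B = n_b,
    n_unmapped = length(unmapped),
    unmapped = list(unmapped),
    has_lengths = has_len,
    has_supports = any(!is.na(sup)),
    eligible_splits = ok_splits,
    eligible_ratios = ok_ratios
  )
}

#' Restrict a tree to a subset of leaves
#'
#' Returns the induced subtree on `keep`, collapsing degree-2 nodes and
#' summing their branch lengths, so that the patristic distance between any
#' two kept leaves is unchanged. This is the generic hook for removing
#' unwanted leaves (e.g. suspected paralogs) before analysis.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain (at least 2).
#' @return A `phylo` object on the kept leaves.
#' @export
prune_leaves <- function(tree, keep) {
  validate_phylo(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("leaves not in tree: ", paste(missing, collapse = ", ")))
  }
  if (length(keep) < 2) abort("prune_leaves needs at least 2 leaves to keep")
  if (length(keep) == ape::Ntip(tree)) return(tree)
  ape::keep.tip(tree, keep)
}

# Fixed column order of the per-tree report; shared by write_report and
# run_batch.
report_schema <- c("tree_id", "n_A", "n_B", "s", "mean_support",
                   "per_split_supports", "d_AA", "d_BB", "d_AB",
                   "D_bar", "D_min", "flags")

#' Write a per-tree report as TSV
#'
#' Serializes per-tree result rows (schema of [run_batch()]) with a
#' deterministic column order, `NA` for undefined statistics, and floats at
#' 6 significant digits. An empty record set yields a header-only file.
#'
#' @param records Tibble of report rows (missing columns are filled with NA).
#' @param dest Output path.
#' @return `dest`, invisibly.
#' @export
write_report <- function(records, dest) {
  records <- as_tibble(records)
  for (col in setdiff(report_schema, names(records))) {
    records[[col]] <- NA
  }
  records <- records[report_schema]
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- ifelse(is.na(x), "NA", trimws(formatC(signif(x, 6), format = "g",
                                                   digits = 6)))
    } else {
      out <- ifelse(is.na(x) | x == "", "NA", as.character(x))
    }
    out
  }
  cells <- lapply(records, fmt)
  lines <- c(paste(report_schema, collapse = "\t"))
  if (nrow(records) > 0) {
    body <- do.call(paste, c(cells, sep = "\t"))
    lines <- c(lines, body)
  }
  ok <- tryCatch({ writeLines(lines, dest); TRUE },
                 error = function(e) abort(paste0("cannot write report to ",
                                                  dest, ": ",
                                                  conditionMessage(e))))
  invisible(dest)
}
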