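#' Read a rooted newick tree with strict validation
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is an
#' `ape` `phylo` object carrying a `length_unit` attribute; every downstream
#' stage checks that attribute rather than guessing units from magnitudes.
#' Node IDs follow the `ape` convention (tips `1..n` in `tip.label` order,
#' internal nodes `n+1..n+Nnode` with the root at `n+1`); these integer IDs are
#' fixed at parse time and are the canonical node references used by all
#' results in this package.
#'
#' @param text A single newick statement terminated by `";"`, or a path to a
#'   file containing one.
#' @param length_unit Unit of the branch lengths: `"subs_per_site"` (expected
#'   substitutions per site, a phylogram), `"Ma"` (million years, a
#'   chronogram), or `"unitless"`.
#' @return A rooted `phylo` object with attribute `length_unit`.
#' @export
read_newick <- function(text,
                        length_unit = c("unitless", "subs_per_site", "Ma")) {
  length_unit <- match.arg(length_unit)
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  if (!grepl(";\\s*$", text)) {
    stop("newick statement must terminate with ';'")
  }
  n_open <- nchar(gsub("[^(]", "", text))
  n_close <- nchar(gsub("[^)]", "", text))
  if (n_open != n_close) {
    stop(sprintf("unbalanced parentheses: %d '(' vs %d ')'", n_open, n_close))
  }
  # bracketed comments are ignored per the strict dialect
  text <- gsub("\\[[^]]*\\]", "", text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("newick parse error: ", conditionMessage(w))
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("newick parse error: input did not yield a tree")
  }
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0)) {
    bad <- which(phy$edge.length < 0)
    lab <- node_label(phy, phy$edge[bad, 2])
    stop("negative branch length on branch to: ", paste(lab, collapse = ", "))
  }
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; a branch length per non-root node is required")
  }
  attr(phy, "length_unit") <- length_unit
  phy
}

#' Write a tree to a newick string
#'
#' Branch lengths are written with 10 significant digits so that a
#' read/write/read cycle preserves topology, labels and lengths.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` (default) the newick string is
#'   returned.
#' @return The newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Branch-length unit of a tree
#'
#' @param tree A `phylo` read by [read_newick()] or built by a simulator.
#' @return The unit string; `"unitless"` when untagged.
#' @export
length_unit <- function(tree) {
  u <- attr(tree, "length_unit")
  if (is.null(u)) "unitless" else u
}

`length_unit<-` <- function(tree, value) {
  attr(tree, "length_unit") <- value
  tree
}

# Hard error on a unit mismatch; modules never coerce units silently.
check_unit <- function(tree, expected) {
  u <- length_unit(tree)
  if (!identical(u, expected)) {
    stop(sprintf("tree branch lengths are '%s' but '%s' is required", u, expected))
  }
  invisible(TRUE)
}

node_label <- function(tree, node) {
  n <- ape::Ntip(tree)
  ifelse(node <= n, tree$tip.label[node], paste0("node", node))
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A rooted `phylo`.
#' @param tips Character vector of tip labels (non-empty). The MRCA of a
#'   single tip is the tip itself.
#' @return Integer node ID.
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"), length(tips) >= 1)
  tips <- unique(as.character(tips))
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) {
    stop("unknown tip labels: ", paste(missing, collapse = ", "))
  }
  idx <- match(tips, tree$tip.label)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

# Depth (sum of branch lengths from the root) for every node, root = 0.
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

# Age before present for every node of a chronogram: the maximum tip depth
# minus the node depth (tips of an ultrametric tree get age 0).
node_ages_chronogram <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_len(ape::Ntip(tree))]) - d
}

# Parent node of each node (0 for the root).
node_parents <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  par <- integer(n_all)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

# Tip indices descended from each node (list over all node IDs).
descendant_tips <- function(tree) {
  n <- ape::Ntip(tree)
  n_all <- n + tree$Nnode
  below <- vector("list", n_all)
  for (i in seq_len(n)) below[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Join a per-taxon table to a tree
#'
#' Aligns table rows to the canonical tip order of the tree (the order of
#' `tree$tip.label`, fixed at parse time). Taxa present in the table but
#' absent from the tree, or vice versa, are reported; in strict mode any
#' mismatch is an error naming the offending taxa.
#'
#' @param tree A `phylo`.
#' @param table A data frame keyed by a `taxon` column (or row names).
#' @param strict If `TRUE` (default) any mismatch between table keys and tip
#'   labels is an error.
#' @return A list with `data` (rows in tip order; tips missing from the table
#'   yield `NA` rows in non-strict mode), `missing` (tips without a table
#'   row) and `extra` (table rows without a tip).
#' @export
join_table <- function(tree, table, strict = TRUE) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(table))
  keys <- if ("taxon" %in% names(table)) as.character(table$taxon) else rownames(table)
  if (anyDuplicated(keys)) {
    stop("duplicate taxon keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  missing <- setdiff(tree$tip.label, keys)
  extra <- setdiff(keys, tree$tip.label)
  if (strict && (length(missing) || length(extra))) {
    stop("tree/table mismatch; missing from table: [",
         paste(missing, collapse = ", "), "]; not in tree: [",
         paste(extra, collapse = ", "), "]")
  }
  idx <- match(tree$tip.label, keys)
  out <- table[idx, , drop = FALSE]
  rownames(out) <- tree$tip.label
  list(data = out, missing = missing, extra = extra)
}
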