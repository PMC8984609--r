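# Phylogenetic accounting on rooted genome trees.
#
# PD here is rooted Faith's PD: the sum of branch lengths on the union of
# root-to-leaf paths of the chosen taxa. With this convention PD of the
# full leaf set equals the total branch length of the tree exactly, and
# phylogenetic gain PG(S) = PD(all) - PD(all \ S) is additive. An unrooted
# (minimal spanning subtree) variant is available behind a flag.

#' Read and validate a rooted genome tree
#'
#' Accepts a newick string or a file path. The tree must be rooted, have at
#' least two uniquely labelled leaves, and carry non-negative branch
#' lengths; missing lengths are set to 0 with a warning.
#'
#' @param x newick text or path to a newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
#' @examples
#' tr <- read_genome_tree("((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B"))
read_genome_tree <- function(x) {
  if (!is_string(x)) stop_field("x", "must be a newick string or file path")
  tree <- tryCatch(
    if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("could not parse newick input", call. = FALSE)
  if (ape::Ntip(tree) < 2L)
    stop("degenerate tree: at least 2 leaves required", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop(sprintf("duplicate leaf label(s): %s",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")), call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch length(s) set to 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted", call. = FALSE)
  tree
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_field("tree", "must be a phylo object")
  if (is.null(tree$edge.length))
    stop_field("tree", "must have branch lengths")
  invisible(tree)
}

#' Faith's phylogenetic distance of a taxon set
#'
#' Rooted Faith's PD: total branch length on the union of the paths from
#' each selected leaf to the root. `faith_pd(tree, tree$tip.label)` equals
#' the tree's total branch length exactly. With `rooted = FALSE` the
#' unrooted variant is returned instead: the length of the minimal subtree
#' spanning the selected leaves only (0 for a single leaf).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param taxa character vector of leaf labels, non-empty.
#' @param rooted include root paths (default TRUE).
#' @return total branch length (same units as the tree).
#' @export
faith_pd <- function(tree, taxa, rooted = TRUE) {
  check_tree(tree)
  taxa <- unique(as.character(taxa))
  if (length(taxa) < 1L) stop_field("taxa", "must contain at least one leaf")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop(sprintf("unknown leaf id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  tr <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  count <- integer(nnode)
  count[match(taxa, tr$tip.label)] <- 1L
  parent <- tr$edge[, 1L]
  child <- tr$edge[, 2L]
  for (i in seq_along(parent))
    count[parent[i]] <- count[parent[i]] + count[child[i]]
  below <- count[child]
  keep <- if (rooted) below > 0L else below > 0L & below < length(taxa)
  sum(tr$edge.length[keep])
}

#' Phylogenetic gain of an ingroup
#'
#' The additional branch length contributed by a set of taxa:
#' `PG(S) = PD(all leaves) - PD(all leaves except S)`. The ingroup must be
#' a strict subset of the leaves (the complement supplies the reference
#' tree).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param ingroup character vector of leaf labels.
#' @return branch length gained.
#' @export
phylogenetic_gain <- function(tree, ingroup) {
  check_tree(tree)
  ingroup <- unique(as.character(ingroup))
  unknown <- setdiff(ingroup, tree$tip.label)
  if (length(unknown))
    stop(sprintf("unknown leaf id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  complement <- setdiff(tree$tip.label, ingroup)
  if (length(complement) == 0L)
    stop("ingroup covers all leaves; complement is empty", call. = FALSE)
  faith_pd(tree, tree$tip.label) - faith_pd(tree, complement)
}

#' Percent of full-tree PD
#'
#' `100 * pd / full_pd`, rounded to `digits` decimals half-away-from-zero —
#' the report-time convention used in PD/PG tables.
#'
#' @param pd PD (or PG) value.
#' @param full_pd PD of the full tree, `> 0`.
#' @param digits decimals retained (default 2).
#' @return percent value.
#' @export
#' @examples
#' pd_percent(37.54, 75.71)          # 49.58
#' pd_percent(75.71 - 37.54, 75.71)  # 50.42
pd_percent <- function(pd, full_pd, digits = 2) {
  check_number(pd, "pd", 0)
  check_number(full_pd, "full_pd", allow_vector = FALSE)
  if (full_pd <= 0) stop_field("full_pd", "must be positive")
  round_half_away(100 * pd / full_pd, digits)
}

#' PD/PG summary table for an ingroup/outgroup partition
#'
#' Emits the four-row table used to report how much phylogenetic diversity
#' a set of new genomes adds to a reference tree: full-tree PD, outgroup
#' PD, ingroup PD, and ingroup PG (`= full - outgroup`, exactly). Percent
#' PD is computed from unrounded internal values and rounded (2 decimals,
#' half away from zero) only in the emitted column; the full-tree row is
#' always 100.00.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param ingroup,outgroup character vectors partitioning the leaf set
#'   (disjoint, jointly exhaustive).
#' @return data.frame with columns `set`, `n_taxa`, `pd`, `percent_pd`.
#' @export
pd_summary <- function(tree, ingroup, outgroup) {
  check_tree(tree)
  ingroup <- unique(as.character(ingroup))
  outgroup <- unique(as.character(outgroup))
  overlap <- intersect(ingroup, outgroup)
  if (length(overlap))
    stop(sprintf("ingroup and outgroup overlap: %s",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  if (!setequal(c(ingroup, outgroup), tree$tip.label))
    stop("ingroup and outgroup must partition the leaf set", call. = FALSE)
  full <- faith_pd(tree, tree$tip.label)
  out_pd <- faith_pd(tree, outgroup)
  in_pd <- faith_pd(tree, ingroup)
  pg <- full - out_pd
  data.frame(
    set = c("full_tree", "outgroup_pd", "ingroup_pd", "ingroup_pg"),
    n_taxa = c(length(tree$tip.label), length(outgroup),
               length(ingroup), length(ingroup)),
    pd = c(full, out_pd, in_pd, pg),
    percent_pd = pd_percent(c(full, out_pd, in_pd, pg), full),
    stringsAsFactors = FALSE
  )
}
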