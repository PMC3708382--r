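## Tree I/O, chronogram validation, bipartitions, Robinson-Foulds.
##
## Trees are ape "phylo" objects throughout. Chronograms (ultrametric,
## branch durations in Myr) get the extra class "chronogram" after
## validation; topologies carry branch lengths in expected
## substitutions/site. The two unit systems are never mixed in one object.

#' Validate and tag a chronogram
#'
#' Checks that a rooted tree is ultrametric (all root-to-leaf duration sums
#' equal within relative tolerance 1e-6), has positive branch durations,
#' at least 4 leaves and unique leaf labels.
#'
#' @param phy an `ape::phylo` tree with branch lengths in Myr.
#' @param tol relative ultrametricity tolerance.
#' @return `phy` with class `c("chronogram", "phylo")`.
#' @export
as_chronogram <- function(phy, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("chronogram requires branch lengths")
  if (length(phy$tip.label) < 4) stop("chronogram requires >= 4 leaves")
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf labels")
  if (any(phy$edge.length <= 0)) stop("all branch durations must be > 0")
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  if ((max(depths) - min(depths)) > tol * max(depths))
    stop("tree is not ultrametric: root-to-leaf depths range ",
         format(min(depths)), " .. ", format(max(depths)))
  class(phy) <- c("chronogram", class(phy)[class(phy) != "chronogram"])
  phy
}

#' Root depth of a chronogram in Myr
#' @param chrono a chronogram.
#' @return scalar depth.
#' @export
root_depth <- function(chrono) {
  max(ape::node.depth.edgelength(chrono)[seq_along(chrono$tip.label)])
}

#' Read a Newick tree
#'
#' @param text Newick string (or a file path if `file = TRUE`).
#' @param rooted if `TRUE` the input is validated as an ultrametric
#'   chronogram; otherwise returned as a plain topology.
#' @param file treat `text` as a path.
#' @return a `phylo` (or `chronogram`) object.
#' @export
read_newick <- function(text, rooted = FALSE, file = FALSE) {
  phy <- tryCatch(
    if (file) ape::read.tree(text) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed Newick input",
         if (!file) paste0(" (near character ",
                           regexpr("[^(),:;A-Za-z0-9_.' -]|$", text)[1], ")"))
  if (is.null(phy$tip.label) || any(!nzchar(phy$tip.label)))
    stop("malformed Newick input: empty leaf label")
  if (rooted) as_chronogram(phy) else phy
}

#' Write a tree to Newick
#'
#' @param phy a `phylo` object.
#' @param path optional file path; if `NULL` the string is returned.
#' @param digits significant digits for branch lengths.
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(phy, path = NULL, digits = 12) {
  s <- ape::write.tree(phy, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

## canonical key for one side of a split: sorted labels of the side NOT
## containing the lexicographically smallest label, joined by "|"
.split_key <- function(side, all_labels) {
  anchor <- min(all_labels)
  if (anchor %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal branch of the unrooted tree defines a split of the leaf
#' set. Splits are canonicalized: the key is the sorted, "|"-joined side
#' that does not contain the lexicographically smallest label. A binary
#' unrooted tree on n leaves yields exactly n - 3 splits.
#'
#' @param phy a `phylo` object with >= 4 leaves.
#' @return character vector of canonical split keys (unique, sorted).
#' @export
bipartitions <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  if (n < 4) stop("bipartitions require >= 4 leaves")
  phy <- ape::unroot(phy)
  phy <- stats::reorder(phy, "postorder")
  labels <- phy$tip.label
  ntot <- n + phy$Nnode
  tipsets <- vector("list", ntot)
  for (i in seq_len(n)) tipsets[[i]] <- labels[i]
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }
  keys <- character(0)
  internal_children <- phy$edge[, 2][phy$edge[, 2] > n]
  for (v in internal_children) {
    side <- tipsets[[v]]
    if (length(side) >= 2 && length(side) <= n - 2)
      keys <- c(keys, .split_key(side, labels))
  }
  sort(unique(keys))
}

#' Robinson-Foulds (symmetric difference) distance
#'
#' Counts the bipartitions present in exactly one of the two unrooted
#' trees. Always even for binary trees; 0 iff identical topologies; at
#' most `2 * (n - 3)`.
#'
#' @param tree_a,tree_b `phylo` objects on the same leaf set.
#' @return non-negative integer.
#' @export
rf_distance <- function(tree_a, tree_b) {
  la <- sort(tree_a$tip.label); lb <- sort(tree_b$tip.label)
  if (!identical(la, lb)) stop("trees have different leaf sets")
  sa <- bipartitions(tree_a); sb <- bipartitions(tree_b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}
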