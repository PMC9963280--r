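#' Construct a chronogram from a "phylo" tree
#'
#' A chronogram is a rooted, ultrametric phylogeny whose branch lengths are
#' in units of absolute time (here Ma).  Node ages are measured backwards
#' from the present: tips sit at age 0 and the root at the crown age.
#' Construction validates every invariant the downstream models rely on and
#' attaches a `node.age` component (one age per node, tips first, in the
#' usual "phylo" node numbering).
#'
#' Ultrametricity is checked on root-to-tip path lengths against the median
#' tip depth, with a tolerance expressed relative to the root age because
#' divergence-dating output typically carries rounding error in its last
#' printed digits.  Polytomies are accepted and treated as hard.
#'
#' @param phy an object of class `"phylo"` with branch lengths.
#' @param tol_rel relative ultrametricity tolerance, as a fraction of the
#'   root age (default `1e-6`).
#' @return an object of class `c("chronogram", "phylo")` with a `node.age`
#'   component (Ma before present).
#' @export
#' @examples
#' tr <- as_chronogram(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' root_age(tr)  # 2
as_chronogram <- function(phy, tol_rel = 1e-6) {
  if (inherits(phy, "chronogram")) return(phy)
  if (!inherits(phy, "phylo")) stop("'phy' must be a \"phylo\" object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0))
    stop("tree has negative branch length(s)")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (is.null(phy$tip.label) || any(!nzchar(phy$tip.label)))
    stop("all tips must carry non-empty labels")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  tip_depth <- depth[seq_len(ntip)]
  ref <- stats::median(tip_depth)
  if (max(tip_depth) <= 0) stop("root age must be > 0 (tree has zero height)")
  tol <- tol_rel * max(tip_depth)
  off <- which(abs(tip_depth - ref) > tol)
  if (length(off))
    stop(sprintf(
      "tree is not ultrametric: tip(s) %s have root-to-tip depth deviating from the median (%.10g) by more than %.3g",
      paste(phy$tip.label[off], collapse = ", "), ref, tol))
  root_age <- max(tip_depth)
  age <- root_age - depth
  age[seq_len(ntip)] <- 0
  age[age < 0] <- 0
  phy$node.age <- age
  class(phy) <- c("chronogram", "phylo")
  phy
}

#' Read a chronogram from a Newick file
#'
#' Branch lengths are interpreted as durations in Ma.  Node ages are
#' recovered by root-to-tip accumulation of branch lengths followed by
#' conversion of depths to ages; the result is validated by
#' [as_chronogram()].
#'
#' @param path path to a Newick file, or `NULL` if `text` is given.
#' @param text optional Newick string instead of a file.
#' @inheritParams as_chronogram
#' @return a `chronogram`.
#' @export
read_newick <- function(path = NULL, text = NULL, tol_rel = 1e-6) {
  phy <- tryCatch(
    suppressWarnings(
      if (is.null(text)) ape::read.tree(file = path)
      else ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(phy))
    stop("malformed Newick in ", if (is.null(text)) path else "'text'")
  if (inherits(phy, "multiPhylo"))
    stop("input contains more than one tree")
  as_chronogram(phy, tol_rel = tol_rel)
}

#' Write a chronogram to a Newick file
#'
#' @param x a `chronogram` (or any `phylo`).
#' @param path output path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the path, invisibly (or the Newick string when `path = NULL`).
#' @export
write_newick <- function(x, path = NULL, digits = 10) {
  if (is.null(path)) return(ape::write.tree(x, digits = digits))
  ape::write.tree(x, file = path, digits = digits)
  invisible(path)
}

#' Node ages of a chronogram
#'
#' @param x a `chronogram`.
#' @return numeric vector of ages (Ma before present), one per node in
#'   "phylo" node order (tips first).
#' @export
node_ages <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  x$node.age
}

#' Root age of a chronogram
#'
#' @param x a `chronogram`.
#' @return the crown age in Ma.
#' @export
root_age <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  x$node.age[length(x$tip.label) + 1L]
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf("Chronogram: %d tips, root age %.4f Ma\n",
              length(x$tip.label), root_age(x)))
  NextMethod()
}

# Node ages usable by the CTMC machinery.  Chronograms carry exact ages; a
# plain rooted phylo is accepted only for time-homogeneous models (where
# absolute ages are irrelevant and only durations matter), with "ages"
# derived from node depths.
.tree_ages <- function(tree, need_ultrametric) {
  if (inherits(tree, "chronogram")) return(tree$node.age)
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo or chronogram")
  if (need_ultrametric)
    return(as_chronogram(tree)$node.age)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}
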