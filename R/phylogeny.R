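#' Read a rooted, time-calibrated phylogeny from Newick
#'
#' Wraps [ape::read.tree()] with the validation the diversity functions
#' need: a single rooted tree with nonnegative branch lengths.  Root age is
#' computed as the maximum tip depth and attached as the `"root_age"`
#' attribute.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object with a `"root_age"` attribute.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("malformed Newick in ", path)
  validate_phylogeny(tree)
}

#' Validate a phylogeny for diversity computation
#'
#' @param tree an [ape::phylo] object.
#' @return the tree with a `"root_age"` attribute.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  ## a basal polytomy (e.g. a star tree) is accepted as a hard polytomy at
  ## the root; the phylo structure always carries a single root node
  age <- root_age(tree)
  if (age <= 0) stop("zero-length tree")
  attr(tree, "root_age") <- age
  tree
}

#' Root age (maximum tip depth) of a tree
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @return numeric scalar, in the tree's time units.
#' @export
root_age <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d[seq_along(tree$tip.label)])
}

#' Check ultrametricity within a relative tolerance
#'
#' Phylogenetic Hill diversity assumes all tips are equidistant from the
#' root.  The check is relative: the spread of tip depths must not exceed
#' `tol` times the root age.
#'
#' @param tree an [ape::phylo] object.
#' @param tol relative tolerance (default `1e-6` of root age).
#' @param action `"error"`, `"warning"`, or `"silent"` on failure.
#' @return logical, `TRUE` when ultrametric within tolerance (invisibly for
#'   non-silent actions).
#' @export
check_ultrametric <- function(tree, tol = 1e-6, action = c("error", "warning", "silent")) {
  action <- match.arg(action)
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  ok <- (max(d) - min(d)) <= tol * max(d)
  if (!ok) {
    msg <- sprintf("tree is not ultrametric: tip depth spread %.3g exceeds %.1g of root age",
                   max(d) - min(d), tol)
    if (action == "error") stop(msg)
    if (action == "warning") warning(msg)
  }
  invisible(ok)
}

#' Reconcile a phylogeny with a community matrix
#'
#' Species in the matrix that are absent from the tree are dropped from
#' phylogenetic computations (their relative-abundance mass is removed and
#' the remaining abundances renormalize implicitly); tips absent from the
#' matrix are pruned.  The dropped species and the fraction of total
#' abundance they carried are reported, mirroring the common practice of
#' computing tree-based diversity on the subset of species with molecular
#' data.
#'
#' @param tree an [ape::phylo] object.
#' @param cm a `community_matrix`.
#' @param strict if `TRUE`, any matrix species missing from the tree is an
#'   error instead of a warning.
#' @return list with elements `tree` (pruned), `counts` (matrix restricted to
#'   shared species), `dropped` (character), and `mass_removed` (fraction of
#'   total abundance dropped).
#' @export
reconcile_tree <- function(tree, cm, strict = FALSE) {
  tree <- validate_phylogeny(tree)
  shared <- intersect(colnames(cm), tree$tip.label)
  dropped <- setdiff(colnames(cm), tree$tip.label)
  if (length(shared) < 2) stop("fewer than two species shared between tree and matrix")
  if (length(dropped)) {
    mass <- sum(unclass(cm)[, dropped, drop = FALSE]) / sum(cm)
    msg <- sprintf("%d species absent from the tree dropped (%.2g%% of total abundance)",
                   length(dropped), 100 * mass)
    if (strict) stop(msg)
    warning(msg)
  } else mass <- 0
  sub <- unclass(cm)[, shared, drop = FALSE]
  keep_rows <- rowSums(sub) > 0
  if (!all(keep_rows))
    warning("site(s) left empty after reconciliation: ",
            paste(rownames(sub)[!keep_rows], collapse = ", "))
  pruned <- ape::keep.tip(tree, shared)
  list(tree = validate_phylogeny(pruned),
       counts = as_community_matrix(sub[keep_rows, , drop = FALSE]),
       dropped = dropped, mass_removed = mass)
}
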