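# Newick I/O and neighbour-joining tree construction (via ape, with the
# validation this pipeline needs at its input boundary).

#' Read and write Newick trees
#'
#' Thin validated wrappers around [ape::read.tree()] / [ape::write.tree()].
#' Round-tripping preserves topology and branch lengths to numerical
#' precision.
#'
#' @param text a Newick string, or a file path when `file` is used instead.
#' @param file optional path to a Newick file.
#' @return `read_newick()` returns an `ape::phylo`; `write_newick()` a
#'   Newick string (invisibly also written to `file` when given).
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) ape::read.tree(file) else
    tryCatch(ape::read.tree(text = text), error = function(e) NULL,
             warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick string: could not parse")
  if (any(!nzchar(tree$tip.label)) || anyNA(tree$tip.label))
    stop("malformed Newick string: unlabeled tip")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' @rdname read_newick
#' @param tree an `ape::phylo`.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration (Saitou & Nei) on a symmetric
#' distance matrix, returning an unrooted tree.  Negative branch lengths,
#' which NJ can produce on non-additive matrices, are clamped to zero with
#' a warning.  For an additive matrix the generating topology and branch
#' lengths are recovered exactly.
#'
#' @param d symmetric numeric matrix with zero diagonal and (row) labels,
#'   or a `dist` object.
#' @return an unrooted `ape::phylo`.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3) stop("need at least 3 taxa for neighbour joining")
  if (!all(is.finite(d))) stop("distance matrix has non-finite entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(nrow(d)))
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  tree
}
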