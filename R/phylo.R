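# Tree construction and queries. Trees are ape "phylo" objects throughout;
# neighbor joining is delegated to ape's reference implementation with a
# lexicographic input ordering (reproducible tie-breaking) and clamping of
# negative branch lengths.

#' Neighbor-joining tree from a distance matrix
#'
#' @param D Symmetric distance matrix (>= 3 taxa) with row/column names;
#'   `NA` or flagged (saturated) entries are refused.
#' @return Unrooted `phylo` tree. Negative NJ branch lengths are clamped to
#'   zero with the deficit moved to the adjacent (parent-side) branch, so
#'   total path lengths are approximately preserved.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (nrow(D) < 3) stop("neighbor joining needs >= 3 taxa")
  if (any(is.na(D))) stop("distance matrix contains NA (saturated?) entries")
  flagged <- attr(D, "flagged")
  if (!is.null(flagged) && any(flagged)) stop("distance matrix has flagged entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  ord <- order(rownames(D))
  D <- D[ord, ord]
  tree <- ape::nj(stats::as.dist(D))
  clamp_negative_branches(tree)
}

clamp_negative_branches <- function(tree) {
  el <- tree$edge.length
  if (is.null(el) || all(el >= 0)) return(tree)
  edge <- tree$edge
  for (e in which(el < 0)) {
    deficit <- el[e]
    el[e] <- 0
    parent <- edge[e, 1]
    up <- which(edge[, 2] == parent)
    if (length(up) == 1) el[up] <- max(0, el[up] + deficit)
  }
  tree$edge.length <- el
  tree
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Codon (or residue) columns are resampled with replacement; each internal
#' edge of the full-data tree is annotated with the percentage of
#' replicates containing its bipartition. Replicates with a degenerate
#' (NA-containing) distance matrix are dropped and counted.
#'
#' @param alignment `codon_alignment` or named character vector of aligned
#'   rows.
#' @param model Distance model passed to [distance_matrix()].
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed Seed; fixed seed gives identical supports.
#' @param R Transition/transversion ratio for dN/dS models.
#' @return `phylo` tree with `node.label` holding support percentages
#'   (`NA` for the root) and attribute `dropped_replicates`.
#' @export
bootstrap_support <- function(alignment, model = "k2p", replicates = 1000,
                              seed = 1, R = 2) {
  ref_D <- distance_matrix(alignment, model = model, R = R)
  ref <- neighbor_joining(ref_D)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  cols <- alignment_columns(alignment)
  ncol_units <- cols$n
  trees <- list()
  dropped <- 0L
  for (r in seq_len(replicates)) {
    idx <- sample.int(ncol_units, ncol_units, replace = TRUE)
    t_r <- tryCatch({
      D <- distance_matrix(cols$subset(idx), model = model, R = R)
      neighbor_joining(D)
    }, error = function(e) NULL)
    if (is.null(t_r)) dropped <- dropped + 1L else trees[[length(trees) + 1L]] <- t_r
  }
  if (length(trees) == 0) stop("all bootstrap replicates degenerate")
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / length(trees), 1)
  ref$node.label <- as.character(support)
  attr(ref, "dropped_replicates") <- dropped
  ref
}

# Column-resampling adapter for both alignment representations.
alignment_columns <- function(alignment) {
  if (inherits(alignment, "codon_alignment")) {
    rows <- retained_codon_rows(alignment)
    mats <- t(vapply(rows, split_codons, character(nchar(rows[1]) / 3)))
    list(n = ncol(mats), subset = function(idx) {
      out <- apply(mats[, idx, drop = FALSE], 1, paste, collapse = "")
      al <- new_codon_alignment(rownames(mats), out)
      al
    })
  } else {
    mats <- t(vapply(alignment, function(r) strsplit(r, "")[[1]],
                     character(nchar(alignment[1]))))
    rownames(mats) <- names(alignment)
    list(n = ncol(mats), subset = function(idx) {
      stats::setNames(apply(mats[, idx, drop = FALSE], 1, paste, collapse = ""),
                      rownames(mats))
    })
  }
}

#' Test monophyly of a tip set
#'
#' Unrooted trees are rooted on `outgroup` first; the test is whether the
#' smallest clade containing `tips` contains no other tips.
#'
#' @param tree `phylo`.
#' @param tips Character vector of tip labels.
#' @param outgroup Tip (or tip set) used to root unrooted input.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, tips, outgroup = NULL) {
  unknown <- setdiff(c(tips, outgroup), tree$tip.label)
  if (length(unknown) > 0) stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else if (!ape::is.rooted(tree)) {
    stop("tree is unrooted; supply an outgroup")
  }
  if (length(tips) <= 1) return(TRUE)
  ape::is.monophyletic(tree, tips)
}

#' Parse a Newick string or file
#'
#' @param text Newick text (or a file path if `file = TRUE`).
#' @param file Treat `text` as a path.
#' @return `phylo` tree; internal node labels (e.g. bootstrap supports) are
#'   preserved in `node.label`.
#' @export
parse_newick <- function(text, file = FALSE) {
  tree <- if (file) ape::read.tree(text) else ape::read.tree(text = text)
  if (is.null(tree)) stop("malformed Newick")
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree `phylo`.
#' @param path Optional output file; when `NULL` the string is returned.
#' @return Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}
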