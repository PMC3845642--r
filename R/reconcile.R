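# Gene-tree/species-tree reconciliation (LCA mapping) and Dollo
# minimum-loss counting from presence/absence.
#
# Branch naming: every species-tree branch is identified by the clade it
# subtends -- the sorted tip labels joined with "+" (a tip branch is just
# the tip label).

species_branch_id <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  paste(sort(tree$tip.label[tip_descendants(tree, node)]), collapse = "+")
}

# parent lookup: vector indexed by node, 0 for root
parent_vec <- function(tree) {
  p <- integer(max(tree$edge))
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# nodes on the path from a (exclusive) up to b (exclusive), where b is an
# ancestor of a (or a itself: empty)
nodes_between <- function(tree, a, b, parents) {
  out <- integer(0)
  if (a == b) return(out)
  cur <- parents[a]
  while (cur != 0 && cur != b) {
    out <- c(out, cur)
    cur <- parents[cur]
  }
  out
}

#' LCA reconciliation of a gene tree with a species tree
#'
#' Standard last-common-ancestor mapping: every gene-tree node maps to the
#' species-tree MRCA of its tip species; a node is a duplication iff it
#' maps to the same species node as one of its children. Losses are
#' counted by the usual gap rule along species-tree paths and placed on the
#' species branches skipped over.
#'
#' @param gene_tree Rooted `phylo` gene tree.
#' @param species_tree Rooted `phylo` species tree (tips = species codes).
#' @param species_of Named character vector: gene-tree tip -> species code
#'   (default parsed from tip labels).
#' @return Object of class `reconciliation`: `duplications` and `losses`
#'   (named count vectors over species-branch ids), `total_dups`,
#'   `total_losses`, `node_events` (per gene-tree internal node:
#'   `"duplication"`/`"speciation"`).
#' @export
lca_reconcile <- function(gene_tree, species_tree, species_of = NULL) {
  if (!ape::is.rooted(gene_tree)) stop("gene tree must be rooted")
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  gtips <- gene_tree$tip.label
  if (is.null(species_of)) {
    species_of <- stats::setNames(species_code_of(gtips), gtips)
  }
  unmapped <- gtips[!(species_of[gtips] %in% species_tree$tip.label)]
  if (length(unmapped) > 0) {
    stop("gene-tree tip(s) mapped to no species-tree tip: ",
         paste(unmapped, collapse = ", "))
  }
  n_gtip <- length(gtips)
  n_gnode <- n_gtip + gene_tree$Nnode
  sparents <- parent_vec(species_tree)

  # species-node depth (root = 0) for LCA computation
  sdepth <- integer(max(species_tree$edge))
  root_s <- setdiff(species_tree$edge[, 1], species_tree$edge[, 2])[1]
  walk <- function(nd, d) {
    sdepth[nd] <<- d
    for (k in species_tree$edge[species_tree$edge[, 1] == nd, 2]) walk(k, d + 1L)
  }
  walk(root_s, 0L)

  s_lca <- function(a, b) {
    while (a != b) {
      if (sdepth[a] < sdepth[b]) b <- sparents[b] else a <- sparents[a]
    }
    a
  }

  # postorder map of gene nodes to species nodes
  M <- integer(n_gnode)
  for (i in seq_len(n_gtip)) {
    M[i] <- match(species_of[gtips[i]], species_tree$tip.label)
  }
  children <- function(nd) gene_tree$edge[gene_tree$edge[, 1] == nd, 2]
  # recursive mapping (trees are modest)
  map_node <- function(nd) {
    if (nd <= n_gtip) return(M[nd])
    kids <- children(nd)
    ms <- vapply(kids, map_node, integer(1))
    Reduce(s_lca, ms)
  }
  root_g <- setdiff(gene_tree$edge[, 1], gene_tree$edge[, 2])[1]
  for (nd in (n_gtip + 1):n_gnode) M[nd] <- map_node(nd)

  dup_counts <- loss_counts <- numeric(0)
  bump <- function(counts, id, by = 1) {
    cur <- if (id %in% names(counts)) counts[[id]] else 0
    counts[id] <- cur + by
    counts
  }
  node_events <- character(0)
  for (nd in (n_gtip + 1):n_gnode) {
    kids <- children(nd)
    is_dup <- any(M[kids] == M[nd])
    node_events[as.character(nd)] <- if (is_dup) "duplication" else "speciation"
    if (is_dup) {
      dup_counts <- bump(dup_counts, species_branch_id(species_tree, M[nd]))
    }
    # losses along each child edge: species nodes strictly between the
    # child's map and this node's map; plus, at a speciation node, no loss
    # at M[nd] itself; at a duplication, a child mapping above a proper
    # descendant implies loss of the other side at every skipped node AND
    # at M[nd] if the child maps strictly below it
    for (kd in kids) {
      between <- nodes_between(species_tree, M[kd], M[nd], sparents)
      skipped <- between
      if (is_dup && M[kd] != M[nd]) {
        # duplication: path effectively starts at M[nd] itself
        skipped <- c(skipped, M[nd])
      }
      for (sn in skipped) {
        # the lost side is every child branch of sn not on the path
        on_path <- c(M[kd], between)
        for (sk in species_tree$edge[species_tree$edge[, 1] == sn, 2]) {
          if (!(sk %in% on_path) && !is_ancestor_of(species_tree, sk, M[kd], sparents)) {
            loss_counts <- bump(loss_counts, species_branch_id(species_tree, sk))
          }
        }
      }
    }
  }
  structure(list(duplications = dup_counts, losses = loss_counts,
                 total_dups = as.integer(sum(dup_counts)),
                 total_losses = as.integer(sum(loss_counts)),
                 node_events = node_events),
            class = "reconciliation")
}

is_ancestor_of <- function(tree, anc, node, parents) {
  cur <- node
  while (cur != 0) {
    if (cur == anc) return(TRUE)
    cur <- parents[cur]
  }
  FALSE
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("<reconciliation>", x$total_dups, "duplication(s),",
      x$total_losses, "loss(es)\n")
  invisible(x)
}

#' Dollo minimum-loss count for a presence/absence pattern
#'
#' Under single-origin (Dollo) parsimony the minimum number of independent
#' losses is the number of maximal all-absent clades below the origin;
#' each loss is placed on the branch subtending such a clade.
#'
#' @param presence Named logical vector: species code -> present. Species
#'   of the tree missing from the vector are an error.
#' @param species_tree Rooted `phylo` species tree.
#' @param origin Node (id or branch label) assumed to carry the single
#'   gain; default the MRCA of the full tip set considered (commonly the
#'   eutherian root). Must be ancestral to every present species.
#' @return List of class `dollo_losses`: `n_losses`, `loss_branches`
#'   (branch ids as in [lca_reconcile()]).
#' @export
dollo_min_losses <- function(presence, species_tree, origin = NULL) {
  tips <- species_tree$tip.label
  scope <- names(presence)
  unknown <- setdiff(scope, tips)
  if (length(unknown) > 0) stop("species not in tree: ",
                                paste(unknown, collapse = ", "))
  present_sp <- scope[presence]
  parents <- parent_vec(species_tree)
  if (is.null(origin)) {
    origin <- if (length(scope) > 1) ape::getMRCA(species_tree, scope)
              else match(scope, tips)
  }
  for (sp in present_sp) {
    if (!is_ancestor_of(species_tree, origin, match(sp, tips), parents) &&
        origin != match(sp, tips)) {
      stop("present species outside origin clade: ", sp)
    }
  }
  # recursion over the origin subtree, restricted to scoped tips
  n_tip <- length(tips)
  losses <- character(0)
  visit <- function(nd) {
    # returns TRUE if subtree (within scope) contains a present species
    if (nd <= n_tip) {
      sp <- tips[nd]
      if (!(sp %in% scope)) return(NA)          # out of scope
      return(sp %in% present_sp)
    }
    kids <- species_tree$edge[species_tree$edge[, 1] == nd, 2]
    vals <- vapply(kids, visit, logical(1))
    in_scope <- !is.na(vals)
    if (!any(in_scope)) return(NA)
    if (any(vals[in_scope])) {
      # present somewhere below: any all-absent child subtree is one loss
      for (k in seq_along(kids)) {
        if (in_scope[k] && !vals[k]) {
          losses <<- c(losses, species_branch_id(species_tree, kids[k]))
        }
      }
      return(TRUE)
    }
    FALSE
  }
  res <- visit(origin)
  if (identical(res, FALSE)) {
    # gene absent everywhere below origin: a single loss at the origin
    losses <- species_branch_id(species_tree, origin)
  }
  structure(list(n_losses = length(losses), loss_branches = losses),
            class = "dollo_losses")
}

#' @export
print.dollo_losses <- function(x, ...) {
  cat("<dollo_losses>", x$n_losses, "independent loss(es)")
  if (x$n_losses > 0) cat(" on:", paste(x$loss_branches, collapse = ", "))
  cat("\n")
  invisible(x)
}
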