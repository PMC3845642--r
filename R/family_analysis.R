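# Lineage assignment, ortholog sets, paralog groups, gene sorting,
# selection summaries, and dN-vs-dS saturation profiles.

#' Assign genes to ancestral lineages by nearest reference
#'
#' Each protein is scored against every lineage reference by global
#' alignment; the best-scoring lineage wins. Genes whose best score falls
#' below `min_score_frac` of the reference self-score are assigned to
#' `"Others"` with a warning.
#'
#' @param calls List of `gene_call` objects (functional calls carry a
#'   protein; pseudogenes are assigned from their best-frame translation of
#'   the defect-masked protein if available, else skipped to `"Others"`).
#' @param references Named character vector: lineage name -> reference
#'   protein.
#' @param min_score_frac Score threshold relative to the reference
#'   self-alignment score (default 0.3).
#' @return Named character vector: gene id -> lineage.
#' @export
assign_lineage <- function(calls, references, min_score_frac = 0.3) {
  if (length(references) == 0) stop("empty reference set")
  self_scores <- vapply(references, function(p)
    pairwise_protein_align(p, p)$score, numeric(1))
  out <- character(0)
  low <- character(0)
  for (call in calls) {
    prot <- call$protein
    if (is.na(prot) || !nzchar(prot)) {
      out[call$id] <- "Others"
      next
    }
    scores <- vapply(references, function(refp)
      pairwise_protein_align(refp, prot)$score, numeric(1))
    best <- which.max(scores)
    if (scores[best] < min_score_frac * self_scores[best]) {
      out[call$id] <- "Others"
      low <- c(low, call$id)
    } else {
      out[call$id] <- names(references)[best]
    }
  }
  if (length(low) > 0) {
    warning("low-score assignment to 'Others': ", paste(low, collapse = ", "))
  }
  out
}

#' Build a one-gene-per-species ortholog set for a lineage
#'
#' When a species has several co-orthologs one is chosen at random
#' (seeded); the choice seed is recorded so sets are reproducible.
#'
#' @param ids Gene ids belonging to one lineage (functional genes).
#' @param species Species code per id (defaults to parsing the ids).
#' @param seed Seed for the random co-ortholog choice.
#' @return Object of class `ortholog_set`: list with `lineage_members`
#'   (named character vector species -> chosen id), `seed`, `n`.
#' @export
build_ortholog_set <- function(ids, species = NULL, seed = 1) {
  if (is.null(species)) species <- species_code_of(ids)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  chosen <- vapply(split(ids, species), function(g)
    if (length(g) == 1) g else sample(g, 1), character(1))
  structure(list(lineage_members = chosen, seed = as.integer(seed),
                 n = length(chosen)), class = "ortholog_set")
}

#' All unordered pairs of an ortholog set (or of any id vector)
#'
#' @param set `ortholog_set`, or a character vector of ids.
#' @return Two-column character matrix of C(n,2) pairs (zero rows, with a
#'   warning, when n < 2).
#' @export
build_ortholog_pairs <- function(set) {
  ids <- if (inherits(set, "ortholog_set")) unname(set$lineage_members) else set
  n <- length(ids)
  if (n < 2) {
    warning("fewer than 2 members: no pairs")
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("a", "b"))))
  }
  idx <- utils::combn(n, 2)
  cbind(a = ids[idx[1, ]], b = ids[idx[2, ]])
}

#' Detect species-specific paralog groups in a lineage gene tree
#'
#' A paralog group is a maximal clade whose functional tips (>= 2) all
#' belong to one species; pseudogene tips may sit inside the clade but are
#' not members.
#'
#' @param tree Rooted `phylo` gene tree (root with an outgroup first).
#' @param species_of Named character vector: tip label -> species code.
#' @param functional Named logical vector: tip label -> functional status
#'   (default: no `ps` suffix in the label).
#' @return List of `paralog_group` objects: `species`, `members`
#'   (functional tip ids), `n`, `pair_count`.
#' @export
detect_paralog_groups <- function(tree, species_of = NULL, functional = NULL) {
  tips <- tree$tip.label
  if (is.null(species_of)) {
    species_of <- stats::setNames(species_code_of(tips), tips)
  }
  if (is.null(functional)) {
    functional <- stats::setNames(!grepl("ps[0-9]*$", tips), tips)
  }
  if (!ape::is.rooted(tree)) stop("gene tree must be rooted")
  n_tip <- length(tips)
  groups <- list()
  claimed <- character(0)
  # preorder over internal nodes: largest clades first => maximality
  node_order <- (n_tip + 1):(n_tip + tree$Nnode)
  clade_sizes <- vapply(node_order, function(nd)
    length(tip_descendants(tree, nd)), integer(1))
  for (nd in node_order[order(-clade_sizes)]) {
    cl_tips <- tips[tip_descendants(tree, nd)]
    fun_tips <- cl_tips[functional[cl_tips]]
    if (length(fun_tips) < 2) next
    if (length(unique(species_of[fun_tips])) != 1) next
    if (any(fun_tips %in% claimed)) next
    claimed <- c(claimed, fun_tips)
    groups[[length(groups) + 1L]] <- structure(
      list(species = unique(species_of[fun_tips]),
           members = fun_tips, n = length(fun_tips),
           pair_count = choose(length(fun_tips), 2)),
      class = "paralog_group")
  }
  groups
}

tip_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) tip_descendants(tree, k)))
}

#' Detect gene sorting between two species in a lineage tree
#'
#' Gene sorting (differential retention of pre-speciation duplicates)
#' shows as interleaving: within the smallest clade containing both
#' species' tips, neither species' tips are monophyletic.
#'
#' @param tree Rooted `phylo` gene tree.
#' @param species_pair Character vector of two species codes.
#' @param species_of Named character vector tip -> species (default parsed
#'   from tip labels).
#' @return List: `sorting` (logical), `shared_clade_tips`.
#' @export
detect_gene_sorting <- function(tree, species_pair, species_of = NULL) {
  tips <- tree$tip.label
  if (is.null(species_of)) {
    species_of <- stats::setNames(species_code_of(tips), tips)
  }
  t1 <- tips[species_of[tips] == species_pair[1]]
  t2 <- tips[species_of[tips] == species_pair[2]]
  if (length(t1) == 0 || length(t2) == 0) {
    stop("species absent from tree: ",
         paste(species_pair[c(length(t1) == 0, length(t2) == 0)], collapse = ", "))
  }
  if (length(t1) < 2 || length(t2) < 2) {
    stop("gene sorting test needs >= 2 tips per species")
  }
  mrca <- ape::getMRCA(tree, c(t1, t2))
  clade <- ape::extract.clade(tree, mrca)
  m1 <- is_monophyletic(clade, intersect(t1, clade$tip.label))
  m2 <- is_monophyletic(clade, intersect(t2, clade$tip.label))
  list(sorting = !m1 && !m2, shared_clade_tips = clade$tip.label)
}

#' Selection summary for a paralog group or ortholog set
#'
#' All pairwise modified Nei-Gojobori estimates (per-pair gap removal),
#' their means with codon-bootstrap standard errors, the mean of pairwise
#' dN/dS ratios (pairs with dS = 0 are excluded from the ratio mean and
#' reported), the count of pairs with ratio > 1, and -- for groups of three
#' or more members -- a one-tail paired t-test of mean dN > mean dS.
#'
#' @param members Character vector of member ids (>= 2).
#' @param alignment `codon_alignment` containing all members.
#' @param R Transition/transversion ratio.
#' @param replicates Bootstrap replicates for the SEs of mean dS / mean dN.
#' @param seed Bootstrap seed.
#' @param ratio_method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @param group_id Label for reporting.
#' @return Object of class `selection_summary`.
#' @export
selection_summary <- function(members, alignment, R = 2, replicates = 1000,
                              seed = 1, ratio_method = c("mean_of_ratios",
                                                         "ratio_of_means"),
                              group_id = NULL) {
  ratio_method <- match.arg(ratio_method)
  if (inherits(members, "paralog_group")) {
    group_id <- group_id %||% paste0(members$species, "-group")
    members <- members$members
  } else if (inherits(members, "ortholog_set")) {
    members <- unname(members$lineage_members)
  }
  if (length(members) < 2) stop("need >= 2 members")
  missing <- setdiff(members, alignment$ids)
  if (length(missing) > 0) stop("members absent from alignment: ",
                                paste(missing, collapse = ", "))
  idx <- match(members, alignment$ids)
  pairs <- utils::combn(length(idx), 2)
  ests <- lapply(seq_len(ncol(pairs)), function(k)
    pair_dnds(alignment, idx[pairs[1, k]], idx[pairs[2, k]], R = R))
  dS <- vapply(ests, function(e) e$dS, numeric(1))
  dN <- vapply(ests, function(e) e$dN, numeric(1))
  ratio <- vapply(ests, function(e) e$ratio, numeric(1))
  n_pairs <- length(ests)

  # bootstrap SEs of the mean dS / mean dN over pairs (codon resampling)
  se <- c(dS = NA_real_, dN = NA_real_)
  if (replicates > 0) {
    mat <- codon_matrix(alignment)
    boot <- bootstrap_se(function(col_idx) {
      sub <- mat[, col_idx, drop = FALSE]
      rows <- stats::setNames(apply(sub, 1, paste, collapse = ""), alignment$ids)
      al <- new_codon_alignment(alignment$ids, rows)
      vals <- vapply(seq_len(ncol(pairs)), function(k) {
        e <- pair_dnds(al, idx[pairs[1, k]], idx[pairs[2, k]], R = R)
        c(e$dS, e$dN)
      }, numeric(2))
      c(dS = mean(vals[1, ]), dN = mean(vals[2, ]))
    }, n_columns = alignment$column_count, replicates = replicates, seed = seed)
    se <- boot$se
  }

  usable_ratio <- !is.na(ratio)
  mean_ratio <- switch(ratio_method,
    mean_of_ratios = if (any(usable_ratio)) mean(ratio[usable_ratio]) else NA_real_,
    ratio_of_means = if (mean(dS, na.rm = TRUE) > 0)
      mean(dN, na.rm = TRUE) / mean(dS, na.rm = TRUE) else NA_real_)

  p_value <- NA_real_
  if (length(members) >= 3) {
    ok <- !is.na(dN) & !is.na(dS)
    if (sum(ok) >= 2) {
      p_value <- tryCatch(
        stats::t.test(dN[ok], dS[ok], paired = TRUE,
                      alternative = "greater")$p.value,
        error = function(e) NA_real_)   # constant differences
    }
  }
  structure(list(
    group_id = group_id %||% paste(members[1], "group"),
    members = members, n = length(members),
    mean_dS = mean(dS, na.rm = TRUE), se_dS = unname(se[["dS"]]),
    mean_dN = mean(dN, na.rm = TRUE), se_dN = unname(se[["dN"]]),
    mean_ratio = mean_ratio, ratio_method = ratio_method,
    pairs_gt1 = sum(ratio > 1, na.rm = TRUE),
    total_pairs = n_pairs,
    pairs_dS_zero = sum(is.na(ratio) & !is.na(dS) & dS == 0),
    p_value = p_value,
    pairwise = data.frame(a = members[pairs[1, ]], b = members[pairs[2, ]],
                          dS = dS, dN = dN, ratio = ratio)),
    class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf("<selection_summary> %s  n=%d  dS=%.3f (%.3f)  dN=%.3f (%.3f)  dN/dS=%s  >1: %d/%d  p=%s\n",
              x$group_id, x$n, x$mean_dS, x$se_dS, x$mean_dN, x$se_dN,
              if (is.na(x$mean_ratio)) "NA" else sprintf("%.3f", x$mean_ratio),
              x$pairs_gt1, x$total_pairs,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Flatten selection summaries into a report table
#'
#' @param summaries List of `selection_summary` objects.
#' @return data.frame with one row per group (NA p-value for two-member
#'   groups).
#' @export
selection_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(x) {
    data.frame(group = x$group_id, n = x$n,
               mean_dS = x$mean_dS, se_dS = x$se_dS,
               mean_dN = x$mean_dN, se_dN = x$se_dN,
               mean_ratio = x$mean_ratio,
               p_value = x$p_value,
               pairs_gt1 = x$pairs_gt1, total_pairs = x$total_pairs,
               stringsAsFactors = FALSE)
  }))
}

#' Saturation profile of dN against dS over ortholog pairs
#'
#' Points are sorted by dS and a two-segment regression locates the
#' breakpoint minimizing the residual sum of squares; a plateau is called
#' when the upper-segment slope falls below `plateau_frac` of the
#' lower-segment slope.
#'
#' @param pairs data.frame with columns `dS`, `dN` (one row per ortholog
#'   pair).
#' @param min_points Minimum points required (default 10).
#' @param plateau_frac Slope-ratio threshold (default 0.25).
#' @return Object of class `saturation_profile`: `points`,
#'   `plateau_detected`, `plateau_onset_dS` (NA when no plateau),
#'   `slope_low`, `slope_high`.
#' @export
saturation_profile <- function(pairs, min_points = 10, plateau_frac = 0.25) {
  pts <- pairs[stats::complete.cases(pairs[, c("dS", "dN")]), , drop = FALSE]
  if (nrow(pts) < min_points) {
    stop("insufficient data: ", nrow(pts), " points < ", min_points)
  }
  pts <- pts[order(pts$dS), ]
  n <- nrow(pts)
  # detection: slope over the lower vs upper half of the dS range
  mid <- (min(pts$dS) + max(pts$dS)) / 2
  lo_half <- pts[pts$dS <= mid, ]; hi_half <- pts[pts$dS > mid, ]
  if (nrow(lo_half) < 3 || nrow(hi_half) < 3) {
    stop("insufficient spread in dS for plateau assessment")
  }
  slope_of <- function(d) unname(stats::coef(stats::lm(dN ~ dS, data = d))[2])
  slope_low <- slope_of(lo_half)
  slope_high <- slope_of(hi_half)
  plateau <- slope_low > 0 && slope_high < plateau_frac * slope_low
  # onset: two-segment breakpoint minimizing the residual sum of squares,
  # each segment keeping at least 5 points to avoid overfitting the tail
  onset <- NA_real_
  if (plateau) {
    margin <- max(5L, n %/% 6L)
    best <- NULL
    for (k in margin:(n - margin)) {
      lo <- pts[1:k, ]; hi <- pts[(k + 1):n, ]
      if (diff(range(lo$dS)) == 0 || diff(range(hi$dS)) == 0) next
      sse <- sum(stats::resid(stats::lm(dN ~ dS, data = lo))^2) +
        sum(stats::resid(stats::lm(dN ~ dS, data = hi))^2)
      if (is.null(best) || sse < best$sse) best <- list(sse = sse, k = k)
    }
    if (!is.null(best)) onset <- pts$dS[best$k]
  }
  structure(list(points = pts, plateau_detected = plateau,
                 plateau_onset_dS = onset,
                 slope_low = slope_low, slope_high = slope_high),
            class = "saturation_profile")
}
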