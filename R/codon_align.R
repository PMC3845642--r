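# Protein-guided codon alignment with complete-deletion site filtering.
#
# Alignment is done on proteins (pairwise Needleman-Wunsch via Biostrings;
# progressive profile merging along an NJ guide tree for >2 sequences) and
# then back-translated so that every alignment column is a codon column.
# Complete deletion removes every codon column containing a gap in any row
# before distances are computed.

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch with affine gaps (default BLOSUM62, gap open 10,
#' extend 0.5).
#'
#' @param a,b Protein strings (non-empty).
#' @param matrix Substitution matrix name available in Biostrings data,
#'   default `"BLOSUM62"`.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return List with aligned strings `a`, `b` (gap `"-"`) and `score`.
#' @export
pairwise_protein_align <- function(a, b, matrix = "BLOSUM62",
                                   gap_open = 10, gap_extend = 0.5) {
  stopifnot(nzchar(a), nzchar(b))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

# --- progressive MSA --------------------------------------------------------

# score of aligning profile column i (list of chars) against column j,
# averaging substitution scores over residue pairs; gap chars contribute 0.
profile_column_score <- function(col_a, col_b, submat) {
  ra <- col_a[col_a != "-"]; rb <- col_b[col_b != "-"]
  if (length(ra) == 0 || length(rb) == 0) return(0)
  mean(submat[ra, rb, drop = FALSE])
}

# Needleman-Wunsch (affine) on two profiles: character matrices rows x cols.
align_profiles <- function(pa, pb, submat, gap_open = 10, gap_extend = 0.5) {
  la <- ncol(pa); lb <- ncol(pb)
  colsA <- lapply(seq_len(la), function(j) pa[, j])
  colsB <- lapply(seq_len(lb), function(j) pb[, j])
  S <- matrix(0, la, lb)
  for (i in seq_len(la)) for (j in seq_len(lb))
    S[i, j] <- profile_column_score(colsA[[i]], colsB[[j]], submat)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, la + 1L, lb + 1L)
  M[1, 1] <- 0
  if (lb >= 1) Y[1, 2:(lb + 1)] <- -gap_open - gap_extend * (seq_len(lb) - 1)
  if (la >= 1) X[2:(la + 1), 1] <- -gap_open - gap_extend * (seq_len(la) - 1)
  # traceback pointers: 1=M,2=X(gap in B),3=Y(gap in A)
  tbM <- tbX <- tbY <- matrix(0L, la + 1L, lb + 1L)
  for (i in 2:(la + 1)) {
    for (j in 2:(lb + 1)) {
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(prev)            # tie: prefer match > delete > insert
      M[i, j] <- prev[k] + S[i - 1, j - 1]; tbM[i, j] <- k
      opn <- c(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend)
      k <- which.max(opn)
      X[i, j] <- opn[k]; tbX[i, j] <- c(1L, 2L)[k]
      opn <- c(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_extend)
      k <- which.max(opn)
      Y[i, j] <- opn[k]; tbY[i, j] <- c(1L, 3L)[k]
    }
  }
  i <- la + 1L; j <- lb + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  path_a <- integer(0); path_b <- integer(0)  # 0 marks a gap column
  while (i > 1L || j > 1L) {
    if (i == 1L) state <- 3L
    if (j == 1L) state <- 2L
    if (state == 1L) {
      path_a <- c(i - 1L, path_a); path_b <- c(j - 1L, path_b)
      state <- tbM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      path_a <- c(i - 1L, path_a); path_b <- c(0L, path_b)
      state <- tbX[i, j]; i <- i - 1L
    } else {
      path_a <- c(0L, path_a); path_b <- c(j - 1L, path_b)
      state <- tbY[i, j]; j <- j - 1L
    }
  }
  gapcol_a <- matrix("-", nrow(pa), 1L)
  gapcol_b <- matrix("-", nrow(pb), 1L)
  out_a <- do.call(cbind, lapply(path_a, function(k)
    if (k == 0L) gapcol_a else pa[, k, drop = FALSE]))
  out_b <- do.call(cbind, lapply(path_b, function(k)
    if (k == 0L) gapcol_b else pb[, k, drop = FALSE]))
  rbind(out_a, out_b)
}

#' Progressive multiple alignment of proteins
#'
#' Pairwise p-distances on pairwise alignments give a guide tree
#' (neighbor joining); profiles are merged postorder along it.
#'
#' @param proteins Named character vector of protein strings (>= 2; a
#'   single sequence is returned unchanged with a warning).
#' @param matrix,gap_open,gap_extend Scoring as in
#'   [pairwise_protein_align()].
#' @return Named character vector of aligned rows (equal length).
#' @export
progressive_msa <- function(proteins, matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  n <- length(proteins)
  if (is.null(names(proteins))) names(proteins) <- paste0("seq", seq_len(n))
  if (n == 1) {
    warning("single sequence: returned unchanged")
    return(proteins)
  }
  if (n == 2) {
    al <- pairwise_protein_align(proteins[[1]], proteins[[2]], matrix,
                                 gap_open, gap_extend)
    return(stats::setNames(c(al$a, al$b), names(proteins)))
  }
  submat <- get_submat(matrix)
  # guide distances: p-distance over pairwise-aligned, gap-excluded columns
  D <- matrix(0, n, n, dimnames = list(names(proteins), names(proteins)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- pairwise_protein_align(proteins[[i]], proteins[[j]], matrix,
                                 gap_open, gap_extend)
    ca <- strsplit(al$a, "")[[1]]; cb <- strsplit(al$b, "")[[1]]
    keep <- ca != "-" & cb != "-"
    d <- if (any(keep)) mean(ca[keep] != cb[keep]) else 1
    D[i, j] <- D[j, i] <- d
  }
  merge_order <- guide_merge_order(D)
  profiles <- lapply(proteins, function(p) {
    matrix(strsplit(p, "")[[1]], nrow = 1)
  })
  names(profiles) <- names(proteins)
  members <- as.list(names(proteins))
  for (pair in merge_order) {
    i <- pair[1]; j <- pair[2]
    merged <- align_profiles(profiles[[i]], profiles[[j]], submat,
                             gap_open, gap_extend)
    rownames(merged) <- NULL
    profiles[[i]] <- merged
    members[[i]] <- c(members[[i]], members[[j]])
    profiles[[j]] <- NULL
    members[[j]] <- NULL
  }
  final <- profiles[[1]]
  rows <- apply(final, 1, paste, collapse = "")
  stats::setNames(rows, members[[1]])[names(proteins)]
}

get_submat <- function(matrix) {
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

# NJ-style agglomeration order on a distance matrix: returns a list of
# index pairs (into the shrinking profile list) to merge.
guide_merge_order <- function(D) {
  labels <- rownames(D)
  active <- seq_along(labels)        # positions in the profile list
  order <- list()
  Dw <- D
  while (length(active) > 1) {
    m <- length(active)
    if (m == 2) {
      order[[length(order) + 1L]] <- c(1L, 2L)
      break
    }
    r <- rowSums(Dw)
    Q <- (m - 2) * Dw - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    # deterministic tie-break: smallest row, then column index
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- min(idx[1, ]); j <- max(idx[1, ])
    order[[length(order) + 1L]] <- c(i, j)
    # merged profile sits at position i; distances by average linkage
    newd <- (Dw[i, ] + Dw[j, ]) / 2
    Dw[i, ] <- Dw[, i] <- newd
    Dw[i, i] <- 0
    Dw <- Dw[-j, -j, drop = FALSE]
    active <- active[-j]
  }
  order
}

# --- codon alignment container ---------------------------------------------

new_codon_alignment <- function(ids, rows, site_mask = NULL) {
  ncol <- nchar(rows[1]) / 3L
  if (is.null(site_mask)) site_mask <- rep(TRUE, ncol)
  structure(list(ids = ids, rows = stats::setNames(rows, ids),
                 site_mask = site_mask, column_count = as.integer(ncol)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment>", length(x$ids), "rows x", x$column_count,
      "codon columns (", sum(x$site_mask), "retained )\n")
  invisible(x)
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Each amino-acid column becomes one codon column; protein gaps become
#' `"---"`. Every CDS must translate exactly to its row's gap-stripped
#' protein. In `mask_stops` mode internal stop codons are tolerated and
#' recoded as `NNN` (missing data) so pseudogenes can participate.
#'
#' @param protein_alignment Named character vector of aligned proteins.
#' @param cds Named character vector of coding sequences (same names).
#' @param mask_stops Allow and mask internal stops (default FALSE).
#' @return `codon_alignment`.
#' @export
backtranslate_to_codons <- function(protein_alignment, cds, mask_stops = FALSE) {
  ids <- names(protein_alignment)
  if (!all(ids %in% names(cds))) {
    stop("missing CDS for: ", paste(setdiff(ids, names(cds)), collapse = ", "))
  }
  rows <- vapply(ids, function(id) {
    prot <- protein_alignment[[id]]
    seq <- toupper(cds[[id]])
    codons <- split_codons(seq)
    aa <- codon_aa(codons)
    # drop one terminal stop if present
    if (length(aa) > 0 && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    if (any(aa == "*")) {
      if (!mask_stops) {
        stop("internal stop codon in CDS '", id, "' at codon ",
             which(aa == "*")[1], "; use mask_stops mode for pseudogenes")
      }
      codons[aa == "*"] <- "NNN"
      aa[aa == "*"] <- "X"
    }
    pchars <- strsplit(prot, "")[[1]]
    res <- pchars[pchars != "-"]
    if (length(res) != length(aa) ||
        any(res != aa & res != "X" & aa != "X")) {
      first_bad <- which(res != aa)[1]
      stop("CDS '", id, "' does not translate to its aligned protein",
           " (first discordant position ", first_bad %||% NA, ")")
    }
    out <- character(length(pchars))
    out[pchars == "-"] <- "---"
    out[pchars != "-"] <- codons
    paste(out, collapse = "")
  }, character(1))
  new_codon_alignment(ids, rows)
}

#' Apply complete deletion to a codon alignment
#'
#' Marks every codon column containing a gap (or masked `NNN` codon) in any
#' row as removed; downstream distance operations see only retained
#' columns. Idempotent.
#'
#' @param alignment `codon_alignment`.
#' @return `codon_alignment` with an updated `site_mask`.
#' @export
complete_deletion <- function(alignment) {
  mat <- codon_matrix(alignment)
  bad <- apply(mat, 2, function(col) any(col == "---" | grepl("N", col)))
  mask <- alignment$site_mask & !bad
  if (!any(mask)) stop("no comparable sites after complete deletion")
  alignment$site_mask <- mask
  alignment
}

# codon columns as a matrix rows x columns (characters of width 3)
codon_matrix <- function(alignment) {
  t(vapply(alignment$rows, function(r) split_codons(r),
           character(alignment$column_count)))
}

#' Extract the retained (masked-true) codon columns as sequences
#'
#' @param alignment `codon_alignment`.
#' @return Named character vector of gap-free codon sequences.
#' @export
retained_codon_rows <- function(alignment) {
  mat <- codon_matrix(alignment)[, alignment$site_mask, drop = FALSE]
  stats::setNames(apply(mat, 1, paste, collapse = ""), alignment$ids)
}

#' Align coding sequences into a codon alignment
#'
#' Convenience wrapper: translate, progressively align the proteins,
#' back-translate, and (optionally) apply complete deletion.
#'
#' @param cds Named character vector of coding sequences.
#' @param mask_stops Tolerate internal stops (pseudogene mode).
#' @param apply_complete_deletion Apply [complete_deletion()] (default TRUE).
#' @return `codon_alignment`.
#' @export
align_codons <- function(cds, mask_stops = FALSE, apply_complete_deletion = TRUE) {
  prots <- vapply(cds, function(s) {
    p <- translate_cds(s)
    p <- sub("\\*$", "", p)
    gsub("\\*", "X", p)      # masked mode: stops as missing residues
  }, character(1))
  if (!mask_stops && any(grepl("X", prots, fixed = TRUE))) {
    # X may also arise from ambiguity codes; only reject true stops
    has_stop <- vapply(cds, function(s) {
      aa <- strsplit(sub("\\*$", "", translate_cds(s)), "")[[1]]
      any(aa == "*")
    }, logical(1))
    if (any(has_stop)) {
      stop("internal stops in: ", paste(names(cds)[has_stop], collapse = ", "),
           "; use mask_stops = TRUE")
    }
  }
  msa <- progressive_msa(prots)
  al <- backtranslate_to_codons(msa, cds, mask_stops = mask_stops)
  if (apply_complete_deletion) al <- complete_deletion(al)
  al
}
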