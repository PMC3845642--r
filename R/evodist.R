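# Pairwise evolutionary distances: p-distance, Kimura 2-parameter, and the
# modified Nei-Gojobori dN/dS estimator with Jukes-Cantor correction and
# bootstrap standard errors.
#
# Counting conventions (documented because the literature varies):
#  * site counting weights each possible change by the assumed
#    transition/transversion ratio R (transitions weight R, transversions
#    weight 1); changes creating stop codons count as nonsynonymous so
#    that S + N = 3 x (codon columns) exactly;
#  * differences between codons are apportioned by unweighted averaging
#    over all minimal mutational pathways, excluding pathways that pass
#    through a stop codon (all pathways used if every one is blocked);
#  * pS and pN are corrected with the one-parameter formula
#    d = -3/4 * log(1 - 4/3 * p); p >= 3/4 is reported as saturated (NA).

#' Proportion of differing sites between two aligned strings
#'
#' @param a,b Equal-length, gap-free residue strings.
#' @return p in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) stop("unequal lengths")
  if (length(ca) == 0) stop("zero-length comparison")
  mean(ca != cb)
}

#' Transition/transversion proportions for a nucleotide pair
#'
#' @param a,b Equal-length, gap-free nucleotide strings.
#' @return Object of class `pairwise_counts`: list with `L` (compared
#'   sites), `p`, `P` (transitions), `Q` (transversions).
#' @export
pairwise_counts <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]; cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("unequal lengths")
  keep <- ca %in% DNA_BASES & cb %in% DNA_BASES
  ca <- ca[keep]; cb <- cb[keep]
  L <- length(ca)
  if (L == 0) stop("no comparable sites")
  diff <- ca != cb
  ts <- diff & is_transition(ca, cb)
  structure(list(L = L, p = mean(diff), P = mean(ts), Q = mean(diff & !ts)),
            class = "pairwise_counts")
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))`.
#'
#' @param counts `pairwise_counts` object, or a transition proportion `P`
#'   when `Q` is also given.
#' @param Q Transversion proportion (when `counts` is numeric `P`).
#' @return Distance (substitutions/site).
#' @export
k2p_distance <- function(counts, Q = NULL) {
  if (inherits(counts, "pairwise_counts")) {
    P <- counts$P; Q <- counts$Q
  } else {
    P <- counts
    if (is.null(Q)) stop("supply Q with a numeric P")
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("saturated: K2P distance undefined for P=",
                               P, ", Q=", Q)
  -0.5 * log(w1 * sqrt(w2))
}

# --- Nei-Gojobori machinery -------------------------------------------------

# Weighted synonymous site count for one codon (R = ts/tv ratio).
ng_codon_sites <- function(codon, R = 1, gc = genetic_code()) {
  bases <- strsplit(codon, "")[[1]]
  aa <- gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    num <- 0; den <- 0
    for (b in setdiff(DNA_BASES, bases[pos])) {
      w <- if (is_transition(bases[pos], b)) R else 1
      alt <- bases; alt[pos] <- b
      altc <- paste(alt, collapse = "")
      den <- den + w
      if (!(altc %in% STOP_CODONS) && gc[[altc]] == aa) num <- num + w
    }
    s <- s + num / den
  }
  s
}

# Average syn/nonsyn difference counts over minimal pathways between two
# codons. Pathways through stop codons are excluded (all used if none
# survives). Returns c(sd, nd).
ng_pair_diffs <- function(c1, c2, gc = genetic_code()) {
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- permutations_of(pos)
  tally <- function(skip_stops) {
    tot_s <- 0; tot_n <- 0; nvalid <- 0
    for (ord in perms) {
      cur <- b1; s <- 0; n <- 0; valid <- TRUE
      for (p in ord) {
        nxt <- cur; nxt[p] <- b2[p]
        ccur <- paste(cur, collapse = ""); cnxt <- paste(nxt, collapse = "")
        if (skip_stops && cnxt %in% STOP_CODONS) { valid <- FALSE; break }
        if (gc[[ccur]] == gc[[cnxt]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (valid) { tot_s <- tot_s + s; tot_n <- tot_n + n; nvalid <- nvalid + 1 }
    }
    if (nvalid == 0) return(NULL)
    c(sd = tot_s / nvalid, nd = tot_n / nvalid)
  }
  tally(TRUE) %||% tally(FALSE)
}

permutations_of <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)       # saturated
  max(0, -0.75 * log(1 - 4 * p / 3))
}

#' Modified Nei-Gojobori dN/dS for a pair of codon sequences
#'
#' Site counts are weighted by the assumed transition/transversion ratio
#' `R` (`R = 1` reduces to the classic unweighted method); differences are
#' averaged over minimal mutational pathways; the Jukes-Cantor correction
#' is applied to the synonymous and nonsynonymous proportions.
#'
#' @param a,b Gap-free, stop-free codon sequences of equal length (apply
#'   [complete_deletion()] first).
#' @param R Transition/transversion ratio used in site counting (default 2).
#' @param replicates If > 0, codon-column bootstrap replicates for
#'   standard errors of dS and dN.
#' @param seed Seed for the bootstrap.
#' @return Object of class `dnds_estimate`: list with `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `dS`, `dN`, `ratio`, `se_dS`, `se_dN`, `R`, `L` (codons
#'   compared). Saturated rates are `NA`.
#' @export
nei_gojobori_modified <- function(a, b, R = 2, replicates = 0, seed = 1) {
  ca <- split_codons(a); cb <- split_codons(b)
  if (length(ca) != length(cb)) stop("unequal codon counts")
  if (length(ca) == 0) stop("empty alignment")
  if (any(c(ca, cb) %in% STOP_CODONS)) stop("stop codon in compared columns")
  est <- ng_core(ca, cb, R)
  if (replicates > 0) {
    boot <- bootstrap_se(function(idx) {
      e <- ng_core(ca[idx], cb[idx], R)
      c(dS = e$dS, dN = e$dN)
    }, n_columns = length(ca), replicates = replicates, seed = seed)
    est$se_dS <- boot$se[["dS"]]
    est$se_dN <- boot$se[["dN"]]
    est$replicates_used <- boot$used
  }
  est
}

# Lazily cached per-codon site counts (per R) and per-codon-pair
# difference counts (R-independent): NG estimation on long alignments and
# bootstrap loops reduce to table lookups.
ng_sites_table <- function(R) {
  key <- sprintf("ng_sites_%.8g", R)
  tab <- .rnasefam_env[[key]]
  if (is.null(tab)) {
    gc <- genetic_code()
    sense <- names(gc)[gc != "*"]
    tab <- vapply(sense, ng_codon_sites, numeric(1), R = R, gc = gc)
    .rnasefam_env[[key]] <- tab
  }
  tab
}

ng_diffs_table <- function() {
  tab <- .rnasefam_env[["ng_diffs"]]
  if (is.null(tab)) {
    gc <- genetic_code()
    sense <- names(gc)[gc != "*"]
    n <- length(sense)
    SD <- ND <- matrix(0, n, n, dimnames = list(sense, sense))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- ng_pair_diffs(sense[i], sense[j], gc)
      SD[i, j] <- d[["sd"]]; ND[i, j] <- d[["nd"]]
    }
    tab <- list(SD = SD, ND = ND)
    .rnasefam_env[["ng_diffs"]] <- tab
  }
  tab
}

ng_core <- function(ca, cb, R) {
  sites <- ng_sites_table(R)
  diffs <- ng_diffs_table()
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * length(ca) - S
  idx <- cbind(match(ca, rownames(diffs$SD)), match(cb, colnames(diffs$SD)))
  Sd <- sum(diffs$SD[idx]); Nd <- sum(diffs$ND[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  ratio <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, ratio = ratio,
                 se_dS = NA_real_, se_dN = NA_real_,
                 R = R, L = length(ca)),
            class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("<dnds_estimate> L=%d codons  dS=%.4f  dN=%.4f  dN/dS=%s\n",
              x$L, x$dS, x$dN,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio)))
  invisible(x)
}

#' Codon-column bootstrap standard errors
#'
#' Resamples column indices with replacement and reports the standard
#' deviation of the replicate estimates. Replicates on which the estimator
#' returns `NA` or errors are dropped and counted.
#'
#' @param estimator Function taking an integer vector of column indices and
#'   returning a named numeric vector of statistics.
#' @param n_columns Number of resampling units (codon columns).
#' @param replicates Number of replicates (>= 100 recommended).
#' @param seed Seed; fixed seed gives bit-identical output.
#' @return List with `se` (named numeric), `used` (replicates retained),
#'   `dropped`.
#' @export
bootstrap_se <- function(estimator, n_columns, replicates, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  vals <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    idx <- sample.int(n_columns, n_columns, replace = TRUE)
    vals[[r]] <- tryCatch(estimator(idx), error = function(e) NULL)
  }
  ok <- !vapply(vals, is.null, logical(1))
  mat <- do.call(rbind, vals[ok])
  complete <- stats::complete.cases(mat)
  mat <- mat[complete, , drop = FALSE]
  se <- apply(mat, 2, stats::sd)
  list(se = se, used = nrow(mat), dropped = replicates - nrow(mat))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Pairwise estimate from an alignment with per-pair gap removal: columns
# gapped/masked in either row are dropped for that pair only.
pair_dnds <- function(alignment, i, j, R = 2, replicates = 0, seed = 1) {
  mat <- codon_matrix(alignment)
  a <- mat[i, ]; b <- mat[j, ]
  keep <- !(a == "---" | b == "---" | grepl("N", a) | grepl("N", b) |
              a %in% STOP_CODONS | b %in% STOP_CODONS)
  if (!any(keep)) stop("no comparable codon columns for pair")
  nei_gojobori_modified(paste(a[keep], collapse = ""),
                        paste(b[keep], collapse = ""),
                        R = R, replicates = replicates, seed = seed)
}

#' Pairwise distance matrix over an alignment
#'
#' @param alignment `codon_alignment` (models `p`, `k2p`, `dN`, `dS`) or a
#'   named character vector of aligned protein rows (model `p`).
#' @param model One of `"p"`, `"k2p"`, `"dN"`, `"dS"`.
#' @param R Transition/transversion ratio for the dN/dS models.
#' @return Symmetric matrix with zero diagonal; saturated pairs are `NA`
#'   and flagged via `attr(, "flagged")` (a logical matrix).
#' @export
distance_matrix <- function(alignment, model = c("p", "k2p", "dN", "dS"), R = 2) {
  model <- match.arg(model)
  if (inherits(alignment, "codon_alignment")) {
    rows <- retained_codon_rows(alignment)
  } else {
    rows <- alignment
  }
  n <- length(rows)
  ids <- names(rows)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  flagged <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- tryCatch(switch(model,
        p = p_distance(rows[[i]], rows[[j]]),
        k2p = k2p_distance(pairwise_counts(rows[[i]], rows[[j]])),
        dN = nei_gojobori_modified(rows[[i]], rows[[j]], R = R)$dN,
        dS = nei_gojobori_modified(rows[[i]], rows[[j]], R = R)$dS),
        error = function(e) NA_real_)
      if (is.na(v)) flagged[i, j] <- flagged[j, i] <- TRUE
      D[i, j] <- D[j, i] <- v
    }
  }
  attr(D, "flagged") <- flagged
  D
}
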