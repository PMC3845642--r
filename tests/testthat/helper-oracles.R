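# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles are deliberately naive re-derivations (explicit
# enumeration) kept separate from the package's table-driven code paths.

GC_TAB <- rnasefam::genetic_code()
SENSE_CODONS <- names(GC_TAB)[GC_TAB != "*"]
STOPS <- c("TAA", "TAG", "TGA")

aa_of <- function(codon) GC_TAB[[codon]]
is_ts <- function(x, y) {
  paste0(sort(c(x, y)), collapse = "") %in% c("AG", "CT")
}

# --- Nei-Gojobori oracle ----------------------------------------------------

# Weighted synonymous-site count of one codon: explicit enumeration of the
# nine single-nucleotide neighbors; stop-creating changes count as
# nonsynonymous; each position carries one transition (weight R) and two
# transversions (weight 1).
oracle_syn_sites <- function(codon, R) {
  nt <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn_w <- 0
    all_w <- 0
    for (alt in setdiff(c("A", "C", "G", "T"), nt[pos])) {
      nb <- nt; nb[pos] <- alt
      nb <- paste(nb, collapse = "")
      w <- if (is_ts(nt[pos], alt)) R else 1
      all_w <- all_w + w
      if (!(nb %in% STOPS) && aa_of(nb) == aa_of(codon)) syn_w <- syn_w + w
    }
    total <- total + syn_w / all_w
  }
  total
}

# All orderings of a vector (explicit recursion).
all_orderings <- function(v) {
  if (length(v) <= 1) return(list(v))
  res <- list()
  for (k in seq_along(v)) {
    for (tail in all_orderings(v[-k])) res <- c(res, list(c(v[k], tail)))
  }
  res
}

# Average (syn, nonsyn) step counts over minimal pathways between two
# codons, skipping pathways that visit a stop codon (all pathways if every
# one is blocked).
oracle_pair_diffs <- function(c1, c2) {
  x <- strsplit(c1, "")[[1]]; y <- strsplit(c2, "")[[1]]
  dpos <- which(x != y)
  if (length(dpos) == 0) return(c(0, 0))
  walk <- function(ord, allow_stops) {
    cur <- x; s <- 0; n <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- y[p]
      a <- paste(cur, collapse = ""); b <- paste(nxt, collapse = "")
      if (!allow_stops && b %in% STOPS) return(NULL)
      if (aa_of2(a) == aa_of2(b)) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  paths <- Filter(Negate(is.null),
                  lapply(all_orderings(dpos), walk, allow_stops = FALSE))
  if (length(paths) == 0) {
    paths <- lapply(all_orderings(dpos), walk, allow_stops = TRUE)
  }
  Reduce(`+`, paths) / length(paths)
}

aa_of2 <- function(codon) if (codon %in% STOPS) "*" else GC_TAB[[codon]]

# Full oracle estimate for two codon sequences.
oracle_dnds <- function(a, b, R) {
  ca <- rnasefam::split_codons(a); cb <- rnasefam::split_codons(b)
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1), R = R)) +
          sum(vapply(cb, oracle_syn_sites, numeric(1), R = R))) / 2
  N <- 3 * length(ca) - S
  d <- mapply(oracle_pair_diffs, ca, cb)
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    max(0, -0.75 * log(1 - 4 * p / 3))
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       dS = jc(Sd / S), dN = jc(Nd / N))
}

# --- pairwise alignment score oracle ---------------------------------------

# Three-state affine-gap DP written independently of the package. Gap
# costs follow the convention of the pairwise op: a gap of length L costs
# gap_open + gap_extend * L.
oracle_align_score <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  la <- length(x); lb <- length(y)
  NEG <- -Inf
  M <- matrix(NEG, la + 1, lb + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in 2:(la + 1)) Ix[i, 1] <- -gap_open - gap_extend * (i - 1)
  for (j in 2:(lb + 1)) Iy[1, j] <- -gap_open - gap_extend * (j - 1)
  for (i in 2:(la + 1)) for (j in 2:(lb + 1)) {
    M[i, j] <- submat[x[i - 1], y[j - 1]] +
      max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
    Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                    Ix[i - 1, j] - gap_extend)
    Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                    Iy[i, j - 1] - gap_extend)
  }
  max(M[la + 1, lb + 1], Ix[la + 1, lb + 1], Iy[la + 1, lb + 1])
}

# --- fixture builders -------------------------------------------------------

template_cds <- function() {
  rnasefam::reverse_translate(rnasefam::canonical_template()$protein)
}

# random sense-codon sequence (no stops)
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

# random rooted tree with positive branch lengths -> additive matrix
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

small_species_tree <- function() {
  rnasefam::parse_newick("((A:30,B:30):40,(C:50,(D:35,E:35):15):20);")
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "rnasefam")
}
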