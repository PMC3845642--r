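# A synthetic canonical RNase template used (a) as the default alignment
# reference for catalytic-triad annotation and (b) as the root protein of
# the gene-family simulator. It is NOT a real gene: it was written to carry
# the canonical features at known coordinates -- an N-terminal signal-like
# stretch, the His...Lys...His catalytic triad, the CKXXNTF signature motif
# (whose Lys is the catalytic lysine), and eight cysteines.

# 129 aa; stop appended when reverse-translated to a 130-codon CDS.
CANONICAL_TEMPLATE_PROTEIN <- paste0(
  "MALLVLGLLALAPLAQA",          # 1-17  signal-like
  "KESRAKKFQR",                 # 18-27
  "QSHMDS",                     # 28-33 (His30 catalytic)
  "SSPSSSSNYC", # 34-43 (C43)
  "NQMMRRRGMT",                 # 44-53
  "SCKRFNTFIH",                 # 54-63 (C55, K56 catalytic, motif CKRFNTF)
  "EDIWNIRSIC",                 # 64-73 (C73)
  "STGAIRACEN",                 # 74-83 (C81)
  "GNPYGENLRI",                 # 84-93
  "SKSSFQVTTC",                 # 94-103 (C103)
  "KLHGGSPWPP",                 # 104-113 (His106 catalytic)
  "CQYRATAGFR",                 # 114-123 (C114)
  "NVVVAC"                      # 124-129 (C129)
)

# Feature coordinates on the template (1-based protein positions).
CANONICAL_TRIAD_POSITIONS <- c(his1 = 30L, lys = 56L, his2 = 106L)
CANONICAL_MOTIF_START <- 55L
CANONICAL_SIGNAL_END <- 17L

#' Synthetic canonical RNase template
#'
#' Returns the synthetic template protein used as the default reference for
#' catalytic-triad annotation and as the simulator's root sequence, together
#' with its feature coordinates.
#'
#' @return List with `protein`, `triad_positions` (named positions of the
#'   two catalytic histidines and the lysine), `motif_start` (first residue
#'   of the CKXXNTF signature), and `signal_end` (last residue of the
#'   signal-like N-terminal stretch).
#' @export
canonical_template <- function() {
  list(protein = CANONICAL_TEMPLATE_PROTEIN,
       triad_positions = CANONICAL_TRIAD_POSITIONS,
       motif_start = CANONICAL_MOTIF_START,
       signal_end = CANONICAL_SIGNAL_END)
}

# Deterministic reverse translation: one fixed codon per amino acid.
PREFERRED_CODON <- c(
  A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTT", G = "GGA",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCA", Q = "CAA", R = "AGA", S = "AGC", T = "ACA", V = "GTT",
  W = "TGG", Y = "TAT"
)

#' Reverse-translate a protein to a CDS with fixed codon choices
#'
#' @param protein Amino-acid string (no stops).
#' @param stop Append a TAA stop codon?
#' @return Nucleotide string.
#' @export
reverse_translate <- function(protein, stop = TRUE) {
  aa <- strsplit(protein, "")[[1]]
  codons <- PREFERRED_CODON[aa]
  if (any(is.na(codons))) {
    stop("cannot reverse-translate residue(s): ",
         paste(unique(aa[is.na(codons)]), collapse = ", "))
  }
  paste0(paste(codons, collapse = ""), if (stop) "TAA" else "")
}
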