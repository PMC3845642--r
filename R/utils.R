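# Internal helpers shared across modules: genetic code access, codon
# splitting, and nucleotide classification. The standard nuclear code is
# hard-wired (via Biostrings::GENETIC_CODE) with a config override hook.

.rnasefam_env <- new.env(parent = emptyenv())

#' Standard genetic code as a named character vector
#'
#' Names are codons (DNA alphabet), values are one-letter amino acids with
#' `"*"` for stop. Callers may pass an alternative table wherever a
#' `genetic_code` argument is exposed.
#'
#' @return Named character vector of length 64.
#' @export
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")
DNA_BASES <- c("A", "C", "G", "T")

is_transition <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) | (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}

#' Split a nucleotide string into codons
#'
#' @param seq Nucleotide string whose length is a multiple of 3.
#' @return Character vector of codons.
#' @export
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3")
  }
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence
#'
#' Codons containing ambiguity codes or gaps translate to `"X"`; stops
#' translate to `"*"`.
#'
#' @param seq Nucleotide string (length a multiple of 3).
#' @param genetic_code Named codon table, default the standard code.
#' @return Amino-acid string.
#' @export
translate_cds <- function(seq, genetic_code = rnasefam::genetic_code()) {
  codons <- split_codons(seq)
  aa <- genetic_code[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# vectorised codon -> aa with "X" fallback (internal)
codon_aa <- function(codons, gc = genetic_code()) {
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Species code from "<species>-<gene>" ids without registry validation
# (internal; used where simulated taxa are routine).
species_code_of <- function(ids) sub("-.*$", "", ids)

# Draw a 32-bit safe derived seed from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 9973) %% 2147483647)
}
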