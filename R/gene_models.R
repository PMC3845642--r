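# Gene/pseudogene classification and canonical-feature annotation.
#
# The operational rule follows the field's convention for intronless RNase
# genes: a sequence is a functional gene iff its coding region is one
# uninterrupted open reading frame of plausible length; one or more
# premature stop codons, or a frame-shifting indel (detected against a
# functional reference), make it a pseudogene.

#' Classify a coding sequence as functional gene or pseudogene
#'
#' A sequence is called functional when some reading frame yields an ORF
#' with no internal stop codon, an ATG start, and a codon count within
#' `length_bounds`. Otherwise every detected defect is located and the call
#' is `pseudogene`. Frameshifts are only detectable when a functional
#' same-lineage `reference` CDS is supplied (nucleotide alignment; any
#' indel whose length is not a multiple of 3 is a frameshift).
#'
#' @param record One-row `seq_record_set` data.frame (or list) with at
#'   least `id` and `sequence`.
#' @param reference Optional functional reference CDS (nucleotide string).
#' @param length_bounds Acceptable ORF length in codons, default
#'   `c(100, 160)` around the family-typical ~130 codons. Includes the stop.
#' @param genetic_code Codon table.
#' @return Object of class `gene_call`: list with `id`, `status`
#'   (`"functional"`/`"pseudogene"`), `defects` (data.frame `kind`,
#'   `codon_position`), `protein` (functional calls only), `frame_used`,
#'   `low_confidence`.
#' @export
classify_gene <- function(record, reference = NULL,
                          length_bounds = c(100L, 160L),
                          genetic_code = rnasefam::genetic_code()) {
  seq <- toupper(if (is.list(record) || is.data.frame(record)) record$sequence else record)
  id <- if (is.list(record) || is.data.frame(record)) record$id else NA_character_
  seq <- gsub("-", "", seq, fixed = TRUE)
  if (nchar(seq) < 60) stop("sequence shorter than 60 nt: ", id)

  frames <- lapply(0:2, function(f) frame_translation(seq, f, genetic_code))
  internal_stops <- vapply(frames, function(x) length(x$stop_codons), integer(1))

  # prefer a clean frame, in frame order
  clean <- which(internal_stops == 0L)
  frame_used <- if (length(clean) > 0) clean[1] - 1L else which.min(internal_stops) - 1L
  fr <- frames[[frame_used + 1L]]

  defects <- data.frame(kind = character(0), codon_position = integer(0),
                        stringsAsFactors = FALSE)
  add_defect <- function(kind, pos) {
    rbind(defects, data.frame(kind = kind, codon_position = as.integer(pos),
                              stringsAsFactors = FALSE))
  }

  for (p in fr$stop_codons) defects <- add_defect("premature_stop", p)

  if (!is.null(reference)) {
    fs <- detect_frameshifts(seq, toupper(reference))
    for (p in fs) defects <- add_defect("frameshift", p)
  }

  n_codons <- fr$n_codons
  if (n_codons < length_bounds[1] || n_codons > length_bounds[2]) {
    defects <- add_defect("truncated", n_codons)
  }
  if (substr(seq, frame_used + 1L, frame_used + 3L) != "ATG" &&
      length(fr$stop_codons) == 0L && nrow(defects) == 0L) {
    # only meaningful for otherwise-intact ORFs
    defects <- add_defect("missing_start", 1L)
  }

  low_confidence <- all(internal_stops > 2L) && is.null(reference)
  if (low_confidence && !("truncated" %in% defects$kind)) {
    defects <- add_defect("truncated", n_codons)
  }

  status <- if (nrow(defects) == 0L) "functional" else "pseudogene"
  protein <- if (status == "functional") fr$protein_no_stop else NA_character_

  structure(list(id = id, status = status, defects = defects,
                 protein = protein, frame_used = frame_used,
                 low_confidence = low_confidence,
                 species_code = if (is.list(record) || is.data.frame(record))
                   record$species_code %||% NA_character_ else NA_character_),
            class = "gene_call")
}

#' @export
print.gene_call <- function(x, ...) {
  cat("<gene_call>", x$id, "-", x$status, "(frame", x$frame_used, ")\n")
  if (nrow(x$defects) > 0) {
    cat("  defects:",
        paste(sprintf("%s@%d", x$defects$kind, x$defects$codon_position),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Translate frame f (0/1/2), trimming the tail to a codon multiple.
# Returns codon count, internal stop positions (codon index), protein.
frame_translation <- function(seq, frame, gc) {
  sub <- substr(seq, frame + 1L, nchar(seq))
  usable <- nchar(sub) - nchar(sub) %% 3L
  sub <- substr(sub, 1L, usable)
  codons <- split_codons(sub)
  aa <- codon_aa(codons, gc)
  n <- length(aa)
  stops <- which(aa == "*")
  terminal <- length(stops) > 0 && stops[length(stops)] == n
  internal <- setdiff(stops, if (terminal) n else integer(0))
  # protein for functional calls: drop terminal stop only
  prot_no_stop <- paste(aa[seq_len(n - as.integer(terminal))], collapse = "")
  list(n_codons = n, stop_codons = internal,
       protein_no_stop = prot_no_stop, has_terminal_stop = terminal)
}

# Frameshift detection by global nucleotide alignment against a reference.
# Returns codon positions (on the reference frame) of indels whose length
# is not a multiple of 3.
detect_frameshifts <- function(seq, reference) {
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(seq),
                                      Biostrings::DNAString(reference),
                                      type = "global")
  shifts <- integer(0)
  ins <- Biostrings::indel(Biostrings::pattern(al))[[1]] # gaps in pattern = deletions vs ref
  del <- Biostrings::indel(Biostrings::subject(al))[[1]] # gaps in subject = insertions vs ref
  for (r in seq_along(ins)) {
    w <- BiocGenerics::width(ins)[r]
    if (w %% 3L != 0L) shifts <- c(shifts, ceiling(BiocGenerics::start(ins)[r] / 3))
  }
  for (r in seq_along(del)) {
    w <- BiocGenerics::width(del)[r]
    if (w %% 3L != 0L) shifts <- c(shifts, ceiling(BiocGenerics::start(del)[r] / 3))
  }
  sort(unique(shifts))
}

#' Annotate canonical RNase features on a protein
#'
#' Checks the CKXXNTF signature motif, the His...Lys...His catalytic triad
#' (assessed at the template-aligned canonical positions, so indels do not
#' break the check), and the cysteine count. A protein is `canonical` when
#' the motif is present, the triad is intact, and 6-8 cysteines are found.
#'
#' @param protein Amino-acid string without internal stops.
#' @param reference Reference profile, default [canonical_template()].
#' @return List of class `feature_annotation`: `signature_motif_span`
#'   (integer start/end or `NULL`), `catalytic_triad_present`,
#'   `cysteine_count`, `canonical`.
#' @export
annotate_canonical_features <- function(protein, reference = canonical_template()) {
  protein <- toupper(protein)
  if (grepl("*", protein, fixed = TRUE)) {
    stop("protein contains internal stop symbol; classify first")
  }
  motif <- regexpr("CK..NTF", protein)
  span <- if (motif > 0) c(start = as.integer(motif),
                           end = as.integer(motif) + 6L) else NULL

  triad <- FALSE
  if (nchar(protein) >= 7) {
    al <- pairwise_protein_align(reference$protein, protein)
    map <- alignment_position_map(al$a, al$b)
    pos <- map[reference$triad_positions]
    aa <- strsplit(protein, "")[[1]]
    ok <- !is.na(pos)
    if (all(ok)) {
      triad <- identical(unname(aa[pos]), c("H", "K", "H"))
    }
  }
  cys <- lengths(regmatches(protein, gregexpr("C", protein, fixed = TRUE)))
  canonical <- !is.null(span) && triad && cys >= 6 && cys <= 8
  structure(list(signature_motif_span = span, catalytic_triad_present = triad,
                 cysteine_count = as.integer(cys), canonical = canonical),
            class = "feature_annotation")
}

# Map positions of unaligned sequence a to positions in unaligned b via an
# aligned pair (gap character "-"). Returns NA where a's residue aligns to
# a gap in b.
alignment_position_map <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  keep <- ca != "-"
  map <- ifelse(cb[keep] != "-", ib[keep], NA_integer_)
  stats::setNames(as.integer(map), NULL)
}

#' Tabulate a census of gene calls into a presence matrix
#'
#' @param calls List of `gene_call` objects.
#' @param lineage_map Named character vector mapping gene id to lineage;
#'   ids missing from the map are counted under `"Others"` with a warning.
#' @param species Optional character vector fixing species (row) order.
#' @param lineages Optional character vector fixing lineage (column) order.
#' @return `presence_matrix` whose cells count functional and pseudogene
#'   calls; cell totals conserve the number of calls.
#' @export
census <- function(calls, lineage_map, species = NULL, lineages = NULL) {
  ids <- vapply(calls, function(x) x$id, character(1))
  sp <- vapply(calls, function(x) x$species_code %||% NA_character_, character(1))
  if (anyNA(sp)) sp[is.na(sp)] <- species_code_of(ids[is.na(sp)])
  status <- vapply(calls, function(x) x$status, character(1))
  lin <- unname(lineage_map[ids])
  if (anyNA(lin)) {
    warning(sum(is.na(lin)), " call(s) without lineage assignment counted as 'Others'")
    lin[is.na(lin)] <- "Others"
  }
  species <- species %||% sort(unique(sp))
  lineages <- lineages %||% sort(unique(lin))
  fun <- ps <- matrix(0L, length(species), length(lineages),
                      dimnames = list(species, lineages))
  for (k in seq_along(ids)) {
    i <- match(sp[k], species); j <- match(lin[k], lineages)
    if (status[k] == "functional") fun[i, j] <- fun[i, j] + 1L
    else ps[i, j] <- ps[i, j] + 1L
  }
  new_presence_matrix(fun, ps)
}
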