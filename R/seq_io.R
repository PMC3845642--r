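# Sequence and table I/O: FASTA in/out with the project's header
# convention ("<species>-<gene>", pseudogenes carry a "ps" suffix),
# presence/copy-number tables ("2 (1)" = 2 functional + 1 pseudogene), and
# the bundled species-code registry.

#' Species-code registry bundled with the package
#'
#' Two- or three-letter codes for the 20 mammals the toolkit was designed
#' around (e.g. `Ml` = little brown bat, *Myotis lucifugus*). Unknown codes
#' in input are accepted with a warning so simulated taxa work.
#'
#' @param path Optional path to a YAML registry overriding the bundled one.
#' @return Named character vector mapping code to species name.
#' @export
species_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_codes.yaml", package = "rnasefam")
  }
  reg <- yaml::read_yaml(path)
  unlist(reg)
}

#' Parse a sequence id into species code, gene label, and declared status
#'
#' The grammar is `<species>-<gene>` with the first hyphen as separator.
#' A gene label ending in `ps` (optionally followed by a copy number, e.g.
#' `RNase14ps2`) declares the sequence a pseudogene.
#'
#' @param id Character vector of ids such as `"Ml-RNase4A"`.
#' @param registry Species registry; codes absent from it trigger one warning.
#' @return data.frame with columns `id`, `species_code`, `gene_label`,
#'   `declared_status` (`"functional"`/`"pseudogene"`).
#' @export
parse_gene_id <- function(id, registry = species_registry()) {
  has_sep <- grepl("-", id, fixed = TRUE)
  if (any(!has_sep)) {
    stop("id(s) without '<species>-<gene>' separator: ",
         paste(utils::head(id[!has_sep], 3), collapse = ", "))
  }
  species_code <- sub("-.*$", "", id)
  gene_label <- sub("^[^-]*-", "", id)
  unknown <- setdiff(unique(species_code), names(registry))
  if (length(unknown) > 0) {
    warning("unknown species code(s) kept verbatim: ",
            paste(unknown, collapse = ", "))
  }
  declared <- ifelse(grepl("ps[0-9]*$", gene_label),
                     "pseudogene", "functional")
  data.frame(id = id, species_code = species_code, gene_label = gene_label,
             declared_status = declared, stringsAsFactors = FALSE)
}

#' Read coding sequences from FASTA
#'
#' Headers are parsed with [parse_gene_id()]; the first whitespace-delimited
#' token is the id, the remainder is kept as a description.
#'
#' @param path FASTA file.
#' @param registry Species registry for code validation.
#' @return data.frame of class `seq_record_set` with one row per record:
#'   `id`, `species_code`, `gene_label`, `declared_status`, `sequence`.
#' @export
read_fasta <- function(path, registry = species_registry()) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) {
    return(empty_seq_record_set())
  }
  ids <- sub("\\s.*$", "", names(set))
  meta <- parse_gene_id(ids, registry = registry)
  meta$sequence <- toupper(as.character(set))
  if (any(!nzchar(meta$sequence))) {
    stop("empty sequence for record(s): ",
         paste(meta$id[!nzchar(meta$sequence)], collapse = ", "))
  }
  class(meta) <- c("seq_record_set", "data.frame")
  rownames(meta) <- NULL
  meta
}

empty_seq_record_set <- function() {
  out <- data.frame(id = character(0), species_code = character(0),
                    gene_label = character(0), declared_status = character(0),
                    sequence = character(0), stringsAsFactors = FALSE)
  class(out) <- c("seq_record_set", "data.frame")
  out
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param records `seq_record_set` data.frame or any data.frame with `id`
#'   and `sequence` columns.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# --- presence/copy-number tables -------------------------------------------

parse_count_cell <- function(cell, row = NA, col = NA) {
  cell <- trimws(cell)
  if (cell == "" || cell == "-") cell <- "0"
  m <- regmatches(cell, regexec("^([0-9]+)?\\s*(?:\\(([0-9]+)\\))?$", cell))[[1]]
  if (length(m) == 0 || (is.na(m[2]) || m[2] == "") && (is.na(m[3]) || m[3] == "")) {
    stop("unparseable count cell '", cell, "' at row ", row, ", column ", col)
  }
  fun <- if (!is.na(m[2]) && nzchar(m[2])) as.integer(m[2]) else 0L
  ps <- if (!is.na(m[3]) && nzchar(m[3])) as.integer(m[3]) else 0L
  c(functional = fun, pseudogene = ps)
}

#' Read a presence/copy-number matrix from TSV
#'
#' The table has one row per species and one column per gene lineage; cells
#' follow the grammar `n`, `n (m)`, `(m)`, `0` where `n` is the functional
#' copy number and `m` (parenthesised) the pseudogene count.
#'
#' @param path TSV file; first column species codes, header row lineage names.
#' @return Object of class `presence_matrix`: a list with integer matrices
#'   `functional` and `pseudogene` (species x lineages).
#' @export
read_presence_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("presence matrix needs a species column plus lineages")
  species <- tab[[1]]
  lineages <- colnames(tab)[-1]
  fun <- ps <- matrix(0L, nrow = length(species), ncol = length(lineages),
                      dimnames = list(species, lineages))
  for (i in seq_along(species)) {
    for (j in seq_along(lineages)) {
      cnt <- parse_count_cell(tab[i, j + 1L], row = species[i], col = lineages[j])
      fun[i, j] <- cnt[["functional"]]
      ps[i, j] <- cnt[["pseudogene"]]
    }
  }
  new_presence_matrix(fun, ps)
}

new_presence_matrix <- function(functional, pseudogene) {
  stopifnot(identical(dim(functional), dim(pseudogene)))
  structure(list(functional = functional, pseudogene = pseudogene),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("Presence/copy-number matrix:", nrow(x$functional), "species x",
      ncol(x$functional), "lineages\n")
  cat("  functional copies:", sum(x$functional),
      " pseudogenes:", sum(x$pseudogene), "\n")
  invisible(x)
}

format_count_cell <- function(fun, ps) {
  if (ps > 0 && fun > 0) sprintf("%d (%d)", fun, ps)
  else if (ps > 0) sprintf("(%d)", ps)
  else as.character(fun)
}

#' Write a presence matrix to TSV
#'
#' Cells use the same grammar as [read_presence_matrix()]; the round trip is
#' lossless.
#'
#' @param x `presence_matrix`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_presence_matrix <- function(x, path) {
  fun <- x$functional
  ps <- x$pseudogene
  cells <- matrix(mapply(format_count_cell, fun, ps),
                  nrow = nrow(fun), dimnames = dimnames(fun))
  out <- data.frame(species = rownames(fun), cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write report tables (census + selection summaries)
#'
#' Emits a census TSV (presence-matrix layout) and a selection TSV with one
#' row per paralog/ortholog group; groups without a test (fewer than three
#' members) get an `NA` p-value cell.
#'
#' @param census `presence_matrix`.
#' @param selection data.frame of selection summaries as returned by
#'   [selection_table()] (may be `NULL`).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_report_tables <- function(census, selection = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  census_path <- file.path(dir, "census.tsv")
  write_presence_matrix(census, census_path)
  files <- c(census = census_path)
  if (!is.null(selection)) {
    sel_path <- file.path(dir, "selection.tsv")
    utils::write.table(selection, sel_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    files <- c(files, selection = sel_path)
  }
  files
}
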