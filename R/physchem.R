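# Protein isoelectric point and charged-residue statistics.
#
# Net charge is the Henderson-Hasselbalch sum over ionizable groups; the
# isoelectric point is found by bisection. The default pKa set is the
# widely used EMBOSS-style table; alternative tables can be supplied since
# published pI values depend on the table used.

#' Default side-chain and terminal pKa table
#'
#' Bjellqvist (ExPASy-style) values, the set behind the pI figures most of
#' the protein literature quotes. `sign` is +1 for groups that are
#' positive when protonated (H, K, R, N-terminus) and -1 for groups
#' negative when deprotonated (D, E, C, Y, C-terminus). An EMBOSS-style
#' alternative is available via [emboss_pka_table()]; published pI values
#' shift by a few tenths of a unit between tables.
#'
#' @return data.frame with columns `group`, `pka`, `sign`.
#' @export
default_pka_table <- function() {
  data.frame(
    group = c("Nterm", "Cterm", "D", "E", "C", "Y", "H", "K", "R"),
    pka   = c(7.5,     3.55,    4.05, 4.45, 9.0, 10.0, 5.98, 10.0, 12.0),
    sign  = c(1,       -1,      -1,  -1,  -1,  -1,   1,   1,    1),
    stringsAsFactors = FALSE
  )
}

#' @rdname default_pka_table
#' @export
emboss_pka_table <- function() {
  data.frame(
    group = c("Nterm", "Cterm", "D", "E", "C", "Y", "H", "K", "R"),
    pka   = c(8.6,     3.6,     3.9, 4.1, 8.5, 10.1, 6.5, 10.8, 12.5),
    sign  = c(1,       -1,      -1,  -1,  -1,  -1,   1,   1,    1),
    stringsAsFactors = FALSE
  )
}

#' Net charge of a protein at a given pH
#'
#' Positive groups contribute `+1/(1 + 10^(pH - pKa))`, negative groups
#' `-1/(1 + 10^(pKa - pH))`. Unknown residues are skipped with a warning.
#'
#' @param protein Amino-acid string.
#' @param pH pH value (vectorized).
#' @param pka pKa table as from [default_pka_table()].
#' @return Net charge (real).
#' @export
net_charge <- function(protein, pH, pka = default_pka_table()) {
  aa <- strsplit(toupper(protein), "")[[1]]
  known <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
             "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (any(!(aa %in% known))) {
    warning("skipping unknown residue(s): ",
            paste(unique(aa[!(aa %in% known)]), collapse = ", "))
    aa <- aa[aa %in% known]
  }
  counts <- table(aa)
  rows <- pka[pka$group %in% c("Nterm", "Cterm", names(counts)), , drop = FALSE]
  chg <- 0
  for (i in seq_len(nrow(rows))) {
    g <- rows$group[i]
    n <- if (g %in% c("Nterm", "Cterm")) 1 else as.numeric(counts[[g]])
    if (rows$sign[i] > 0) {
      chg <- chg + n / (1 + 10^(pH - rows$pka[i]))
    } else {
      chg <- chg - n / (1 + 10^(rows$pka[i] - pH))
    }
  }
  chg
}

#' Isoelectric point by bisection
#'
#' Bisects [net_charge()] on pH in `[0, 14]` until `|charge| < tol`.
#'
#' @param protein Amino-acid string with at least one ionizable group.
#' @param pka pKa table.
#' @param tol Charge tolerance at the returned pH (default 1e-4).
#' @return pI (real). If the charge does not change sign on `[0, 14]` the
#'   boundary value is returned with attribute `boundary = TRUE`.
#' @export
isoelectric_point <- function(protein, pka = default_pka_table(), tol = 1e-4) {
  lo <- 0; hi <- 14
  c_lo <- net_charge(protein, lo, pka)
  c_hi <- net_charge(protein, hi, pka)
  if (c_lo < 0 || c_hi > 0) {
    # charge is decreasing in pH; no sign change -> boundary
    out <- if (c_lo < 0) lo else hi
    attr(out, "boundary") <- TRUE
    return(out)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    c_mid <- net_charge(protein, mid, pka)
    if (abs(c_mid) < tol) return(mid)
    if (c_mid > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Count basic (R+K) and acidic (D+E) residues
#'
#' @param protein Amino-acid string.
#' @return Named integer vector `c(basic = , acidic = )`.
#' @export
count_charged_residues <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  c(basic = sum(aa %in% c("R", "K")), acidic = sum(aa %in% c("D", "E")))
}

#' Charge profile of a protein
#'
#' @param protein Amino-acid string (conventionally the mature peptide;
#'   pass `signal_end` to strip an N-terminal signal sequence first).
#' @param id Label for reporting.
#' @param signal_end Last residue of the signal peptide to remove (0 = none).
#' @param pka pKa table.
#' @return data.frame row: `id`, `basic_count`, `acidic_count`,
#'   `net_charge_pH7`, `pI`.
#' @export
charge_profile <- function(protein, id = NA_character_, signal_end = 0,
                           pka = default_pka_table()) {
  if (signal_end > 0) protein <- substr(protein, signal_end + 1, nchar(protein))
  cc <- count_charged_residues(protein)
  data.frame(id = id,
             basic_count = cc[["basic"]], acidic_count = cc[["acidic"]],
             net_charge_pH7 = net_charge(protein, 7, pka),
             pI = as.numeric(isoelectric_point(protein, pka)),
             stringsAsFactors = FALSE)
}
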