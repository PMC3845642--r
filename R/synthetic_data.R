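# Gene-family birth-death simulator: duplication, loss, pseudogenization
# and codon-level sequence evolution along a dated species tree, emitting
# sequences plus a ground-truth event log and the true gene tree.
#
# The codon model is mutation-acceptance: point mutations are proposed per
# nucleotide site with a transition bias kappa, nonsynonymous changes are
# accepted at relative rate omega, and stop-creating changes are rejected
# while a copy is functional. Pseudogenized copies evolve neutrally
# (omega = 1, stops allowed) and may duplicate further.

#' Simulation parameters
#'
#' Rates are per gene copy per unit branch length (the species-tree time
#' unit, conventionally My).
#'
#' @param lambda Duplication rate (default 0.002).
#' @param mu Loss rate (default 0.0005).
#' @param psi Pseudogenization rate (default 0.001).
#' @param omega Nonsynonymous/synonymous rate ratio for functional copies
#'   (default 0.4, a typical purifying-selection value).
#' @param omega_dup Optional omega assigned to the new copy born at each
#'   duplication (models post-duplication shifts in selection).
#' @param kappa Transition/transversion rate ratio of the mutation process
#'   (default 2).
#' @param subst_rate Proposed mutations per nucleotide site per unit branch
#'   length (default 0.003, in the mammalian neutral range when the unit
#'   is My).
#' @param root_codons Root CDS length in codons including the stop
#'   (default 130).
#' @param branch_overrides Named list: species-branch id (tip label, or
#'   sorted tip labels joined with `+`) -> list overriding any of
#'   `lambda`, `mu`, `psi`, `omega` on that branch.
#' @param defect_types Defect kinds injected at pseudogenization, subset of
#'   `c("stop", "indel")` (default `"stop"`, which keeps pseudogenes
#'   codon-framed so they can be carried in alignments).
#' @param seed Seed for the whole simulation.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(lambda = 0.002, mu = 0.0005, psi = 0.001,
                       omega = 0.4, omega_dup = NULL, kappa = 2,
                       subst_rate = 0.003, root_codons = 130,
                       branch_overrides = list(),
                       defect_types = "stop", seed = 1) {
  stopifnot(lambda >= 0, mu >= 0, psi >= 0, omega >= 0, kappa > 0,
            subst_rate >= 0, root_codons >= 30)
  structure(list(lambda = lambda, mu = mu, psi = psi, omega = omega,
                 omega_dup = omega_dup, kappa = kappa,
                 subst_rate = subst_rate, root_codons = root_codons,
                 branch_overrides = branch_overrides,
                 defect_types = defect_types, seed = as.integer(seed)),
            class = "sim_params")
}

#' Evolve a codon sequence for a given expected mutation load
#'
#' @param seq Coding sequence (length a multiple of 3; stop-free except
#'   for an optional terminal stop when `functional`).
#' @param t Expected proposed mutations per nucleotide site.
#' @param omega Acceptance ratio for nonsynonymous changes relative to
#'   synonymous ones (values > 1 scale synonymous acceptance down).
#' @param kappa Transition/transversion proposal bias.
#' @param functional Reject stop-creating changes and keep the terminal
#'   stop codon fixed (default TRUE).
#' @param seed Optional seed (otherwise the ambient RNG stream is used).
#' @return Evolved sequence (same length).
#' @export
evolve_codon_sequence <- function(seq, t, omega = 1, kappa = 2,
                                  functional = TRUE, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  if (t <= 0) return(seq)
  bases <- strsplit(toupper(seq), "")[[1]]
  L <- length(bases)
  hi <- L
  lo <- 1L
  if (functional && L >= 3 &&
      paste(bases[(L - 2):L], collapse = "") %in% STOP_CODONS) {
    hi <- L - 3L          # terminal stop held fixed
  }
  if (functional && L >= 3 && paste(bases[1:3], collapse = "") == "ATG") {
    lo <- 4L              # start codon held fixed
  }
  n_sites <- hi - lo + 1L
  n_prop <- stats::rpois(1, t * n_sites)
  if (n_prop == 0) return(paste(bases, collapse = ""))
  gc <- genetic_code()
  acc_nonsyn <- omega / max(1, omega)
  acc_syn <- 1 / max(1, omega)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  for (k in seq_len(n_prop)) {
    site <- lo - 1L + sample.int(n_sites, 1)
    cur <- bases[site]
    if (!(cur %in% DNA_BASES)) next
    if (stats::runif(1) < kappa / (kappa + 2)) {
      new <- ts_map[[cur]]
    } else {
      new <- sample(setdiff(DNA_BASES, c(cur, ts_map[[cur]])), 1)
    }
    cpos <- (site - 1) %/% 3
    cod <- bases[(cpos * 3 + 1):(cpos * 3 + 3)]
    old_cod <- paste(cod, collapse = "")
    cod[(site - 1) %% 3 + 1] <- new
    new_cod <- paste(cod, collapse = "")
    if (functional && new_cod %in% STOP_CODONS) next
    syn <- !(old_cod %in% STOP_CODONS) && !(new_cod %in% STOP_CODONS) &&
      identical(gc[[old_cod]], gc[[new_cod]])
    p_acc <- if (syn) acc_syn else acc_nonsyn
    if (stats::runif(1) < p_acc) bases[site] <- new
  }
  paste(bases, collapse = "")
}

#' Inject pseudogene defects into a functional CDS
#'
#' Introduces at least one premature stop codon and/or 1-2 nt indel at
#' random internal positions.
#'
#' @param seq Functional CDS.
#' @param rate Expected number of defects (>= 1 enforced when rate > 0;
#'   `rate = 0` returns the input unchanged).
#' @param types Defect kinds to draw from, subset of `c("stop", "indel")`.
#' @param seed Optional seed.
#' @return Defective sequence.
#' @export
inject_pseudogene_defects <- function(seq, rate = 1, types = c("stop", "indel"),
                                      seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  if (rate <= 0) return(seq)
  n <- max(1L, stats::rpois(1, rate))
  for (k in seq_len(n)) {
    type <- if (length(types) == 1) types else sample(types, 1)
    n_cod <- nchar(seq) %/% 3
    pos <- sample(seq(10L, max(11L, n_cod - 10L)), 1)   # internal codon
    if (type == "stop") {
      stop_cod <- sample(STOP_CODONS, 1)
      substr(seq, pos * 3 - 2, pos * 3) <- stop_cod
    } else {
      w <- sample(1:2, 1)
      at <- pos * 3 - 2
      if (stats::runif(1) < 0.5) {
        seq <- paste0(substr(seq, 1, at - 1), substr(seq, at + w, nchar(seq)))
      } else {
        ins <- paste(sample(DNA_BASES, w, replace = TRUE), collapse = "")
        seq <- paste0(substr(seq, 1, at - 1), ins, substr(seq, at, nchar(seq)))
      }
    }
  }
  seq
}

# TRUE if the sequence is visibly disrupted: off-frame length or an
# internal stop codon.
has_orf_defect <- function(seq) {
  if (nchar(seq) %% 3L != 0L) return(TRUE)
  aa <- strsplit(translate_cds(seq), "")[[1]]
  n <- length(aa)
  any(aa[-n] == "*")
}

# Root CDS: the synthetic canonical template for 130 codons, otherwise a
# generated stop-free gene with planted motif and cysteines.
root_cds <- function(n_codons) {
  if (n_codons == 130L) return(reverse_translate(CANONICAL_TEMPLATE_PROTEIN))
  n_aa <- n_codons - 1L
  aa_pool <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "N", "P", "Q",
               "R", "S", "T", "V", "W", "Y")
  prot <- c("M", sample(aa_pool, n_aa - 1L, replace = TRUE))
  motif_at <- max(2L, n_aa %/% 3)
  prot[motif_at:(motif_at + 6L)] <- c("C", "K", "S", "S", "N", "T", "F")
  cys_extra <- sample(setdiff(seq(2, n_aa), motif_at:(motif_at + 6L)), 6)
  prot[cys_extra] <- "C"
  reverse_translate(paste(prot, collapse = ""))
}

#' Simulate a gene family along a species tree
#'
#' A birth-death-pseudogenization process per gene copy (exponential
#' waiting times) with codon-level sequence evolution. All live copies are
#' transmitted to both daughters at each speciation. Returns extant
#' sequences plus the complete ground truth.
#'
#' @param species_tree Rooted `phylo` with branch lengths.
#' @param params `sim_params`.
#' @param family Family label used in gene names (default `"FAM"`).
#' @return List of class `family_simulation`:
#'   `records` (`seq_record_set` of extant sequences; pseudogenes carry a
#'   `ps` name suffix), `events` (data.frame `time`, `branch`, `event`,
#'   `gene`), `gene_tree` (`phylo`, pruned to extant copies, internal node
#'   labels `"D"`/`"S"`; `NULL` when < 2 survive), `true_dup_nodes`
#'   (duplication nodes surviving in the pruned tree), `omegas` (named per
#'   extant copy).
#' @export
simulate_family <- function(species_tree, params = sim_params(),
                            family = "FAM") {
  stopifnot(inherits(species_tree, "phylo"), !is.null(species_tree$edge.length))
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  env <- new.env()
  env$events <- list()
  env$records <- list()
  env$omegas <- numeric(0)
  env$copy_counter <- 1L
  env$live_guard <- 1L
  env$tip_counter <- stats::setNames(integer(length(species_tree$tip.label)),
                                     species_tree$tip.label)

  n_tip <- length(species_tree$tip.label)
  parents <- parent_vec(species_tree)
  root_s <- setdiff(species_tree$edge[, 1], species_tree$edge[, 2])[1]
  kids_of <- function(nd) species_tree$edge[species_tree$edge[, 1] == nd, 2]
  edge_len <- function(child) {
    species_tree$edge.length[which(species_tree$edge[, 2] == child)]
  }
  branch_id <- function(child) species_branch_id(species_tree, child)

  branch_rates <- function(bid, status) {
    ov <- params$branch_overrides[[bid]] %||% list()
    lambda <- ov$lambda %||% params$lambda
    mu <- ov$mu %||% params$mu
    psi <- if (status == "functional") (ov$psi %||% params$psi) else 0
    omega <- ov$omega %||% params$omega
    list(lambda = lambda, mu = mu, psi = psi, omega = omega)
  }

  log_event <- function(time, branch, event, gene) {
    env$events[[length(env$events) + 1L]] <-
      data.frame(time = time, branch = branch, event = event, gene = gene,
                 stringsAsFactors = FALSE)
  }

  # Simulate one copy lineage from time `at` (measured from the top of the
  # species branch leading into `snode`) to the bottom of that branch and
  # beyond. Returns NULL (extinct) or list(nwk, pendant).
  sim_lineage <- function(seq, status, omega, gene, snode, at, abs_time) {
    blen <- if (snode == root_s) 0 else edge_len(snode)
    bid <- if (snode == root_s) "root" else branch_id(snode)
    elapsed <- 0
    repeat {
      rates <- branch_rates(bid, status)
      omega_here <- if (status == "functional") {
        if (is.na(omega)) rates$omega else omega
      } else 1
      total <- rates$lambda + rates$mu + rates$psi
      remaining <- blen - at
      wait <- if (total > 0) stats::rexp(1, total) else Inf
      if (wait >= remaining) {
        # reach the bottom of this species branch
        seq <- evolve_codon_sequence(seq, remaining * params$subst_rate,
                                     omega = omega_here, kappa = params$kappa,
                                     functional = status == "functional")
        pend <- elapsed + remaining
        kids <- kids_of(snode)
        if (length(kids) == 0) {       # species tip: emit record
          if (status == "pseudogene" && !has_orf_defect(seq)) {
            # neutral drift may have reverted the planted stop; a dead copy
            # stays dead, so re-disrupt before emission
            seq <- inject_pseudogene_defects(seq, rate = 1,
                                             types = params$defect_types)
          }
          sp <- species_tree$tip.label[snode]
          env$tip_counter[sp] <- env$tip_counter[sp] + 1L
          label <- paste0(sp, "-", family, env$tip_counter[sp],
                          if (status == "pseudogene") "ps" else "")
          env$records[[label]] <- list(id = label, species_code = sp,
                                       sequence = seq, status = status)
          env$omegas[label] <- omega_here
          return(list(nwk = label, pendant = pend))
        }
        subs <- list()
        for (kd in kids) {
          r <- sim_lineage(seq, status, omega, gene, kd, 0,
                           abs_time + remaining)
          if (!is.null(r)) subs[[length(subs) + 1L]] <- r
        }
        if (length(subs) == 0) return(NULL)
        if (length(subs) == 1) {
          subs[[1]]$pendant <- subs[[1]]$pendant + pend
          return(subs[[1]])
        }
        nwk <- paste0("(", paste(vapply(subs, function(s)
          paste0(s$nwk, ":", sprintf("%.8f", s$pendant)), character(1)),
          collapse = ","), ")S")
        return(list(nwk = nwk, pendant = pend))
      }
      # an event happens on this branch
      seq <- evolve_codon_sequence(seq, wait * params$subst_rate,
                                   omega = omega_here, kappa = params$kappa,
                                   functional = status == "functional")
      at <- at + wait
      abs_time <- abs_time + wait
      elapsed <- elapsed + wait
      u <- stats::runif(1) * total
      if (u < rates$lambda) {
        env$copy_counter <- env$copy_counter + 1L
        env$live_guard <- env$live_guard + 1L
        if (env$live_guard > 1e4) stop("explosive growth: > 10^4 copies")
        new_gene <- paste0("g", env$copy_counter)
        log_event(abs_time, bid, "duplication", new_gene)
        new_omega <- if (status == "functional") {
          params$omega_dup %||% omega
        } else omega
        left <- sim_lineage(seq, status, omega, gene, snode, at, abs_time)
        right <- sim_lineage(seq, status, new_omega, new_gene, snode, at,
                             abs_time)
        if (is.null(left) && is.null(right)) return(NULL)
        if (is.null(left) || is.null(right)) {
          sv <- left %||% right
          sv$pendant <- sv$pendant + elapsed
          return(sv)
        }
        nwk <- paste0("(", left$nwk, ":", sprintf("%.8f", left$pendant),
                      ",", right$nwk, ":", sprintf("%.8f", right$pendant),
                      ")D")
        return(list(nwk = nwk, pendant = elapsed))
      } else if (u < rates$lambda + rates$mu) {
        log_event(abs_time, bid, "loss", gene)
        env$live_guard <- env$live_guard - 1L
        return(NULL)
      } else {
        log_event(abs_time, bid, "pseudogenization", gene)
        status <- "pseudogene"
        seq <- inject_pseudogene_defects(seq, rate = 1,
                                         types = params$defect_types)
        omega <- 1
      }
    }
  }

  seq0 <- root_cds(as.integer(params$root_codons))
  res <- sim_lineage(seq0, "functional", NA_real_, "g1", root_s, 0, 0)

  records <- if (length(env$records) == 0) empty_seq_record_set() else {
    df <- do.call(rbind, lapply(env$records, function(r)
      data.frame(id = r$id, species_code = r$species_code,
                 gene_label = sub("^[^-]*-", "", r$id),
                 declared_status = r$status, sequence = r$sequence,
                 stringsAsFactors = FALSE)))
    rownames(df) <- NULL
    class(df) <- c("seq_record_set", "data.frame")
    df
  }
  events <- if (length(env$events) == 0) {
    data.frame(time = numeric(0), branch = character(0),
               event = character(0), gene = character(0))
  } else do.call(rbind, env$events)

  gene_tree <- NULL
  true_dups <- 0L
  if (!is.null(res) && nrow(records) >= 2) {
    gene_tree <- parse_newick(paste0(res$nwk, ";"))
    true_dups <- sum(gene_tree$node.label == "D")
  }
  structure(list(records = records, events = events, gene_tree = gene_tree,
                 true_dup_nodes = true_dups, omegas = env$omegas,
                 params = params),
            class = "family_simulation")
}

#' @export
print.family_simulation <- function(x, ...) {
  cat("<family_simulation>", nrow(x$records), "extant copies,",
      nrow(x$events), "events,", x$true_dup_nodes,
      "surviving duplication node(s)\n")
  invisible(x)
}

#' Write simulation outputs (FASTA + truth log + true tree)
#'
#' @param sim `family_simulation`.
#' @param dir Output directory.
#' @return Named vector of files written.
#' @export
write_simulation <- function(sim, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(fasta = file.path(dir, "simulated_family.fasta"),
             events = file.path(dir, "truth_events.tsv"))
  write_fasta(sim$records, files[["fasta"]])
  utils::write.table(sim$events, files[["events"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$gene_tree)) {
    files <- c(files, tree = file.path(dir, "true_gene_tree.nwk"))
    write_newick(sim$gene_tree, files[["tree"]])
  }
  files
}
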