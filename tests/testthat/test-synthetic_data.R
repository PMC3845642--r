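# The gene-family simulator and its ground-truth contracts.

test_that("with all rates zero every species gets exactly one functional gene", {
  sp <- small_species_tree()
  sim <- simulate_family(sp, sim_params(lambda = 0, mu = 0, psi = 0, seed = 3))
  expect_equal(nrow(sim$records), 5)
  expect_setequal(sim$records$species_code, sp$tip.label)
  expect_true(all(sim$records$declared_status == "functional"))
  expect_equal(nrow(sim$events), 0)
  expect_equal(sim$true_dup_nodes, 0)
})

test_that("the same seed reproduces sequences and the event log exactly", {
  sp <- small_species_tree()
  s1 <- simulate_family(sp, sim_params(psi = 0.005, seed = 14))
  s2 <- simulate_family(sp, sim_params(psi = 0.005, seed = 14))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$events, s2$events)
  expect_identical(write_newick(s1$gene_tree), write_newick(s2$gene_tree))
  s3 <- simulate_family(sp, sim_params(psi = 0.005, seed = 15))
  expect_false(identical(s1$records$sequence, s3$records$sequence))
})

test_that("sequence evolution respects t = 0, omega = 0, and seeding", {
  cds <- template_cds()
  expect_identical(evolve_codon_sequence(cds, 0, seed = 1), cds)
  evolved <- evolve_codon_sequence(cds, 0.3, omega = 0, kappa = 2, seed = 5)
  expect_false(identical(evolved, cds))           # synonymous changes happen
  expect_identical(translate_cds(evolved), translate_cds(cds))
  e1 <- evolve_codon_sequence(cds, 0.1, omega = 0.5, seed = 9)
  e2 <- evolve_codon_sequence(cds, 0.1, omega = 0.5, seed = 9)
  expect_identical(e1, e2)
  # functional mode keeps the frame stop-free
  aa <- translate_cds(evolve_codon_sequence(cds, 0.5, omega = 1, seed = 11))
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
})

test_that("injected defects are seeded, disruptive, and classifier-visible", {
  cds <- template_cds()
  expect_identical(inject_pseudogene_defects(cds, rate = 0), cds)
  d1 <- inject_pseudogene_defects(cds, rate = 1, seed = 4)
  d2 <- inject_pseudogene_defects(cds, rate = 1, seed = 4)
  expect_identical(d1, d2)
  set.seed(31)
  for (rep in 1:10) {
    d <- inject_pseudogene_defects(cds, rate = 1)
    # a frameshift deep in the gene needs the reference to be visible
    call <- classify_gene(list(id = "Hs-Xps", sequence = d), reference = cds)
    expect_equal(call$status, "pseudogene")
  }
  # stop-type defects are classifier-visible even without a reference
  for (rep in 1:5) {
    d <- inject_pseudogene_defects(cds, rate = 1, types = "stop")
    call <- classify_gene(list(id = "Hs-Xps", sequence = d))
    expect_equal(call$status, "pseudogene")
  }
})

test_that("estimated dN/dS recovers the generating omega at neutrality", {
  cds0 <- template_cds()
  set.seed(47)
  ratios <- replicate(20, {
    a <- evolve_codon_sequence(cds0, 0.25, omega = 1, kappa = 2)
    b <- evolve_codon_sequence(cds0, 0.25, omega = 1, kappa = 2)
    aa <- substr(a, 1, 387); bb <- substr(b, 1, 387)
    nei_gojobori_modified(aa, bb, R = 2)$ratio
  })
  expect_gt(mean(ratios), 0.8)
  expect_lt(mean(ratios), 1.2)
})

test_that("the truth log conserves extant copy numbers along root paths", {
  sp <- small_species_tree()
  sim <- simulate_family(sp, sim_params(lambda = 0.01, mu = 0.004,
                                        psi = 0.002, seed = 33))
  expect_gt(nrow(sim$events), 0)
  # ancestor branch ids of each species (including its own tip branch)
  anc_branches <- function(code) {
    par <- rnasefam:::parent_vec(sp)
    nd <- match(code, sp$tip.label)
    out <- character(0)
    while (nd != 0 && nd %in% sp$edge[, 2]) {   # every node below the root
      out <- c(out, rnasefam:::species_branch_id(sp, nd))
      nd <- par[nd]
    }
    c(out, "root")
  }
  for (code in sp$tip.label) {
    branches <- anc_branches(code)
    ev <- sim$events[sim$events$branch %in% branches, ]
    expected <- 1 + sum(ev$event == "duplication") - sum(ev$event == "loss")
    expect_equal(sum(sim$records$species_code == code), expected,
                 info = code)
  }
})

test_that("a terminal-branch duplication burst yields a recoverable paralog group", {
  sp <- small_species_tree()
  params <- sim_params(lambda = 0.0005, mu = 0, psi = 0,
                       branch_overrides = list(E = list(lambda = 0.08)),
                       seed = 8)
  sim <- simulate_family(sp, params)
  n_e <- sum(sim$records$species_code == "E")
  expect_gt(n_e, 1)      # the 20x-elevated branch actually burst
  groups <- detect_paralog_groups(sim$gene_tree)
  grp_species <- vapply(groups, function(g) g$species, character(1))
  expect_true("E" %in% grp_species)
  g <- groups[[match("E", grp_species)]]
  expect_equal(sort(g$members),
               sort(sim$records$id[sim$records$species_code == "E" &
                                     sim$records$declared_status == "functional"]))
})

test_that("LCA reconciliation of the true gene tree recovers true duplication counts", {
  sp <- small_species_tree()
  for (seed in c(2, 9, 27, 41, 63)) {
    sim <- simulate_family(sp, sim_params(lambda = 0.008, mu = 0.003,
                                          seed = seed))
    if (is.null(sim$gene_tree)) next
    rec <- lca_reconcile(sim$gene_tree, sp)
    expect_equal(rec$total_dups, sim$true_dup_nodes, info = paste("seed", seed))
  }
})

test_that("omega contrasts simulated per branch separate cleanly", {
  sp <- small_species_tree()
  params <- sim_params(lambda = 0, mu = 0, psi = 0, omega = 0.3,
                       branch_overrides = list(
                         A = list(omega = 2), B = list(omega = 2)),
                       seed = 55)
  sim <- simulate_family(sp, params)
  expect_equal(unname(sim$omegas[paste0(c("A", "B"), "-FAM1")]), c(2, 2))
  expect_equal(unname(sim$omegas[["C-FAM1"]]), 0.3)
})
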