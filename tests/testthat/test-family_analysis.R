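# Lineage assignment, ortholog/paralog machinery, selection summaries,
# saturation profiles.

test_that("lineage assignment finds the nearest reference and flags junk", {
  tmpl <- canonical_template()$protein
  set.seed(61)
  refA <- tmpl
  refB <- translate_cds(evolve_codon_sequence(
    reverse_translate(tmpl, stop = FALSE), 0.5, omega = 1, functional = FALSE))
  refB <- gsub("\\*", "A", refB)
  refs <- c(LinA = refA, LinB = refB)
  qA <- translate_cds(evolve_codon_sequence(
    reverse_translate(refA, stop = FALSE), 0.03))
  callA <- list(id = "Hs-q1", protein = qA)
  callB <- list(id = "Hs-q2", protein = refB)
  junk <- list(id = "Hs-q3", protein = strrep("GW", 40))
  got <- suppressWarnings(assign_lineage(list(callA, callB, junk), refs))
  expect_equal(unname(got[c("Hs-q1", "Hs-q2", "Hs-q3")]),
               c("LinA", "LinB", "Others"))
  expect_warning(assign_lineage(list(junk), refs), "Others")
  expect_error(assign_lineage(list(callA), character(0)), "empty reference")
})

test_that("ortholog sets choose one gene per species reproducibly", {
  ids <- c("Hs-R1", "Mm-R1A", "Mm-R1B", "Bt-R1")
  s1 <- build_ortholog_set(ids, seed = 4)
  s2 <- build_ortholog_set(ids, seed = 4)
  expect_identical(s1$lineage_members, s2$lineage_members)
  expect_equal(s1$n, 3)
  expect_equal(sum(grepl("^Mm", s1$lineage_members)), 1)
  expect_equal(nrow(build_ortholog_pairs(s1)), 3)
})

test_that("pair enumeration gives C(n,2)", {
  expect_equal(nrow(build_ortholog_pairs(paste0("S", 1:18))), 153)
  expect_equal(nrow(build_ortholog_pairs(paste0("S", 1:13))), 78)
  expect_warning(p0 <- build_ortholog_pairs("S1"), "fewer than 2")
  expect_equal(nrow(p0), 0)
})

test_that("species-specific paralog clades are detected, pseudogenes excluded", {
  tr <- parse_newick(paste0(
    "(Out-G0:10,((Ml-G1:1,(Ml-G2:1,Ml-G3ps:1):1):5,",
    "((Hs-G1:1,Hs-G2:1):4,(Cp-G1:2,Hg-G1:2):3):2):5);"))
  tr <- ape::root(tr, outgroup = "Out-G0", resolve.root = TRUE)
  groups <- detect_paralog_groups(tr)
  spp <- sort(vapply(groups, function(g) g$species, character(1)))
  expect_equal(spp, c("Hs", "Ml"))
  ml <- groups[[which(vapply(groups, function(g) g$species == "Ml", logical(1)))]]
  expect_equal(sort(ml$members), c("Ml-G1", "Ml-G2"))   # ps tip not a member
  expect_equal(ml$pair_count, 1)
  # all-singleton tree has no groups
  tr2 <- parse_newick("((Hs-G1:1,Mm-G1:1):1,Bt-G1:2);")
  tr2 <- ape::root(tr2, outgroup = "Bt-G1", resolve.root = TRUE)
  expect_length(detect_paralog_groups(tr2), 0)
})

test_that("gene sorting is interleaving of two species in a shared clade", {
  mixed <- parse_newick(paste0(
    "(Out-G0:10,((Hg-G1:1,Cp-G1:1):1,(Hg-G2:1,Cp-G2ps:1):1):5);"))
  mixed <- ape::root(mixed, outgroup = "Out-G0", resolve.root = TRUE)
  expect_true(detect_gene_sorting(mixed, c("Hg", "Cp"))$sorting)
  clean <- parse_newick(paste0(
    "(Out-G0:10,((Hg-G1:1,Hg-G2:1):1,(Cp-G1:1,Cp-G2:1):1):5);"))
  clean <- ape::root(clean, outgroup = "Out-G0", resolve.root = TRUE)
  expect_false(detect_gene_sorting(clean, c("Hg", "Cp"))$sorting)
  expect_error(detect_gene_sorting(clean, c("Hg", "Zz")))
})

test_that("duplications predating a speciation produce gene sorting in simulation", {
  # force an early duplication burst on the (D,E) stem, then losses
  sp <- small_species_tree()
  params <- sim_params(lambda = 0, mu = 0, psi = 0,
                       branch_overrides = list("D+E" = list(lambda = 0.2)),
                       seed = 60)
  sim <- simulate_family(sp, params)
  nd <- sum(sim$records$species_code == "D")
  ne <- sum(sim$records$species_code == "E")
  skip_if(nd < 2 || ne < 2, "burst too small under this seed")
  res <- detect_gene_sorting(sim$gene_tree, c("D", "E"))
  expect_true(res$sorting)
})

test_that("selection summaries have C(n,2) pairs and behave on degenerate input", {
  cds0 <- template_cds()
  cds <- setNames(rep(cds0, 3), paste0("Ml-G", 1:3))
  al <- align_codons(cds)
  s <- selection_summary(names(cds), al, replicates = 0)
  expect_equal(s$total_pairs, 3)
  expect_equal(s$mean_dS, 0)
  expect_equal(s$mean_dN, 0)
  expect_true(is.na(s$mean_ratio))       # all pairs dS == 0
  expect_equal(s$pairs_dS_zero, 3)
  expect_true(is.na(s$p_value))
  # two-member groups never get a p-value
  s2 <- selection_summary(names(cds)[1:2], al, replicates = 0)
  expect_true(is.na(s2$p_value))
})

test_that("selection summaries are invariant to member order and detect omega contrast", {
  set.seed(71)
  cds0 <- template_cds()
  hi <- sapply(1:5, function(i) evolve_codon_sequence(cds0, 0.15, omega = 2))
  lo <- sapply(1:5, function(i) evolve_codon_sequence(cds0, 0.15, omega = 0.2))
  cds <- c(hi, lo)
  names(cds) <- c(paste0("Ml-H", 1:5), paste0("Rn-L", 1:5))
  al <- align_codons(cds)
  sh <- selection_summary(paste0("Ml-H", 1:5), al, replicates = 100, seed = 2)
  sl <- selection_summary(paste0("Rn-L", 1:5), al, replicates = 100, seed = 2)
  expect_equal(sh$total_pairs, 10)
  expect_gt(sh$mean_ratio, sl$mean_ratio)
  expect_gt(sh$mean_dN / sh$mean_dS, 1)
  expect_lt(sl$mean_dN / sl$mean_dS, 1)
  # order invariance
  sh_perm <- selection_summary(rev(paste0("Ml-H", 1:5)), al,
                               replicates = 100, seed = 2)
  expect_equal(sh_perm$mean_ratio, sh$mean_ratio)
  expect_equal(sh_perm$mean_dS, sh$mean_dS)
  # ratio-of-means alternative
  sh_rm <- selection_summary(paste0("Ml-H", 1:5), al, replicates = 0,
                             ratio_method = "ratio_of_means")
  expect_equal(sh_rm$mean_ratio, sh_rm$mean_dN / sh_rm$mean_dS)
})

test_that("co-ortholog choice robustness: recent duplicates barely move the mean ratio", {
  set.seed(81)
  cds0 <- template_cds()
  base <- sapply(1:6, function(i) evolve_codon_sequence(cds0, 0.12, omega = 0.5))
  names(base) <- paste0("S", 1:6, "-G1")
  # species S1 gets two very recent co-orthologs
  dupA <- evolve_codon_sequence(base[[1]], 0.002)
  dupB <- evolve_codon_sequence(base[[1]], 0.002)
  cds <- c(base[-1], "S1-G1a" = dupA, "S1-G1b" = dupB)
  al <- align_codons(cds)
  ratios <- sapply(c("S1-G1a", "S1-G1b"), function(pick) {
    members <- c(names(base[-1]), pick)
    selection_summary(members, al, replicates = 0)$mean_ratio
  })
  expect_lt(abs(diff(ratios)), 0.05)
})

test_that("saturation profiles separate plateaued from constant-slope data", {
  set.seed(91)
  dS <- runif(60, 0.01, 0.6)
  const <- data.frame(dS = dS, dN = 0.5 * dS + rnorm(60, 0, 0.005))
  prof1 <- saturation_profile(const)
  expect_false(prof1$plateau_detected)
  plateaued <- data.frame(dS = dS,
                          dN = ifelse(dS < 0.2, 0.5 * dS, 0.1) +
                            rnorm(60, 0, 0.005))
  prof2 <- saturation_profile(plateaued)
  expect_true(prof2$plateau_detected)
  expect_lt(abs(prof2$plateau_onset_dS - 0.2), 0.08)
  expect_error(saturation_profile(const[1:3, ]), "insufficient")
})
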