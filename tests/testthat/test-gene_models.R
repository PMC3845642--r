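# Functional/pseudogene classification and canonical-feature annotation.

test_that("an intact 390-nt ORF is functional with a 129-aa protein", {
  cds <- template_cds()
  expect_equal(nchar(cds), 390)
  call <- classify_gene(list(id = "Hs-G1", sequence = cds, species_code = "Hs"))
  expect_equal(call$status, "functional")
  expect_equal(nchar(call$protein), 129)
  expect_equal(call$frame_used, 0)
  expect_false(grepl("*", call$protein, fixed = TRUE))
})

test_that("a premature stop codon makes a located pseudogene call", {
  cds <- template_cds()
  substr(cds, 148, 150) <- "TAA"          # codon 50
  call <- classify_gene(list(id = "Hs-G1ps", sequence = cds))
  expect_equal(call$status, "pseudogene")
  expect_true(any(call$defects$kind == "premature_stop" &
                    call$defects$codon_position == 50))
})

test_that("a 1-nt deletion is reported as a frameshift when a reference is given", {
  cds <- template_cds()
  mutant <- paste0(substr(cds, 1, 3 * 29), substr(cds, 3 * 29 + 2, nchar(cds)))
  call <- classify_gene(list(id = "Hs-G1ps", sequence = mutant),
                        reference = cds)
  expect_equal(call$status, "pseudogene")
  fs <- call$defects[call$defects$kind == "frameshift", ]
  expect_equal(nrow(fs), 1)
  expect_equal(fs$codon_position, 30)
})

test_that("inserting an in-frame stop anywhere flips a functional call", {
  cds <- template_cds()
  set.seed(101)
  for (pos in sample(2:128, 15)) {
    mutant <- cds
    substr(mutant, 3 * pos - 2, 3 * pos) <- "TGA"
    call <- classify_gene(list(id = "Hs-G1", sequence = mutant))
    expect_equal(call$status, "pseudogene")
    expect_true(pos %in%
                  call$defects$codon_position[call$defects$kind == "premature_stop"])
  }
})

test_that("ORFs outside the codon-length bounds are flagged truncated", {
  short <- paste0("ATG", strrep("GCT", 40), "TAA")    # 42 codons
  call <- classify_gene(list(id = "Hs-G2", sequence = short))
  expect_equal(call$status, "pseudogene")
  expect_true("truncated" %in% call$defects$kind)
  # but passes with permissive bounds
  call2 <- classify_gene(list(id = "Hs-G2", sequence = short),
                         length_bounds = c(30, 160))
  expect_equal(call2$status, "functional")
})

test_that("canonical features are recognized on the template protein", {
  tmpl <- canonical_template()
  ann <- annotate_canonical_features(tmpl$protein)
  expect_true(ann$canonical)
  expect_equal(unname(ann$signature_motif_span["start"]), tmpl$motif_start)
  expect_true(ann$catalytic_triad_present)
  expect_true(ann$cysteine_count >= 6 && ann$cysteine_count <= 8)
  expect_equal(substr(tmpl$protein, ann$signature_motif_span["start"],
                      ann$signature_motif_span["start"] + 1), "CK")
})

test_that("losing a catalytic residue or the motif breaks canonicity", {
  tmpl <- canonical_template()
  prot <- tmpl$protein
  # mutate the second catalytic His
  broken <- prot
  substr(broken, tmpl$triad_positions[["his2"]],
         tmpl$triad_positions[["his2"]]) <- "Q"
  ann <- annotate_canonical_features(broken)
  expect_false(ann$catalytic_triad_present)
  expect_false(ann$canonical)
  # degrade the signature motif
  no_motif <- sub("CKRFNTF", "AKRFNTA", prot)
  ann2 <- annotate_canonical_features(no_motif)
  expect_null(ann2$signature_motif_span)
  expect_false(ann2$canonical)
  # triad check survives an indel upstream (alignment-based positions)
  shifted <- paste0(substr(prot, 1, 20), substr(prot, 24, nchar(prot)))
  expect_true(annotate_canonical_features(shifted)$catalytic_triad_present)
})

test_that("census counts conserve calls and split functional/pseudogene", {
  cds <- template_cds()
  bad <- cds; substr(bad, 88, 90) <- "TAG"   # codon 30
  mk <- function(id, seq) classify_gene(list(id = id, sequence = seq))
  calls <- list(mk("Ml-R1A", cds), mk("Ml-R1B", cds), mk("Ml-R1Cps", bad),
                mk("Hs-R1", cds), mk("Hs-R4", cds))
  lmap <- c("Ml-R1A" = "RNase1", "Ml-R1B" = "RNase1", "Ml-R1Cps" = "RNase1",
            "Hs-R1" = "RNase1", "Hs-R4" = "RNase4")
  cm <- census(calls, lmap)
  expect_equal(cm$functional["Ml", "RNase1"], 2L)
  expect_equal(cm$pseudogene["Ml", "RNase1"], 1L)
  expect_equal(cm$functional["Hs", "RNase4"], 1L)
  expect_equal(sum(cm$functional) + sum(cm$pseudogene), length(calls))
  # unmapped gene falls into Others with a warning
  expect_warning(cm2 <- census(calls, lmap[-5]), "Others")
  expect_equal(cm2$functional["Hs", "Others"], 1L)
})

test_that("simulated functional and pseudogenized copies classify correctly", {
  sp <- small_species_tree()
  sim <- simulate_family(sp, sim_params(psi = 0.01, seed = 21))
  for (i in seq_len(nrow(sim$records))) {
    call <- classify_gene(sim$records[i, ])
    expect_equal(call$status, sim$records$declared_status[i],
                 info = sim$records$id[i])
  }
})
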