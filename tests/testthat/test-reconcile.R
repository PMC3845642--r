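# LCA reconciliation and Dollo minimum-loss counting.

test_that("a congruent single-copy gene tree has no events", {
  sp <- parse_newick("((A:1,B:1):1,C:2);")
  gt <- parse_newick("((A-G1:1,B-G1:1):1,C-G1:2);")
  rec <- lca_reconcile(gt, sp)
  expect_equal(rec$total_dups, 0)
  expect_equal(rec$total_losses, 0)
})

test_that("the 4-tip double-copy case is one root duplication, no losses", {
  # brute-force over scenarios for ((A1,B1),(A2,B2)) on (A,B): any valid
  # history needs >= 1 duplication; one duplication before the split with
  # both copies retained explains the tree with zero losses, so (1, 0) is
  # the event-minimal reconciliation
  sp <- parse_newick("(A:1,B:1);")
  gt <- parse_newick("((A-G1:2,B-G1:2):1,(A-G2:2,B-G2:2):1);")
  rec <- lca_reconcile(gt, sp)
  expect_equal(rec$total_dups, 1)
  expect_equal(names(rec$duplications), "A+B")
  expect_equal(rec$total_losses, 0)
})

test_that("a duplication with one lost copy places the loss on the right branch", {
  sp <- parse_newick("(A:1,B:1);")
  gt <- parse_newick("(A-G1:2,(A-G2:1,B-G1:1):1);")
  rec <- lca_reconcile(gt, sp)
  expect_equal(rec$total_dups, 1)
  expect_equal(rec$total_losses, 1)
  expect_equal(names(rec$losses), "B")
  # and a deeper case: gene absent from one species of a 3-species tree
  sp3 <- parse_newick("((A:1,B:1):1,C:2);")
  gt3 <- parse_newick("(A-G1:2,C-G1:2);")
  rec3 <- lca_reconcile(gt3, sp3)
  expect_equal(rec3$total_dups, 0)
  expect_equal(rec3$total_losses, 1)
  expect_equal(names(rec3$losses), "B")
  expect_error(lca_reconcile(parse_newick("(A-G1:1,Z-G1:1);"), sp3),
               "no species-tree tip")
})

test_that("simian-style duplication maps to the ancestral branch", {
  # two gene clades, each holding both descendant lineages; outgroup gene
  # single-copy: the duplication belongs on the ancestral internal branch
  sp <- parse_newick("((Cat:30,Platy:30):20,Prosim:50);")
  gt <- parse_newick(paste0(
    "(((Cat-R7:30,Platy-R7:30):15,(Cat-R8:30,Platy-R8:30):15):5,",
    "Prosim-R78:50);"))
  rec <- lca_reconcile(gt, sp)
  expect_equal(rec$total_dups, 1)
  expect_equal(names(rec$duplications), "Cat+Platy")
  expect_equal(rec$total_losses, 0)
})

test_that("Dollo loss counts cover the degenerate patterns", {
  sp <- small_species_tree()   # ((A,B),(C,(D,E)))
  all_present <- setNames(rep(TRUE, 5), c("A", "B", "C", "D", "E"))
  expect_equal(dollo_min_losses(all_present, sp)$n_losses, 0)
  one_absent <- all_present; one_absent[["D"]] <- FALSE
  d1 <- dollo_min_losses(one_absent, sp)
  expect_equal(d1$n_losses, 1)
  expect_equal(d1$loss_branches, "D")
  sister_absent <- all_present; sister_absent[c("D", "E")] <- FALSE
  d2 <- dollo_min_losses(sister_absent, sp)
  expect_equal(d2$n_losses, 1)
  expect_equal(d2$loss_branches, "D+E")
})

test_that("Dollo counting is monotone under adding an absent species to the scope", {
  sp <- small_species_tree()
  spp <- c("A", "B", "C", "D", "E")
  set.seed(77)
  for (rep in 1:30) {
    scope <- sample(spp, sample(2:4, 1))
    pres <- setNames(sample(c(TRUE, FALSE), length(scope), replace = TRUE),
                     scope)
    if (!any(pres)) pres[sample(length(scope), 1)] <- TRUE
    origin <- ape::getMRCA(sp, spp)      # fixed origin: the root
    base <- dollo_min_losses(pres, sp, origin = origin)$n_losses
    extra <- setdiff(spp, scope)
    if (length(extra) == 0) next
    pres2 <- c(pres, setNames(FALSE, sample(extra, 1)))
    expect_gte(dollo_min_losses(pres2, sp, origin = origin)$n_losses, base)
  }
})

test_that("Dollo and LCA agree on single-copy families", {
  sp <- small_species_tree()
  # gene retained in A, C, E only; gene tree congruent with the species tree
  gt <- parse_newick("(A-G1:40,(C-G1:30,E-G1:30):10);")
  rec <- lca_reconcile(gt, sp)
  pres <- setNames(c(TRUE, FALSE, TRUE, FALSE, TRUE),
                   c("A", "B", "C", "D", "E"))
  dollo <- dollo_min_losses(pres, sp)
  expect_equal(rec$total_dups, 0)
  expect_equal(rec$total_losses, dollo$n_losses)
  expect_setequal(names(rec$losses), dollo$loss_branches)
})

test_that("loss counts match the printed study patterns on the bundled inputs", {
  sp <- parse_newick(fixture_path("species_tree_20mammals.nwk"), file = TRUE)
  pm <- read_presence_matrix(fixture_path("gene_counts_20mammals.tsv"))
  eutherians <- setdiff(sp$tip.label, c("Md", "Oa"))
  losses_for <- function(lin) {
    pres <- setNames(pm$functional[eutherians, lin] > 0, eutherians)
    dollo_min_losses(pres, sp)
  }
  r23 <- losses_for("RNase2/3")
  expect_equal(r23$n_losses, 3)
  expect_setequal(r23$loss_branches, c("Cp+Hg", "Am+Cf", "La"))
  expect_equal(losses_for("RNase5")$n_losses, 4)
  r78 <- losses_for("RNase7/8")
  expect_equal(r78$n_losses, 2)
  expect_setequal(r78$loss_branches, c("Mm+Rn", "Cf"))
})
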