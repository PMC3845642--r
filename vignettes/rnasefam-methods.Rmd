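---
title: "Methods: models, conventions, and design choices in rnasefam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions, and design choices in rnasefam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasefam)
```

`rnasefam` re-implements, as a tested and reusable toolkit, the standard
analysis chain for the evolution of a multigene family — worked out on the
mammalian ribonuclease (RNase) A superfamily, a classic host-defense
family of intronless genes of roughly 130 codons carrying a
His…Lys…His catalytic triad, a CKXXNTF signature motif, and 6–8
conserved cysteines. This vignette explains the models and conventions
the package commits to, the parameters that matter, what the simulator
does and does not emulate, and the choices made where the design was
genuinely open.

## Gene vs pseudogene calls

A sequence is a *functional gene* when some reading frame yields one
uninterrupted ORF: no internal stop codon, an ATG start, and a codon count
inside configurable bounds (default 100–160 codons, around the
family-typical ~130). Anything else is a *pseudogene*, and
`classify_gene()` reports each defect with its codon position:
`premature_stop`, `frameshift`, `missing_start`, or `truncated`.

Frameshifts are only called when a functional reference CDS from the same
lineage is supplied: the query is globally aligned to the reference at the
nucleotide level and every indel whose length is not a multiple of three
is a frameshift. Without a reference, only the stop-codon and length-bound
rules apply — this keeps the rule deterministic where a manual genome
curation would otherwise be needed. When all three frames are riddled with
stops and no reference is available, the call is a pseudogene flagged
low-confidence.

The ORF length bounds are configuration, not biology: the family's
literature says only "approximately 130 amino acids", so the defaults are
wide and exposed as an argument.

Canonical-feature annotation (`annotate_canonical_features()`) checks the
signature motif by pattern (`CK..NTF`), counts cysteines exactly, and
assesses the catalytic triad at *alignment-mapped* positions: the query is
aligned to a bundled canonical template and the template's triad columns
are read off the query, so indels upstream of a catalytic residue do not
break the check. The template is synthetic — written to carry the
canonical features at known coordinates — and doubles as the simulator's
root sequence; it is not a real gene and is documented as such.

## Codon alignment and complete deletion

Alignment is protein-guided: proteins are aligned (pairwise
Needleman–Wunsch via Biostrings under BLOSUM62, gap open 10, extend 0.5;
progressive profile merging along an NJ guide tree for more than two
sequences) and then back-translated so every column is a codon column.
This guarantees frame-preserving codon columns for the dN/dS counting
below. The recent within-species paralogs that carry most of the
scientific weight align essentially gap-free either way, so nothing hinges
on reproducing any particular aligner's heuristics; a pre-aligned FASTA
can be supplied instead when a published alignment must be injected.

*Complete deletion* removes every codon column with a gap in any row
before distances are computed — the strictest of the usual missing-data
policies, and the one the downstream counting methods assume. Pseudogenes
can participate in trees through a stop-masked mode in which internal
stops become missing data (`NNN`), but they are rejected from dN/dS
estimation.

## Distances and the modified Nei–Gojobori estimator

`p_distance()` and `k2p_distance()` are the standard proportion and
Kimura two-parameter corrections; K2P refuses saturated inputs
(`1 − 2P − Q ≤ 0` or `1 − 2Q ≤ 0`) rather than returning a complex
number.

`nei_gojobori_modified()` implements pairwise dN/dS by weighted counting:

* **Site counting.** At each codon position the three possible changes
  are weighted by the assumed transition/transversion ratio `R`
  (transition weight `R`, each transversion weight 1); the synonymous
  site fraction is the weighted share of synonymous changes. Changes that
  create a stop codon count as nonsynonymous, which keeps the invariant
  `S + N = 3 × codons` exact. With `R = 1` this reduces to the classic
  unweighted method.
* **Difference counting.** Differences between two codons are averaged,
  unweighted, over all minimal mutational pathways, excluding pathways
  that pass through a stop codon (if every pathway is blocked, all are
  used). Pathway handling is the one place counting implementations
  genuinely differ: this package's estimates match Biopython's NG86
  exactly on codon pairs whose pathways avoid stops, and differ only by
  this convention when they do not.
* **Correction.** The synonymous and nonsynonymous proportions get the
  one-parameter correction `d = −3/4 · log(1 − 4p/3)`; `p ≥ 3/4` is
  reported as saturated (`NA`), and `dN/dS` is undefined when `dS = 0`.

The transition/transversion ratio `R` defaults to 2.0 — a typical
mammalian nuclear value — and is exposed everywhere, because the original
analyses this package emulates do not state the value they used.
Standard errors come from codon-column bootstrap (resampling codon
columns with replacement; the SE is the standard deviation of replicate
estimates), seeded and bit-reproducible. An analytical variance would be
the other defensible choice; the bootstrap was chosen because it applies
unchanged to every derived statistic (per-pair rates, group means).

## Trees

Neighbor joining is delegated to ape's reference implementation, with two
reproducibility policies on top: taxa are fed in lexicographic order (so
ties break identically regardless of input order), and negative NJ branch
lengths are clamped to zero with the deficit moved to the parent-side
branch. NJ is exact on additive matrices, which the tests exploit as an
oracle. Bootstrap supports resample alignment columns, rebuild the tree,
and count bipartitions; replicates default to 1,000 and degenerate
replicates (saturated distances) are dropped and counted. Monophyly
queries require an explicit outgroup for unrooted trees — no silent
midpoint rooting.

## Ortholog sets, paralog groups, selection summaries

An *ortholog set* takes one gene per species for a lineage, choosing at
random (seeded, recorded) among co-orthologs; with recent duplicates the
choice is immaterial, and a property test asserts the mean ratio moves by
less than 0.05 between choices. A *paralog group* is a maximal clade in
the lineage gene tree whose functional tips (at least two) all belong to
one species — pseudogenes may sit inside the clade but are not members.
*Gene sorting* between two species is called when neither species' tips
are monophyletic inside their smallest shared clade.

Selection summaries average all pairwise estimates within a group. The
headline "mean dN/dS" is the **mean of pairwise ratios** (pairs with
`dS = 0` excluded and reported), not the ratio of means — in the source
analyses the printed group values are only consistent with the former —
with ratio-of-means available as an option. For groups of three or more
members a one-tail paired t-test of pairwise `dN − dS > 0` is attached;
it is a pragmatic screen, and its caveat (pairwise values from the same
members are not independent) is acknowledged rather than corrected.

Saturation profiles make a qualitative claim algorithmic: dN-vs-dS points
are split at the midpoint of the dS range, a plateau is declared when the
upper-half slope falls below a configured fraction (default 0.25) of the
lower-half slope, and the onset is then located by a two-segment
least-squares breakpoint constrained to keep at least five points per
segment (unconstrained breakpoints overfit the noisy tail). These
thresholds are package configuration, not a claim about the original
procedure.

## Reconciliation and Dollo losses

`lca_reconcile()` is standard last-common-ancestor mapping: each gene-tree
node maps to the species-tree MRCA of its descendant species; a node is a
duplication iff it maps to the same species node as one of its children;
losses follow the usual gap rule, placed on the species branches skipped
over. `dollo_min_losses()` counts, under single-origin parsimony, the
maximal all-absent clades below the origin — each is one loss, placed on
the branch subtending it. The two agree on single-copy families, which is
property-tested.

Presence of a lineage in a species defaults to *functional-only* (a
species with nothing but pseudogenes counts as having lost the gene),
matching how loss counts are usually quoted for this family; a flag flips
pseudogene-bearing species to "present".

The bundled 20-mammal species tree encodes the study phylogeny
constraints (mouse+rat sister, naked mole rat+guinea pig sister,
dog+giant panda sister, gibbon inside the apes, elephant basal among the
eutherians, opossum then platypus outgroups). Divergence times are
round-number annotations in My; no computation consumes them.

## Isoelectric points

Net charge is the Henderson–Hasselbalch sum over ionizable groups; pI is
found by bisection on pH ∈ [0, 14] to |charge| < 1e−4 (property-tested
against a brute-force grid). The default pKa table is the Bjellqvist
(ExPASy-style) set — the one behind most published pI figures for these
proteins — with an EMBOSS-style alternative bundled; published pI values
depend on the table used, so comparisons carry a ±0.3 tolerance and the
table is swappable. pI is conventionally computed
on the mature peptide (signal stripped via `signal_end`), since these are
secreted proteins. A small reference FASTA with the mature human
RNase2/EDN and RNase3/ECP peptides (transcribed from the public database
entries) ships with the package for the classic cationicity contrast.

## The simulator

`simulate_family()` runs a birth–death–pseudogenization process per gene
copy along a dated species tree: exponential waiting times with per-copy
rates λ (duplication), μ (loss), and ψ (pseudogenization, functional
copies only); all live copies are transmitted to both daughters at every
speciation; pseudogenized copies evolve neutrally (ω = 1, stops allowed)
and may duplicate further — a pattern real pseudogene clades show.
Per-branch overrides let a single terminal branch carry, say, a 20×
duplication burst; `omega_dup` models post-duplication selection shifts.

Sequence evolution is mutation–acceptance rather than rate-matrix
exponentiation: proposals arrive as a Poisson process per site (κ-biased
toward transitions), nonsynonymous proposals are accepted at relative
rate ω, and stop-creating changes are rejected while a copy is
functional. This is transparent, exactly seedable, and sufficient for the
package's estimator-recovery tests; it is not a likelihood model to fit.
Three small policies keep the ground truth exact: functional copies hold
their ATG start and terminal stop fixed; pseudogenes are re-disrupted at
emission if neutral drift happened to revert the planted defect (a dead
copy stays dead); and the default injected defect is a premature stop —
not an indel — so pseudogenes stay codon-framed and can ride along in
alignments and trees (indels are available via `defect_types`).

Defaults are chosen to be realistic for a mammalian tree measured in My:
substitution proposals at 0.003 per site per My (the neutral mammalian
range), λ = 0.002, μ = 0.0005, ψ = 0.001 per copy per My, ω = 0.4 for
functional copies, κ = 2, roots of 130 codons. Under these settings a
20-species, 220-My tree yields family sizes in the dozens — the same
order as the real census.

What the simulator does *not* emulate: within-gene indel evolution in
functional copies, gene conversion and recombination (documented for the
rodent host-defense RNases), rate variation among sites, and base
composition drift. Passing recovery tests on simulated data therefore
shows estimator correctness under the generating model, not robustness to
those real-data complications.

The ground truth returned with every simulation — event log, true gene
tree with duplication nodes labelled, per-copy ω — is what makes the rest
of the package testable end to end: the reconciliation tests assert exact
recovery of surviving duplication counts over 100 seeded simulations, and
the selection tests assert that ω = 2 and ω = 0.3 groups separate by more
than three combined standard errors.

## Problem sizes and reproducibility

The shipped tests run the full chain at deliberately modest sizes — five
or six species trees for simulation loops, 100–200 bootstrap replicates,
25–50 replicate pairs for recovery rates — which keeps the whole suite in
the minutes range while leaving every statistical tolerance comfortably
wide. Every stochastic step takes an explicit seed, and equal seeds give
byte-identical sequences, trees, supports, and reports (the run manifest
records seeds and settings; its timestamp is the only non-reproducible
byte).

## Known limitations

* Frameshift detection needs a reference; genes pseudogenized purely by
  regulatory decay are invisible to sequence-level classification either
  way.
* The progressive MSA is a plain profile aligner; for deeply diverged
  lineage sets a dedicated aligner will do better, and its output can be
  injected as a pre-aligned FASTA.
* The one-tail paired t-test on pairwise values ignores their
  non-independence; treat small p-values as a screen, not an inference.
* Plateau detection is threshold-based; on fewer than ~20 points the
  onset estimate is coarse.
* LCA reconciliation is parsimony, trusting the gene-tree topology;
  bootstrap-weak clades propagate their uncertainty into event counts.
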