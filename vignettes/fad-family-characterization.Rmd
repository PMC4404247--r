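---
title: "Characterizing membrane-bound fatty acid desaturase gene families"
author: "fadkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing membrane-bound fatty acid desaturase gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadkit)
```

## The problem

Membrane-bound fatty acid desaturases (FADs) introduce double bonds into
the acyl chains of membrane lipids; in plants their activity is central to
cold acclimation, because membrane fluidity at low temperature depends on
the level of fatty-acid unsaturation. The family divides into four
subfamilies — First, Omega, Front-end and Sphingolipid Desaturases — that
share a diagnostic architecture: three short histidine-rich motifs
("histidine boxes") that coordinate the catalytic di-iron centre.

Characterizing the family in a newly sequenced genome is a standard,
multi-stage exercise: find the candidate genes, confirm them by domain
architecture, classify them into subfamilies on a phylogeny, examine motif
conservation, exon–intron structure and gene duplication, and profile
expression under the stress of interest by quantitative PCR. `fadkit`
implements the full exercise as composable R functions plus a
`run_pipeline()` orchestrator, and pairs it with a synthetic-data
generator so that every stage is testable against planted ground truth
without downloading a genome.

## Stage by stage

### Identification (`screen_candidates`, `assign_names`)

Each proteome entry is scored by its best Smith–Waterman local alignment
against a panel of reference anchor proteins spanning the four
subfamilies, then confirmed by the histidine-box scan. Acceptance requires
the alignment score and identity thresholds *and* the presence of boxes 1
and 2. Box 3 is deliberately not required: genuine family members are
known in which the third box has been lost (a degenerate FAD2 pattern),
and requiring it would silently drop them. Candidate sets are made
non-redundant by locus id (isoform suffixes `.1`, `.2`, … collapse onto
their locus, keeping the best-scoring isoform).

There is no universal equivalent of a BLAST cutoff for this screen, so
`min_score` (default 100 substitution-matrix units) and `min_identity`
(default 0.40) are explicit, documented parameters. The defaults pass
every planted family member at ≥ 40 % identity to its anchor while
rejecting unrelated sequences by orders of magnitude in score.

Accepted hits are named by anchor orthology: the anchor's family stem plus
an ordinal suffix in order of descending score (ties broken by
lexicographic locus id); a stem with a single hit carries no suffix.

### Alignment (`global_align`, `local_align`, `progressive_msa`)

The package carries its own affine-gap Gotoh kernel (in C++) because the
progressive multiple alignment needs profile–profile dynamic programming,
which no installed package exposes, and because deterministic tie-breaking
matters for reproducible pipelines. Conventions, all configurable:

* substitution matrix BLOSUM62 (taken from Biostrings), gap open 10, gap
  extend 0.5 — ClustalX-like defaults;
* a gap run of length *k* costs `open + (k-1) * extend`; end gaps are
  penalized in global mode;
* traceback ties resolve diagonal → up → left, so results are identical
  across platforms;
* identity is the fraction of residue–residue columns that match, and
  coverage is measured against the **longer** sequence — the convention
  the duplication criteria below require.

`progressive_msa` follows the classic recipe: a neighbor-joining guide
tree on fractional shared 3-mer distances, then profile–profile global
alignment in guide-tree postorder. It is deliberately minimal — no
iterative refinement, no position-specific gap penalties — which is
sufficient for the within-family divergences the pipeline handles, and is
validated in the test suite by recovering planted homologous columns.

### Motif architecture (`scan_histidine_boxes`, `detect_er_motif`, `detect_cytb5`, `build_box_logo`)

The three boxes are matched as `H-x(3,4)-H`, `H-x(2,3)-H-H` and
`[HQ]-x(2,3)-H-H`; a glutamine-opened third box is the known signature of
the Front-end subfamily. Search is leftmost-greedy — the leftmost feasible
box 1 whose spacing windows admit a box 2 (and then a box 3) wins, with
shorter matches preferred at equal starts — under configurable spacing
windows (box1–box2 within 25–40 residues, box2–box3 within 100–200).

Spacing is counted as residues **strictly between** the end of one box and
the start of the next (end-exclusive). The literature reports "31 or 32
residues between" the first two boxes without defining the boundary
convention; this package fixes end-exclusive counting, documents it, and
plants its synthetic data under the same convention, so recoveries are
exact. If an external annotation uses a different convention its spacings
will differ by a constant ±2 and the spacing windows can be shifted
accordingly.

The ER-retrieval motif test is position-strict: exactly the final five
residues are matched against Φ-X-X-[KRDE]-Φ (Φ ∈ {F, Y, W, I, L, V}).
Cytochrome-b5 detection is a proxy — the invariant heme-binding HPGG
tetrapeptide within the N-terminal 80 residues — because re-implementing
profile-HMM domain search is out of scope; the flag is advisory and is
treated as such throughout.

Box logos are position-frequency tables with per-column information
content R = log2(20) − H bits, gaps excluded and frequencies renormalized
over residues.

### Phylogeny (`pairwise_p_distance`, `poisson_correct`, `nj_tree`, `bootstrap_supports`, `classify_subfamilies`)

Distances are protein p-distances under pairwise deletion (columns with a
gap in either row are excluded per pair), corrected for multiple hits by
the Poisson model d = −ln(1 − p). The correction is undefined at p = 1
and `poisson_correct` treats a saturated pair as an error. Inside the
bootstrap only, a resampled replicate that saturates a pair caps p just
below 1 instead of aborting — the cap affects a replicate's branch
lengths, not the bipartition counts the supports are computed from.

Trees are built by the Saitou–Nei neighbor-joining agglomeration on the
Q-criterion, with two numerical policies: ties on Q break by the
lexicographically smallest pair of cluster representatives, and negative
branch lengths clamp to zero with a message. The result is an unrooted
`ape::phylo` object (any rooting for display is presentational), and the
implementation is cross-checked in the tests against both closed-form
quartets and `ape::nj`.

Bootstrap supports resample alignment columns with replacement, rebuild
the NJ tree per replicate, and report for each internal bipartition of the
original tree the percentage of replicates containing it. The
conventional full-scale choice is 1000 replicates; the test suite and the
acceptance script run 100, which is ample for the clean synthetic signal
and keeps the suite desk-scale. Supports are reported on the original
topology rather than a majority-rule consensus.

Subfamily classification is anchor-guided: an unlabeled leaf takes the
subfamily of the smallest clade (bipartition side of the unrooted tree)
containing it and at least one anchor, provided every equally small such
clade is pure for a single subfamily; any conflict or mixture yields
`unclassified` rather than a guess.

### Duplications (`find_duplications`)

A gene pair is a duplication event when its global protein alignment
passes both classical criteria strictly: identity of the aligned regions
> 80 % *and* aligned coverage > 80 % of the longer sequence. A passing
pair is *tandem* when both genes share a chromosome with no annotated
gene between them, otherwise *segmental*. Chains of tightly linked
passing pairs (connected components of adjacent pairs) collapse to a
single event, keeping the highest-identity pair as representative — so a
tandem array of three near-identical genes counts once.

Alignment is protein-level by default (robust to synonymous divergence);
passing CDS sequences switches the comparison to the nucleotide level.
Strict adjacency ("no intervening gene") is used for "tightly linked"; no
wider distance window is applied.

### Expression (`delta_delta_ct`, `cluster_profiles`, `classify_response`)

Relative expression follows the 2^−ΔΔCt method: ΔCt = Ct(gene) −
Ct(reference) per biological replicate, ΔΔCt = mean ΔCt(condition) −
mean ΔCt(calibrator), RQ = 2^−ΔΔCt. Replicates aggregate as the
arithmetic mean of ΔCt — equivalently the geometric mean of RQ — and the
replicate standard deviation of ΔCt is carried along. Amplification-
efficiency correction (Pfaffl-type) is out of scope.

Profiles cluster agglomeratively with uncentered-correlation distance and
average linkage, the combination popularized by the early expression-
clustering tools; the leaf ordering is the heat-map row order. A constant
profile has no direction under a correlation-type distance and is a named
error.

Response labels over a stress time course are **descriptive, not
inferential**: the extreme log2 RQ across post-calibrator time points is
compared with configurable cutoffs (|log2 RQ| ≥ 1 strong, ≥ 0.5 slight).
The underlying studies report "significantly up-regulated" without a
numeric rule; the defaults encode the conventional two-fold reading and
are exposed as parameters.

## The synthetic generator

`gen_desaturase_protein`, `gen_genome` and `gen_ct_table` produce data
whose planted features the pipeline must recover *exactly*:

* boxes are planted at subfamily-specific spacings — 31 residues between
  boxes 1 and 2 in First/Omega, 32 in Front-end/Sphingolipid; four
  residues inside box 1 for First, three elsewhere; 127 residues between
  boxes 2 and 3 for First and 161 for the ω-3 cluster (the two values the
  family literature states), with 150 and 140 chosen once for Front-end
  and Sphingolipid, which the literature leaves unstated, inside the
  scan window;
* background positions draw uniformly from the amino acids excluding H
  and Q, so the planted boxes are provably the only ones present (H alone
  would suffice for boxes 1–2; excluding Q also pins the Q-opened third
  box), and planted-recovery tests can assert exact coordinates;
* family members and duplicate partners derive from a cluster founder by
  point substitution only, avoiding planted positions, so a target
  identity maps deterministically onto a substitution count and measured
  identity lands within ±2 points; requested sub-unit coverage is
  achieved by truncation, independent of identity;
* tandem pairs are laid out adjacently on one chromosome with no
  intervening gene; segmental partners go to different chromosomes; exon
  counts drive the GFF3 exon features (1-based inclusive, `##gff-version
  3`, gene/mRNA/exon/CDS with `Parent` links);
* Ct values follow Ct = base_gene − log2(FC) + ε with ε ~ N(0, noise_sd²)
  i.i.d. per well, the reference gene at FC ≡ 1, and three biological
  replicates by default; no technical-replicate layer is modeled, since
  the motivating experimental designs report biological replication only.

`default_study_plan()` freezes the reference conditions the acceptance
machinery uses: 19 genes in the four subfamilies (1 First / 11 Omega / 5
Front-end / 2 Sphingolipid) on 13 chromosomes, four duplication pairs
(one tandem inside the FAD2 cluster, three segmental), the family's
characteristic exon-count profile (eight exons throughout the ω-3
cluster, single-exon FAD2 genes with one three-exon outlier that is also
excluded from the expression design, ten exons for FAD6, five for the
First member, two for the Δ4 pair), 81 decoys for the 100-protein screen,
a 0/3/6/12 h cold-stress design with 7 strongly induced and 5 strongly
suppressed genes among 18, and Ct noise of 0.2 cycles.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: realistic codon usage or intron sequence;
shared ancestry *between* families of a subfamily (each cluster founder is
independent, so subfamily-level clades in the synthetic phylogeny are
family-level clades); insertion/deletion divergence between duplicates;
amplification-efficiency variation or technical replicates in qPCR; and
annotation noise of every kind (split/merged gene models, missing exons).
Results on real genomes depend on annotation quality in ways the
synthetic round trip cannot probe.

## Numerical choices, in one place

* Gap cost `open + (k-1) * extend`; DP tie-breaks diagonal → up → left;
  the lowest-coordinate cell wins ties for the local-alignment start.
* Mw/pI use the Expasy-style average residue masses and Bjellqvist-type
  pKa set stored as data in `physchem_table()`; pI is found by bisection
  on [0, 14] to 1e-4 pH. The upstream tools leave their constant sets
  uncited, so agreement with them is expected to ±0.01 kDa and ±0.1 pH,
  not bit-exact.
* Duplication thresholds are strict inequalities; a pair at exactly 0.80
  is rejected.
* NJ ties break lexicographically; negative branches clamp to 0; the
  bootstrap caps saturated p-distances at 1 − 1e-9 inside replicates.
* Ambiguity code `X` carries the mean residue mass and zero charge, and
  is flagged.
* The expression stage aggregates replicates as mean ΔCt; labels use
  |log2 RQ| cutoffs 1 and 0.5.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by design:
alignment oracles on ≤ 10-mers, quartet inversions, a 19-gene genome with
81 decoys (100-protein screen), MSAs of up to ~27 sequences × ~700
columns, and 100 bootstrap replicates. All sizes are parameters; nothing
in the implementation is specific to them.

## Limitations

Identification is alignment-based screening, not profile-HMM search; very
remote homologs that a curated HMM would catch can be missed, and the
cytochrome-b5 proxy is weaker than a domain model. The NJ/Poisson
combination is the classical distance pipeline, chosen for fidelity to
standard practice rather than statistical efficiency; likelihood methods
are out of scope. Duplication classification uses strict adjacency and
sequence criteria only — no synteny blocks, no Ka/Ks dating. Expression
labels are descriptive cutoffs, not hypothesis tests.
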