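---
title: "Comparative analysis of mitochondrial cox1 group I introns"
author: "intronscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of mitochondrial cox1 group I introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronscape)
```

## The problem

Fungal mitochondrial *cox1* genes are riddled with large (often >1 kbp)
self-splicing group I introns. Most of these introns carry a homing
endonuclease gene (heg) whose product cleaves intron-less alleles at a
specific target site and thereby copies the intron into them ("homing"),
including laterally across species and even kingdoms. Opposed to this gain
mechanism, heg decay — frameshifts and premature stop codons eroding the
open reading frame — is read as the first step toward precise intron loss.
The comparative questions are: which introns across species are *the same*
intron (orthologous insertions), how are intact and eroded copies
distributed over the species tree, and what does the distribution of
intron counts per gene say about the balance of gain and loss?

`intronscape` turns that analysis into a reproducible pipeline:

1. **Gene-model extraction** (`read_genbank`, `build_gene_model`): exon
   structure from a CDS join, introns as the gaps, splicing, translation,
   length metrics.
2. **heg integrity calling** (`scan_orfs`, `assign_family`, `call_heg`,
   `detect_frameshift`, `detect_chimera`): each intron is scanned for ORFs,
   assigned to a heg family by local protein alignment against a reference
   set, and called `intact`, `eroded` or `absent`, with machine-readable
   evidence.
3. **Position-class (Pcl) classification** (`project_site`, `cluster_pcls`,
   `name_pcls`): the insertion site of each intron is expressed as a codon
   index plus phase in its own spliced CDS, projected through a pairwise
   protein alignment onto one designated reference COX1 frame, and introns
   sharing an exact (reference residue, phase) site form a named position
   class — the operational unit of intron orthology.
4. **Landscape matrix** (`build_landscape`, `summarize_landscape`): the
   species-by-Pcl matrix of `absent`/`intact`/`eroded` states with its
   marginal counts.
5. **Dynamics** (`intron_count_histogram`, `fit_log_model`): the number of
   species as a function of intron count, and a least-squares fit of the
   logarithmic decay model `y = a ln(x) + b`.
6. **Synthetic data** (`simulate_landscape` and friends): a
   phylogeny-driven generator with complete ground truth, so every stage
   above is testable offline.

## Coordinate and site conventions

All genomic coordinates are 1-based inclusive (the GenBank convention);
every exported TSV states this in a header comment. Reverse-strand genes
are reverse-complemented on ingest so downstream code sees only the coding
strand.

An intron's site in the spliced CDS is summarized by
`offset = number of CDS nt 5' of the intron`:
`codon_index = offset %/% 3 + 1`, `phase = offset %% 3`. Phase `+1` means
the intron interrupts the codon between nt 1 and nt 2, `+2` between nt 2
and nt 3; phase 0 sites sit on a codon boundary and are attributed to the
*following* codon. This last choice is arbitrary but must be fixed; one
convention applied uniformly cancels out in any within-frame comparison.

Translation defaults to NCBI table 4 (mold/protozoan mitochondrial), the
appropriate table for fungal mtDNA; it is configurable per record.
Annotated introns shorter than 30 nt are rejected as annotation noise —
real mitochondrial *cox1* introns are orders of magnitude larger.

## Alignment model

Pairwise global (Needleman–Wunsch) and local (Smith–Waterman) alignment
with affine gaps backs every comparison; there is deliberately **no
multiple alignment** — every site projection is pairwise against one
designated reference protein, which keeps Pcl coordinates independent of
which other species are in the analysis, and hence order-invariant.

Scoring defaults: BLOSUM62, gap open 10, gap extend 1 (as positive costs;
a gap of length L costs `open + L*ext`), DNA match +5 / mismatch −4.
Identity percentages divide by alignment columns excluding terminal-gap
columns; internal gaps count as mismatches. Similarity additionally counts
substitutions within the standard strong conservation groups (STA, NEQK,
NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW). These conventions are stated
openly because published identity percentages are convention-sensitive;
with other denominators the same alignments give different numbers.

Optimality is not taken on faith: `align_score_exhaustive()` enumerates
*every* gapped alignment of short sequences (an exponential reference
implementation, in C++) and the test suite checks the dynamic-programming
scores against it on a thousand random pairs per run.

## heg integrity calling

The caller formalizes qualitative criteria — an intact heg is a single
uninterrupted ORF; an eroded heg is recognizable homology broken by
frameshifts, stops, or truncation:

* **intact**: one start-to-stop ORF (≥ `min_aa`, default 100 aa) whose
  local alignment to its best family reference covers ≥ `intact_cov`
  (default 0.8) of the reference *including the C-terminal region*
  (`cterm_tol`, default 10%), with no conflicting fragment evidence. The
  C-terminus requirement matters: an ORF truncated shortly before the
  natural stop still covers 80% of the reference but is not a full gene.
* **eroded**: stop-to-stop fragments (≥ 30 aa) collectively cover
  ≥ `eroded_cov` (default 0.3) of one family reference, but are split
  across frames (frameshift), split by stops in one frame
  (premature_stop), miss ≥ 10% at a terminus (truncated_terminus), or
  simply cover too little for an intact call (low_coverage).
* **absent**: anything else.

Score thresholds are calibrated, not guessed. Full-length family
assignment requires a raw local score ≥ 80, the conventional
clearly-homologous bar for these families
(`calibrate_family_threshold()` recomputes a data-driven equivalent as a
quantile of shuffled-query scores). Fragment-level evidence uses a
threshold of 60: we measured the null distribution of random 30–200 aa
peptides against 250-aa references at ~8,000 comparisons — 99th percentile
43, 99.9th percentile 56, maximum 70 — while genuine eroded-heg fragments
score in the hundreds. Because *each intron* generates tens of fragment
comparisons, the per-comparison quantile must sit above the 99th
percentile, hence 60; and an eroded call additionally requires its best
fragment to clear the full-length bar of 80. Without these two guards,
chance fragment hits accumulate enough nominal "coverage" to turn a few
percent of truly heg-less introns into false eroded calls.

A chimera — a complete invader heg inserted in-frame inside a recipient
heg of a different family — is called when an internal segment of the ORF
aligns to one family while the prefix *and* suffix align to a single other
family. A segment matching at the end of the ORF with no recipient suffix
is deliberately not a chimera (it is a tandem arrangement) and is flagged
as such.

## Position classes

Clustering of projected sites is exact by default (tolerance 0): introns
belong to the same Pcl iff they share the reference residue *and* phase.
This mirrors the biology — the insertion site is determined by the DNA
sequence the homing endonuclease recognizes, so orthologous introns sit at
nucleotide-precise sites. A tolerance of 1 residue (single linkage, same
phase) is available for noisy projections but is not the default. When a
site projects opposite a gap in the reference, the nearest aligned column
is used and the projection is flagged `gap_adjacent` rather than silently
trusted.

Pcl names run A…Z, AA, AB… in 5'→3' site order, so alphabetical order and
gene order agree by construction. The identity structure of the classes is
*validated*, not assumed: `validate_identity_structure()` checks that
every intact endonuclease is more similar to the members of its own Pcl
than to any member of another, and reports violations without
auto-resolving them — position defines the class, identity corroborates
it, and a disagreement is something a curator should see.

Rarity: a Pcl is `rare` if its members span a single species or at most
`max_rare_species` (default 4) species within one taxonomic unit at the
configured rank (default order) — the formalization of "found once or
shared only by closely related species"; everything else is `widespread`.
Both knobs are configuration because "closely related" has no unique
formal definition.

## The dynamics fit

The histogram of species counts over intron counts is fitted with
`y = a ln(x) + b` by ordinary least squares. `ln(0)` is undefined and the
published form of the model uses `Ln(x)` directly, so the default policy
excludes the x = 0 class; `shift_plus_one` (fit on `ln(x+1)`) is provided
so intronless species can participate when desired. R² is reported as
`1 − SS_res/SS_tot`. Noiseless data round-trips the coefficients to
1e-9, which the tests assert; a logarithmic *decrease* (negative `a`) with
a reasonable R² is the signature of a cohort drifting toward intron loss
rather than a random gain/loss equilibrium, which would look Gaussian.

## What the simulator emulates — and what it does not

`simulate_landscape()` generates annotated gene records with full ground
truth under the generative model the analysis assumes. A reference
COX1-like CDS (default 520 codons) drifts along a species tree; each
intron family owns one exact (residue, phase) site and an ancestral heg
(default 250 aa) embedded in core flanks ending in the group I terminal G.
Per branch, event counts are Poisson(rate × branch length):

* **loss** excises the intron precisely, restoring the exon junction;
* **gain** inserts a *fresh drifted copy of the ancestral sequence*
  (lateral-transfer semantics — a regained intron does not remember the
  lineage's lost copy);
* **erosion** injects a frameshift (1–2 nt indel) and/or a premature stop
  into the heg, at a position drawn uniformly over the central 10–80% of
  the gene — an indel in the last few codons neither functionally erodes
  an endonuclease nor leaves any signature a homology method could read
  as erosion, so the generator only plants events that mean what the
  truth table says they mean;
* **chimera** inserts a foreign-origin (cob-like) heg, stop stripped, at
  an internal codon boundary of an intact recipient heg.

Sequence drift uses i.i.d. per-site substitution (a hit redraws the base
uniformly over all four, so the expected mismatch fraction is 3/4 of the
rate). The CDS and intact heg drift under a frame-preserving variant that
reverts stop-creating substitutions and keeps the start codon — otherwise
"intact" would silently decay into "eroded" with no logged event and the
truth table would lie.

Default study conditions, chosen once as a loss-dominated regime and then
left alone: 50 species on a coalescent tree rescaled to depth 1, 20 cox1
families plus 2 foreign invader families, loss 0.5 / gain 0.15 / erosion
0.3 events per branch-length unit, substitution 0.05 per site per unit,
chimera rate 0.01. Under these conditions a run plants roughly 600
introns, a quarter of them eroded, across all 20 sites.

What the simulator does **not** emulate — and therefore what passing tests
do not show about real data: no indels in the exons (so protein
projections are unrealistically clean; real alignments can misplace a
site near gappy regions), no codon-usage or rate heterogeneity, no
secondary-structure constraint on the intron cores, no annotation errors,
and sequence divergence far milder than the 31–56% within-family
identities seen between kingdoms. The pipeline's behaviour under those
stresses is bounded by the `gap_adjacent` flagging and the clustering
tolerance, not demonstrated by the closure tests.

## Problem sizes and reproducibility

The validation suite runs the full pipeline closure at 10 species × 6
families, the partition-recovery and conservation checks on the 50 × 20
study cohort, erosion recovery on 500 planted introns, chimera recovery
on 100 planted composites, and the aligner-vs-enumeration check on 1,000
random pairs of length ≤ 8 — sizes chosen to exercise every code path at
desk scale. Every stochastic step is a pure function of its seed: the same
`sim_config(seed = )` reproduces byte-identical artifacts, which the
pipeline tests assert file-by-file. `scripts/acceptance.R` recomputes the
headline quantities from scratch with a caller-supplied seed.

## Known limitations

* Only sense-strand heg are scanned; template-strand ORFs are out of scope.
* Group classification of an intron uses a deliberately lightweight
  terminal-nucleotide heuristic (`classify_intron_group`); real group
  assignment needs the secondary structure, which this package does not
  model.
* The GenBank reader parses the subset of the format the pipeline needs
  (single record, CDS/intron features, join/complement locations); fuzzy
  locations (`<`, `>`) are rejected rather than interpreted.
* `validate_identity_structure()` is quadratic in intact members; for
  hundreds of members, subsample or restrict to the Pcls under scrutiny.
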