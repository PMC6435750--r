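---
title: "Delineating picophytoplankton clades from V4 metabarcodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating picophytoplankton clades from V4 metabarcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picoclade)
```

## The problem

Coastal picophytoplankton groups such as the Mamiellophyceae (the green
algae *Ostreococcus*, *Micromonas*, *Bathycoccus*, *Mantoniella*) harbour
clades that differ ecologically but are nearly identical over the 18S rRNA
V4 metabarcode — sometimes by as little as two bases over a ~341-column
alignment. Conventional OTU clustering at 99% identity merges such clades
and erases their distinct biogeography. `picoclade` implements the
alternative workflow: work at the resolution of exact amplicon single
variants (ASVs), confirm them across independently processed datasets,
delineate clades by diagnostic alignment signatures plus dual-tree
phylogenetic criteria, and only then map distributions.

## The pipeline model

1. **Quality filtering** (`quality_filter`). Reads are kept when strictly
   longer than 300 bp and free of `N`. The length boundary is strict
   because the criterion is "longer than"; the ambiguity rule can be
   widened to all IUPAC degeneracy codes (`ambiguity = "any"`), but the
   default removes `N` only, the usual metabarcoding convention.
2. **Dereplication into ASVs** (`dereplicate`). One ASV per distinct
   normalized sequence (uppercase, `U→T`, gaps stripped); per-sample
   counts are multiplicities, so read totals are conserved exactly at
   every stage. ASV ids are `ASV_<dataset>_<rank>`, ranked by descending
   total reads with ties broken by sequence lexicographic order — a
   deterministic naming that matches how such tables are usually
   published.
3. **Major-ASV selection** (`select_major`). The 200-read threshold is
   *inclusive* (≥ 200). Published descriptions of this filter alternate
   between "more than" and "at least"; the observed minimum in the
   published table (205 reads) does not discriminate between the two
   readings, so we chose the inclusive rule and exposed it in
   `pipeline_config()`.
4. **Cross-dataset confirmation** (`cross_confirm`). The default mode is
   `exact` ("strictly identical sequence"). A `containment` mode accepts
   substring matches because two independently amplified and sequenced
   renditions of the same samples can differ in trimming; it is offered,
   never silently applied.
5. **Identity and OTU lumping** (`percent_identity`, `otu_lumping`). Two
   gap conventions are implemented: `all_columns` (denominator = full
   alignment length; a shared gap column counts as a match) and
   `ungapped_pair_columns` (columns gapped in either sequence are dropped
   from numerator and denominator). The default is the pairwise-ungapped
   convention common in metabarcoding tools; reports state the mode used.
   Identities are kept at full precision internally and rounded half-up
   to one decimal only for reporting (`round_identity`), matching the
   precision at which such values are printed. A clade pair is *lumped*
   at a threshold when **any** cross-clade pair reaches it
   (single linkage), mirroring the behaviour of greedy OTU clustering:
   one near-identical pair suffices for two clades to end up in one OTU.
6. **Signature discovery** (`discover_signatures`). The published figures
   show signatures but never formalize a discovery rule; we formalize the
   natural strict rule: a column is diagnostic for a clade when all clade
   members carry a state there that no member of any other clade carries.
   Gaps are legitimate diagnostic states (indel signatures are visible in
   real V4 alignments; `gap_is_state = FALSE` disables this). A member
   carrying an ambiguity code compatible with the candidate state counts
   as carrying it — on both sides of the rule — which is the conservative
   choice: within-clade it tolerates miscalled references, outside the
   clade it vetoes columns that might not be exclusive. A `majority` mode
   (fraction ≥ `min_fraction` within, zero carriers outside) is available
   for noisier references.
7. **Signature classification** (`classify_by_signature`). The default
   demands every signature position match (`min_match_fraction = 1`),
   because real clade profiles here are short and fully fixed. Ties are
   reported as `"ambiguous"` and never broken — when clades differ by two
   bases, guessing is worse than abstaining.
8. **Clade criteria** (`evaluate_clade`). A candidate clade passes when it
   is monophyletic in both the ML and the Bayesian tree and its ML
   bootstrap exceeds 70%. Monophyly is defined on the unrooted tree via
   edge bipartitions, since both FastTree and MrBayes consensus trees are
   effectively unrooted and rooting is a display choice. "Greater than
   70%" is read strictly (70 fails; `inclusive = TRUE` flips this). The
   bootstrap criterion applies to the ML tree only: the published wording
   ties the numeric threshold to bootstrap values, and no posterior
   threshold is stated — an optional `min_posterior` is exposed for users
   who want one.
9. **Biogeography** (`relative_abundance`, `presence_mask`,
   `habitat_summary`). Abundance is percent of the sample's group reads;
   samples below 100 group reads are excluded (inclusive floor, same
   reasoning as the 200-read rule). Presence uses "lower than 1% means
   absent", so exactly 1.0% is present. Multiple ASVs of one species are
   pooled **before** thresholding (`pool_by_taxon`), matching how pooled
   species maps are drawn.
10. **Primer screening** (`evaluate_primer_set`). Oligo binding is
    modelled ungapped: sliding-window placement minimizing
    degenerate-aware mismatches, ties to the leftmost site. Degenerate
    codes match by base-set intersection on both sides — a permissive
    convention that never overcounts mismatches for properly degenerate
    primers. Mismatches within the 3′-terminal window (default 3 bases,
    configurable) are flagged, since those are the ones that most degrade
    amplification; no thermodynamic model is attempted.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `min_len` | 300 | bp | strict "longer than" read filter |
| `min_asv_reads` | 200 | reads | major-ASV floor, inclusive |
| `min_sample_group_reads` | 100 | reads | sample floor, inclusive |
| `presence_threshold_pct` | 1.0 | % of group reads | boundary counts as present |
| `min_bootstrap` | 70 | % | strict (> 70) on the ML tree |
| `otu_identity_threshold_pct` | 99.0 | % identity | standard OTU threshold under scrutiny |
| `three_prime_window` | 3 | bases | "3′ end" is not quantified; 3 is the usual qPCR rule of thumb |

Latitudinal band edges (66.5°, 55°, 35° absolute latitude for
polar/subpolar/temperate/tropical) are **our** choice of conventional
oceanographic cut-offs; published habitat tables use these band names
without defining them numerically. Hemispheres are folded by absolute
latitude; note that a June snapshot samples the two hemispheres at
opposite seasons — a caveat for interpretation, not computation.
Mediterranean and lagoon flags are read from metadata columns, never
inferred from coordinates.

## The synthetic-data generator

Field-scale inputs (two multi-million-read datasets) are not
redistributable at package scale, so `simulate_metabarcoding` generates
data with the statistical structure the analysis assumes and emits the
ground truth:

* `gen_reference_clades` plants `n_diag` strictly exclusive fixed columns
  per clade on a random background (default 341 columns, 5 clades — the
  scale of the *Ostreococcus* analysis). At a column owned by clade *i*,
  members of every other clade alternate between two background states;
  this makes the column diagnostic *only* for its owner, so strict
  discovery must recover exactly the planted positions — the sharpest
  possible recovery oracle. Consequently pairwise consensus identity is
  bounded below by `100·(1 − 2·n_diag/columns)`. Intra-clade variation is
  confined to private background columns.
* `gen_samples` draws rectangular latitudinal niches (bands cycled across
  clades) with an occupancy probability, and compositions from a
  symmetric Dirichlet with small concentration (default 0.3) so one or
  two clades dominate each sample — reproducing the observed pattern that
  most clades do not co-occur. Every sample is guaranteed at least one
  occupant from its own band.
* `gen_reads` draws integer per-clade read counts (multinomial at the
  sample's depth) and then applies independent per-base substitutions for
  each of the two datasets, which share identical true haplotypes — the
  property that makes exact cross-dataset confirmation work. The
  *realized* pre-error read fractions are recorded as the recovery truth:
  an exact pipeline can recover what was sequenced, not the latent
  composition behind the multinomial draw, so recovery tests at error 0
  can and do demand exact equality.

What the generator does **not** emulate: indels and chimeras (the error
model is substitution-only, keeping the ASV space enumerable), PCR
primer bias, rRNA copy-number variation, and the spatial autocorrelation
of real stations. Passing recovery tests therefore demonstrates
correctness of the pipeline's logic under its stated assumptions, not
robustness to every artefact of real amplicon data.

## Numerical choices

* Identity rounding is half-up (base R's `round` is banker's rounding);
  full precision is kept internally, including in lumping decisions.
* The internal neighbor-joining builder (`nj_tree`) exists so the clade
  criteria are testable end to end without external ML/Bayesian software;
  it is not a replacement for those inferences. Q-matrix ties are broken
  by the lexicographically smallest pair of labels (merged nodes keyed by
  their smallest contained leaf), making topologies reproducible; on
  additive matrices path lengths reproduce the input exactly.
* A defining bipartition can be represented on either side of a binary
  root; support lookup prefers the node whose tip set equals the member
  set and falls back across the root edge, so support values never depend
  on the arbitrary rooting of the input newick.
* Degenerate edge cases error loudly rather than return sentinels: zero
  comparable columns in `ungapped_pair_columns` mode, a retained sample
  with zero group reads, a singleton clade's within-clade identity
  (reported absent, not 0), an unplaceable oligo (`binding_site_found =
  FALSE`, counts absent).

## Problem sizes in the test-suite

The suite exercises the pipeline at deliberately compact sizes chosen to
make properties sharp and runs reproducible: alignments of 60–341
columns, 2–5 clades, 6–40 samples, depths of 300–1500 reads per sample,
error rates 0–0.05, and 100-tree random suites for the monophyly and
neighbor-joining oracles. End-to-end recovery at error 0 is asserted
exactly; at 1% per-base error the composition recovered from major ASVs
is asserted to track the planted truth (correlation > 0.9), since with
341-column amplicons most reads then carry at least one error and exact
recovery is no longer the right expectation.

## Known limitations

* Signature discovery requires queries pre-aligned to the reference
  coordinate system; the package does not build alignments.
* The strict signature rule is our formalization; references with
  within-clade polymorphism at otherwise-diagnostic columns need the
  `majority` mode and a considered `min_fraction`.
* Primer screening ignores indels, melting temperature and amplicon
  length; a mismatch count is a screen, not a prediction of qPCR
  efficiency.
* Published mismatch counts for specific qPCR sets depend on oligo
  sequences published elsewhere; the screening functions are exercised on
  constructed and planted cases instead.
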