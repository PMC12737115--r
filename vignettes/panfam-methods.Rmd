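---
title: "Methods: pangenome family classification, Ka/Ks, promoter SVs and association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome family classification, Ka/Ks, promoter SVs and association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panfam)
```

`panfam` implements a pangenome gene-family pipeline as five analysis
stages plus a synthetic-data generator. This vignette describes the models
and procedures behind each stage, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data do and do not
establish about behavior on real genomes.

## Family identification and occupancy classification

Domain hits come from HMMER3 `--domtblout` tables, one per-genome search
against a family profile. A gene is a family member when at least one hit
satisfies **E-value < `evalue_max`** (default `1e-5`) and **profile
coverage > `min_coverage`** (default `0.70`). Both inequalities are
strict. Coverage is computed on the *profile* coordinates,
`(hmm_to - hmm_from + 1) / profile_len`: domain "alignment length" most
naturally normalizes by the domain model's length, which is constant
across genomes, whereas target-side normalization would vary with each
protein's length. Multiple qualifying domains in a gene count once.

Members are grouped into pan-genes by single-linkage clustering on global
pairwise protein identity, computed as
`(max length − Levenshtein distance) / max length` (unit-cost global
alignment identity) with linkage threshold `identity_min = 0.90`. Single
linkage at 90% is deliberately permissive: allelic copies of one gene
across accessions are nearly identical (the generator's copies sit around
96%), while distinct family members fall far below the threshold, so the
precise identity measure matters little in the regime the clustering has
to resolve. A published pan-gene assignment can be injected via `pan_map`
to bypass clustering entirely. Pan-gene ids are assigned from the sorted
member keys, making the output invariant to input order.

Occupancy over an `n`-genome panel partitions pan-genes into

* **core**: occupancy = n,
* **private**: occupancy = 1,
* **near-core**: `near_core_min_frac * n` ≤ occupancy < n (default 0.90),
* **dispensable**: everything between private and near-core.

The near-core/dispensable boundary is a convention rather than a derived
quantity; 90% is the common soft-core cutoff (24–25 of 26 genomes). The
boundary is exposed as a parameter. "Private" is strictly occupancy = 1; a
gene present in, say, 3 of 26 genomes is dispensable even if it is rare.

## Ka/Ks estimation

Haplotype pairs within a pan-gene are protein-aligned
(Needleman–Wunsch/BLOSUM62), back-translated to codon alignments (gapped
columns dropped in whole codons, terminal stops trimmed, translations
validated), and passed to one of two counting estimators. Only the
standard genetic code is supported — the intended substrate is nuclear
plant genes.

**NG86.** Synonymous site fractions per codon come from exhaustive
enumeration of the nine single-nucleotide changes; changes to stop codons
are excluded from both numerator and denominator, so each position still
contributes one full site and `N + S = 3 × codons` holds exactly. Codons
differing at 2–3 positions are resolved by averaging over all substitution
orderings, excluding orderings that pass through a stop codon (if every
ordering does, all are kept and stop-involving steps count as
nonsynonymous). Proportions `pN = Nd/N`, `pS = Sd/S` are Jukes–Cantor
corrected, `d = −(3/4)·ln(1 − 4p/3)`; at `p ≥ 0.75` the rate is undefined
and the estimate carries a `saturated` flag. ω is reported only when Ks is
defined and positive — Ks = 0 pairs yield `omega = NA` rather than an
infinite ratio, and such pairs are excluded from downstream proportions.

**Approximate YN.** The Yang–Nielsen-style estimator refines NG86 in three
ways. (i) *κ estimation*: codon positions that are fourfold-degenerate in
both sequences and positions that are nondegenerate in both form two site
classes; transition/transversion difference proportions in each class get
K80 corrections, the transition and transversion distances are averaged
across classes weighted by class size, and `κ = 2A/B` (bounded to
[0.1, 99]; κ falls back to 1 when a class is empty or saturated).
(ii) *Weighted counting*: mutation targets are weighted by
`κ^(transition)` times the F3x4 position-specific frequency of the target
base (frequencies from both sequences with a 0.5 pseudocount per base), in
both site counting and pathway resolution, where a path's weight is
`κ^(transitions) × ω^(nonsynonymous steps)`. (iii) *Correction*: K80-style
corrections are applied separately to the synonymous and nonsynonymous
difference classes using their own transition/transversion split. Because
pathway weights depend on ω, counting is iterated: starting at ω = 1,
differences are recounted with the updated ω until Ka and Ks move by less
than `1e-6` (cap 100 iterations; hitting the cap flags `nonconverged` and
returns the last iterate). Below 30 codons the function warns that
estimates are unstable.

Per-gene selection signal is the proportion of pairs with ω > 1
(`summarize_selection()`). Genes with fewer than `min_haplotypes = 2`
haplotypes cannot form pairs and are listed as excluded; undefined ω
pairs leave the denominator. No hard "positively selected" call is made —
the threshold on that proportion is left to the user, and the pairwise
table feeds density plots directly.

Validation relies on the generator: `evolve_codon_pair()` evolves two
lineages from a uniform-sense-codon ancestor by accept/reject
single-nucleotide proposals with relative rates κ (transitions) and ω
(nonsynonymous), stop proposals rejected, each lineage's substitution
count drawn Poisson at half the requested divergence. At 300 codons and
divergence 0.3–0.4, the suite checks YN↔NG86 agreement at κ = 1 (median
relative difference ~2–3%), κ recovery (median κ̂ ≈ 2.0–2.3 at true 2),
and ω recovery (mean ω̂ increasing in true ω; essentially no ω̂ > 1 at
true ω = 0.2 and nearly all at true ω = 2).

## Promoter SV calling

Promoter windows are the `window = 2000` bp upstream of the annotated
gene start, strand-corrected (minus-strand windows reverse-complemented)
and silently truncated at contig edges with a warning. SVs are called
from a *reference-anchored multiple alignment* (the aligner is external;
generated fixtures emit alignments directly), with all coordinates
projected onto the reference row as 0-based half-open intervals for BED
compatibility.

Per sample, a maximal run of columns where the sample is gapped and the
reference is not is a **deletion**; a maximal run where the reference is
gapped and the sample is not is an **insertion**, anchored at the single
reference position following the run. Two rules keep events honest:
columns gapped in *both* rows carry no length information and are
transparent — they neither break nor extend a run (they arise when a
third sample has an insertion elsewhere); and leading/trailing gap runs
of a sample are missing flanks, not deletions, since alignment ends
cannot distinguish absence of sequence from absence of data. Events
shorter than `min_len = 50` bp are dropped.

Events merge into shared regions by single linkage within type:
deletions link at reciprocal overlap ≥ `overlap_frac = 0.5`, insertions
link when anchors are within `anchor_tol = 10` bp. Mixed types never
merge — a deletion and an insertion at the same locus are different
alleles, not one region. Clusters carried by fewer than `min_share = 5`
distinct samples are discarded; survivors are numbered `Region1..k` left
to right on the reference, a deterministic function of coordinates.
Genotyping marks carriers; the reference row is never a carrier because
every event is defined relative to it. Region sequences for motif
scanning are the modal member-event sequence (deleted reference segment
or inserted segment), with per-carrier sequences available.

The merge rule for partially overlapping events is this module's own
convention — reciprocal overlap at 0.5 is the common SV-comparison
default. On generated data, where carriers of one planted SV share exact
breakpoints, every planted variant meeting the thresholds returns as
exactly one region; real aligner output has ragged breakpoints that this
rule is designed to absorb, but that absorption is exercised only lightly
by the substitution-noise fixtures.

## Motif scanning

PWMs come from MEME minimal files (pseudocount `0.1` distributed by the
background, rows renormalized; missing background means uniform) or from
literal site strings via `consensus_pwm()` (match probability 0.95,
remainder spread evenly). Windows score
`sum(log2(pwm[pos, base] / background[base]))`. The p-value is *exact*
under the background model: per-position scores are discretized to
integers at 1/1000 bit and convolved position by position into the full
null distribution of the window score, whose inclusive upper tail at the
observed (equally discretized) score is the p-value. Discretization error
is bounded by `width / 1000` bits, far below reporting precision, and the
dynamic program agrees with brute-force enumeration of all `4^width`
windows exactly at the discretization — that equivalence is asserted in
the tests for widths up to 8. Defaults mirror FIMO: `p_max = 1e-4`, both
strands, uniform background. No multiple-testing correction is applied to
hits; the annotation reports family/motif presence per region, with
zero-hit regions listed explicitly. Windows containing non-ACGT
characters are skipped with a message rather than scored.

## Association

Samples split into SV-present and SV-absent groups per region
(`split_by_genotype()`); groups smaller than 2 make a region untestable,
which is reported rather than silently dropped. The test is the classical
pooled-variance two-sided Student's t (`df = n_a + n_b − 2`); Welch is
available by flag but the pooled form is the default because it is the
convention the labels follow. Degenerate inputs are explicit: zero pooled
variance with equal means gives `t = 0, p = 1`; with different means,
`p = 0` and a `degenerate` flag. Labels are `*` p < 0.05, `**` p < 0.01,
`***` p < 0.001, `ns` otherwise, driven by raw p-values; a
Benjamini–Hochberg column is provided alongside for rigor but does not
drive the labels, matching how small fixed panels of regions are
conventionally reported. The same machinery applies to any binary sample
covariate via `associate_by_metadata()`.

Calibration on generated data: type-I error over 1000 null 12-vs-12
tests sits within 0.05 ± 0.02, and power at a 2-SD effect with 12 vs 12
exceeds 0.80 by a wide margin. On the five-region fixture with effects
planted only at Region1 and Region5, exactly those two regions are
starred at the tested seed. Averaged over noise replicates the
*joint* exact-recovery rate is noticeably below the single-region power
(~0.5–0.6): the two planted effects inflate each other's residual
variance (each acts as an unmodelled binary covariate in the other's
marginal test), and carrier sets overlap. This is a property of marginal
two-group testing itself, not of the implementation, and it is why the
acceptance report also separates the planted-star and null-star rates.

## Synthetic data and what it shows

Each generator is deterministic given `seed` (RNG state is restored on
exit), returns a truth record sufficient to score downstream stages, and
writes standard formats (domtblout, FASTA, aligned FASTA, YAML truth)
when asked. Conventions chosen where nothing was prescribed: uniform base
composition; protein ancestors of length 200 with ~2% per-copy residue
mutation; promoter reference of 2000 bp with 24 samples; background
substitution rate 0.005/bp; expression effects in noise-SD units so power
reads directly off the effect size; the five-SV promoter preset
(`five_sv_promoters()`) plants deletion/insertion/insertion/deletion/
insertion of 80/120/60/55/150 bp with 7/9/6/5/10 carriers.

Generated alignments are built from the known edits, so they are
internally consistent (removing gaps reproduces the unaligned sequences
exactly) and isolate the SV caller from aligner behavior. That is also
the main caveat: passing tests demonstrate correctness of the calling,
merging, scoring and testing logic under clean breakpoints and
substitution-only noise — they do not demonstrate robustness to aligner
artifacts, repeat-induced ambiguity, or non-uniform composition, all of
which real promoter panels have. Likewise the codon simulator matches the
estimators' assumed mutation process (HKY-like rates, site-independent),
so estimator recovery results are internal-consistency checks, not
evidence about model misspecification.

## Problem sizes and numerical notes

The shipped suites run at deliberately modest sizes — 300-codon pairs
with 50–100 replicates per condition, 24-sample 2000-bp promoter panels,
PWM widths 4–21 — chosen so the full validation cycle completes in
seconds to minutes while keeping every statistical band comfortably
separated from its threshold. Numerical edges are handled explicitly
rather than propagated: correction-domain failures flag `saturated`,
YN iteration caps flag `nonconverged`, ω at Ks = 0 is `NA`, PWM p-values
are clamped into (0, 1], and region numbering, pan-gene ids and cluster
membership are all deterministic functions of their inputs.
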