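---
title: "DNJ-stem methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNJ-stem methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnjstem)
```

This vignette is the package's own account of its methods: what is being
modeled, which parameters matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and
where the design was genuinely open.

## The junction model

An IGH junction (IMGT convention: codon 104 cysteine through codon 118
tryptophan/phenylalanine, plus strand) decomposes as

```
v_part · n1 · [d2_part · n0] · d_part · n2 · j_part
```

with the bracketed parts present only in D-D tandem fusions. In BCP-ALL,
ongoing recombination re-uses an existing DJ join: V-to-DJ recombination
replaces everything 5' of the D (drawing a fresh V, fresh N1, and eroding
the D's 5' end), VH replacement swaps only the V (leaving the D and even
the N1's 3' tail intact, sometimes with a ≤ 5 bp remnant of the replaced
V), and D-to-DJ recombination prepends a second D. All three preserve the
junction's 3' end. The **DNJ-stem** — the last at-most-3 D nucleotides,
the N2 region, and all J nucleotides — is therefore the family key. Two
clonotypes belong to one family iff their stems are *string-identical*;
no fuzzy matching is attempted, because the stem's stability is a
biological invariant, not a similarity heuristic, and because tolerant
matching would silently merge unrelated families.

When the upstream annotation pipeline supplies junction regions they are
used as-is (after checking they concatenate to the junction). Otherwise
`decompose_junction()` infers them: the J part is the longest junction
suffix occurring verbatim in the called J germline (minimum 4 nt), the V
part analogously from the left, and the D part is the best exact match of
length ≥ `min_d_match` against any catalog D in the remaining middle.

* `min_d_match` (default **5 nt**): three or four random nucleotides
  match some D segment too often by chance; five is the shortest length
  at which a match in a typical N region is unlikely. The threshold also
  governs the D-versus-N-fallback branch of the stem rule, which the
  underlying laboratory pipelines do not document; it is exposed as a
  parameter for exactly that reason.
* Tie-breaks (longest match, then J-proximal, then smallest catalog
  rank) make decomposition deterministic and biased toward the
  biologically retained 3' D end.

## Noise filtering and the evolution consensus

Within a family, the filter removes (i) *satellites*: non-top members
within Levenshtein distance `satellite_max_edit` (default **2**) of the
top member's junction that share its 5' gene — the error cloud a PCR +
sequencing pipeline drapes around any abundant clone — and (ii)
*sub-floor* members below **3 reads** or **0.01% of usable reads**. The
same-gene requirement protects true VH-replacement members, which by
construction change the 5' gene. The top member is never removed.

The consensus call is a conjunction, each predicate configurable via
`evolution_policy()`:

| predicate | default | rationale |
|---|---|---|
| members after filter | ≥ 3 | two clonotypes cannot show a *pattern* of variability |
| distinct 5' genes | ≥ 2 | ongoing recombination draws new V (or incoming D) genes |
| distinct junction lengths | ≥ 2 | trimming + N addition varies lengths |
| satellite ratio | ≤ 0.5 | a family mostly made of top-member near-copies is an error cloud |
| complexity guard | informative | see below |

Two points deserve explanation because the underlying published
procedure leaves them open.

**Noise ratio.** The fraction of removed clonotypes is reported both as
`noise_ratio` (all removals) and `satellite_ratio` (top-member-similar
removals only); the consensus consults the latter. Every abundant clone
carries a satellite fringe below the abundance floor, so counting floor
removals against the family would penalize exactly the high-depth
samples the method is designed for; what actually signals a spurious
family is similarity to the top member.

**Stem complexity.** `is_complex` scores the stem's N-derived portion
(N2, or the N-fallback contribution) as complex when it is ≥ 2 nt with
≥ 2 distinct bases. At the defaults this is reported but not gating
(`relaxed_members = 3`, the member floor itself): an exact-match stem
already spans the D 3' end, N2 and the *entire* J region, so under the
simulated study conditions three independent surviving members with gene
and length diversity co-occur on one stem by chance with probability on
the order of 10⁻³ per stable stem — the guard would cost real
sensitivity (families of 3–4 members with a short N2 are common among
genuinely evolving stems) while defending against an event that is
already rare. For repertoires where stem specificity is genuinely weaker
— short J matches, heavy P-nucleotide use, mature malignancies — raise
`relaxed_members` to re-arm the guard.

## Mechanism classification

For evolving families only. Mother candidates are members with read
count ≥ `mother_abundance_factor` (default **10**) times the family
median, falling back to the single top member; the published description
("one or more highly abundant mother clonotypes") gives no number, so
this is a parameter. Per member:

* **VH replacement** requires (i) D 5'-site stability — the member's D
  part equals the reference D part with at most
  `d5_stability_tolerance` (default **1 nt**, absorbing sequencing error
  and minor exonuclease nibbling) eroded, *and* the 3'-most ≤ 4 nt of
  the mother's N1 still sit immediately 5' of the member's D — and (ii)
  a footprint: a 3' tail (5 down to `min_footprint_evidence` = **2** nt;
  single-base matches are uninformative) of a mother V found in the
  member's N1. An incoming V that is not downstream of the mother's V on
  the locus is flagged (`upstream_incoming_flag`) but not vetoed, since
  such exceptions occur in real data and may be annotation errors.
* **D-to-DJ** covers members carrying a second, upstream D (tandem) and
  IGH-DJ-library members joining the root.
* **V-to-DJ** covers VJ members whose D part aligns with the reference D
  (as a suffix, possibly eroded) but that fail the stability check —
  i.e. fresh N1.
* Everything else, including replacement members whose footprint was
  fully trimmed away (a known, deliberate blind spot), is
  **undetermined**.

The stem summary is a majority vote among classified members, with
`mixed` declared when both classes each exceed `mixed_fraction`
(default **20%**) of classified members; the published account reports
mixed stems as rare but gives no quantitative rule.

## Markers, MRD, tracking

A stem is a **marker** when its family sum reaches 5% of usable reads or
1% of cell equivalents, or when it is evolving at any abundance. Usable
reads — junction-bearing reads after cIT-QC exclusion — are the
denominator for every percentage. Cell equivalents come from the
spike-in: `cells_per_read = qc_cells / qc_reads`, and the sample's total
cell-equivalent denominator is taken as `usable_reads × cells_per_read`;
the published definition does not state the denominator, and this choice
(the sample's own patient-cell equivalents) is recorded here explicitly.
A consequence worth knowing: with this denominator, % cells and % reads
coincide numerically, so the 1%-of-cells criterion behaves as a 1%-of-
reads criterion whenever spike-in data are present.

Follow-up member search applies **no abundance floor** — the 3-read/0.01%
filter is an evolution-calling device, not a detection threshold — and
stem MRD is the sum over detected members, hence always ≥ the top-member
MRD. Tracking flags the failure modes of single-clonotype MRD (top
member vanished while siblings persist, top member displaced from rank
1, new members emerging) and emits the corresponding recommendations:
report the family sum, follow the stem rather than a member for evolving
stems, and follow both libraries when the stem is rooted (detected in
IGH-VJ *and* IGH-DJ).

## Fisher's exact test

`fisher_exact_2x2()` computes the two-sided p by the minimum-likelihood
rule — sum the hypergeometric probabilities of all tables (margins
fixed) whose point probability does not exceed the observed table's —
because "two-sided Fisher" is ambiguous and this is the convention of
the common statistical defaults. Point probabilities are compared with a
relative tie tolerance of 1e-10: distinct hypergeometric weights at
relevant table sizes differ relatively by far more, and floating-point
noise by far less, so the tolerance can neither merge distinct weights
nor split equal ones. Zero-margin tables return p = 1 with a warning.
Associations are patient-level by default (matching how per-patient
evolution rates are compared between groups), and p-values are reported
raw — no multiple-testing correction by default.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with ground-truth labels for every stem and clonotype. Defaults define
the study conditions used throughout validation:

* cohort: 25 patients × 6 leukemic stems (2 evolving + 4 stable), i.e.
  50 evolving + 100 stable stems per seed; 50,000 usable reads per
  library; leukemic fraction 0.8 at diagnosis; 150 polyclonal background
  clonotypes per library; cIT-QC 2,500 reads / 40 cell equivalents.
* junctions: uniform 0–4 nt trimming per segment end, geometric
  N-region lengths (mean 4, max 12).
* evolving stems: mechanism mix 70% V-to-DJ, 22% VH replacement, 6%
  D-to-DJ, 2% mixed, reflecting the relative frequencies reported for
  the real cohort. Burst sizes are truncated-geometric with mean 8 on
  support [3, 400] — a "burst" of fewer than three members is not an
  observable family under any rule-based caller, so the evolving truth
  label starts at three. Replacement stems carry 1 + Poisson(2) chains
  of 1–4 rounds each (multi-round replacement with numerous members is
  the described phenotype); mothers are drawn among V genes with at
  least four downstream partners, because a most-distal V cannot be
  replaced. Tandem stems carry 2 + Poisson(2) incoming Ds. Footprint
  lengths are drawn from 0–5 (0 = remnant erased, the classifier's
  intended blind spot).
* biases: the rank-1 (most D-proximal) V is up-weighted 5× in bursts
  and the designated incoming D 9× in tandems, echoing the strong
  real-locus usage biases.
* abundances: stems receive symmetric-Dirichlet shares of the leukemic
  fraction; mothers are up-weighted (shape 15) against members (shape
  1), DJ roots shape 5 — reproducing the observed pattern that
  replacement families have dominant mothers while bursts spread over
  many lowly abundant members. Read counts are one multinomial draw at
  the configured depth.
* noise: abundant clonotypes emit Poisson(2) satellites with 1–2
  junction substitutions at 1–2 reads; background clonotypes are
  independent rearrangements, with any whose stem collides with a
  leukemic stem dropped so truth labels stay exact (at the toy-locus
  size such collisions would otherwise occur at a low but non-zero
  rate).
* scenarios: `bm_pb_pair` thins the BM sample binomially (default
  retention 0.1) into a PB replicate; `longitudinal` re-draws family
  compositions at reduced leukemic fractions (5% at day 6, 0.2% at day
  22), optionally kills the diagnostic top member, and lets burst stems
  emit one new member.

What the generator does **not** emulate: somatic hypermutation (BCP-ALL
precursors are pre-germinal-center), P-nucleotide insertion, primer or
sequencing-quality artifacts beyond substitution satellites, chimeras,
and the real locus's 50+ V genes (the bundled toy locus has 10 V / 6 D /
3 J synthetic segments whose D 5-mers are mutually and V/J-disjoint, so
D assignment is unambiguous at the default `min_d_match`). Passing tests
therefore demonstrate that the implementation is faithful to its rules
and recovers planted structure under realistic abundance and noise
regimes — not that the rules themselves are optimal for any particular
real dataset, nor that stem specificity holds on loci with shorter
usable J regions.

## Problem sizes and numerical choices

Validation runs the full pipeline on ten seeds of the default cohort
(1,500 stems, ~250 sample libraries) and verifies: evolving-label
sensitivity ≥ 0.90 and specificity ≥ 0.95 against truth; ≥ 90% correct
mechanism summaries among replacement stems whose planted footprints are
all ≥ 2 nt; 100% stem preservation across simulated burst, replacement
and tandem members; exact agreement of stem grouping with a brute-force
pairwise oracle on 5 × 1,000 decomposed junctions; exact agreement of
the Fisher implementation with integer-arithmetic enumeration on all
44,515 tables of total ≤ 30; and stem-MRD dominance plus kill-off
tracking on longitudinal presets. These sizes keep the whole suite in a
few minutes on one core while leaving every estimate's Monte-Carlo error
far from its acceptance margin; all of them recompute from scratch in
`scripts/acceptance.R`.

Degenerate inputs are values, not crashes, where the domain has a
convention (QC normalization unavailable, zero-margin Fisher tables),
and errors where silence would mislead (empty repertoires, zero-depth
follow-ups — a sample with no usable reads must never be reported as
MRD-negative). Ties are broken deterministically everywhere (read count,
then junction string, then clonotype id), so identical inputs give
byte-identical outputs; `emit_cohort()` output is reproducible per seed.

## Known limitations

* The consensus thresholds stand in for an unpublished rule set; they
  are honest, documented defaults — not a reconstruction — and live in
  one place (`evolution_policy()`).
* Stems link by exact string identity; somatic hypermutation or
  sequencing error inside the stem splits a family (real pipelines face
  the same trade-off).
* Mechanism classification reconstructs mother→member pairs, not full
  replacement-chain order; replacement without a surviving footprint is
  undetermined by design.
* % cell equivalents requires spike-in data in both the diagnostic and
  the follow-up sample; otherwise % reads is reported and flagged.
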