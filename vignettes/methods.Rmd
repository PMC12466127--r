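---
title: "Methods: non-coding SNVs in tumor-specific enhancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-coding SNVs in tumor-specific enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerSNV)
```

This vignette explains the models and procedures the package implements,
the choices made where the design was genuinely open, what the synthetic
data do and do not emulate, and the package's known limitations.

## Coordinate conventions

All region coordinates are BED-style 0-based half-open `[start, end)`;
variant positions are VCF-style 1-based. The two conventions meet in
exactly one function, `vcf_pos_in_interval()`, which tests
`start <= pos - 1 < end`. Every other operation works in one convention
only, which keeps off-by-one reasoning local to one line of code.
Abutting intervals merge: a regulatory region is treated as a closed
genomic segment, so `[0,10)` and `[10,20)` become `[0,20)`.

## Group-specific accessible regions

Peak calling itself is out of scope; inputs are per-sample peak sets.
The region universe is the merged union of all samples' peaks across
both cohorts. For each merged region and each cohort, *recurrence* is
the fraction of samples with at least 1 bp of peak overlap — a
deliberately simple presence/absence rule with no reciprocal-overlap
requirement, because merged regions are usually much wider than the
question "is this sample open here at all?" requires. A region is:

* **A-specific** if recurrence ≥ `f_min` (default 0.5) in cohort A and
  ≤ `f_max` (default 0.1) in cohort B (symmetrically for B-specific);
* **shared** if it is recurrent (≥ `f_min`) in at least one cohort and
  specific to neither;
* dropped if recurrent in neither cohort — it is not "active" anywhere.

The recurrence-threshold consensus stands in for a count-based
differential-accessibility test: it reproduces the qualitative
three-way partition (A-specific / B-specific / shared), is monotone in
its thresholds, and has exact planted-truth semantics the test suite can
verify. Note one deliberate reading: a region recurrent in A whose
recurrence in B lies strictly between `f_max` and `f_min` is classed
*shared* rather than left unclassified, so that the three statuses
partition all recurrent regions. With the default thresholds separated
by 0.4 of recurrence mass this intermediate band is rarely populated,
and the synthetic generator never populates it.

## Element classification and enrichment

Each specific region receives exactly one class by priority
promoter > insulator > enhancer (first annotation track with ≥ 1 bp
overlap wins; no overlap means "other"). Promoters are the most
confidently mapped element class, hence their precedence; the order is a
configuration knob (`class_priority`).

Per-class enrichment between groups uses the Pearson chi-square on the
2×2 table `[[count_A, total_A − count_A], [count_B, total_B − count_B]]`
via the closed form χ² = N(ad−bc)²/((a+b)(c+d)(a+c)(b+d)), one degree of
freedom, two-sided, **without** Yates continuity correction: with group
totals in the tens of thousands the correction is immaterial, and the
closed form is bit-reproducible against an independent contingency
implementation (the tests require agreement to 1e-9 relative). No
multiple-testing correction is applied across the three classes; the
report instead carries two conventional significance tiers
(`alpha_strict = 0.001`, `alpha_ns = 0.05`). A zero marginal (class
absent from both groups) raises an error rather than silently returning
a zero statistic.

## SNV–enhancer overlap and candidate ranking

Somatic SNVs are first filtered against a known-SNP catalog by exact
`(chrom, pos, ref, alt)` match — allele-aware, so a different alternate
allele at a catalogued position remains somatic. Filtered SNVs are
intersected with the enhancer-class subset of one group's specific
regions; SNVs hitting no element go to a spill-over list rather than
being dropped, and the test suite checks conservation of counts.

Hotspots are single-linkage clusters of SNV positions per chromosome
with gap ≤ 7 bp (`hotspot_gap`): on a line this is "split sorted
positions where consecutive gaps exceed 7". The 7 bp scale matches the
window within which independently discovered mutations were observed to
co-locate in targeted resequencing.

Candidates are ranked lexicographically by (distinct patients ↓, SNV
count ↓, curated genes within the neighborhood ↓, has a high-confidence
enhancer–gene interaction ↓, element ID ↑). Patient recurrence
deliberately outranks raw SNV count, and interactions act only as a
tiebreak, never a filter. The gene neighborhood is ±1 Mb
(`neighborhood_bp`) measured from the element midpoint to the gene's
nearest edge; the midpoint anchor is a declared choice where either
element edge would have been equally defensible.

## TF binding-affinity shifts

A position frequency matrix is converted to log-odds weights
`w[b, j] = log2(((counts[b, j] + pc) / (colsum_j + 4 pc)) / bg[b])` with
pseudocount `pc = 0.25` per cell and a uniform background — the standard
construction when no organism-specific background is trusted. Both are
configurable. A motif whose achievable score range is empty
(S_min = S_max) is rejected as uninformative.

The *relative score* of a window is
(S_best − S_min)/(S_max − S_min) ∈ [0, 1], where S_best is the best raw
alignment score over **both strands** and over exactly those offsets at
which the motif covers the variant base (on the minus strand, coverage
is assessed after reverse-complementing the window). Constraining the
scan to variant-covering alignments means a wild-type/mutant score
difference can only arise where the variant is actually scored, and it
implements "affinity change within ±7 bp of the mutation" for the
default 15 bp window (`flank = 7`). `N` bases contribute weight 0, their
expectation under the background, rather than failing — degraded
archival material does produce them.

Shift categories: **novel** when wt < 0.80 ≤ mut relative score
(`site_threshold = 0.80`, the conventional motif-match cutoff),
**lost_site** for the reverse crossing, **gain**/**loss** when
|Δrel| ≥ `delta_min = 0.05` without a threshold crossing, else
**neutral**. The top-K shortlist (default 5) orders by |Δrel|, ties by
max(wt, mut) then TF name, so the ranking is a total order.

## Validation-cohort statistics

The genotype table has one row per tissue specimen (patient, section,
tumor/peritumoral compartment) and one column per target region, cells
in {WT, MUT(chrom:posREF>ALT), NS}. Throughout, NS (non-sequenced) cells
are excluded from denominators — counting them as wild-type would bias
every frequency downward. Specifically:

* **callability** = non-NS fraction over tumor specimens, flagged above
  0.85 (strict);
* **frequency** = MUT/(MUT+WT) over tumor specimens; a region with no
  callable cell reports missing, not zero;
* **burden** and **co-occurrence** aggregate at patient level (any
  section counts), among patients with at least one callable region;
* **multifocal concordance** = among patients with ≥ 2 callable sections
  in a region, the fraction whose sections all carry an identical call
  (same mutant allele, or all WT) — the strictest defensible reading of
  section agreement — flagged above 0.75 (strict, so exactly 0.75 is
  *not* "over 75%");
* **peritumoral exclusivity** checks, for every patient with a tumor
  mutation and a peritumoral specimen, that no peritumoral cell is
  mutated, naming offenders when it fails.

## What the synthetic data emulate — and what they do not

The generators produce every pipeline input with a planted ground truth
serialized alongside (`ground_truth.json`). Where a target fraction must
be achieved exactly (frequencies, callability, concordance, dropout),
counts are planted by round-half-up integer arithmetic and the realized
counts recorded, so recovery tests assert exact equality instead of
stochastic closeness. All generators are pure functions of
(parameters, seed); repeated calls are byte-identical.

The `paper_like` preset of `simulate_study()` fixes the study
conditions: a 2 × 1.2 Mb genome at GC 0.41 (long enough to place a
curated gene beyond the ±1 Mb neighborhood on the same chromosome),
cohorts of 9 and 12 samples, 400/480/300 planted A-/B-specific/shared
regions — the two groups' published region totals scaled by ~1/47, with
per-group element-class mixes equal to the published class proportions
(so the A group plants ~39 specific enhancers), 39 whole-genome
patients whose planted SNVs mimic the discovery pattern (two candidates
with two mutated sites each, one candidate with a 3-patient recurrent
SNV plus a 5 bp hotspot neighbor), two germline decoys recorded in the
known-SNP set, five spill-over SNVs, and a 54-patient genotype table
with 11 two-section multifocal patients, 9 peritumoral specimens, 25
mutated and 7 co-occurring patients. The per-region genotype plan pairs
the highest mutation frequency (30%) with the lowest callability (50%)
in the same region, one region with no alterations (trivially fully
concordant), and concordances {0.60, 0.90, 1.00, 0.82, 0.78} — jointly
reproducing the reported patterns: 4/5 regions > 85% callable, 4/5
regions > 75% concordant, burden 25/54 ≈ 46.3%.

Planted gain/loss motifs are constructed so the favored allele's window
scores exactly 1.0 (its consensus is that window's subsequence across
the variant) while the variant column strongly penalizes the other
allele. Because a short consensus can by chance recur in the sequence
context and lift the disfavored allele over the site threshold, the
construction searches motif length and variant-column placement until
the disfavored allele scores below 0.7 at every variant-covering
alignment — the planted novel/lost-site contrast is thereby guaranteed
by construction, for any seed, not by luck.

What the synthetic data do **not** model: read-level signal (no FASTQ or
BAM), peak-boundary jitter between samples (peaks of one planted region
are coordinate-identical across samples, so "exact recovery" includes
coordinates; real consensus peaks would need overlap-based matching),
correlated dropout, mutational signatures or sequence-context bias of
SNVs, FFPE artifacts, and dinucleotide background structure in motifs.
Passing the planted-truth tests therefore demonstrates correctness of
the pipeline's logic under its stated model, not robustness to every
noise process of real tumor data.

## Numerical choices and degenerate inputs

* Chi-square via the closed form with `pchisq(..., lower.tail = FALSE)`;
  zero marginals error out.
* Relative scores are exactly strand-symmetric: the minus-strand scan
  re-scores the reverse-complemented window, so
  rel(w) = rel(revcomp(w)) with no floating-point asymmetry.
* Allele-swap antisymmetry of Δrel is exact (the same two doubles are
  subtracted in opposite orders).
* Planted-count arithmetic uses round-half-up (`floor(x + 0.5)`), not
  banker's rounding, so realized counts match the recorded plan.
* Ties in candidate ranking and top-K TF ranking break on identifiers,
  making every ordering deterministic.
* Empty inputs are first-class: zero SNVs, zero profiles, an empty
  known-SNP set and a zero-mutation genotype plan all produce empty
  results, not errors; genuinely contradictory configurations
  (`f_max >= f_min`, infeasible genotype plans, windows off a
  chromosome end) error out before any compute.

## Problem sizes

The test suite and the acceptance script run the `paper_like` preset
(~1,200 regions, 21 peak samples, 39 + 54 patients, 10 motifs), an
exhaustive PWM cross-check over ≥ 1,000 random 15-mers for motif lengths
4–6, and a 1,000-permutation calibration of the enrichment test — a few
minutes on one core in total. These sizes were chosen so every planted
structure (40-ish group-A enhancers, three candidates, five validation
regions) exists at realistic proportions while each individual check
stays brute-force verifiable.

## Known limitations

* The specificity rule is a consensus heuristic, not a count-based
  differential test; regions with intermediate recurrence in both
  groups land in "shared".
* The further contrast that would narrow specific enhancers down to a
  "dynamic" subset is not modeled; the pipeline exposes only the
  per-class 2×2 enrichment.
* Motif hits are not calibrated to p-values, and no claim is made about
  which real TFs match — that depends on the motif database a user
  supplies.
* The package is assembly-agnostic and never validates genome-assembly
  identity between its inputs.
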