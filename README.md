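# enhancerSNV

Non-coding somatic single-nucleotide variants (SNVs) rarely get the
attention coding mutations do, yet when they land in a tumor-type-specific
enhancer element (EE) they can rewire transcription-factor (TF) binding and
with it the tumor's regulatory program. `enhancerSNV` is an R package for
exactly this analysis path, aimed at regulatory-genomics researchers working
with tumor cohorts:

1. **Group-specific chromatin accessibility** — from two cohorts of
   per-sample peak sets (e.g., ATAC-seq peaks from two tumor types), call
   regions recurrently accessible in one group and not the other
   (recurrence ≥ *f*<sub>min</sub> = 0.5 in the group, ≤ *f*<sub>max</sub> =
   0.1 in the other), plus shared regions.
2. **Regulatory-element classification and enrichment** — classify each
   specific region against promoter / insulator (IE) / enhancer (EE)
   annotation tracks (priority promoter > IE > EE) and test per-class
   enrichment between groups with a Pearson chi-square on the 2×2 table,
   χ² = N(ad−bc)² / ((a+b)(c+d)(a+c)(b+d)), 1 df, no continuity correction.
3. **SNV–enhancer overlap** — intersect per-patient somatic SNVs (VCF)
   with the group-specific EEs, cluster mutation positions into hotspots
   (single linkage, ≤ 7 bp), and rank candidate EEs by patient recurrence,
   SNV count, curated disease genes within ±1 Mb and enhancer–gene
   interaction evidence.
4. **TF binding-affinity shifts** — score the 15 bp wild-type and mutant
   windows (variant at the center) against a PWM library. Per motif the
   *relative score* is the min–max normalized best log-odds alignment
   score, rel = (S − S<sub>min</sub>)/(S<sub>max</sub> − S<sub>min</sub>) ∈
   [0, 1], maximized over both strands across all alignments covering the
   variant. Shifts are categorized as gain / loss (|Δrel| ≥ 0.05) or novel
   / lost site (crossing the 0.80 site threshold), and ranked top-5 by
   |Δrel|.
5. **Validation-cohort summaries** — from a targeted-sequencing genotype
   table (specimens × regions, calls WT / MUT / NS): per-region
   callability and mutation frequency (NS excluded from denominators),
   patient-level burden and co-occurrence, allele-aware known-SNP
   filtering, multifocal section concordance, and peritumoral exclusivity.

A first-class synthetic-data module generates every input — genome, peak
cohorts, annotation tracks, genes and interactions, per-patient VCFs,
JASPAR-style motif libraries with planted gain/loss effects, genotype
tables — with a machine-readable planted ground truth, so the entire
pipeline is testable end to end without any external download.

## Worked example

```r
library(enhancerSNV)

sim <- simulate_study(seed = 1)          # paper-like synthetic study
rep <- run_all(sim, pipeline_config())   # the full pipeline

rep$specificity
#> $n_A_specific
#> [1] 400
#> $n_B_specific
#> [1] 480
#> $n_shared
#> [1] 300

rep$enrichment[, c("class", "prop_A", "prop_B", "chi2", "p_value")]
#>       class prop_A     prop_B         chi2      p_value
#> 1  promoter 0.3775 0.37916667  0.002576617 0.9595164572
#> 2 insulator 0.1250 0.10208333  1.147626500 0.2840465580
#> 3  enhancer 0.0975 0.03541667 14.112979658 0.0001721518

head(rep$candidates[, c("element_id", "n_patients", "n_snvs", "rank")])
#>           element_id n_patients n_snvs rank
#> 1 chr1:305741-306223          4      4    1
#> 2 chr1:174194-174605          2      2    2
#> 3 chr1:157349-157764          2      2    3
```

The group-A-specific regions are enriched for enhancers relative to group
B (χ² = 14.1, p = 1.7e-4) while promoters are similarly distributed
(p = 0.96); the top-ranked candidate enhancer is the one carrying the
planted recurrent SNV (4 patients). Scanning that candidate's SNVs against
the motif library surfaces the planted effects, e.g.:

```r
rep$tf_scans[["chr1:157526A>C"]]$top[1, c("tf", "wt_rel", "mut_rel", "category")]
#>               tf    wt_rel mut_rel category
#> 1 PLANTED_GAIN_1 0.6912533       1    novel
```

and the validation-cohort stage reports per-region callability (4 of 5
regions above 85%), the highest mutation frequency (30.3%), sample burden
(46.3%), 7 co-occurring patients, 4 of 5 regions above 75% multifocal
concordance, and no peritumoral mutations.

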