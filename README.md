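# hervtriage

Targeted case-control triage of variants in human endogenous retrovirus
(HERV) and *Alu* intervals near cancer predisposition genes (CPGs).

Roughly 8% of the human genome is retroviral. HERV loci — mostly solo long
terminal repeats (LTRs) — are dense in regulatory elements but are routinely
discarded from genome-wide association scans because of their repetitive
sequence and uneven coverage. This package implements the analysis layer of
a *targeted* alternative: restrict attention to retroviral intervals within
a fixed radius (default 20 kb) of differentially expressed CPGs, compare
case genotypes against a reference control cohort with ancestry and sex as
covariates, and push every candidate variant through an explicit exclusion
cascade before calling it interesting. It is aimed at statistical-genetics
analysts who have per-cohort VCFs and annotation tables and want a
deterministic, fully testable desk-scale pipeline.

## What it computes

* **Region selection** — differential-expression filter on the gene table
  (`|log2FC| > 1`, adjusted p < 0.05, both strict), gap-distance selection
  of elements within the radius, merge into non-overlapping regions
  (0-based half-open; bookended intervals are not merged), and positional
  classification (exonic > intronic > strand-aware upstream/downstream).
* **Cohort handling** — VCF reading (vcfR), multiallelic splitting into
  per-alternate biallelic records, case/control merge with
  `missing_to_ref` semantics (a variant absent from one cohort's file is
  coded homozygous reference there; explicit `./.` stays missing), unfolded
  alternate-allele frequencies, and a multi-trial stratified 3:2
  training/validation split (round-half-up, so 138 cases give 83/55).
* **Ancestry** — supervised admixture estimation from ancestry-informative
  markers (AIMs) against fixed reference-population frequencies
  `p_km`: each genotype is modelled as `g_m ~ Binomial(2, Σ_k q_k p_km)` and
  the admixture vector `q` is maximized by EM on the simplex; categorical
  labels follow threshold rules (EUR > 0.90; AFR, EAS ≥ 0.70; HIS when the
  Native American component is ≥ 0.10 and dominant over AFR/EAS; else AMR).
* **Association** — per-variant additive logistic regression by IRLS with
  Wald tests, unadjusted and adjusted (sex + continuous ancestry
  components), odds ratios `OR = exp(β)`, a Bonferroni-style threshold
  `α / n_variants`, and the confounding statistic
  `|OR_adj − OR_unadj| / OR_unadj` (flagged at a strict > 10% change).
* **Triage** — confirmation requires same-sample-type significance in both
  the training and validation set; exclusion codes are †
  (training/validation case-frequency inconsistency), ‡ (crossed
  blood/tumor × train/validation significance), and ◊ (internal-control vs
  external-database frequency discrepancy, with multiallelic-split variants
  exempt but flagged inconclusive); a rare-variant screen (case MAF ≥ 10%,
  controls ≤ 1%, ≥ 10× external enrichment), a somatic-candidate flag
  (tumor − blood MAF shift), and genotype-r² linkage clustering.
* **Retroelements** — localization of variants in *Alu* substructure (left
  monomer, A-rich linker, right monomer, 3′ poly(A) tail) and the
  poly(A)-tail run length before/after applying a substitution: a
  single-base spacer change can merge adjacent A runs, e.g. A²⁹·G·A⁷ with
  G>A goes from a 29 bp to a 37 bp tail.

A synthetic-data module generates every input the pipeline consumes (VCF,
BED, TSV, FASTA) with known ground truth — planted common hits, confounded
variants, case-only rare variants, somatic candidates, a linked pair, a
multiallelic site, and out-of-region decoys — so the whole chain is tested
end to end.

## Worked example

```r
library(hervtriage)

cfg <- sim_config(seed = 1)                 # desk-scale synthetic study
sim <- simulate_inputs(cfg, "study_inputs") # writes VCFs, BED, TSV, FASTA
res <- run_pipeline(pipeline_config("study_inputs", "study_out", seed = 1))

str(res$counts[c("n_de_genes", "n_elements_selected", "n_regions",
                 "n_variants_tested", "n_confirmed")])
#> List of 5
#>  $ n_de_genes         : int 6
#>  $ n_elements_selected: int 12
#>  $ n_regions          : int 12
#>  $ n_variants_tested  : int 120
#>  $ n_confirmed        : int 3
```

Six of the twelve simulated genes pass the differential-expression filter;
their intronic and flanking HERV intervals give 12 merged target regions
holding 120 testable variants (decoy variants beyond the radius are
dropped). The three planted common hits are confirmed in both the training
and validation sets; `study_out/triage.tsv` lists each variant with its MAF
columns, exclusion codes, rare class, somatic flag and linkage cluster, and
`study_out/manifest.tsv` records an md5 for every output, byte-identical
across reruns with the same seed.

The poly(A) machinery on its own:

```r
s <- paste0("CC", strrep("A", 29), "G", strrep("A", 7), "CC")
polyA_extension(s, anchor = 3, pos = 32, ref = "G", alt = "A")
#> $before      $after      $extension
#> [1] 29       [1] 37      [1] 8
```

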