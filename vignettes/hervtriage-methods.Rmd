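---
title: "Methods: targeted variant triage in retroviral regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted variant triage in retroviral regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervtriage)
```

# The problem and the model

Human endogenous retroviruses (HERVs) and *Alu* elements occupy a large
fraction of the genome but are usually invisible to genome-wide association
scans: repetitive sequence depresses mapping quality, and frequency filters
remove exactly the loci where coverage is thin. `hervtriage` implements a
targeted alternative for a case-control design. The unit of analysis is a
biallelic variant (multiallelic sites are split per alternate allele) inside
a retroviral interval that lies within a fixed radius of a cancer
predisposition gene that is differentially expressed in the tumor type of
interest. The enrichment argument is biological: retroviral LTRs are dense
in transcription-factor binding sites, so variation near dysregulated genes
is where regulatory consequences are most plausible.

Association uses additive logistic regression per variant. With dosage
$g \in \{0,1,2\}$ and case indicator $y$,

$$\operatorname{logit} P(y=1) = \beta_0 + \beta_g g
  \quad\text{(unadjusted)},\qquad
  \operatorname{logit} P(y=1) = \beta_0 + \beta_g g + \beta_s s +
  \boldsymbol\beta_a^\top \mathbf{q}_{-\mathrm{EUR}}
  \quad\text{(adjusted)},$$

where $s$ is sex and $\mathbf{q}_{-\mathrm{EUR}}$ are the continuous
admixture components with the European component dropped as baseline
(retaining all $K$ components would be collinear with the intercept).
Fitting is iteratively reweighted least squares with Wald p-values
$2\Phi(-|\hat\beta/\widehat{se}|)$, matching the convention of the standard
GWAS toolchain. Effect sizes are reported as $OR = e^{\hat\beta}$, and
covariate-driven distortion is summarized by the confounding fraction
$|OR_{adj} - OR_{unadj}|/OR_{unadj}$, flagged when strictly above 10%.

Ancestry is estimated supervised: given a reference panel of per-population
alternate-allele frequencies $p_{km}$ at $M$ ancestry-informative markers
(AIMs), an individual's genotypes follow
$g_m \sim \mathrm{Binomial}(2, f_m)$ with $f_m = \sum_k q_k p_{km}$, and the
admixture vector $\mathbf q$ on the simplex is maximized by EM:

$$q_k \leftarrow \frac{1}{2M'} \sum_{m}
  \left[ g_m \frac{q_k p_{km}}{f_m} +
  (2-g_m) \frac{q_k (1-p_{km})}{1-f_m} \right],$$

over the $M'$ non-missing markers, initialized uniform. The log-likelihood
is non-decreasing (asserted in tests) and the update preserves the simplex
exactly. This is the same model family as the classical Bayesian clustering
approach used for supervised ancestry assignment, but deterministic and
fast; burn-in and replicate settings have no analogue here. When the panel
is uninformative (identical frequencies in all populations) the likelihood
is flat and the uniform vector is returned with a warning rather than an
arbitrary vertex. Categorical labels apply threshold rules in order:
EUR if $q_{EUR} > 0.90$; AFR if $q_{AFR} \ge 0.70$; EAS if
$q_{EAS} \ge 0.70$; HIS if the Native American component is $\ge 0.10$ and
exceeds both the African and East Asian components; otherwise AMR.

# The triage cascade

A variant is **confirmed** when its adjusted-model p-value is below the
multiplicity threshold ($\alpha$ divided by the number of variants tested,
configurable because the effective number of tests is a design choice) in
*both* the training and validation sets for the *same* sample type. The
`adjusted_only` flag marks variants significant only after covariate
adjustment. Confirmed candidates then face three exclusion screens whose
codes are unioned, never ordered:

* **†** training/validation case-frequency inconsistency: absolute
  difference > 0.10, or fold-ratio outside $[1/2, 2]$ when both
  frequencies are positive;
* **‡** a crossed significance pattern (one sample type significant in
  training, the other in validation, with no same-type confirmation) —
  this screen also excludes unconfirmed variants, since the pattern is by
  construction incompatible with confirmation;
* **◊** internal-control vs external-reference frequency discrepancy:
  absolute difference > 0.10 *and* fold-change > 2, an external frequency
  of exactly zero counting as infinite fold-change. Variants that arose
  from a multiallelic split are exempt — their database frequencies are
  not comparable allele-for-allele — and are flagged inconclusive instead.

The † and ◊ thresholds are stated qualitatively in the screening
literature ("inconsistent", "large variations"); the defaults here were
chosen so that, applied to a bundled 27-variant reference table of case,
internal-control and external frequencies, the ◊ screen flags exactly the
eight variants marked discrepant in that table and none of the unmarked
rows. That regression fixture is part of the test suite, and both
thresholds are configuration knobs.

Variants absent from the control cohort cannot be fitted by logistic
regression at all: with every control homozygous reference the likelihood
is monotone (quasi-complete separation). The fitter detects separation and
flags the result with missing p-values rather than reporting a finite
artifact of the iteration cap — such variants flow to the **rare screen**
instead: extraction at case MAF ≥ 10% (a size at which the
normal-approximation power to see a 10-percentage-point difference is
about 0.82 at $n = 74$), rarity when all control frequencies are ≤ 1%, and
enrichment when the case frequency is at least 10× the external reference
frequency (absent or zero external counts as enriched). Note that under
these conjunct thresholds a rare variant is almost always also enriched;
the distinct `rare` level is reachable only at boundary configurations.
Somatic candidates are flagged by a blood→tumor MAF shift of at least
`somatic_delta` (default 0.02, the smallest shift among reported
candidates in screens of this kind). Rare and somatic candidates are
clustered by genotype $r^2$ (squared Pearson correlation of dosage vectors
over pairwise-complete samples) at a default threshold of 0.8, single
linkage.

# Interval conventions

All internal coordinates are 0-based half-open (BED native); VCF positions
are converted at I/O boundaries. The gap between $[a,b)$ and $[c,d)$ is
$\max(0, c-b, a-d)$, so overlapping *and* bookended pairs have gap 0, and
an element is selected when its gap to a gene body is at most the radius
(20 kb default, measured from the gene body — whether flank distance should
instead be measured from transcript ends is ambiguous in the screening
literature, and gene body is assumed here). Region merging joins intervals
only when they share at least one base: bookended intervals stay separate,
merging is idempotent, and the merged regions cover exactly the union of
input base positions (tested against a brute-force position-set oracle).
Positional classification has precedence exonic > intronic > flank, with
flanks strand-aware (the 5′ side of a minus-strand gene lies at higher
coordinates).

# Poly(A)-tail arithmetic

*Alu* elements are ~300 bp dimers: left monomer, A-rich linker, right
monomer, 3′ poly(A) tail. Tail length gates retrotransposition competence,
and genomic tails average 21–26 bp. The package measures the maximal
*strict* homopolymer run of the tail base (A on the element's sense strand,
T for a minus-strand element read on the reference strand) containing the
annotated tail anchor, before and after applying a single-nucleotide
substitution. A substitution that removes a one-base spacer between two A
runs merges them: extension $= \mathrm{left} + \mathrm{right} + 1 -
\mathrm{before}$. A²⁹·G·A⁷ with G>A goes 29→37; A²⁵·C·A¹⁰ with C>A goes
25→36. Runs are pure homopolymers — no mismatch tolerance — because that is
the only convention under which those worked examples are arithmetically
consistent. Indels are rejected explicitly rather than mis-measured. The
anchor requirement means distant A runs created elsewhere in the sequence
never count as the tail.

# The synthetic study and what it does (not) emulate

`sim_config()` fixes the study conditions; `simulate_inputs()` writes every
input file. Defaults: 4 reference populations, 85 AIMs, 200 cases / 800
controls, 120 in-region variants plus 10 out-of-radius decoys, 2%
missingness, 12 genes of which 6 pass the differential-expression filter.
Sizes were chosen so the full pipeline (including ~480 logistic fits and
1000 EM runs) completes in about a minute on one CPU while keeping planted
effects reliably recoverable.

Choices worth explaining:

* **AIM divergence.** Panel frequencies follow a Balding–Nichols
  construction: ancestral frequency $a_m \sim U(0.1, 0.9)$ perturbed per
  population with $p \sim \mathrm{Beta}(a(1-F)/F, (1-a)(1-F)/F)$, clamped
  to $[0.01, 0.99]$, with `divergence` playing $F$. The default is
  $F = 0.55$: AIMs are *selected* markers with continental frequency
  differentials of roughly 0.3–0.6, far above random-SNP differentiation.
  This matters quantitatively. The Fisher information for $\mathbf q$
  scales with the squared cross-population frequency differential; at
  random-SNP divergence ($F \approx 0.15$) the Cramér–Rao bound for a
  4-way admixed individual from 85 markers is near 0.1 per component, so
  *no* estimator recovers $\mathbf q$ to 0.05 mean error there — the EM is
  verified against a BFGS likelihood oracle and a simplex grid search, and
  the residual error at low divergence is an information limit, not an
  estimator defect. At the AIM-like default, mean recovery error over the
  cohort admixture mixture is ≈ 0.03–0.04, which the acceptance suite
  bounds at 0.05.
* **Admixture distribution.** Individuals are a mixture of mostly-one-
  population draws (concentrated Dirichlet) and broadly admixed ones,
  emulating an American study cohort; a `fixed_admixture` override
  supports degenerate single-population simulations.
* **Phenotype model.** $\operatorname{logit} P = \beta_0 + \sum_v \beta_v
  g_v + \beta_{anc} q_{AFR} + \beta_s s$, sampled until the case and
  control quotas fill. Planted common hits default to $\beta_v = 1.2$ per
  allele at ancestral frequency 0.3 — effect sizes in targeted screens of
  this kind are not published to that precision, so the default is chosen
  for reliable recoverability at the default sample sizes, not for
  fidelity to any particular study. Confounded variants carry *no* direct
  effect but are strongly population-stratified (frequency ≈ 0.7 in the
  African-ancestry population vs ≈ 0.08 elsewhere) while ancestry loads on
  the phenotype, so their unadjusted OR is inflated and the confounding
  fraction exceeds 10%.
* **Rare and somatic planting.** Case-only rare variants (per-allele
  frequency 0.15 in cases, absent from the control file) exercise both the
  missing-to-ref merge and the separation path. Tumor genotypes are the
  germline copy except at somatic candidates, where each remaining
  reference allele converts to the alternate with probability
  `somatic_shift` (default 0.12, expected MAF gain ≈ 0.10). The
  conditional-gain construction — rather than independently resampling
  tumor genotypes at a shifted frequency — keeps the blood→tumor MAF delta
  tight around its expectation (germline sampling noise cancels), which is
  both the more faithful picture of a somatic mutation on a germline
  background and the reason planted candidates are reliably recoverable at
  $n = 200$.
* **What is not emulated.** No read-level error model, no genotype-calling
  artifacts, no linkage structure beyond the planted duplicated pair, no
  relatedness, and no local-ancestry variation along the genome. Passing
  the end-to-end tests therefore demonstrates that the statistical
  machinery recovers planted signal under the stated generative model — it
  says nothing about robustness to calling artifacts or cryptic
  relatedness in real cohorts.

# Numerical choices and degenerate inputs

* IRLS converges on score norm < 1e-8 or parameter change < 1e-10, capped
  at 100 iterations; weights are floored at 1e-12. Separation is declared
  on a diverging coefficient path (>30 during iteration) or a final
  coefficient magnitude > 15, and flagged results carry missing p-values.
  Firth-style penalization is deliberately not the default, to reproduce
  the behavior of the reference GWAS toolchain.
* The strict >10% confounding rule uses a 1e-12 epsilon so that an
  exactly-10% change represented inexactly in binary floating point does
  not flag.
* EM stops on max $|\Delta q| <$ 1e-6 within 2000 iterations; hitting the
  cap returns the current estimate with a warning (per-sample warnings are
  aggregated into one summary by the cohort-level wrapper). Ties at a flat
  likelihood resolve to the uniform vector.
* `stratified_split` allocates round-half-up $0.6\,n_s$ per stratum and
  compares `n_trials` seeded shuffles by the maximum per-stratum deviation
  from 0.6, returning the earliest minimizer — deterministic given the
  seed. With per-stratum counts fixed the score ties across trials; the
  multi-trial machinery matters when strata definitions make exact
  allocation impossible and is kept as a configuration knob.
* Monomorphic variants, all-missing genotype vectors, empty strata,
  symbolic alleles and half-calls (`0/.`) all have explicit, tested
  behaviors (flagged result, error, skip-with-warning, skip-with-warning,
  missing, respectively).
* The orchestration layer is `pipeline_config()` + `run_pipeline()`; an R
  API is the natural interface for this analysis audience, so no shell
  subcommand wrapper is shipped. Outputs are plain TSV/BED with md5s in a
  manifest; with a fixed seed, reruns are byte-identical (the VCF writer
  emits no timestamps and never compresses, which is also why a minimal
  writer is used instead of a gzip-only library writer).

# Known limitations

Supervised ancestry assigns one genome-wide $\mathbf q$ per individual;
locus-level ancestry is out of scope, so adjustment can be imperfect in
regions whose local ancestry deviates from the genome-wide average. The
exclusion-screen thresholds are reverse-engineered from a single published
candidate table and should be re-examined for other cohorts. The rare
screen's conjunct control bounds make `rare`-but-not-enriched nearly
unreachable, as noted above. Linkage clustering is $O(p^2)$ in the number
of rare/somatic candidates, which is fine at screen scale but not for
genome-wide variant sets.
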