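---
title: "Methods: cross-cancer PRS pleiotropy scans with prspleio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cancer PRS pleiotropy scans with prspleio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prspleio)
```

## The analysis

`prspleio` implements a cross-phenotype pleiotropy scan built around
cancer-specific polygenic risk scores (PRS). The pipeline takes a literature
catalog of published variant–cancer associations, harmonizes it against the
genotype panels of one or more cohorts, prunes each cancer's variants to an
independent set, scores every individual, and then asks whether the PRS for
one cancer predicts *other* cancers (and non-cancer risk factors), pooling
cohorts by fixed-effects meta-analysis.

For individual $i$ and cancer $c$, the score is the weighted allele-dosage
sum

$$S_{ic} = \sum_{j \in V_c} d_{ij}\,\beta_j,$$

where $d_{ij} \in [0,2]$ is the expected count of the effect allele
(possibly fractional from imputation) and $\beta_j$ is the published
per-allele log odds ratio. Each score is standardized within cohort,
$z = (S - \mu)/\sigma$ (sample $\sigma$, $n-1$ denominator), and entered in
multivariable logistic regressions

$$\operatorname{logit} P(Y_{io} = 1) = \alpha + \theta\, z_{ic} + \gamma' C_i$$

for every outcome cancer $o$, with covariates $C$: age at specimen
collection, sex (omitted for sex-specific cancers), the first 10 ancestry
principal components, and genotyping batch/array as categorical indicators.
Inference is Wald throughout: $p = 2\Phi(-|\hat\theta/\widehat{se}|)$ for
logistic models and the two-sided $t$ analogue for linear (secondary-trait)
models. Per-cohort estimates are pooled with inverse-variance fixed-effects
weights $w_k = 1/se_k^2$; heterogeneity is reported as Cochran's $Q$ (with a
$\chi^2_{k-1}$ test) and $I^2 = \max(0, (Q - (k-1))/Q)$, left undefined
(`NA`) rather than zero for single-study input.

## Catalog curation and harmonization

The raw catalog is reduced to one association per (variant,
phenotype/sub-phenotype, ancestry group): records with a known effect allele
and effect estimate beat records without one, then the smallest p-value
wins. Ties break by higher imputation score, then lexicographic study id —
a convention we fixed for determinism, since the source procedure is silent
on ties. Eligibility filters then retain autosomal variants from
populations of at least 70% European ancestry at genome-wide significance
($p \le 5\times10^{-8}$).

Each curated record is matched to a cohort panel by identifier, then
position, then the best LD proxy with $r^2 \ge 0.8$ (highest $r^2$, ties to
the nearest base pair) within a configurable ±500 kb window. Allele coding
is reconciled against the counted (alt) allele: if the effect allele is the
panel's other allele the contribution is computed on $2-d$; if the alleles
match only after strand complement the record is flagged strand-flipped and
re-resolved. The two representations — complemented dosage, or negated
weight — produce identical standardized scores, an invariance the test
suite asserts to 1e-10. Strand-ambiguous A/T and C/G variants are dropped
when MAF $\ge 0.45$ because strand, and hence the effect allele, cannot be
determined near 0.5; below that the allele identity itself resolves the
match. Frequency filters drop non-biallelic sites, MAF $< 0.01$, variants
absent from the reference-frequency table, and cohort-vs-reference MAF
differences $> 0.10$. Cohort MAF is $\min(f, 1-f)$ of mean dosage / 2 over
QC-passed samples. Without a reference table the concordance filter
downgrades to a warning so the pipeline stays runnable on self-contained
fixtures.

Per-cancer independence is enforced by greedy priority pruning at
$r^2 < 0.3$: candidates are processed broadest phenotype first, then
ascending p, descending imputation score, lexicographic id, and accepted if
their LD against every previously accepted variant is below threshold.
Variant sets for different cancers are pruned independently of each other.
Cross-chromosome pairs are assumed independent without lookup; pairs with
no LD information are treated as independent and noted in the pruning
report. The exact tie-break order inside the priority queue is our
documented convention — the upstream tooling does not specify one.

## Cohort preparation

Sample QC removes call rate < 0.97 and heterozygosity or PC1/PC2 values
more than 5 within-cohort standard deviations from the mean. Cases are
defined by the earliest-dated primary diagnosis only; two primaries on the
same date make the individual a case for both outcomes. Controls have no
registry diagnosis, no self-reported cancer and no cancer-coded cause of
death; sex-specific cancers restrict both sets to the relevant sex, and
analyses are restricted to cancers with at least 650 cases summed across
cohorts (configurable). Incident/prevalent sensitivity splits compare the
diagnosis date to the specimen-collection date; a diagnosis exactly on the
collection date counts as prevalent — the source is silent on this tie, a
fixed convention was required, and the same-date case is closer in kind to
disease present at collection. Secondary phenotypes are prepared by
censoring values outside the assay's reportable range (on the raw scale,
before any transform), natural-log transforming right-skewed biomarkers
(CRP, HbA1c, IGF-1), and deriving waist-to-hip ratio.

## Multiplicity

Three Bonferroni families mirror the analysis structure: 0.05/16 = 0.0031
for the PRS-by-cancer matrix, 0.05/m for the per-variant scan where m is
the number of unique variants in the pruned union across PRS (798 at the
scale of the original analysis — the package computes m from its own pruned
set rather than hard-coding it), and 0.05/20 = 0.0025 for the secondary
phenotypes. Benjamini–Hochberg q-values are reported alongside; the FDR is
applied globally across each scan's results by default (a per-family switch
exists) because the matrix-wide scan is a single planned family.

## The synthetic-data generator

Real GERA/UK Biobank-style cohort data are access-controlled, so the
package ships a generator whose defaults state the simulated world used by
the acceptance suite, chosen once and not revisited:

* **Genotypes.** Haplotypes from a latent Gaussian copula: within an LD
  block each variant loads on a shared factor with loading $\sqrt\rho$, an
  allele is carried when the latent value falls below the allele-frequency
  quantile, dosage is the sum of two independent haplotypes. $\rho$ cycles
  through {0, 0.3, 0.6, 0.9} across ten 4-variant blocks, giving realized
  dosage $r^2$ of about {0, 0.03, 0.15, 0.49} — deliberately clear of the
  0.3 pruning threshold on both sides. Allele frequency is constant within
  a block (0.15–0.45 across blocks) because mixed frequencies under
  thresholding push high-$\rho$ pairs toward the pruning boundary, which
  would make trap outcomes seed-dependent.
* **Disease.** Two cancers by default: one with per-SD log odds ratio
  $\ln(1.3)$ — the scale of the stronger PRS–own-cancer associations — and
  one null, both at baseline prevalence 5% (logit intercept), with modest
  age and sex effects (0.03 per decade, 0.2 for male sex). Cohort size
  defaults to 20,000 per cohort, matching the acceptance criterion's stated
  world. Diagnosis dates are uniform over 2000–2015 with per-cohort
  specimen dates of 2008-01-01 / 2009-07-01, so incident and prevalent
  cases both occur.
* **Secondary traits.** Linear in the standardized true PRS with Gaussian
  noise (default slope 0.1 vs 0).
* **Traps.** The catalog plants one instance of every failure mode the
  curation and harmonization stages must catch — duplicate records,
  missing-effect records, strand-flipped codings, ambiguous A/T variants at
  MAF 0.47, MAF 0.005 variants, reference-discordant variants, absent leads
  with and without a usable proxy, and prunable LD partners — and records
  each trap's expected fate, so tests can assert that the dropped set
  equals the planted set *exactly*, not merely in count.
* **Ancestry PCs** are standard normals uncorrelated with genotype by
  default; a `confound_pcs` switch correlates PC1 with a genotype block for
  confounding experiments. PCs here are nuisance covariates, not a
  population-structure model.

What the generator does **not** emulate: realistic human LD maps (block
correlation is exchangeable, not distance-decaying), imputation-quality
variation (info scores are drawn, not earned), relatedness, ancestry
admixture, registry coding noise, or survival-dependent sampling. A green
test therefore establishes that the *machinery* is correct — filters drop
exactly what they should, estimators recover planted parameters at nominal
coverage — not that the original cohort results are reproduced; those
require the access-controlled data.

Determinism: one global seed; every stage draws its own substream seed from
it (`substream_seed`), so identical configs give byte-identical outputs and
single stages can be re-run in isolation.

## Numerical choices and degenerate inputs

* Logistic fits use IRLS with tolerance 1e-12 so the saturated 2×2 fit
  matches the cross-product odds ratio and Woolf standard error to 1e-6.
* Separation or non-convergence (|coefficient| ≥ 15, se ≥ 100, or IRLS
  failure) marks an estimate non-converged; it is excluded from the
  meta-analysis with a warning, never penalized or patched.
* A constant exposure, a constant PRS, or a standardization population
  smaller than two samples is an error, not an NA.
* Missing dosages are mean-imputed per variant (2 × allele frequency)
  before scoring; imputed genotype data rarely have missingness, and a
  deterministic fallback keeps scores well-defined.
* Pairwise $r^2$ over fewer than two shared non-missing samples, or with a
  constant vector, is reported as missing LD, and the pruner then treats
  the pair as independent with a logged note.
* Region enrichment divides proportions by region span in Mb for the
  size-normalized variant; positions follow BED's 0-based half-open
  convention; a zero-background region reports an undefined (NA) ratio,
  not infinity. Enrichment is descriptive — no test is attached, by
  design.

## Open design points we fixed

* **Standardization population**: all QC-passed samples of the cohort, once
  per cohort — the natural reading of "its mean and standard deviation";
  a mask argument allows controls-only or subset standardization.
* **Sensitivity LD-overlap threshold**: variants are removed from an
  exposure PRS when $r^2 \ge 0.3$ with a known outcome-cancer variant — the
  independence threshold reused, configurable, since no separate cutoff is
  printed for this step.
* **Enrichment denominators**: counts and proportions are emitted both per
  association and per unique variant, since either denominator is
  defensible for the published percentages.

## Limitations

Firth-corrected or mixed-model association, random-effects meta-analysis,
genome-wide (shrinkage) scoring, indel normalization and multi-allelic
decomposition are out of scope. The per-variant scan refits a plain
logistic model per (variant, outcome) pair and is quadratic in panel size ×
outcomes; it is intended for catalog-scale panels (hundreds of variants),
not genome-wide data.
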