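---
title: "Longitudinal methylome-transcriptome integration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal methylome-transcriptome integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasurg)
```

## The analysis problem

Metabolic surgery in severely obese patients produces rapid weight loss, but
skeletal-muscle insulin sensitivity improves only towards the end of the
first year. A paired longitudinal design — muscle biopsies and
hyperinsulinemic-euglycemic clamps at baseline and at 2, 12, 24 and 52 weeks
after surgery, plus a lean control group measured once — makes it possible to
ask *when* transcriptional and epigenetic changes occur and how they relate
to each other and to clinical phenotypes. The characteristic findings this
package's pipeline is built to detect are:

* a large wave of differential gene expression already at 2 weeks, most of
  it transient (significant at 2 weeks, back to baseline by 52 weeks);
* differential DNA methylation appearing late, essentially only at 52 weeks;
* direction-concordant coupling between late methylation and expression:
  promoter hypomethylation with upregulation, gene-body hypermethylation
  with upregulation, and the mirrored patterns for downregulation;
* over-representation of late methylation changes among the transiently
  expressed genes — the "reprogramming" signature.

`run_full()` executes the whole chain (probe QC, differential statistics,
temporal classification, enrichment, integration, candidate filtering,
clinical indices, phenotype correlation) and emits a machine-readable report
whose every count is re-derived from the stage tables by an internal audit.

## Statistical model and conventions

**Differential testing.** Within-subject contrasts (each follow-up week vs
baseline) use a paired two-tailed t-test on subject-aligned values; the
between-group contrast (controls vs obese baseline) uses Welch's unequal-
variance t-test. The package deliberately mirrors the asymmetric
significance convention of array studies in this field: expression calls are
made on the *unadjusted* p-value (`p < alpha_expr`, default 0.05), while
methylation p-values are Benjamini-Hochberg adjusted across tested probes
and called at `q < alpha_q_meth` (default 0.05). Both thresholds are
configurable; the defaults reproduce the convention, not a recommendation.

**Effect sizes.** Expression effects are mean log-scale differences.
Methylation effects are reported as delta-beta in percentage points:
`100 * (mean after - mean before)` for unpaired contrasts and 100 times the
mean within-subject difference for paired contrasts. Betas are tested on the
beta scale rather than on M-values, because the delta-beta thresholds of the
downstream candidate filter are defined on the beta scale; this trades some
statistical efficiency near the boundaries for interpretability, and is a
documented limitation.

**Degenerate inputs.** Zero-variance situations are resolved by convention
so that genome-wide scans stay total: equal constant groups give `t = 0,
p = 1`; unequal constant groups give `p = 0` with a warning; features with
fewer than two complete observations (or pairs) carry missing p-values and
are excluded from the BH denominator. A delta-beta of exactly zero counts as
hypermethylated in the hypomethylation fraction (tie rule).

**Probe QC.** Probes on chromosomes X and Y are always removed (mixed-sex
cohort); SNP-flagged probes are removed for unpaired analyses but kept for
paired ones, where a genotype-driven shift affects both members of a pair
equally; probes missing in more than `max_missing_frac` (default 0.05,
a conservative choice — the rule set itself does not prescribe one) of
samples are removed. Detection-p filtering is out of scope because it needs
raw intensities.

**Enrichment.** All enrichment questions (CpG-island relation, the
promoter/body/intergenic collapse, reprogramming) are four-field chi-square
tests without Yates correction by default (a flag enables it); gene-set
over-representation uses the one-sided hypergeometric tail. The tested
universe defaults to the QC-passed probe set, configurable, since published
chi-square statements rarely state their universe.

**Integration rules.** A CpG is linked to a gene purely through the
manifest's gene annotation — no distance window. A probe annotated to
several genes contributes one link per gene, so link totals can exceed
unique-probe totals; both are reported. The promoter zone is TSS200, TSS1500,
5'UTR and first exon; the gene body is Body plus 3'UTR (the 3'UTR assignment
is a design choice; both zone sets are arguments). The candidate filter
requires at least `min_cpgs = 2` significant CpGs with `|delta-beta| > 5`
percentage points; the threshold count is read as ">= 2", and both values
are configurable.

**Temporal classes.** "Returned to baseline" is operationalized primarily as
loss of significance at 52 weeks; a strict variant additionally requires
non-significance at 12 and 24 weeks. Both are reported because published
transient counts use both senses. A gene significant at 2 and 52 weeks in
opposite directions is `other`, not `constant`.

**Phenotype correlation.** Pearson correlation with a t-based two-tailed
p-value. The default `pooled_levels` scheme pools all obese sample-
timepoints; this mirrors the raw-count convention of clinical correlation
tables but violates independence across repeated measures — the alternative
`delta_52w` scheme (per-subject 52-week changes) avoids that at the cost of
n. Counts change strongly between schemes; neither is adjusted for multiple
testing by default.

## The synthetic cohort generator

`generate_cohort()` produces a complete fake study with recorded ground
truth. It is first-class, tested code: the package's end-to-end claims are
claims about what the pipeline recovers from these cohorts.

* **Design**: `n_ob = 16` obese subjects with samples at weeks
  0/2/12/24/52 (the omics subset size of the motivating design, not the
  full clinical cohort) and `n_con = 14` controls at week 0.
* **Expression**: per-gene baseline `N(7, 1.5)` on the log scale, subject
  random intercept (SD 0.5) and residual `N(0, 0.7)`. Planted classes shift
  the mean at 2 weeks only (transient), at all post-surgery weeks
  (constant), or at 52 weeks only (late-coupled). The planted shift is
  expressed in units of the SD of a within-subject difference
  (`sqrt(2) * expr_noise_sd`), the noise scale that governs power in a
  paired design; a 1-unit effect at n = 16 therefore has a noncentrality of
  4 and is detectable with high (~0.95) power, which is what makes >= 80%
  recovery a meaningful calibration target rather than a coin flip. The
  residual SD of 0.7 log-units is typical of log-scale array residual
  variation.
* **Methylation**: per-probe baseline on the logit scale from a trimodal
  mixture (40% low around logit -2.5, 40% high around +2.5, 20%
  intermediate), emulating the bimodal beta distribution of array data;
  per-(subject, probe) random effect (logit SD 0.2) inducing within-subject
  correlation; per-measurement probe noise (logit SD 0.3). Planted 52-week
  shifts of `delta_beta_pp = 10` percentage points are applied on the beta
  scale with clipping to [0.01, 0.99]; planting is restricted to probes
  whose baseline leaves room for the full shift, so the planted magnitude
  is always exactly the configured one. Each effect gene owns 3 planted
  probes (methylation changes typically span several CpGs of a region),
  with signs satisfying the promoter/body concordance rules. Transient and
  constant genes carry planted late methylation as well — that is the
  reprogramming structure the integration stage is meant to find.
* **Manifest**: probes are assigned to genes round-robin (the integration
  logic uses only the manifest's gene field, so genomic geometry is not
  modeled); ~25% intergenic, ~5% on X/Y, ~3% SNP-flagged, ~2% annotated to
  two genes; region features and island relations drawn from fixed
  EPIC-like proportions.
* **Phenotypes**: group-mean trajectories (see
  `reference_phenotype_trajectories()`) with the hallmark free-fatty-acid
  spike at 2 weeks (676 -> 1057 umol/l) and late clamp M-value improvement,
  plus subject-level Gaussian noise whose scale multiplier
  `pheno_noise_scale` reproduces the configured means exactly at 0.

What the generator does **not** emulate: linkage/co-methylation block
structure, batch and cell-composition effects, array normalization
artefacts, missing-at-random structure, and the heavy-tailed effect-size
distributions of real biology. Passing recovery tests therefore demonstrate
that the pipeline's logic and statistics behave as specified under a known
model — they do not certify performance on real array data.

## Validation strategy and problem sizes

The test-suite properties are run at three scales, chosen so the whole suite
finishes in seconds while the calibrated claims keep their meaning:

* rule-level tests on handcrafted micro-fixtures with hand-computed or
  exhaustively enumerated expectations (Welch vs a 70-relabeling permutation
  oracle, BH step-up by hand, chi-square expected counts, hypergeometric
  closed forms);
* property tests on reduced cohorts (200-500 genes, 1,000-4,000 probes);
* acceptance-level recovery and null-control checks at the full default
  conditions (2,000 genes, 20,000 probes, n_ob = 16), where >= 80% of
  planted transient genes, planted differentially methylated CpGs, and
  late-coupled candidate genes must be recovered, and a null cohort must
  stay within the Benjamini-Hochberg false-discovery bound.

`scripts/acceptance.R` re-runs the full-scale recovery from scratch against
the installed package and writes the measured rates as JSON.

## Known limitations

* Beta-scale t-tests lose power for probes near the [0, 1] boundaries
  compared with M-value analysis.
* The pooled-levels correlation scheme treats repeated measures as
  independent observations.
* Listwise dropping of incomplete pairs is the simplest defensible
  missing-data policy; no imputation is attempted.
* No covariate adjustment or mixed modeling: the clinical
  repeated-measures covariance modeling that complements this kind of
  analysis is out of scope, as are array preprocessing, GO-database
  retrieval, and enhancer annotation.
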