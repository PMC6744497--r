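# metasurg

Longitudinal integration of skeletal-muscle gene expression, EPIC-style DNA
methylation and clinical phenotypes around metabolic surgery.

## The problem

In severely obese patients, surgically induced weight loss improves muscle
insulin sensitivity only towards the end of the first year, while gene
expression reacts within two weeks — mostly transiently — and DNA
methylation changes appear late, at 52 weeks. Analyzing such a study
requires a chain of paired statistics and rule-based integration steps:

* **Differential testing** per gene/probe: paired two-tailed t-tests for
  each follow-up week against baseline, Welch's t-test for controls vs
  obese baseline. Expression is called significant on the unadjusted
  p-value (`p < 0.05`); methylation is Benjamini–Hochberg adjusted and
  called at `q < 0.05`, with effects reported as Δβ in percentage points
  (negative = hypomethylation).
* **Temporal classification** of genes over 2/12/24/52 weeks into
  `transient_2w`, `constant`, `late_only`, `never` and `other`, with a
  strict-transient flag.
* **Probe QC**: X/Y probes always removed; SNP-flagged probes removed only
  for unpaired analyses; missingness filter.
* **Concordance rules** linking methylation to expression per gene:
  upregulation with promoter hypomethylation or gene-body
  hypermethylation is *concordant* (mirrored for downregulation); a
  candidate gene carries ≥ 2 significant CpGs with |Δβ| > 5 pp.
* **Enrichment**: four-field chi-square tests over CpG-island relations and
  the promoter/body/intergenic collapse; "reprogramming" enrichment of
  late methylation among transiently expressed genes; one-sided
  hypergeometric gene-set over-representation.
* **Clinical indices**: Adipo-IR (fasting FFA × fasting insulin), clamp
  M-value (time-weighted steady-state glucose infusion rate per BSA or kg),
  metabolic flexibility ΔRQ, respirometry ratios RCR = state3/state4 and
  LCR = state4/state_u.
* **Phenotype correlation**: Pearson correlation of features with clinical
  parameters, pooled across obese sample-timepoints or on 52-week changes.

A synthetic cohort generator (`generate_cohort()`) plants known transient,
constant and late methylation-coupled effects with recorded ground truth, so
the entire pipeline is validated end-to-end on recoverable structure.

## Worked example

```r
library(metasurg)

cfg <- pipeline_config(sim = sim_config(seed = 1))  # default study conditions
res <- run_full(cfg)
r <- res$report

r$deg_counts[["2"]]$n_significant    # 218 genes differentially expressed at 2w
r$temporal_class_counts$transient_2w # 174 transient genes
r$dmc_counts[["2"]]$n_significant    # 0   DMCs at 2 weeks
r$dmc_counts[["52"]]$n_significant   # 610 DMCs at 52 weeks
r$integration$n_candidates           # 122 candidate genes
r$reprogramming$p                    # 3.8e-67
```

With the default simulated cohort (16 obese subjects at 5 timepoints, 2,000
genes, 20,000 probes; 100 transient, 20 constant and 100 late-coupled
planted genes), the run reproduces the study's qualitative structure: a wave
of ~218 differentially expressed genes at 2 weeks of which 174 are
transient, essentially no differential methylation at 2 weeks (0 CpGs)
against 610 CpGs at 52 weeks, genic enrichment of those late DMCs (the
planted CpGs sit on genes, so the intergenic fold is 0.01 with
p ≈ 3 × 10⁻⁴⁶), 122 candidate genes passing the ≥ 2-CpG / > 5 pp filter, and
a strongly significant reprogramming association between transient
expression and late methylation (chi-square p ≈ 10⁻⁶⁷).

Clinical indices work directly on phenotype values:

```r
adipo_ir(676, 21)          # 14196  (obese baseline, umol/l x uU/ml)
percent_change(676, 1057)  # +56.4% FFA rise at 2 weeks
percent_change(676, 527)   # -22.0% FFA change at 52 weeks
delta_rq(0.92, 0.80)       # 0.12   metabolic flexibility
```

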