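# methStages

Stage-resolved differential DNA methylation and variability analysis for
case/control methylome studies, modelled on bone-marrow mesenchymal
stromal cell (MSC) cohorts spanning the monoclonal gammopathy (MGUS) →
smoldering myeloma (SMM) → multiple myeloma (MM) progression against
healthy donors (HD).

The package is for epigenomics analysts who have probe-level β-value
matrices (EPIC-like arrays), sample sheets with stage/age/sex metadata,
and probe annotation, and who want reproducible, tested implementations
of the standard discovery pipeline:

* **DMP calling** — differentially methylated positions by mean shift:
  empirical-Bayes moderated t-statistics on M-values
  (M = log₂(β/(1−β))), adjusted for age and sex, called at
  |Δβ| ≥ 0.1 and p < 0.01. The moderated t shrinks per-probe residual
  variances s²ᵍ towards a prior (d₀, s₀²) estimated by moment-matching
  log s² to a scaled log-F distribution (digamma/trigamma inversion),
  with posterior variance s̃² = (d₀s₀² + d·s²)/(d₀ + d) and d₀ + d
  degrees of freedom.
* **DVP calling (iEVORA)** — differentially variable positions:
  Bartlett's variance-homogeneity test on β-values at BH FDR < 0.05,
  regularized by a two-sample t-test (p < 0.05) that guards against
  single-outlier artifacts; called probes ranked by t p-value.
* **Progression set algebra** — per-stage calls combined into MM-only,
  SMM∩MM and all-three components whose union is the
  progression-associated CpG set; paired mono/co-culture calling and
  call-set overlaps with direction concordance.
* **Genomic context** — CpG-island-relation and 15-state chromHMM
  enrichment by Fisher-exact 2×2 odds ratios against a probe background.
* **Integration** — nearest-TSS gene mapping, moderated-t differential
  expression (p < 0.05), and the four-way cross of methylation ×
  expression direction (hyper-down, hyper-up, hypo-down, hypo-up).
* **RRBS support** — per-CpG coverage filtering (≥ 5 valid reads in
  every compared group) with methylation fractions.
* **Synthetic data** — a generator that plants mean-shift DMPs,
  outlier-driven DVPs, covariate effects, annotation context and
  methylation-coupled expression with a full ground-truth table, so the
  entire pipeline is testable without any download.

## Worked example

```r
library(methStages)

sim <- simulate_methylome(n_probes = 2000, n_dmp = 100, n_dvp = 50, seed = 1)
ann <- simulate_annotation(rownames(sim$beta),
                           planted_probes = sim$truth$probe_id,
                           island_enrichment = 3, seed = 2)

beta <- filter_probes(sim$beta, ann$annotation)   # drop chrX/Y + blacklist
beta <- quantile_normalize(beta)
M <- beta_to_m(beta)

calls <- lapply(c(MGUS = "MGUS", SMM = "SMM", MM = "MM"),
                function(st) call_dmps(beta, M, sim$sheet, st, "HD"))
mm <- calls$MM
head(mm[mm$called, ], 3)
#>       probe_id delta_beta     t        p direction called
#> 20  cg00000021      0.244  33.6 3.84e-15     hyper   TRUE
#> 77  cg00000081      0.231  45.9 4.45e-17     hyper   TRUE
#> 124 cg00000130     -0.241 -88.1 3.66e-21      hypo   TRUE
```

Each row is one CpG: `delta_beta` is the MM-minus-HD difference of mean
normalized β (here ≈ the planted 0.25 shift), `t`/`p` come from the
moderated test on M-values, and `called` applies the joint
|Δβ| ≥ 0.1 & p < 0.01 criterion.

```r
prog <- progression_sets(lapply(calls, called_sets))
prog
#> hyper: MM-only 14, SMM&MM 14, all three 15, union 43
#> hypo: MM-only 14, SMM&MM 12, all three 9, union 35
```

The union (43 hyper + 35 hypo CpGs) is the progression-associated set:
changes present in overt disease that appear only at MM, from SMM
onwards, or across all stages.

```r
enr <- category_enrichment(prog$hyper$union, ann$annotation,
                           "cgi_relation", rownames(beta))
enr[enr$level == "Island", c("level", "odds_ratio", "log_odds_ratio", "p")]
#>    level odds_ratio log_odds_ratio        p
#> 1 Island       3.78           1.33 2.58e-05
```

The generator planted a 3-fold CpG-island over-representation among
affected probes; the enrichment recovers an odds ratio of 3.8 with a
Fisher-exact p of 3e-05.

`run_pipeline(config)` chains all of the above (filtering,
normalization, per-stage DMP/DVP calling, progression sets, enrichment,
optional expression integration) from a YAML or list config and writes
result TSVs, BED exports, a count summary and a manifest with md5
checksums; reruns with the same config and seed are bit-identical.

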