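---
title: "Stage-resolved differential methylation and variability: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved differential methylation and variability: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analytical problem

Bone-marrow mesenchymal stromal cells (MSCs) from monoclonal gammopathy
(MGUS), smoldering myeloma (SMM) and multiple myeloma (MM) patients carry
DNA methylation aberrations relative to healthy donors (HD), and these
changes accumulate along disease progression. Two distinct signals matter:

* **DMPs** (differentially methylated positions) — CpGs whose *mean*
  methylation shifts between a disease stage and controls;
* **DVPs** (differentially variable positions) — CpGs whose *variance*
  differs, typically because a subset of patient samples drifts away from
  an otherwise stable methylation state. Variability changes are a
  hallmark of early neoplastic stages.

`methStages` implements both callers, the set algebra that extracts
progression-associated CpGs from per-stage calls, genomic-context
enrichment, nearest-gene mapping with expression integration, a paired
variant for mono/co-culture designs, RRBS coverage filtering, and a
synthetic-data generator that plants all of these effects with a recorded
ground truth.

## Scales: beta-values and M-values

A CpG's methylation fraction $\beta \in [0,1]$ is intuitive but
heteroskedastic: its variance shrinks near the boundaries. All hypothesis
tests for mean shifts therefore run on the M-value scale,
$M = \log_2\{\beta/(1-\beta)\}$, while effect sizes ($\Delta\beta$) are
reported on the beta scale where "a 10% methylation change" has its usual
meaning. `beta_to_m()` clips $\beta$ into $[\varepsilon, 1-\varepsilon]$
with $\varepsilon = 10^{-6}$ before the logit, bounding $|M|$ at about
19.93 so the transform never produces infinities while preserving
ordering. $\Delta\beta$ is computed on quantile-normalized beta-values
(the same matrix the tests see, back on the interpretable scale); the
choice of normalized rather than raw beta for effect sizes is a
deliberate convention, documented here because either is defensible.

## The DMP model

For each probe the M-values follow an ordinary linear model with an
intercept, a disease-vs-control indicator, and additive age and sex
covariates; samples missing a covariate are excluded (with a logged
count) rather than silently imputed. Per-probe residual variances $s^2_g$
with $d$ degrees of freedom are shrunk towards a common prior by
empirical Bayes: the distribution of $\log s^2_g$ is moment-matched to a
scaled log-F, solving

$$\text{trigamma}(d_0/2) = \overline{(e_g - \bar e)^2}\tfrac{n}{n-1} -
  \text{trigamma}(d/2), \qquad
  e_g = \log s_g^2 - \psi(d/2) + \log(d/2),$$

by Newton inversion of the trigamma function, giving the prior
$(d_0, s_0^2)$ and posterior variances
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$. The moderated $t$ uses
$d_0 + d$ degrees of freedom. When the corrected spread of log-variances
is non-positive the prior degrees of freedom are infinite and the prior
collapses onto the mean observed variance. The implementation is
validated against the standard array-analysis reference implementation to
$10^{-8}$ on seeded matrices.

A probe is a DMP when $|\Delta\beta| \ge 0.1$ **and** the moderated-t
p-value is below 0.01 — raw, not FDR-adjusted, which is the conventional
criterion for this joint filter (the effect-size condition is the real
guard against multiplicity; a `adjust = TRUE` flag enables BH for users
who want it). Direction is the sign of $\Delta\beta$ (hyper/hypo).

The "paired t-test with age and sex covariates" phrasing common in this
literature is interpreted as a group-contrast design with additive
covariates: pairing across unrelated donors is undefined. True
fixed-effect pairing (`call_dmps_paired()`) is reserved for the
mono/co-culture design, where each donor genuinely appears under both
conditions; there the effect size is the mean within-pair
$\Delta\beta$.

## The DVP model (iEVORA)

Variance calling follows the iEVORA scheme on beta-values (the scale on
which the algorithm was described): per probe, Bartlett's
variance-homogeneity test between the two groups,

$$T = \frac{(N-k)\ln s_p^2 - \sum_i (n_i-1)\ln s_i^2}{C}, \qquad k = 2,$$

with BH FDR across probes (q < 0.05), then a regularizing two-sample
t-test (p < 0.05, Welch by default since variance heterogeneity is the
tested hypothesis) that discards hits driven by a single outlier — the
known failure mode of pure variance tests. Called probes are ranked by
t p-value (ties by Bartlett q, then probe id, for determinism). Direction
is the sign of the group mean beta difference; the literature labels DVPs
hyper/hypo without stating a rule, and the mean-difference sign is
deterministic and matches the outlier direction under the planted model.
The FDR-first-then-t order follows the algorithm's published description.
Setting `t_p_threshold = 1` switches the regularization off, leaving pure
Bartlett-FDR calling.

A property worth knowing when planning a study: for $k$ outliers of
constant size among $n$ disease samples, as the background noise becomes
small the regularizing t-statistic converges to
$\sqrt{kn/(n-k)}$ *independently of the outlier magnitude*. With 3
outliers in 10 samples that is $\approx 1.96$ (two-sided p $\approx$
0.07–0.08), just outside the 0.05 cut, so single-direction,
constant-size outlier bursts need to involve at least 4 of 10 samples
before the t-regularized caller fires; the Bartlett stage alone detects
the 3-of-10 configuration essentially always. The package's validation
reports both sensitivities side by side.

## Progression set algebra and overlaps

Given per-stage called sets (hyper and hypo separately),
`progression_sets()` extracts the accumulative-change components:
MM-only, SMM∩MM without MGUS, and all three stages; their union is the
progression-associated set. The three components are pairwise disjoint
and the union is contained in the MM calls — both asserted on every run.
A probe called hyper in one stage and hypo in another contradicts the
accumulation model; such probes are excluded and logged (the exclusion is
a design decision, chosen because "accumulative change" implies a
consistent direction). `overlap_sets()` intersects any two call sets and
reports direction-concordant and discordant subsets, as used for the
co-culture-vs-patient comparison.

## Enrichment, gene mapping and expression integration

`category_enrichment()` tests each CpG-island-relation level (island,
N/S shore, N/S shelf, open sea) or each of the 15 chromHMM states with a
disjoint 2×2 table — query vs background-minus-query — using the sample
odds ratio $(ad)/(bc)$ with the Haldane–Anscombe +0.5 correction at zero
cells and Fisher's exact two-sided p-value. The background defaults to
all probes surviving QC filtering, the analysis-respecting version of
"all probes on the array". Raw per-level fractions are reported for
distribution-style summaries.

Probes map to the single nearest gene TSS on the same chromosome
(equidistant ties to the lexicographically first symbol; distances signed
negative upstream relative to strand). The single-nearest rule replaces
region-based association schemes because it is the stated convention for
this analysis. Differential expression uses the same moderated-t
machinery per gene (p < 0.05, duplicate probe rows averaged on load), and
`integrate_meth_expr()` crosses methylation with expression direction
into the four categories hyper-down, hyper-up, hypo-down, hypo-up, with
genes carrying DMPs in both directions flagged ambiguous.

## The synthetic-data generator

`simulate_methylome()` emulates EPIC-like data: per-probe baselines drawn
from a bimodal logit-scale mixture (modes near $\beta = 0.10$ and 0.85,
logit sd 0.5), per-sample logit-normal noise (sd 0.05), and small
additive age/sex effects (per-probe coefficients with sd 0.003/yr and
0.05). The logit-normal noise model — rather than Beta noise — makes the
M-value model exactly Gaussian, so the moderated-t machinery is tested
under its own assumptions. Default cohort sizes are HD = 8, MGUS = 10,
SMM = 8, MM = 9, the scale of a typical myeloma MSC cohort; tests run at
$10^3$–$10^4$ probes rather than 850k, which leaves every statistical
property intact while keeping the suite fast.

Planted DMPs shift the affected groups' mean on the logit scale to hit a
target $\Delta\beta$ (default 0.25) exactly at the baseline; planted DVPs
convert a fixed fraction (default 0.3) of each affected group's samples
into outliers shifted by a fixed beta amount (default 0.4), the
outlier-driven structure that motivates the t-regularization. Each
planted probe carries a stage pattern (MM-only, SMM+MM, all three,
MGUS-only, SMM-only) so the progression algebra has a known answer.
Annotation is laid out on five synthetic autosomes (strictly increasing
positions, EPIC-like island fractions, 15 chromHMM states, optional
island over-representation among planted probes, a small blacklist and
sex-chromosome fraction) with 200 genes per chromosome — enough that
probe-to-gene multiplicity stays modest; genes whose linked planted
probes disagree in direction are left uncoupled so that each coupled
gene's expression response is a single Bernoulli draw of the coupling
probability (default 0.9, sign opposing methylation). RRBS tables draw
Poisson depths with binomial methylated counts per group.

What the generator does **not** emulate: Infinium I/II chemistry biases,
batch effects, spatial probe correlation, cell-composition
heterogeneity, and the long-tailed outlier structure of real arrays.
Passing recovery tests therefore demonstrates correctness of the
machinery under a clean generative model, not performance on real IDAT
data.

## Numerical and interface choices

* Quantile normalization maps every sample onto the across-sample mean
  quantile vector; ties receive the mean of their rank span's target
  quantiles. It is idempotent to $10^{-10}$ and is a no-op (with a
  warning) on a single sample.
* Zero-variance probes get `NA` Bartlett/t results with a logged count
  and are excluded from FDR; zero-coverage RRBS sites are dropped, never
  divided by.
* RRBS sites must reach $\ge 5$ valid reads in **every** group being
  compared, so group contrasts share one site set.
* Missing beta in more than 20% of any group's samples drops the probe
  (logged); the threshold is a convention, stated here because upstream
  literature is silent on missingness.
* Delimiters are auto-detected (tab vs comma) on the header line and can
  be forced; coordinates are 1-based in all tables and 0-based half-open
  only in BED exports.
* The pipeline is driven by `run_pipeline()` with a YAML or list config;
  an R function rather than a shell entry point because the package's
  users work in R. The manifest records the scientific parameters, seed,
  package version and md5 checksums of every output, and reruns are
  bit-identical.

## Worked example

```{r, eval = FALSE}
library(methStages)

sim <- simulate_methylome(n_probes = 2000, n_dmp = 100, n_dvp = 50,
                          seed = 1)
ann <- simulate_annotation(rownames(sim$beta),
                           planted_probes = sim$truth$probe_id,
                           island_enrichment = 3, seed = 2)

beta <- filter_probes(sim$beta, ann$annotation)
beta <- quantile_normalize(beta)

calls <- lapply(c(MGUS = "MGUS", SMM = "SMM", MM = "MM"), function(st)
  call_dmps(beta, beta_to_m(beta), sim$sheet, st, "HD"))
prog <- progression_sets(lapply(calls, called_sets))
prog

enr <- category_enrichment(prog$hyper$union, ann$annotation,
                           "cgi_relation", rownames(beta))
enr[enr$level == "Island", c("level", "odds_ratio", "p")]
```

## Known limitations

* The callers assume two-group comparisons; multi-group ANOVA-style
  contrasts are out of scope.
* The moderated fit uses fixed-effect pairing, not random-effect
  duplicate-correlation models.
* Only quantile normalization is provided; background correction (Noob)
  and batch correction are explicitly out of scope, as are motif
  scanning and ontology databases (gene lists are exportable for
  external tools).
* Chromosome labels `chrX`/`chrY` (or `X`/`Y`) are the recognized sex
  chromosomes; non-human nomenclatures need pre-mapping.
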