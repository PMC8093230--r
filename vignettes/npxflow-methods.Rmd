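---
title: "Models and methods behind npxflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind npxflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npxflow)
library(dplyr)
```

npxflow implements the computational chain of next-generation proximity
extension assay (PEA) plasma proteomics: a synthetic-data generator with
recorded ground truth, counts-to-NPX normalization with quality control,
batch and cross-platform harmonisation, longitudinal variance
decomposition, pQTL mapping, and clinical association / stratification.
This vignette explains the models, the defaults, and the choices made
where the underlying procedures are conventionally under-specified.

## The generative model

True log2 abundance of protein $p$ for subject $i$ at visit $v$ is

$$x_{ivp} = \mu_p + s_p\,[\text{male}_i] + \textstyle\sum_k \beta_{pk} g_{ik}
 + d_p\,[\text{T2D}_i] + r_p\,[\text{responder}_i] + b_{ip} + e_{ivp},$$

with $b_{ip} \sim N(0, \sigma^2_{between})$ a stable subject level and
$e_{ivp} \sim N(0, \sigma^2_{within})$ the visit-to-visit fluctuation.
Defaults $\sigma_{between} = 0.5$, $\sigma_{within} = 0.125$ log2 units
encode the stylised fact the variance module is built to detect: most
plasma proteins vary far more between people than within a person over
months. Effect sizes default to 1 log2 unit (a two-fold change) on 10% of
proteins for sex, disease and drug-response effects, with random sign —
large enough to be individually detectable at cohort sizes of 50–200, so
recovery rates measure the pipeline rather than asymptotics.

Genotypes are drawn in Hardy–Weinberg proportions inside LD blocks: each
subject carries two haplotypes per block, and every variant copies its
haplotype's founder allele with a flip probability (default 0.05). This
produces high within-block and null between-block $r^2$ without a full
coalescent model, which is all the pruning and conditional-analysis logic
needs. Cis proteins get a transcription start site within 0.5 Mb of their
causal variant; trans proteins a TSS on another chromosome.

### The assay (count) layer

Sequencing counts for well $w$ and assay $a$ are negative binomial with
mean $depth_w \cdot 2^{x + po_{plate(w)} + bo_{batch(w)}}$ and variance
$\mu + \phi \mu^2$. The dispersion default $\phi = 0.001$ together with
`depth_mean = 100` and baseline abundances in $[3, 7]$ log2 units gives
per-assay counts of roughly $10^3$–$10^4$ and technical replicate CVs of
3–5% on the linear scale — the performance band production PEA-NGS panels
are validated to, and the calibration under which the plate/batch recovery
properties of the normalization chain are asserted.

Each well receives the five control classes. The extension control is a
DNA-level construct that tracks only sequencing depth; the incubation
control is an immuno-based assay and therefore picks up the plate and
batch offsets like the protein assays do. This distinction is deliberate:
if plate offsets also hit the extension control, extension normalization
would cancel them exactly and the plate-control step would have nothing to
do. Negative controls read a constant background (default $2^0$, about six
log2 units below the weakest protein), plate controls a fixed plasma-pool
vector, sample controls a fixed reference-plasma vector. Plates hold
`plate_capacity` wells of which eight are controls (3 negative, 3 plate,
2 sample); all visits of a subject are co-located on one plate whenever
capacity permits, and bridging samples are re-run scattered across the
plates of every non-reference batch.

## Counts to NPX

NPX generation follows the three standard steps:

1. **Extension normalization**: $extnpx_{sa} = \log_2(count_{sa}/ext_s)$.
   Zero counts use a pseudocount of 0.5 (recorded in the output
   attributes); wells without a positive extension count cannot be
   normalized and are excluded with a reason.
2. **Sample QC**: a sample flags when its incubation-control log2 ratio
   deviates more than 0.3 from the median of the study samples on its
   plate. The scale of this control is not conventionally stated; we use
   the extension-normalized log2 ratio so the ±0.3 threshold is in
   NPX-like units. Flagged samples are marked and excluded from
   downstream defaults, never deleted.
3. **Plate-control adjustment**: per assay, values are shifted by the
   plate's plate-control median and re-anchored to the median of
   plate-control values across plates *of the same batch*. The
   within-batch anchor is a deliberate choice: batches run months apart
   are normalized independently in practice, and a global anchor would
   silently absorb between-batch level differences, leaving the bridging
   step vacuous. With a single batch the anchor is global, and the
   adjustment is idempotent either way.

The order is extnpx → flag → plate adjustment, so a grossly deviating
sample is flagged before any of its statistics can influence others (the
plate adjustment itself is driven by control wells only).

**LOD** is the per-assay, per-plate median of negative-control NPX plus
three times their sample SD, with a fixed +0.2 log2 fallback when the SD
degenerates to zero. Values below LOD are annotated, never removed.

**Bridging** subtracts, per assay, the median paired difference over the
bridging samples; it refuses to run on fewer than two bridges. Bridging
is transitive up to small tolerances on clean data and, with eight
scattered bridges, leaves residual batch offsets below 0.1 log2 units for
the vast majority of assays at the default noise calibration.

**Cross-platform normalization** equalises per-protein medians between
platforms by subtracting the platform median and adding the pooled
median — an affine shift that provably leaves Pearson and Spearman
correlations untouched. Concordance reports per-protein and per-sample
correlations, their medians, and the fraction of assays above $r = 0.7$.

## Variance decomposition

CV is only meaningful on a ratio scale, so NPX values are linearized as
$2^{NPX}$ before computing it (an NPX-scale option exists behind the
`scale` flag for comparability). The inter-individual CV of a protein is
the mean over visits of the CV across individuals within the visit; the
intra-individual CV is the mean over individuals of the CV across that
individual's visits. Subjects with fewer than two visits and visits with
fewer than two subjects are skipped, with counts recorded. Under the
lognormal generative model the closed forms
$CV = \sqrt{e^{\sigma^2 \ln^2 2} - 1}$ (with $\sigma^2$ the relevant log2
variance) are used as test oracles; small-replicate SD bias
($E[s] = c_4 \sigma$) is accounted for where visits number only 2–3.

## pQTL mapping

Genotype QC applies, in order: individuals with more than 5% missing
genotypes, variants with missing rate above 0.05, variants with MAF below
5% (recomputed from retained individuals), and variants failing a 1-df
chi-square Hardy–Weinberg test at $P < 0.001$. A ledger records removals
per filter.

The phenotype is the per-subject median NPX across QC-pass visits. The
scan is ordinary least squares of that baseline on the additive allele
count with age and sex (0/1, male = 1) as covariates, computed by
Frisch–Waugh residualization so the whole protein × variant grid is two
matrix products; variants with missing genotypes fall back to
complete-case fits that match `stats::lm` exactly. The significance
threshold is Bonferroni-style, genome-wide $5\times10^{-8}$ divided by
the number of proteins; both pieces are exposed because the printed
threshold in this literature does not always equal the quotient of its
stated ingredients.

A variant is **cis** when it lies on the same chromosome within 1 Mb of
the protein gene's TSS — the boundary is inclusive, a documented reading
of "within" — and **trans** otherwise. Independent signals per protein
are found greedily: take the lowest-P variant as sentinel (ties broken by
chromosome, then position), prune candidates within 1 Mb on the same
chromosome with $r^2 > 0.1$ to the sentinel (cross-chromosome pairs are
never LD-pruned), refit the rest with all sentinels as covariates, keep
those with conditional $P < 0.01$, and iterate. Sentinel-vs-candidate
$r^2$ (not all-pairs pruning) is used because it is the most direct
reading of the stated procedure; the greedy result is test-verified
against a naive rule-by-rule implementation on randomized small
instances.

## Clinical associations and stratification

HOMA-IR is insulin (mU/L) × glucose (mmol/L) / 22.5; BMI is kg/m².
Differential expression fits, per protein, an additive linear model with
covariates first and the factor last (sequential sums of squares, so the
factor F-test is covariate-adjusted), BH-adjusts across proteins and
calls the DE set at FDR 0.05. Fold change is the difference of
factor-level means of NPX, which is already log2. Imbalance triggers a
warning, not failure. One property worth knowing: testing a
subject-level factor (like sex) across repeated visits is
pseudo-replicated when the between-subject variance dominates — the
F-test's null is anticonservative. Power and precision guarantees are
therefore stated on the baseline (one-row-per-subject) design; the
cross-visit form is available and matches common practice, but its raw
p-values should be read accordingly.

Protein–clinical associations use a linear mixed model with a random
intercept per subject and fixed effects for the parameter, sex, age and
visit. P-values use the Satterthwaite degrees-of-freedom approximation
(via lmerTest) rather than Kenward–Roger: the two agree closely for
random-intercept models at these sizes, the acceptance surface
(calibration, recovery) is insensitive to the difference, and
Satterthwaite avoids a heavy additional dependency. Significance is
adjusted $P < 0.01$, BH across proteins.

Stratification: obesity is baseline BMI strictly above 30 (exactly 30 is
non-obesity by documented policy). Metformin response is the
fasting-glucose decrease from baseline to the final visit: above
1 mmol/L responder, below 0.1 non-responder, between the two (inclusive)
indeterminate. An instability override assigns indeterminate when two
successive per-visit changes have opposite signs and both exceed
1.5 mmol/L in magnitude, capturing trajectories whose net decrease is
meaningless (for example −2.8 then +1.6).

Embeddings centre and scale each protein, then use deterministic PCA or,
for UMAP, the `umap-learn` implementation through the system `python`
with a fixed `random_state` (no maintained R implementation is available
in this package's dependency set; the subprocess keeps the seed contract
exact).

## Problem sizes, determinism, and limitations

Everything is driven by a single integer seed; identical configs
reproduce outputs byte for byte, including plate randomization and UMAP.
The test-suite and acceptance runs use deliberately desk-scale designs —
typically 50–200 subjects, 20–100 proteins, up to a few hundred variants,
6 plates in 2 batches — chosen so each statistical property is measured
with adequate replication while a full run stays in seconds. The
generator emulates the *statistical* structure of PEA studies (variance
components, controls, plates, batches, LD, clinical trajectories); it
does not model antibody cross-reactivity beyond a constant background,
read-level sequencing, Ct-level qPCR mechanics, population structure or
relatedness (no kinship correction is implemented, matching the target
analysis), or informative missingness. Passing recovery tests therefore
demonstrates that the pipeline's inferences are correct under its stated
model, not that real plasma data obey that model.

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 40, n_t2d = 20, n_proteins = 30,
                  plate_capacity = 96, seed = 1)
res <- run_pipeline(cfg, outdir = tempfile("npxflow"))
glance(res$variance)
glance(res$pqtl)
```
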