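---
title: "Inflammatory biologic age: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inflammatory biologic age: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`inflammage` estimates a subject's *inflammatory biologic age* (BA) from a
panel of circulating inflammatory biomarkers, forms **delta age** (ΔAge = BA −
chronologic age, in years), and carries ΔAge through a family-aware downstream
analysis: a feature-wide linear mixed-model scan, a weighted expression score
with survival follow-up, pathway and overlap enrichment, a greedy dense-module
search on a protein–protein interaction (PPI) network, and a
methylation–expression integration. This vignette explains the models, the
tunable parameters, the synthetic-data generator, and the numerical and design
choices that were genuinely open.

```{r setup, message = FALSE}
library(inflammage)
```

# The Klemera–Doubal estimator

Each biomarker $x_j$ is regressed on chronologic age (CA) by ordinary least
squares, yielding intercept $q_j$, slope $k_j$ (units/year), residual SD $s_j$
and correlation $r_j$. The uncorrected biologic age pools the per-biomarker
readings with inverse-variance weights,

$$\mathrm{BA_E} = \frac{\sum_j (x_j - q_j)\,k_j/s_j^2}{\sum_j k_j^2/s_j^2},$$

and the reported estimate blends in chronologic age as one more "biomarker"
with variance $s_\mathrm{BA}^2$:

$$\mathrm{BA_{EC}} = \frac{\sum_j (x_j - q_j)\,k_j/s_j^2 + \mathrm{CA}/s^2_\mathrm{BA}}
{\sum_j k_j^2/s_j^2 + 1/s^2_\mathrm{BA}}, \qquad
\Delta\mathrm{Age} = \mathrm{BA_{EC}} - \mathrm{CA}.$$

$\mathrm{BA_{EC}}$ is therefore a convex combination of $\mathrm{BA_E}$ and
CA; $s^2_\mathrm{BA}$ governs the shrinkage. It is estimated as
$\widehat{\mathrm{Var}}(\mathrm{BA_E}-\mathrm{CA}) -
\frac{1-r_\mathrm{char}^2}{r_\mathrm{char}^2}\cdot
\frac{(\mathrm{CA_{max}}-\mathrm{CA_{min}})^2}{12\,m}$, i.e. the spread of the
raw offset minus the sampling noise of $\mathrm{BA_E}$, with the noise term
summarized through a characteristic correlation $r_\mathrm{char}$ of the
$m$-biomarker panel.

**The characteristic-correlation choice.** Two variants are implemented in
`kd_r_char()`. The default, `"mean_odds"`, solves
$r_\mathrm{char}^2/(1-r_\mathrm{char}^2) = \tfrac1m\sum_j r_j^2/(1-r_j^2)$;
under this definition the correction term equals the actual sampling variance
of $\mathrm{BA_E}$ (the inverse total information $1/\sum_j k_j^2/s_j^2$
scaled by the uniform-age variance), so the shrinkage stays consistent when
panel correlations are heterogeneous — which is exactly the situation with
inflammatory markers, whose age correlations range from ≈0 to ≈0.35. The
alternative `"weighted_rms"` ($\sqrt{\sum w_j r_j^2/\sum w_j}$ with
$w_j = k_j^2/s_j^2$) up-weights the strongest biomarkers, overestimates
$r_\mathrm{char}$ and hence $s^2_\mathrm{BA}$, and under-shrinks: on synthetic
cohorts $\mathrm{BA_{EC}}$ then tracks the latent truth no better than CA
alone. A side effect worth knowing: because `mean_odds` shrinks harder, the SD
of ΔAge is *smaller* than the generating latent offset SD (≈4.4 y against a
7 y latent at the default panel strength); the weaker `weighted_rms` shrinkage
reproduces a ΔAge SD close to the latent SD. Both behaviours are asserted in
the test suite, each under its own variant.

When the $s^2_\mathrm{BA}$ estimate is non-positive (possible by sampling
noise when the panel is weak), the fallback is
$s^2_\mathrm{BA} = \mathrm{Var}(\mathrm{BA_E}-\mathrm{CA})$, which keeps the
estimator defined while preserving the shrinkage structure; a warning is
emitted.

Other KD choices: training and scoring default to the same sample (a
`fit`/`transform` split is exposed for external reference panels); subjects
missing any biomarker are dropped by default (`na_action = "renormalize"`
redistributes weights over observed biomarkers); an optional per-biomarker log
transform (default off) accommodates skewed markers such as CRP and IL-6;
biomarkers with $|r_j|$ below `r_floor` (default 0.01) are flagged but
retained — their weights are already negligible.

# The association scan

For each feature $i$ (gene expression or CpG β-value) the model is

$$y_i = \beta_i \,\Delta\mathrm{Age} + X\gamma + u + \varepsilon,$$

with $u$ a family-level random intercept (equivalently, any symmetric PSD
kinship matrix) and $\varepsilon$ i.i.d. noise. The implementation follows the
one-decomposition strategy of genome-wide mixed-model scans: the grouping
covariance is eigendecomposed once (for exchangeable family blocks the
eigenvectors are closed-form — the per-family mean vector plus a Helmert
complement — and the rotation is sparse), after which each feature needs only
a 1-D REML profile optimization of the variance ratio
$\lambda = \sigma_g^2/\sigma_e^2$ (coarse log-spaced grid shared across
features, then Brent refinement per feature). Estimates match `lme4::lmer`
REML fits to ~6 decimals, and collapse exactly to OLS when subjects are
unrelated. p-values are two-sided Wald. Wald calibration is asymptotic in the
number of *families*: with only a few dozen families the variance-ratio
estimate is noisy and null z-scores are visibly heavy-tailed, so calibration
checks in the test suite use ≥100 families (300 subjects in sibships of
three), where the approximation is expected to hold.

Significance uses the Bonferroni threshold $\alpha = 0.05/n_\text{features}$
(at the transcriptome scale of 17,873 transcripts this is $2.8\times10^{-6}$),
and significant features are partitioned by effect sign. Non-convergent fits
fall back to OLS with `converged = FALSE`; rank-deficient covariate sets abort
with the collinear columns named; missing feature values are complete-case per
feature. Which "technical covariates" enter is left to the caller — the
covariate list is a plain column-name argument.

# Expression score and survival

The per-subject score is the weighted sum
$\mathrm{Score}_j = \sum_i \beta_i G_{ij}$ over significant genes, with the
scan effect sizes as weights — exactly linear in both factors. Its mortality
association is a Cox proportional-hazards fit with Efron tie handling and a
family-clustered robust (sandwich) variance, in two adjustment tiers (age +
sex; plus smoking, diabetes, hypertension treatment, lipid treatment,
prevalent cardiovascular disease, prevalent cancer). Follow-up is
administratively censored at 10 years by default. Because a weighted-sum
score has no natural unit, the hazard ratio is reported both per score unit
and per SD of score; the per-SD scale is the anchored one. Whether to
standardize before fitting was an open choice: standardizing changes nothing
about the test statistic and makes the HR interpretable, so per-SD is the
headline number. A Schoenfeld-type diagnostic failure warns but does not
abort.

# Enrichment

Pathway enrichment is per-set Fisher's exact testing of the 2×2 table
(significant-in-set, significant-outside, set-not-significant, remainder)
against a configurable universe, with the ratio of enrichment
$n_\mathrm{hit}/\mathbb{E}[n_\mathrm{hit}]$ and Benjamini–Hochberg FDR across
the sets actually tested (those with ≥ `min_set_size` = 10 universe genes).
The default universe is the set of genes tested in the scan, since the
background of web-based enrichment tools is not recoverable; restricting the
universe to genes annotated to ≥1 set is a caller-side choice. The two-sided
Fisher p uses the point-probability convention (sum of all table
probabilities ≤ the observed table's, with the customary $10^{-7}$ relative
tie tolerance). For the overlap of two gene lists, `overlap_test()` defaults
to the one-sided enrichment tail: an overlap "enrichment" question is
directional, and the one-sided tail is what reported overlap p-values of this
kind reproduce. Gene symbols are matched exactly after one uppercasing pass.

# Dense-module search

Nodes carry the score $g_i = \Phi^{-1}(1-p_i)$ truncated at 0 for $p>0.5$
(computed on the upper-tail side so $p$-values at the $10^{-30}$ floor do not
overflow); a signed variant colours display output. The module score is

$$Z_m = \frac{\sum_{i \in M} g_i}{\sqrt{k}}, \qquad k = |M|,$$

the standard dense-module objective — the $\sqrt{k}$ normalization is what
makes expansion self-limiting, since adding a weak neighbor lowers the score
and stops the search. Growth is strict best-first: all distance-1 neighbors of
the current module are scored, the single best candidate is added only if
$Z'>Z_m$ strictly (ties broken by higher $g$, then lexicographic symbol), and
the search stops at the first non-improving step, so every trace is strictly
increasing. One module is grown per seed — the top 25 scan genes by p-value —
and the merged subnetwork is the induced subgraph on the union of members.
Unscored network nodes participate with $g = 0$ so they can still act as
connectors (hub genes that are not themselves associated can be pivotal).
Whether the original procedure added one neighbor per step or accepted any
improver in arbitrary order is not recoverable; best-first with deterministic
tie-breaks was chosen because it is order-independent and reproducible, and
the per-step maximality is oracle-checked on exhaustively enumerated small
graphs.

# Methylation integration

The epigenome-wide scan reuses the identical mixed-model contract on CpG
β-values. A gene (from the significant expression list) is a *differentially
methylated gene* (DMG) iff it contains ≥1 CpG with $p < 0.05/N$, where $N$ is
the total number of tested CpGs mapped to the listed genes — shared across
genes, so the cutoff does not depend on per-gene CpG counts. "Tested genes"
is interpreted as the significant expression-gene list (the procedure is
defined inside that analysis); the most significant CpG is chosen among all
CpGs in the gene, ties resolved by smaller p then lexicographic CpG id.

Enrichment of DMGs among the significant genes is permutation-based: random
same-size gene sets are drawn without replacement from the scanned-gene
universe and their DMG counts form the null; the empirical p uses the add-one
estimator $(1+\#\{\text{null} \ge \text{obs}\})/(n_\mathrm{perm}+1)$, which
can never be exactly zero. The null machinery is oracle-checked against the
closed-form hypergeometric mean. Default $n_\mathrm{perm}$ is $10^5$
(desk-scale); $10^6$ is a parameter away.

Attenuation: for each DMG the expression model is refit adding the gene's
most significant CpG as a covariate; "attenuated" means any decrease in
$|\beta|$ (no magnitude threshold — none is defensible without a reference),
and the attenuated fraction is reported. A constant CpG column marks the gene
indeterminate rather than failing.

# The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which everything else is validated.

* **Cohort.** CA uniform on 50–85 y; latent offset $\delta \sim N(0, 7^2)$
  independent of CA, so BA\_true = CA + δ with the ~7 y offset spread of an
  older community cohort; subjects in 800 families of 2–3 (2000 subjects).
* **Biomarkers.** Linear in BA\_true — precisely the generative model under
  which Klemera–Doubal is consistent, which is what makes parameter recovery
  a meaningful test. Noise is calibrated against the shared BA\_true factor so
  realized biomarker–age correlations approximate the targets (defaults 0.35
  down to 0.02; seven of nine clearly age-correlated); one designated pair
  (the CRP/IL-6 analog) shares an extra latent factor sized for r ≈ 0.52.
  Only approximate targets are guaranteed. Gaussian marginals are the
  default; a log-normal option exponentiates the same latent (pairing with
  the KD log-transform option), since heavy-tailed marginals are a plausible
  but unverifiable feature of real panels.
* **Expression.** True genes (50 of 1000, signs fixed at a 2:1
  positive:negative split) carry `effect × δ` plus covariate effects, a
  family random intercept (SD 0.3) and unit noise. Effect magnitudes are
  `effect_size_sd × U(0.5, 1.5)` with default scale 0.08 expression units per
  year. That scale was calibrated **once** by simulation and frozen: the
  scan's exposure is the *estimated* ΔAge, whose correlation with the latent
  δ is only ≈0.45 at the default panel strength, so true effects must be
  ≈2.7× larger than a naive power calculation suggests for planted genes to
  clear a transcriptome-scale Bonferroni bar with ~90% power.
* **Methylation.** Each gene owns 3 CpGs; β-values are logistic-squashed
  latents (hence always in [0,1]). For mediated genes (half of the true
  genes) the lead CpG's latent has correlation `mediation_strength` (default
  0.5) with standardized δ, and the same latent carries a
  `mediation_strength` share of the gene's expression effect — so adjusting
  for the CpG genuinely attenuates, fully so in the
  `mediation_strength = 1`, zero-noise limit.
* **Network / gene sets.** Erdős–Rényi background (mean degree 4) plus a
  planted connected cluster of 15 true genes (random spanning path + 40%
  extra edges); one gene set enriched for all true genes among 50 random
  sets.
* **Survival.** Exponential times with hazard
  `0.015 × exp(0.08·(age − mean age) + log(1.62)·z)` per year, `z` the
  standardized latent score, administratively censored at 10 y — giving event
  counts (~15%) and a per-SD hazard ratio in the range reported for
  inflammatory expression scores.
* **Reproducibility.** One root seed; each data type draws from a
  deterministically derived sub-stream, and generators restore the caller's
  RNG state.

What the generator does **not** emulate: raw array intensities or
normalization artifacts, probe-level structure, realistic LD or genotypes,
cell-type deconvolution, non-exchangeable kinship. Passing tests therefore
demonstrate that the estimators recover the structure they assume — not that
real cohort data satisfy those assumptions.

# Numerical choices and degenerate inputs

* Fisher 2×2: margins of zero return p = 1 with a degeneracy flag; two-sided
  summation uses the $10^{-7}$ relative tie tolerance shared by standard
  implementations (and by the enumeration oracle in the tests).
* BH adjustment delegates to `stats::p.adjust(method = "BH")` with an
  explicit test count `m` (which may exceed the supplied p-vector).
* REML grid spans $\lambda \in \{0\} \cup 10^{[-3,3]}$ (quarter-decade
  steps); the boundary $\lambda = 0$ is kept if it beats the interior
  optimum, which also makes the unrelated-subjects case exactly OLS.
* p = 0 inputs to the node-score map are capped at $10^{-30}$ with a
  warning; quantiles are computed with `lower.tail = FALSE` to avoid
  catastrophic cancellation.
* ΔAge-vs-CA independence checks report "degenerate" (no warning) when the
  correlation is undefined, e.g. constant ΔAge.
* Pipeline summaries are written with fixed JSON formatting, so identical
  seeds produce byte-identical output files.

# Problem sizes used by the shipped checks

Checks run at the sizes that make their question answerable on a desk
machine, chosen as part of the package design: KD recovery and the
generator-condition checks at the full default n = 2000 over 10 seeds; null
scan calibration as 100 scans of 1000 features on 300 subjects in 100
families; mediation contrast at n = 500 over 10 seeds; the end-to-end
pipeline at n = 400–600 subjects and 200–600 genes; the acceptance script at
the full default configuration with $10^5$ permutations.

# Known limitations

* The Wald p-values carry no small-sample degrees-of-freedom correction;
  with few families they are anti-conservative (see the calibration note
  above).
* `s2_BA` estimation subtracts two noisy quantities; weak panels can trigger
  the fallback, which over-weights the biomarker side.
* The module search is greedy: it certifies per-step maximality, not global
  optimality of the final module.
* Attenuation is a directional flag, not a mediation effect size; no causal
  claim is implied.
* The family random effect is exchangeable within family; a general kinship
  matrix is accepted but the generator never produces one.
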