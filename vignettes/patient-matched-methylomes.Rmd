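---
title: "Patient-matched differential methylomes: model, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-matched differential methylomes: model, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpair)
```

## Why a pairwise, per-patient model

Methylomes of multiple metastases from one patient resemble each other far
more than metastases of the same tissue from different patients. Any
cross-patient contrast therefore mixes the signal of interest (site-specific
reprogramming) with dominant patient effects. `methpair` removes the patient
effect by construction: the unit of analysis is the *pair difference
profile*, the chromosome-ordered sequence of

$$x_t = \text{log2ratio}_{\text{intra}}(t) - \text{log2ratio}_{\text{extra}}(t)$$

over the CpGs shared by the two samples of a patient. CpGs missing in either
sample are dropped (the HMM has no missing-data emission), positions are
1-based array coordinates, chromosomes follow the natural order
chr1..chr22, chrX, chrY, and position ties are broken by CpG identifier.

## The three-state HMM

Neighbouring CpGs carry strongly correlated differences — `autocorr_curve()`
on any simulated (or real) profile shows lag-1 autocorrelation far above the
within-chromosome permutation null of `permutation_band()`. The classifier
is therefore a first-order three-state HMM with Gaussian emissions rather
than a per-CpG threshold:

* states `-`, `=`, `+` for decreased, unchanged, increased methylation in
  the intracranial sample, in fixed order with $\mu_- < \mu_= < \mu_+$;
* emission $x_t \mid S_t = i \sim N(\mu_i, \sigma_i^2)$;
* one shared parameter set trained jointly over **all** chromosome
  sequences of **all** pairs, so calls remain comparable across patients;
* the start distribution applies independently at every chromosome start
  (chromosomes are treated as independent sequences);
* per-CpG assignment by posterior decoding, i.e. the state maximising the
  forward–backward marginal $\gamma_t(i)$.

Defaults (log2-ratio units): initial means $(-3, 0, 3)$, initial SDs
$(0.3, 0.5, 0.3)$, start probabilities $(0.1, 0.8, 0.1)$ reflecting that
most CpGs do not change, and every transition-matrix row initialised to
$(0.1, 0.8, 0.1)$.

### MAP (Bayesian) Baum-Welch

Training must keep the two altered states anchored at their biologically
interpretable positions even when altered CpGs are rare. Each state carries
a conjugate Normal–Inverse-Gamma prior

$$\mu_i \mid \sigma_i^2 \sim N\!\big(m_i, \sigma_i^2/\kappa_i\big), \qquad
\sigma_i^2 \sim \text{InvGamma}(\alpha_i, \beta_i), \quad
\beta_i = (\alpha_i + 1)\, s_i^2,$$

so the prior mode of $\sigma_i^2$ is exactly the configured $s_i^2$.
Defaults: $\kappa = (10^6, 10^3, 10^6)$ and $\alpha = (5\times10^5, 10,
5\times10^5)$ — the altered states are effectively pinned (the data mass of
a genome-scale run is small against $\kappa$ and $2\alpha$), the unchanged
state adapts freely. The M-step maximises the EM surrogate plus log prior
*exactly*:

$$\mu_i \leftarrow \frac{\kappa_i m_i + \sum_t \gamma_t(i)\, x_t}
{\kappa_i + \sum_t \gamma_t(i)}, \qquad
\sigma_i^2 \leftarrow \frac{\sum_t \gamma_t(i)(x_t-\mu_i)^2
+ \kappa_i(\mu_i - m_i)^2 + 2\beta_i}
{\sum_t \gamma_t(i) + 2\alpha_i + 3}.$$

The $\kappa_i(\mu_i-m_i)^2$ term and the "+3" (rather than "+2") in the
denominator come from the $\sigma$-dependence of the conditional mean
prior; we use the exact joint maximiser because it is what guarantees the
monotonicity of the penalized log-likelihood
$\log p(x \mid \theta) + \log p(\theta)$ that `fit_diffmeth_hmm()` records
per iteration and the test suite asserts (slack $10^{-8}$). For pinned
states the difference from the simpler plug-in update is $O(1/\alpha)$ —
numerically invisible at the default hyperparameters. Setting
$\kappa_i = 0$ drops the mean prior; `shape_sds = 0` is read as a flat
(improper) variance prior and drops the Inverse-Gamma term, so with both at
zero the updates are exactly maximum-likelihood Baum-Welch (verified
against an independent plain-R implementation in the tests). Start and
transition probabilities always get plain ML updates from expected counts;
only their initial values are part of the reference configuration, and
the hyperparameter search that originally produced the default
$\kappa, \alpha$ values is out of scope here — those values are simply the
defaults.

Numerical choices: scaled (Rabiner) forward–backward recursions, stable for
$10^5$-CpG chromosomes; emission densities floored at $10^{-300}$; a
variance floor of $10^{-6}$ prevents collapse when a state captures a
single point; a state with no posterior mass *and* no prior support
($\kappa_i = 0$) raises an error rather than dividing by zero. Convergence:
relative change of the penalized log-likelihood below `tol = 1e-4`, at most
`max_iter = 500` iterations; hitting `max_iter` flags the fit as
unconverged instead of throwing. After training, states are relabelled if
necessary so that the means are increasing — a guard against label
switching when the priors are weakened, inert at the defaults. An exact
posterior tie at decoding resolves to `=`: no alteration is claimed without
a posterior majority.

### Conformity

`conformity()` is the percentage of shared CpGs on which two pairs' decoded
states agree, computed over *all* shared CpGs (not only altered ones — the
restricted variant would exaggerate differences between nearly-unaltered
pairs). `conformity_group_test()` compares within-patient against
between-patient conformities with a one-sided Wilcoxon rank-sum test, exact
for ten or fewer values without ties, otherwise the normal approximation
with tie correction.

## The synthetic cohort

`simulate_cohort()` is the package's study population. Its defaults are the
conditions the analysis is designed for: 14 patients contributing
$(1,1,2,2,3,1,1,2,2,1,1,2,1,4)$ pairs (24 pairs), emission means
$(-3,0,3)$ and SDs $(0.3,0.5,0.3)$, start/stationary distribution
$(0.1,0.8,0.1)$, self-transition weight $0.9$. The transition matrix is
built as $A = s I + (1-s)\mathbf{1}\pi^\top$, which makes the configured
$\pi$ the *exact* stationary law — so target altered fractions translate
directly into realized fractions (binomial-with-autocorrelation tolerance
$(1+s)/(1-s)$ times the i.i.d. variance).

Sample-level synthesis draws a per-patient baseline profile
(`patient_effect_sd`, default 2 log2-ratio units) plus per-sample tissue
noise (`tissue_effect_sd`, default 0.25); the extracranial sample is
baseline + noise and the intracranial sample is the extracranial sample
plus the pair delta, so the profile delta equals the literal sample
difference to the bit. The 8:1 effect ratio makes both samples of a patient
co-cluster under Manhattan/ward.D2 — the patient-dominated regime the
clustering checks exercise. Multiple pairs of one patient share a base
truth path with 5% label noise (`label_noise`), emulating histologically
distinct regions of one metastasis; this is what makes within-patient
conformity exceed between-patient conformity.

What the generator does **not** emulate: beta-value preprocessing and probe
filtering (inputs are taken as clean log2-ratios), copy-number or mutation
co-variation, batch effects, and — importantly — *cross-patient recurrence*
of alterations: truth paths are independent across patients, so no CpG is
systematically altered in most patients and candidate counts at the
"more than 50% of patients" rule are near zero on default cohorts. Tests of
the recurrence logic therefore use planted fixtures; green tests show the
selection machinery is correct, not that real cohorts contain such genes.
The same independence means simulated expression rarely yields genome-wide
significant per-gene shifts (a gene's shift flips sign with its per-patient
methylation direction); the coupling checks work at the gene-patient
instance level instead.

### Annotation geometry

`simulate_annotations()` tiles a deliberately *sparse* regulatory genome:
CpG spacing averages 1.5 kb, each gene has a single-CpG body, a short
(400 bp) promoter that only sometimes captures the upstream CpG, and a
single-CpG enhancer about one expected state-run-length (10 CpGs)
downstream; successive genes are 20 CpGs apart. The reason is statistical:
the enrichment test is per-CpG Fisher, which assumes independent CpGs,
while HMM states come in runs of about 10 CpGs at the default persistence.
With dense gene bodies, each gene would contribute a block of fully
correlated CpGs and the Fisher test would be badly anticonservative; with
this geometry each gene contributes roughly one independent state draw, and
the neutral-pathway false-flag rate in the test suite is consistent with
its nominal level. EPIC-style dense annotations would need a block-aware
test (e.g. gene-level collapsing) — a known limitation of the per-CpG
test on real arrays.

The constructed-enriched pathway targets a CpG-level odds ratio
(`enrich_odds`, default 5) for decreased methylation against the reference
pair's truth by mixing altered-body genes with background genes in the
computed proportion; a gene-level sampling scheme turned out to undershoot
the intended CpG-level odds substantially (dilution by promoter/enhancer
CpGs plus saturation of the altered-gene pool), which is why the
composition is computed rather than sampled with weights. The neutral
pathway and the background pathways are uniform draws, independent of the
truth. The default pathway size (60 genes) comes from the power
calculation: at odds 5 and 5000 CpGs the enriched pathway should be
detected at $q < 0.05$ with margin, while the neutral one stays at its
nominal false-flag rate.

## Enrichment, candidates, clinical and expression analyses

* **Background universe** for each Fisher test: all CpGs measured in that
  pair (the natural universe when every pair is analysed on its own);
  directions are tested separately, one-sided for overrepresentation.
* **FDR families**: BH adjustment runs within one pair and one panel (gene
  regions; island context; transposons; pathways), mirroring how per-pair
  enrichment panels are read; the family scope is configurable by passing
  category subsets.
* **Consensus and ranking**: per patient, a CpG's consensus is the strict
  majority of decreased vs increased calls across the patient's pairs,
  ties counting as unchanged (which excludes non-decidable CpGs); each
  patient then contributes at most one vote per direction to the CpG
  ranking. Gene candidates require at least one linked CpG (promoter,
  enhancer or gene-body links only) at the patient threshold; a gene may
  appear in both direction lists if distinct CpGs support each — the
  general contract, even though thresholded real cohorts may never produce
  such a gene. Decreasing the threshold can only grow the candidate set.
* **Clinical**: the per-patient burden `n_diff` averages over the
  patient's pairs; the balance score is undefined (reported `NA`) when no
  CpG is altered. The clinical scatter tables add descriptive Spearman
  correlations, clearly labelled exploratory — no formal inference is
  attached, matching the descriptive use of these plots.
* **Expression**: per-gene one-sample t-tests on intra-minus-extra
  log2-ratios are two-sided (sidedness is not dictated by the three
  relation classes), BH-adjusted across genes; only FDR hits get the
  paired follow-up test, with per-patient averaging over multiple regions
  so each patient counts once. Zero-variance ratio vectors are flagged,
  not tested. Relation classes: (i) decreased methylation with increased
  expression, (ii) decreased/decreased, (iii) increased/decreased;
  increased/increased falls outside the canonical classes and is reported
  as `"other"`.

## Cluster stability

`bootstrap_support()` implements the multiscale bootstrap for
Manhattan/ward.D2 trees (ward.D2: squared dissimilarities internally,
heights on the original scale). Features are resampled with replacement at
relative sizes $r \in \{0.5, 0.6, \ldots, 1.4\}$ (the standard ten-scale
grid); $BP_r$ is the fraction of bootstrap trees containing a node's exact
leaf set; the approximately unbiased value comes from the weighted
least-squares fit $z(BP_r) = d\sqrt{r} + c/\sqrt{r}$ with
$z = \Phi^{-1}(1 - BP_r)$ and $AU = 100\,\Phi(c - d)$, the standard
signed-distance/curvature model. Counts are clamped half a replicate away
from 0 and $n_{boot}$ for finite $z$; a node present in every replicate at
every scale reports $BP = AU = 100$ directly, a node never observed
reports $BP = 0$ with missing AU, and a degenerate fit falls back to BP
only (flagged in `au_ok`). The desk-scale default is `n_boot = 1000`
(10,000 is supported and simply slower).

## Problem sizes used by tests and the acceptance script

Chosen so the full suite runs comfortably on one CPU: forward–backward
oracle checks enumerate all $3^n$ paths for sequences up to length 8;
parameter recovery trains on the default cohort (24 pairs × 2 chromosomes
× 5000 CpGs); autocorrelation uses one 10,000-CpG chromosome with 1000
permutations; enrichment power/type-I runs 20 seeded 5000-CpG cohorts;
cluster stability bootstraps a 300-feature, 28-sample cohort 1000 times
per scale; Fisher oracle checks cover every 2×2 table with total at most
30.

## Known limitations

* The prior parameterisation realises the reference hyperparameter
  names and values within a documented conjugate scheme, validated by its
  limits
  (pinning as $\kappa \to \infty$, ML as the priors vanish) and by
  parameter recovery.
* Per-CpG Fisher enrichment ignores spatial correlation of calls; on dense
  real annotations it is anticonservative (see the geometry discussion).
* The simulator has no cross-patient recurrence mechanism, so
  population-level candidate counts are not emulated, only the selection
  logic.
* Survival modelling, GO enrichment against live databases, array
  preprocessing and probe filtering are out of scope; inputs are assumed
  normalized.
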