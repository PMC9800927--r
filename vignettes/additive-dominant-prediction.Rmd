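---
title: "Additive-dominant genomic prediction for clonal crops with gpdom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive-dominant genomic prediction for clonal crops with gpdom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpdom)
```

## The problem

Clonally propagated crops such as cassava carry high heterozygosity, and for
yield traits a large share of the genetic variance comes from dominance
deviations rather than breeding values. Two consequences matter for a
breeding program: (i) clones are advanced on their *genotypic* value (the
clone is propagated as-is, so dominance is inherited wholesale), while
parents are chosen on their *breeding* value (only additive effects
transmit); and (ii) prediction models that ignore dominance can misallocate
variance and lose accuracy on dominance-dominated traits. `gpdom` implements
a complete two-stage genomic evaluation for this setting: trial-level mixed
models, deregressed BLUPs, additive and dominance genomic relationship
matrices, G-BLUP/RKHS/Bayesian marker-effect predictors, shared
cross-validation, and selection-gain analytics.

## Stage one: from plots to deregressed BLUPs

Phenotypes come from many unbalanced location-year trials. For each trait we
fit, by REML (through lme4),

$$y_{ijl} = \mu + c_i + \beta_j + r_{l(j)} + \varepsilon_{ijl},$$

with clone $c_i \sim N(0, \sigma^2_c)$ random, the location-year
combination $\beta_j$ fixed, and replicates nested in trials random.
Location-years carrying a single record would leave the fixed design
singular and are dropped with a warning. The per-clone prediction error
variance (PEV) comes from the conditional variances of the random-effect
solutions, giving the reliability $r^2_i = 1 - \mathrm{PEV}_i/\hat\sigma^2_c$
and the deregressed BLUP $y_{d,i} = \mathrm{BLUP}_i / r^2_i$, which removes
shrinkage so that stage two is not doubly regressed. Clones with
$r^2_i < 0.05$ (default, overridable) are excluded: near-zero reliabilities
turn the quotient into noise amplification. Deregressed records enter stage
two unweighted; a reliability-weighting option exists but is off by default.

Dry matter content is measured gravimetrically: a root sample is weighed in
air (WA) and submerged (WW), and
$\mathrm{DMC}(\%) = \frac{WA}{WA - WW} \times 158.3 - 142$. Values outside
the plausible 17–38% amplitude are flagged (not clamped). Dry root yield is
$\mathrm{FRY} \times \mathrm{DMC}/100$.

## Marker codings and relationship matrices

Dosages count the major allele (markers are orientation-flipped so
$p \ge 0.5$ when loaded). After call-rate ($\ge 0.90$) and MAF ($> 0.05$,
strict) filtering and mean imputation ($2p_i$ per missing call), three
designs are built per marker with major-allele frequency $p$ and $q = 1-p$:

| genotype | additive $Z$ | classical dominance $H$ | genotypic dominance $H^*$ |
|---|---|---|---|
| MM | $1$ | $-2q^2$ | $-2pq$ |
| Mm | $0$ | $2pq$ | $p^2+q^2$ |
| mm | $-1$ | $-2p^2$ | $-2pq$ |

The additive design is column-centered by default (subtracting $2p-1$), so
GEBVs are deviations; centering moves only the intercept. The classical
(breeding) dominance coding has zero mean and zero covariance with the
additive coding under Hardy–Weinberg proportions, which is what makes the
additive and dominance variance components separable; the genotypic (Su)
coding parameterizes total genotypic dominance instead. Mean-imputed
fractional dosages are rounded to the nearest class for the dominance
designs only — the classes are categorical, while the additive design can
carry the expectation.

The matrices are
$G = ZZ^\top / 2\sum_i p_i q_i$ (VanRaden),
$D = HH^\top / \sum_i (2p_iq_i)^2$ (classical),
$D^* = H^*H^{*\top} / \sum_i 2p_iq_i(1 - 2p_iq_i)$ (genotypic), each scaled
so the expected diagonal is ~1 under Hardy–Weinberg proportions; the
denominators are exposed as overridable constants. The RKHS kernel is
$K = \exp(-h \cdot d^2_{ij} / \mathrm{median}(d^2))$ on squared Euclidean
distances between $\{-1,0,1\}$ marker rows, median taken over off-diagonal
entries (the diagonal would drag the median toward zero); $h = 1$ by
default, and a plain-distance switch exists since kernel conventions vary.
Before fitting, matrices are conditioned to positive semidefiniteness by a
diagonal shift of $|\lambda_{\min}| + 10^{-6}$ only when needed — diagonal
inflation preserves the off-diagonal structure that eigenvalue truncation
would distort.

## Stage two: G-BLUP, RKHS and the REML engine

The additive-dominant model on deregressed BLUPs is
$y_d = J\mu + Za + Hd + \epsilon$ with $a \sim N(0, G\sigma^2_a)$,
$d \sim N(0, D\sigma^2_d)$, $\mathrm{COV}(a,d) = 0$, and one record per
clone (incidences are selections of kernel rows). RKHS is the same solver
with the single kernel $K$; the genotypic-value variance plays the role of
$\sigma^2_g$. Variance components are estimated by average-information REML:
the AI step is tried first (with step-halving when a full step overshoots),
and an EM step — guaranteed uphill but slow — is the fallback; components
pinned at the $10^{-8}$ boundary with an inward gradient are held fixed so
they cannot ill-condition the AI system. The response is standardized to unit
variance during estimation so the clamp and tolerances are scale-free.
Convergence requires a relative component change below $10^{-6}$ or a
restricted-log-likelihood change below $10^{-8}$, within 500 iterations —
fits whose residual variance sits at the zero boundary (kernels rich enough
to interpolate the deregressed BLUPs) approach it geometrically and use a
few hundred. Solutions for all kernel clones, including
genotyped-unphenotyped ones, come from the converged covariance structure —
this is also how cross-validation folds are predicted. GEBV is the additive
solution vector; GEGV is the sum of genetic solutions ($\hat a + \hat d$, or
$\hat g$ for RKHS).

Genomic heritabilities are reported as
$\hat h^2 = \hat\sigma^2_a / (\hat\sigma^2_g + \hat\sigma^2_e)$ and
$\hat H^2 = \hat\sigma^2_g / (\hat\sigma^2_g + \hat\sigma^2_e)$ with
$\hat\sigma^2_g$ the total genomic variance. Because stage two runs on
deregressed clone means, its residual reflects deregression noise, not plot
noise; when we compare recovered heritabilities against plot-level targets
(below) we therefore combine the stage-two genetic components with the
stage-one plot residual.

```{r heritability-example}
# printed variance components -> heritabilities, e.g. a dominance-dominated
# trait: var_a = 6.4, var_g = 17.9, var_e = 28.5
round(heritabilities(6.4, var_g = 17.9, var_e = 28.5), 3)
```

## Bayes B and Bayes C-pi

The marker-effect models put a point mass at zero (probability $\pi$) on
each additive (and optionally classical-dominance) effect. Bayes B gives
every marker its own scaled-inverse-$\chi^2$ effect variance (df 5); the
scale is solved so the prior genetic variance matches half the phenotypic
variance split equally across effect classes — a weakly informative default
exposed in `mcmc_config()`. Bayes C-pi shares one effect variance per class
and samples $\pi$ from its Beta posterior under a uniform prior. Its
per-marker prior scale adapts to the current $\pi$ (base scale divided by
$1-\pi$), keeping the prior on the *total* genetic variance: without this,
$\pi$ and the common variance trade off indecisively on weakly informative
data. The $\pi$ chain starts sparse (0.9). The in-pipeline Bayes C-pi
estimate is the default Bayes B prior per trait and model. Default chains:
20,000 iterations, 4,000 burn-in, thinning 10, all reproducible given the
seed (the sampler uses R's RNG).

Genomic variances are accounted as the per-iteration variance across clones
of the genetic values ($Za$, $Hd$, and their sum), averaged over the kept
samples — a value-based convention, documented so users comparing against
$\sum 2pq\alpha^2$-style formulas know the difference. Convergence is
monitored on the residual-variance chain with the Raftery–Lewis run-length
diagnostic (via coda), reporting the dependence factor relative to an
independent chain.

## Cross-validation and method comparison

A single seeded 5-fold × 3-repetition plan (balanced, hash-stamped) is
served to every method, so the comparison is paired at the fold level. Each
fold is predicted from the remaining four; predictive ability is
$\hat r = \mathrm{COR}(\mathrm{Pred}_{Val}, \mathrm{BLUP}_{Val})$ against
the stage-one BLUPs of the held-out clones (a deregressed-BLUP switch
exists), using GEBV for additive models and GEGV for additive-dominant and
RKHS models. Dispersion bias
$\hat b = \mathrm{COV}(\mathrm{Pred}_{Train}, \mathrm{BLUP}_{Train}) /
\mathrm{VAR}(\mathrm{Pred}_{Train})$ is computed on the training partition
as defined (a validation-set variant is available, off by default); 1 means
correctly dispersed predictions. Methods are compared per statistic with the
mixed model `value ~ method + (1 | rep:fold)` fitted by ML, a
likelihood-ratio $\chi^2$ for the method effect, and Tukey all-pairs
contrasts rendered as compact letters (multcomp); missing bias cells are
excluded pairwise.

## Selection analytics

For a selection proportion $sp$, the genomic selection differential is the
mean stage-one BLUP of the top $\lceil sp \cdot n \rceil$ clones ranked by
GEBV/GEGV, minus the overall mean; phenotypic selection ranks by the BLUP
itself. BLUP is the merit scale throughout — expected gain is a difference
of predicted clone means, and ranking ties are broken by clone id for
determinism. Shortening the breeding cycle by the genomic-to-phenotypic
cycle-length ratio GB/PB gives
$\mathrm{Efficiency} = SD_{GS} / (SD_{PS} \times GB/PB)$: genomic selection
per unit time beats phenotypic selection when this exceeds 1. Selection
coincidence between any two rules is Cohen's kappa on the binary
selected/unselected codes; two identical constant selections have
$\kappa = 1$, two different constant ones $\kappa = 0$ with a warning.

## The synthetic panel generator

`sim_config()` emulates the study system: ~900 heterozygous clones,
thousands of SNPs with frequencies uniform on [0.05, 0.95], ~20 unbalanced
location-year trials with 3 replicates, a 0.3 clone-trial incidence and 5%
lost plots. Trait profiles carry plot-level variance targets calibrated to
additive-dominant partitions estimated for cassava root traits —
`FRY_like` (6.4 / 11.5 / 28.5 for $\sigma^2_a/\sigma^2_d/\sigma^2_e$,
dominance-dominated, $h^2 \approx 0.14$, $H^2 \approx 0.39$), `DRY_like`
(0.71 / 0.78 / 2.55) and `DMC_like` (1.92 / 0.18 / 1.92,
additive-dominated, $h^2 \approx 0.48$, $H^2 \approx 0.52$). Trial and
replicate variances default to $\sigma^2_e$ and $\sigma^2_e/4$ — location-year
shifts of the same order as plot noise are typical of multi-year root-yield
series. Effects are simulated on the classical (orthogonal) scale so the
additive and dominance targets are well-defined — a genotypic-scale switch
exists for contrast experiments — and marker coefficients are rescaled so
realized variances hit the targets exactly. DMC plots are emitted with
back-solved WA/WW weights so the gravimetric formula recovers the simulated
value to machine precision. An inbreeding parameter perturbs genotype
frequencies away from Hardy–Weinberg ($F < 0$ gives the excess
heterozygosity of clonal germplasm; default 0).

What the generator does *not* emulate: linkage disequilibrium (markers are
independent, so there are no local haplotype effects and marker-based
kinships are better behaved than on real GBS data), pedigree or family
structure, genotype-by-environment interaction, and epistasis. Passing
recovery tests on these panels therefore demonstrates the estimators'
internal consistency under their own assumptions, not robustness to the LD,
structure and G×E of real germplasm.

```{r worked-example, eval = FALSE}
cfg <- sim_config("FRY_like", n_clones = 200, m_markers = 500, seed = 1)
panel <- simulate_panel(cfg)
s1 <- fit_stage1(panel$trials, "FRY")
rec <- deregress(s1)
des <- build_designs(impute_mean(panel$genotypes))
fit <- fit_gblup(setNames(rec$dblup, rec$clone),
                 list(additive = condition_psd(additive_G(des)),
                      dominance = condition_psd(dominance_classical(des))))
heritabilities(fit)
```

## Numerical and design choices

* **Variance-component clamp** at $10^{-8}$ keeps $V$ invertible while
  letting components vanish effectively; boundary components are excluded
  from AI updates.
* **Heritability recovery scale.** Simulation checks compare
  $\hat\sigma^2_a/(\hat\sigma^2_g + \hat\sigma^2_{e,\mathrm{plot}})$
  (stage-two genetic components, stage-one plot residual) against the
  configured plot-level targets; both numerator and denominator are
  estimated, nothing is read from the simulation truth.
* **Problem sizes.** The shipped checks run at n = 600 clones × 3,000
  markers × 6 trials for heritability recovery (median of 10 seeds),
  n = 400 × 1,500 for the directional cross-validation contrast (3 panels
  per profile), n = 200 × 1,000 × 5,000 iterations for Bayes B null
  calibration, and a full six-method pipeline at n = 200 × 500 with 2,000
  iterations. These sizes put Monte-Carlo error comfortably inside the
  asserted margins while a full run stays in the minutes range.
* **Sampling error of $\hat h^2$.** On an unrelated HWE panel the standard
  deviation of the G-BLUP $\hat h^2$ grows like $\sqrt{2m}/n$, so per-seed
  windows of ±0.1 are only meaningful when $m \lesssim n^2/200$; median-based
  checks are used at larger marker counts.
* **Ties and determinism.** Fold assignment, marker order, clone order and
  selection cuts are all deterministic given seeds; selection ties break on
  clone id.
* **Deregression floor** 0.05 reliability; **MAF rule** strict (`> 0.05`
  retained); both logged and overridable.

## Limitations

Single-trait models only (no multi-trait or G×E covariances); no pedigree
(P-BLUP) or single-step matrices; imputation is marker-mean (an LD-aware
imputer should precede the package on real data); Bayes samplers are
single-chain (run several seeds for between-chain diagnostics); the method
comparison assumes complete fold blocks per method.
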