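---
title: "Models and methods behind epiaccel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epiaccel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiaccel)
```

epiaccel implements a complete epigenetic-aging analysis for blood
methylation data: DNAm age estimation, blood-cell deconvolution, the
universal / intrinsic / extrinsic age-acceleration statistics, and the group
and meta-analysis layer on top. Because the cohorts this kind of analysis is
usually run on are restricted, the package is built around a synthetic
cohort generator with exact ground truth; this vignette explains the
generative model, the estimators, the defaults and the numerical choices,
and what the simulation-based verification does and does not establish about
real data.

## The generative model

A simulated cohort is drawn as follows, per sample $i$:

1. **Age**: $\mathrm{age}_i \sim \mathrm{Uniform}(40, 90)$ years — the adult
   age span typical of blood methylation aging studies.
2. **Intrinsic epigenetic age**:
   $e_i = \mathrm{age}_i + \delta_{g(i)} + \gamma\,\mathbf{1}[\text{male}] +
   \varepsilon_i$, with group offset $\delta_g$ (years), sex effect
   $\gamma = 0.8$ y (the order of magnitude reported for sex effects on
   epigenetic age), and $\varepsilon_i \sim N(0, 3^2)$ y. The 3-year SD
   matches the typical discrepancy between well-calibrated clocks and
   chronological age.
3. **Cell composition**: mean composition
   $m_i = \mathrm{softmax}(\text{base} + \text{slope} \cdot \mathrm{age}_i +
   \text{shift}_{g(i)})$ over eight compartments (naive CD8+ T, exhausted
   CD8+ T, CD4+ T, NK, B, plasmablast, monocytes, granulocytes), then
   $w_i \sim \mathrm{Dirichlet}(\kappa\, m_i)$ with $\kappa = 150$.
4. **Probes**: *clock* probes move with the transformed intrinsic age
   identically in all cell types,
   $\mu_p(e) = \mathrm{clamp}_{[0,1]}(\alpha_p + \beta_p F(e))$; *signature*
   probes are cell-type-specific constants whose "on" level exceeds all
   other cell types by at least 0.6 beta units; *noise* probes are flat.
   Defaults: 120 clock, 80 signature, 100 noise probes.
5. **Observation**: $x_{pi} = \mathrm{clamp}_{[0,1]}(\sum_c w_{ic}\mu_{pc} +
   N(0, 0.02^2))$.

Two design principles matter. First, **intrinsic and extrinsic effects are
channelled separately**: group intrinsic offsets enter only through $e_i$
(shared by all cell types), and extrinsic effects enter only through the
composition logits. This is exactly the dichotomy the intrinsic/extrinsic
acceleration measures are meant to resolve, so the generator provides a
clean ground truth for testing which measure responds to which
perturbation. Second, **one probe universe is shared** across the training
cohort and all analysis datasets of a run, so a clock trained once transfers
across datasets and multi-dataset meta-analysis is meaningful.

### Composition trajectories

No consensus quantitative trajectory exists for how each compartment's
proportion moves with age, so the slopes are free configuration parameters.
The defaults encode the canonical immunosenescence picture at
literature-plausible magnitudes: naive CD8+ T cells decline from roughly 5%
of blood at 40 y to about 1% at 80 y ($-0.04$ logit/y); exhausted
(CD28−CD45RA−) CD8+ T cells expand markedly in the elderly ($+0.05$
logit/y); plasmablasts rise modestly ($+0.02$ logit/y); the remaining
compartments are held flat. Baseline logits put the mid-age (65 y)
composition near granulocytes 55%, CD4+ T 15%, monocytes 8%, NK 5%, B 5%,
naive CD8+ T 5%, exhausted CD8+ T 2%, plasmablast 1%. The Dirichlet
concentration $\kappa = 150$ gives a granulocyte-fraction SD of about 0.04
at fixed age — individual variation on the tighter side of what whole-blood
deconvolution shows, chosen so composition is a measurable signal rather
than the dominant noise source.

### What the generator does not emulate

Infinium type I/II probe chemistry and dye bias, batch and chip effects,
SNPs under probes, detection-p missingness patterns, non-blood tissue
panels, and a naive/memory split of the CD4+ T compartment. Beta-scale
noise is additive Gaussian with clamping — chosen for transparent moments —
rather than logit-normal. Consequently, passing tests establish the
*statistical machinery* (the estimators respond to the signals they are
defined to measure, at realistic noise), not robustness to array
artefacts; conclusions about a real cohort still require the usual
platform-level QC.

## Preprocessing

Beta values follow the standard offset ratio
$\beta = \max(M,0)/(\max(M,0)+\max(U,0)+100)$; the offset (default 100
fluorescence units) keeps low-intensity probes away from extreme ratios,
and `betas_to_intensities()` provides the exact algebraic inverse used in
round-trip tests.

Published clock software references each sample to a gold standard as part
of a BMIQ-based normalization of the two Infinium probe designs. The
simulator deliberately has no probe-design axis, so the package implements
the contract rather than the chemistry: `normalize_to_gold_standard()` is a
per-sample quantile calibration that maps each sample's empirical beta
distribution (over the probes shared with the gold profile) onto the gold
distribution. The gold profile is the clock's training-mean profile — the
only canonical profile a fitted clock carries. The map is rank-preserving,
idempotent, and exact on the gold sample itself. The pipeline leaves this
step off by default in simulate mode: forcing every sample onto one fixed
marginal distribution discards between-sample location signal that the
simulated clock probes carry, and the harmonization it provides is aimed at
externally loaded data (`normalize = TRUE` in the config).

Probe blacklisting (`drop_probes()`) and constant-mean imputation
(`impute_missing_clock_probes()`) implement the SNP-probe robustness
re-analysis: removed clock CpGs re-enter as constants (their training
means), shifting all predictions equally and thus cancelling in the
acceleration residuals.

## The clocks

The age transform $F$ is logarithmic below the adult age $A$ and linear
above, $F(\mathrm{age}) = \log(\mathrm{age}+1) - \log(A+1)$ for
$\mathrm{age} \le A$ and $(\mathrm{age}-A)/(A+1)$ above — the published
form of the pan-tissue clock's calibration, with $A = 20$ y configurable.
Its exact inverse converts linear predictors back to years.

Two clocks are trained by elastic net (`glmnet`, mixing $\alpha = 0.5$,
penalty by 10-fold cross-validated MSE at `lambda.min`, fold assignment
fixed by seed):

- the **primary clock** on clock + noise probes — a pan-tissue-style,
  cell-intrinsic age estimator;
- the **blood clock** on *all* probes including the cell-type signatures, so
  it partially tracks composition. This mirrors why blood-trained clocks
  are composition-sensitive, and it is the EEAA input.

The pipeline trains both on a separately simulated neutral training cohort
(single group, default $n = 300$) sharing the analysis probe universe,
mirroring how published clocks are external to the cohorts they score. In
simulate mode the probe-class labels come from the generator's truth; with
loaded data the user supplies the probe subsets (defaulting to all probes).

## Deconvolution

Broad cell proportions are estimated per sample by non-negative least
squares against the signature-probe reference matrix (Lawson–Hanson NNLS via
`pracma::lsqnonneg`). The raw coefficients are reported alongside
sum-normalized proportions, and no sum-to-one constraint is imposed: the
reference-based projection interprets coefficients as cell "counts", and
IEAA consumes the raw scale. Granulocytes are one compartment (the
methylation references cannot separate neutrophils from eosinophils and
basophils). The naive CD8+ T, exhausted CD8+ T and plasmablast scores come
from penalized estimators trained on the simulator's known abundances —
functional stand-ins for the advanced estimators shipped with published
clock software, whose coefficients are not public. The exhausted-CD8 score
is taught on the percent scale; score units are otherwise arbitrary, which
is harmless downstream because the Klemera–Doubal composite is invariant to
marker rescaling.

## Acceleration measures

- **AgeAccel**: residual of DNAm age from a natural cubic spline (df = 4,
  least squares) of DNAm age on age fitted in the designated reference
  group only; with fewer than 30 reference samples a linear fit is used.
  The reference group's mean acceleration is zero by construction.
- **IEAA**: OLS residual of DNAm age on age and the seven cell covariates
  (naive CD8+ T, exhausted CD8+ T, plasmablast scores; CD4+ T, NK,
  monocyte, granulocyte raw NNLS coefficients). Orthogonality to every
  regressor is exact by OLS algebra.
- **EEAA**: the Klemera–Doubal composite
  $BA = \sum_j (x_j - q_j) k_j / s_j^2 \big/ \sum_j k_j^2/s_j^2$ over the
  blood-clock age and the three immunosenescence markers, residualised on
  age. The variant used is the pure weighted average of the four markers
  (no chronological-age augmentation term), matching the "weighted
  average" construction; markers enter unstandardized, since $s_j$ already
  provides the scaling. The calibration $(q_j, k_j, s_j)$ is an OLS
  marker-on-age fit computed on each analysis dataset itself (a frozen
  calibration can be reused via `write_kd_model()`/`read_kd_model()`).
  Markers whose age slope fails $|t| > 2$ carry no usable age signal and
  are excluded with a warning; $s_j$ is floored at $10^{-6}|k_j|$ so a
  noiseless, perfectly linear marker cannot produce an infinite weight.

On the fitting cohort all three measures are mean-zero and numerically
uncorrelated with age — definitional invariants that the test suite checks
to $10^{-6}$.

Because both simulated clocks learn the *same* intrinsic process $e_i$ from
the same probe universe, IEAA and EEAA share more signal here than across
two independently derived clocks on real data; their correlation on default
cohorts runs about 0.65–0.85, versus the moderate (≈0.5) correlations
typical of real blood datasets. The package's sanity band for this
correlation is (0.2, 0.9).

## Group statistics and meta-analysis

Group comparisons use one-way ANOVA (equivalently the squared pooled-variance
t statistic for two groups) or Kruskal–Wallis with midrank tie correction,
reported with per-group mean ± 1 SE. Raw p-values are reported without
multiple-testing correction, matching how such group comparisons are
conventionally presented. Two-group contrasts are converted to signed z
scores (Welch form, sign fixed by the configured group order) and combined
across datasets by Stouffer's method with $\sqrt{n_i}$ weights by default
(equal weights available — the weighting scheme is a configuration point,
not a fixed convention). Mean differences are pooled by inverse-variance
fixed effects with a normal 95% CI. Covariate models are OLS with factor
covariates expanded against their first level; binary outcomes use
maximum-likelihood logistic regression with Wald tests, and complete
separation is detected and raised as an error rather than reported as an
absurd estimate.

## Numerical and degenerate-input choices

- RNG: one master seed; per-stage substream seeds are drawn once under it
  (`sample.int`), so every stage is independently reproducible and partial
  reruns are stable. Library code restores the caller's RNG state.
- Quantile calibration resolves ties by stable order, making it idempotent
  and exact on the gold sample.
- Zero-variance probes receive zero clock coefficients; constant covariates
  are dropped with warnings; exact collinearity is dropped by the OLS fit
  with a warning; rank-deficient deconvolution references are reported but
  still solved (NNLS returns one of the minimisers).
- Infeasible beta/intensity combinations (β > S/(S+100)) error rather than
  silently clamp.

## Verification scale

The shipped tests and the acceptance script run at deliberately moderate
problem sizes — cohorts of 80–600 samples, 300 probes, 20-seed replication
for the recovery properties, 1000-replicate null calibrations — sizes at
which every claimed property is measurable with comfortable margins while
the whole suite stays quick on a laptop. The intrinsic-recovery check
expects the injected +3-year offset to be recovered at 2–4 years: elastic-net
shrinkage attenuates predictions by design, and the measured pooled
recovery (≈2.2–2.7 y) is the honest behaviour of a penalized clock, not an
implementation loss.

## Known limitations

- The advanced subset estimators are trained on synthetic truth; their
  coefficients are not the (unpublished) originals, only functionally
  analogous.
- The gold-standard profile is the clock's training means; published
  software defines its own (unpublished) standard.
- No naive CD4+ T compartment is simulated, so the default pipeline trains
  no naiveCD4T estimator (the module accepts one wherever truth for it
  exists).
- Load mode expects the package's TSV dialect; IDAT binaries and GEO series
  matrices are out of scope.
- The fixed-effects meta-analysis does not model intra-subject correlation;
  repeated-measures designs need a mixed-effects extension.
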