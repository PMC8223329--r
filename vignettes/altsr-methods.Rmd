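---
title: "Methods: cross-lagged and mediation models for longitudinal methylation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-lagged and mediation models for longitudinal methylation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altsr)
```

# The analysis

`altsr` implements a three-stage longitudinal analysis of DNA methylation
and cardiovascular disease (CVD) in twin cohorts: an epigenome-wide scan
with nested random effects, bivariate autoregressive latent trajectory
models with structured residuals (ALT-SR) for the direction of
within-person association between methylation and cardiometabolic traits,
and latent growth curve mediation from methylation through a trait to CVD.
This vignette documents the models, their assumptions, the numerical
choices, and what the synthetic-cohort validation does and does not
establish.

# Stage 1: the epigenome-wide scan

For each CpG site, the methylation beta value \(y_{ijt}\) (person *i* in
pair *j*, occasion *t*) is modelled as

\[
y_{ijt} = \beta_0 + \beta_1\,\mathrm{CVD}_{ijt} + \beta_2\,\mathrm{age}_{ijt}
        + \beta_3\,\mathrm{sex}_{ij} + \beta_4\,\mathrm{smoking}_{ijt}
        + u_j + v_{ij} + \varepsilon_{ijt},
\]

with independent Gaussian random intercepts for twin pair
(\(u_j\)) and person within pair (\(v_{ij}\)). The CVD indicator is
time-dependent: occasions strictly before the diagnosis age code 0,
occasions at or after it code 1, and never-diagnosed persons are 0
throughout. Sex codes female = 1; smoking is the ordinal numeric coding 1
(never) / 2 (ex) / 3 (current), entered as a single covariate rather than
dummy-coded because the coding itself, not a factor expansion, is the
stated convention. Estimation is restricted maximum likelihood via
**lme4**; fixed-effect inference uses large-sample Wald z tests (no
Satterthwaite degrees of freedom), the simplest defensible default when
only p-values are reported downstream. Singletons form pairs of size one;
their pair-variance contribution is absorbed without special-casing.

CpGs are selected for the downstream stages if they pass the
epigenome-wide threshold (0.05 divided by the number of tested CpGs,
rounded to one significant figure — 2×10⁻⁷ for a 255,356-CpG panel), or,
if none do, the 20 lowest-p CpGs are taken, with ties broken by CpG id so
the selection is reproducible.

A caveat worth stating because the synthetic cohort makes it visible: when
persons have *individual methylation slopes* over age, the intercept-only
mixed model is misspecified for a time-dependent exposure (the indicator
is monotone in time within person), and its type-I error at
\(\alpha = 0.05\) inflates to roughly 14% under the generator defaults.
The calibration checks therefore simulate null CpGs under the scan's own
covariance structure (no person-specific slopes), where the scan is
calibrated (≈5%, uniform p-values). Applied to real cohorts, this is a
genuine limitation of intercept-only EWAS scans of time-coded outcomes,
not an artifact of this implementation.

The case-only onset analysis regresses CVD onset age on a per-person
methylation summary (first, last, random, or mean of the available
measurements) with a twin-pair random intercept and the same covariates
taken at the summarised measurement (averaged for the mean summary),
restricted to persons diagnosed after at least one measurement occasion,
at the Bonferroni level 0.05/(20 × 4) = 6.25×10⁻⁴.

# Stage 2: the bivariate ALT-SR model

For one CpG (methylation rescaled ×10, see below) and one trait observed
at occasions with slope loadings \(\lambda_t \in \{0, 2, 3, 5, 6\}\)
(years from the first occasion), each construct decomposes into a linear
latent growth curve plus an occasion-specific structured residual:

\[
\mathrm{meth}_t = i_m + \lambda_t s_m + e_{m,t},\qquad
\mathrm{trait}_t = i_r + \lambda_t s_r + e_{r,t},
\]

with the residuals following a lag-1 vector autoregression across adjacent
occasions:

\[
\begin{pmatrix} e_{m,t} \\ e_{r,t} \end{pmatrix}
 = \begin{pmatrix} a_{t-1} & b_{t-1} \\ d_{t-1} & c_{t-1} \end{pmatrix}
   \begin{pmatrix} e_{m,t-1} \\ e_{r,t-1} \end{pmatrix} + \zeta_t .
\]

The *a* and *c* paths are the autoregressive (within-person carry-over)
effects of methylation and trait; *b* carries the trait residual into the
next methylation residual and *d* carries the methylation residual into
the next trait value — the two cross-lagged directions whose asymmetry is
the scientific question. All four path sets are freely estimated per
transition (labelled by starting occasion: a3, a5, a6, a8). Residual
variances and the within-occasion residual covariance are
equality-constrained across occasions except the first, whose residual is
exogenous to the autoregression. The 4×4 covariance of the growth factors
is fully free: the model's purpose is to separate stable between-person
association (the growth-factor covariances) from within-person dynamics
(the residual paths), and constraining cross-construct growth covariances
would push between-person covariance into the cross-lags. Sex and baseline
age regress onto the four growth factors (baseline age centred at 70
internally; this shifts latent means only), plus statin-ever use for the
lipid traits; covariates do not touch the structured residuals.

HDL and LDL lack first-occasion measurements, so their models use four
occasions with loadings 0, 1, 3, 4 — the original spacing re-anchored at
the second occasion, preserving the time metric.

Free-parameter bookkeeping for the five-occasion model: 10 growth-factor
covariances + 4 growth-factor means + 6 residual (co)variance parameters +
16 paths + 8 covariate effects = 44 (the four-occasion lipid model also
has 44: 12 paths, 12 covariate effects).

Model fit is screened with the likelihood-ratio chi-square (p > 0.05),
RMSEA < 0.06 and CFI > 0.95; the screen is recorded on each fit but never
used to drop models, since cross-lag patterns are reported for all
converged models. Significance of paths uses cluster-robust standard
errors with the twin pair as cluster, at 0.05/(20 CpGs × 7 traits) ≈
3.6×10⁻⁴.

## Why rescale methylation by 10?

Beta values live in [0, 1] with residual standard deviations of a few
percent, so raw-scale variance parameters are ~10⁻³–10⁻⁴ while trait
variances are ~1–300. The ×10 rescaling evens the parameter scales for the
optimizer. Standardized estimates are invariant to the rescaling (checked
to 1e-4 in the tests), so no scientific quantity depends on it.

# Stage 3: latent growth mediation

Two parallel linear growth curves (same loadings) for methylation and the
trait, with freely covarying exogenous growth factors (methylation
intercept and slope, trait intercept), occasion-specific measurement
residuals, the binary CVD indicator as a single-indicator outcome, and six
structural regressions: m1 (methylation intercept → trait slope), m2
(methylation slope → trait slope), and x1–x4 (methylation intercept/slope
and trait intercept/slope → CVD). Indirect effects are the products
x4·m1 and x4·m2 with first-order delta-method standard errors; totals are
x1 + x4·m1 and x2 + x4·m2, which hold as exact algebraic identities in
every converged fit. Only the trait *slope* receives mediation paths: the
mediation question is whether methylation levels and changes act on CVD
through subsequent trait *change*.

Analysis is restricted to observations strictly before the diagnosis age;
diagnosed persons keep the outcome indicator even when no pre-diagnosis
record remains (their count is logged). Two deliberate modelling
assumptions, both documented because the study software family treats them
the same way: the binary outcome enters as a continuous endogenous
variable (a linear-probability convention — effects are risk differences,
and heteroscedasticity is partly absorbed by the cluster-robust errors),
and delta-method rather than bootstrap intervals are used for the product
terms.

# The estimation engine

No SEM package is assumed; the package carries a full-information maximum
likelihood engine specialized to path models with latent variables:

* **Specification** is a declarative parameter table (loading, regression,
  covariance, mean rows; `:=` rows define derived quantities), compiled to
  LISREL-with-means matrices \(\Lambda, B, \Psi, \Theta, \alpha, \nu\)
  plus covariate regressions \(\Gamma\). Rows sharing a label share one
  free parameter. Exogenous covariates are conditioned on (fixed
  regressors); their moments are not model parameters.
* **Likelihood**: rows are grouped by missingness pattern and each
  contributes the Gaussian log-density of its observed subvector with
  per-row means \(\mu_i = \nu + \Lambda(I-B)^{-1}(\alpha + \Gamma x_i)\).
  The likelihood and its analytic gradient are computed in compiled code
  (RcppArmadillo); the gradient accumulates per-pattern weight matrices
  and reduces each parameter's derivative to a few precomputed products,
  which is what makes replicate-level simulation studies affordable.
* **Optimization**: quasi-Newton (`nlminb`) with parameter-scale
  preconditioning from the start values, a BFGS polish when the scaled
  gradient is not yet flat, and two jittered restarts on failure.
  Start values: fixed loadings as declared; free variances at half the
  observed variance of the associated manifest; regressions and
  covariances at 0; manifest intercepts at sample means; free latent means
  at the least-squares solution of the manifest sample means under the
  template loadings (growth-factor means start near the data — starting
  them at zero costs many iterations when trait means are far from zero).
  Convergence requires relative log-likelihood change below 1e-9 and a
  scaled gradient norm (each \(|g_k|\) measured against its parameter's
  natural scale, relative to the log-likelihood magnitude) below 1e-5;
  non-convergence is reported as a no-output record, never silently
  accepted. Negative variance estimates are flagged (Heywood), not
  constrained away.
* **Fit statistics**: the likelihood-ratio statistic is computed against
  an unrestricted conditional Gaussian model estimated by EM (required
  under missingness); with complete data this reduces to the classical
  Wishart discrepancy, an identity the tests verify. The independence
  baseline (free means and variances, everything else zero) factorises
  into univariate fits. RMSEA = \(\sqrt{\max(T-df,0)/(df\,n)}\) with *n*
  the number of analysis rows (persons, not clusters); CFI =
  \(1 - \max(T-df,0)/\max(T_b-df_b, T-df, 0)\); a saturated model (df = 0)
  reports RMSEA 0 and CFI 1 by convention.
* **Cluster-robust covariance**: sandwich \(A^{-1} B A^{-1}\) with the
  observed information *A* (finite differences of the analytic gradient)
  and *B* the outer product of per-cluster score sums scaled by
  \(G/(G-1)\); with singleton clusters this equals the ordinary sandwich.
* **Standardization** scales estimates by model-implied standard
  deviations, including the covariate-explained share of latent variance;
  a standardized simple-regression slope equals the Pearson correlation
  (one of the closed-form oracles in the tests, alongside a two-predictor
  path model checked against `lm()` on standardized data — no independent
  SEM implementation is available here, so the cross-checks are
  closed-form rather than cross-software).

# The synthetic twin cohort

The generator is the package's ground truth and emulates the structure of
an aging Swedish twin cohort: 83 MZ pairs, 155 DZ pairs and 59 single
twins (535 individuals; singleton zygosity split 21/37/1 MZ/DZ/unknown to
match the 187/347/1 individual margin), baseline age Normal(72.7, 9.3²)
years shared within pair, 58.5% female, smoking a persistent per-person
category with a 10% per-occasion switch probability (initial shares
0.55/0.29/0.16 giving ~16% baseline current smokers), 18% statin-ever
users. Five assessment occasions carry slope loadings 0, 2, 3, 5, 6, and
age at occasion = baseline age + loading, since the loadings are the time
metric.

Methylation–trait dynamics follow the bivariate ALT-SR process read
generatively, with co-twin resemblance injected through a pair-level share
of the latent *intercept* variance (MZ 0.5, DZ 0.25) — the simplest
mechanism that makes cluster-robust errors and MZ/DZ stratification
matter; innovations are never shared. Signal CpGs couple to one trait each
(cross-lag d = 0.25 scaled to the trait's innovation units, b = 0 by
default); null CpGs have all dynamic paths at zero and no outcome link.
Where several signal CpGs map to one trait, the cohort keeps the trait
series from the first; later CpGs couple to a latent copy, so their
realized cross-lag is diluted — panels used to probe coupling keep at most
one signal CpG per trait. Latent methylation maps to the beta scale by the
inverse logit centred at 0.5 with small latent SD (clipped to
[0.001, 0.999] as a guard; >99.9% of values are unclipped by
construction). The linear model on (rescaled) beta values is then an
approximation whose slope is the logistic derivative at the centre; the
exact-recovery checks therefore run on the latent (linear) scale, while
cohort-level checks are qualitative (direction detection).

Events are drawn per category from a logistic function of a signal CpG's
latent growth factors, with intercepts −0.42 / −1.38 / −1.67 giving
marginal prevalences near 39.6 / 20.2 / 15.9 percent; diagnosis age is
uniform over baseline − 2 to baseline + 10 years, so some diagnoses
precede all occasions and some fall between occasions. The SATSA-like
missingness preset removes HDL and LDL entirely at the first occasion and
retains methylation samples with probability 0.5 per occasion, so the
fraction of persons with ≥3 of 5 measurements is 0.5, matching the
study's 269/535.

Trait units are the customary ones (lipids mmol/L, blood pressure mmHg,
BMI kg/m²) with intercept/slope means and variances chosen to be
realistic for an old-age cohort (`trait_defaults()`); the methylation
latent-scale defaults are chosen for numerical stability, as no
distributional information about per-CpG means and variances is available
to emulate.

What passing tests show — and do not show. The generator draws all latent
structure from Gaussians, misses genuine features of array data (probe
noise heteroscedasticity, cell-composition and batch structure, meQTL
architecture, non-Gaussian trait tails), and its missingness is
missing-completely-at-random where real attrition is not. Green tests
establish that the estimators recover the parameters of their own
generating process, are calibrated under correct specification, and detect
cross-lag direction asymmetry at realistic sample sizes — not that the
pipeline's assumptions hold in any particular real cohort.

# Problem sizes used in validation

Chosen to make the Monte-Carlo checks decisive while keeping the whole
validation suite re-runnable in minutes on one CPU:

* generator-versus-engine moment match: one sample of n = 50,000 subjects,
  agreement within 3 standard errors elementwise;
* cross-lag recovery and direction detection: 50 replicates of 400 twin
  pairs (pair ICC 0.4), generative b = 0, d = 0.3; mean a/b/c/d within 3
  Monte-Carlo standard errors, and more significant methylation→trait than
  trait→methylation paths in ≥95% of replicates;
* EWAS calibration: 1,000 null CpGs on the 535-person default cohort;
  power: 25 replicates of 5 strongly linked CpGs among 200 nulls, with a
  narrow early diagnosis window so most case occasions code 1 (a diffuse
  window dilutes the time-dependent contrast — a scenario choice, not a
  fitted constant);
* chi-square screen calibration: 100 replicates at n = 1,000;
* mediation recovery and delta-method calibration: 50 replicates at
  n = 500 from the mediation model's own implied moments, with slope
  variances (0.04) comparable to their sampling noise — with much smaller
  slope variance the trait-slope factor is weakly identified and x4 is
  unstable, which is a property of the design, not the estimator.

# Known limitations

* The linear-probability treatment of the binary outcome makes x1–x4 risk
  differences; probit/logistic outcome links are out of scope.
* Delta-method intervals for products are first-order; they can be
  anticonservative for small samples or near-zero products (the
  calibration test bounds this at n = 500).
* The fit-index screen is descriptive; no Satorra–Bentler or other
  robust corrections to the chi-square are applied.
* With sparse repeated measurements the number of distinct missingness
  patterns grows quickly; fits remain correct but slower, and weakly
  identified corners (e.g. near-zero slope variance) can end in flagged
  Heywood estimates or no-output records.
* Nonlinear growth, time-varying covariates inside the SEM, and
  multi-indicator measurement models are out of scope.
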