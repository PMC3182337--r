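---
title: "Methods: growth curve models with fractional polynomial time transformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth curve models with fractional polynomial time transformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

For one gene, let $y_{ij}$ be the (log-scale) expression of subject
$i = 1, \dots, N$ at its $j$-th observed time $t_{ij}$, $j = 1, \dots, n_i$.
`fpgcm()` fits

$$
y_{ij} = \beta_0 + \sum_{b=1}^{p} \beta_b f_b(t_{ij})
       + b_{i0} + \sum_{g} b_{ig} f_g(t_{ij}) + e_{ij},
\qquad \mathbf{b}_i \sim N(0, \mathbf{G}), \quad e_{ij} \sim N(0, \sigma_e^2),
$$

where the $f_b$ are fractional polynomial (FP) transformations of offset
time. FP powers are restricted to the fixed set
$\varphi = \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$; $\varphi_b = 0$ means
$\ln t$ and a repeated power multiplies the previous term by $\ln t$, so a
second-order model is
$\beta_0 + \beta_1 t^{\varphi_1} + \beta_2 t^{\varphi_2}$ for
$\varphi_1 < \varphi_2$ and
$\beta_0 + \beta_1 t^{\varphi_1} + \beta_2 t^{\varphi_1}\ln t$ for
$\varphi_1 = \varphi_2$. The grid therefore contains 8 first-order and 36
second-order candidates; negating coefficients flips each curve, so the
family covers rises, declines, saturations, transients and U-shapes with at
most three fixed-effect parameters. Orders above two are deliberately
rejected: on the short series typical of expression time courses they
overfit, and the second-order family already spans the curvature shapes of
practical interest.

Assumptions worth stating explicitly:

* **Additive (log) expression scale.** Input values are assumed
  preprocessed, background-corrected and log-transformed (the package's own
  generator uses log2). Trend magnitudes and fold changes are additive on
  this scale.
* **Missing completely at random.** Subjects contribute exactly their
  observed rows. The likelihood is valid when a chip's absence is unrelated
  to the expression values; informative missingness is out of scope.
* **Gaussian random intercept (optionally slopes) and residuals**, one
  grouping level (subject). No crossed or nested structures, no covariates
  beyond time.

## Estimation

Writing $\mathbf{V}_i = \sigma_e^2(\mathbf{I} + \mathbf{Z}_i
\Lambda\Lambda^\top \mathbf{Z}_i^\top)$ with
$\mathbf{G} = \sigma_e^2 \Lambda\Lambda^\top$, both $\beta$ (by generalized
least squares) and $\sigma_e^2$ are profiled out of the REML criterion, so
the numerical optimization runs only over the relative covariance factor
$\Lambda$:

* random intercept: a single ratio $\lambda = \sigma_b^2/\sigma_e^2$,
  maximized by one-dimensional search on $\log\lambda \in [-15, 8]$
  (criterion tolerance $10^{-8}$) with the boundary $\lambda = 0$ checked
  explicitly and boundary estimates reported as 0;
* random slopes: the log-Cholesky parameterization of $\Lambda$ (diagonal on
  the log scale), Nelder–Mead with relative tolerance $10^{-12}$, started
  from a within/between decomposition of OLS residuals.

Per-subject work uses the Woodbury identity at the dimension of
$\mathbf{Z}_i$, so fitting cost is linear in observations. Numerical
safeguards:

* $\sigma_e^2$ is floored at $10^{-8}$ inside the criterion, which keeps
  log-likelihoods and AIC finite on noise-free (degenerate) series; the
  reported estimate itself may be 0.
* Generalized cross-products are factored after column equilibration, so
  collinearity is detected on the correlation scale. This matters because FP
  columns are wildly differently scaled ($t^3$ versus $t^{-2}$); a plain
  Cholesky pivot test would confuse scaling with singularity. Designs that
  are singular (for example all observations at one time) yield
  `converged = FALSE` with a reason, never an exception — in batch screening
  such candidates are simply dropped, and a gene with no converged candidate
  is flagged `unfit`, never silently significant.
* ML and REML are both available; a fit stores both maximized criteria (each
  from its own profile optimization).

REML matches `lme4::lmer` to at least six digits on common instances (a test
cross-checks this), but the implementation is self-contained so that a
hundred thousand small fits in the simulation engine stay fast.

## Screening and inference

Per gene, every grid candidate is fitted and the converged fit with the
lowest AIC wins; AIC counts fixed effects plus free variance parameters. Ties
are broken by the canonical (lexicographic) grid order, making screens
byte-reproducible across platforms. By default the AIC uses the REML
criterion, matching the estimation method; since REML criteria across
different fixed-effect designs are only approximately comparable, a note is
emitted once per screen and `selection = "ML"` is available.

Inference on the best model's time coefficients uses Wald $z$ tests with an
asymptotic normal reference. The choice is deliberate: mixed-model
denominator degrees of freedom are contested, and the screen needs only a
per-gene ranking statistic. A documented alternative (`wald = "t"`) uses a
$t$ reference with residual degrees of freedom $n - p - 1$, which is more
conservative on severely reduced designs. The test suite *measures* the
consequences of the default rather than assuming them: on null data the
realized false discovery proportion of a BH call at $q = 0.1$ runs somewhat
above nominal when per-gene sample sizes shrink (the normal tail is lighter
than the appropriate $t$ tail), and AIC pre-selection followed by testing in
the selected model — the classic post-selection caveat, reproduced here by
design — adds mild additional inflation. Neither effect is corrected,
matching the procedure as specified; both are quantified in
`test-screen.R`/`test-acceptance.R`.

Across genes, one BH pass controls the FDR. For first-order screens the
gene-level p-value is $p_{\beta_1}$; for second-order screens it is
$\max(p_{\beta_1}, p_{\beta_2})$ — the intersection–union combination of the
rule that a gene is called only when *both* time coefficients are
significant, which keeps a single FDR layer over genes. Unfit genes
contribute no test and are excluded from the BH denominator. Lowering the
threshold provably never enlarges the rejection set.

## The synthetic-data generator and the power study

`simulate_timecourse()` emulates a time-course chip experiment on the log2
scale: $y_{gij} = \beta_0 + \beta_{1g} t_j + b_{gi} + e_{gij}$ with subject
random intercepts $b_{gi} \sim N(0, \sigma_b^2)$ and residuals
$e_{gij} \sim N(0, \sigma_e^2)$, independent across genes. The default study
design is 20 subjects at 6 equally spaced time points spanning 10 hours
(0, 2, …, 10 h; the spacing within the stated span is the package's choice),
four groups of 10 trend genes with fold changes 2, 2.5, 3 and 3.5, and the
remainder null. A fold change $f$ is mapped to the additive total change
$\log_2 f$ over the span, i.e. slope $\beta_1 = \log_2(f)/10$ per hour —
the natural endpoint ratio on the raw scale for a linear trend.
`apply_missingness()` blanks exactly $\mathrm{round}(\pi \cdot N \cdot T)$
whole chips uniformly at random (identically across genes, the way arrays
actually go missing), redrawing if a subject would lose every chip; a
cell-level mechanism is available for sensitivity analysis. The power study
screens with the grid restricted to the linear model ($\varphi = 1$), calls
BH at FDR < 0.1, and pools detection indicators over replicates × genes per
cell (binomial Monte-Carlo standard errors attached).

**Noise defaults.** The reference study design does not state its noise
levels; the shipped defaults $\sigma_e = 0.5$, $\sigma_b = 0.3$ (log2 scale)
were fixed once as values typical of microarray log-expression variability
and are recorded in the shipped configuration as reconstructions. The power
surface is very sensitive to $\sigma_e$: with 120 observations per gene the
slope standard error is $\sigma_e/\sqrt{1400} \approx 0.013$ at complete
data, so with these defaults even fold-2 genes ($\beta_1 = 0.1$) are
detected essentially always, and power only drops below 1 for fold-2 genes
once half or more of the chips are missing — exactly what the acceptance
study computes. Roughly double the residual noise would be needed before the
fold-2 column becomes a sensitive instrument at complete data. Null genes
carry both the random intercept and residual noise (whether the reference
design gave its null genes residual noise on top of subject effects is
unstated; giving them both is the conservative reading).

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: array-level normalization artifacts, intensity-
dependent (heteroskedastic) noise, heavy-tailed outliers, correlation
between genes (BH's FDR control is exact here because the simulated genes
are independent), probe-level effects, and informative missingness. The
power table should be read as a best-case MCAR benchmark, not a promise
about any particular laboratory dataset.

**Problem sizes.** The shipped study runs 25 replicates of 1,000-gene
datasets (40 trend + 960 null) per missing proportion — a deliberate
desk-scale choice that keeps a full power surface within minutes while
leaving per-cell Monte-Carlo standard errors at about 0.03 or less. Replicates and gene
counts scale up by configuration (`sim_config()`).

**Seeding.** Every stochastic function takes an explicit seed; the study
driver derives independent child seeds for each replicate's generation and
masking from the master seed, so the full table is byte-reproducible.

## Other design decisions

* **Time offset.** When the earliest time is 0, a +1 offset is applied to
  all times before any FP transformation (logs and negative powers require
  $t > 0$); the offset is applied exactly once, is configurable, and is
  recorded on the dataset.
* **Missing markers.** Empty cells and case-insensitive `NA` in matrix files
  are missing — the common export dialects. Duplicate (subject, time) chips
  are an error rather than silently averaged.
* **Minimum data per gene.** Defaults of 4 observations for first-order and
  6 for second-order screens; second-order fits need more than three time
  points per subject in practice to identify curvature.
* **Clustering.** Mean profiles (per nominal time, over observed subjects)
  are standardized per gene and clustered with Euclidean distance and
  complete linkage — defaults chosen for determinism and shape (rather than
  level) grouping; per-time means missing for a gene are imputed by the gene
  mean for the distance computation only. Pattern families group significant
  genes by (selected powers, coefficient signs); note that the sign
  interacts with whether the basis itself rises or falls, so families are
  qualitative shape classes, not simple up/down labels. Rendering is out of
  core: the module exports leaf orders, merge heights and fitted curves as
  plain tables.

## Known limitations

* Selection and inference use the same data (AIC, then Wald tests in the
  selected model) with no post-selection correction — inherited from the
  procedure being implemented and measured, not corrected, by the tests.
* Wald $z$ p-values are anti-conservative for genes observed on few chips;
  prefer `wald = "t"` when per-gene sample sizes are small.
* REML-based AIC comparisons across fixed-effect designs are approximate.
* One grouping level, no covariates, Gaussian errors only.
* Under chip-level missingness all genes share one design, which the screen
  exploits for speed; the general per-gene path handles arbitrary cell-level
  holes at higher cost.
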