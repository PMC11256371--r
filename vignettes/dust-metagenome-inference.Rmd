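---
title: "Debiased Lasso inference for dust-metagenome differential abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Debiased Lasso inference for dust-metagenome differential abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustdab)
```

## The problem

Indoor dust exposes occupants to the whole microbial community at once, so
testing one taxon at a time answers the wrong question: any single-taxon
association may be an echo of a correlated neighbour. `dustdab` relates a
genus-by-sample metagenome count table to continuous respiratory outcomes —
FEV1 and FVC (ml), their ratio (a proportion in (0, 1]), and FeNO (ppb, an
airway-inflammation marker) — testing **each taxon while controlling for all
other taxa** and for epidemiological covariates. The vehicle is one joint
high-dimensional linear model per outcome:

$$ y = Z\gamma + X\beta + \varepsilon $$

where the columns of $X$ are centered/scaled within-sample relative
abundances of all $p$ taxa, and $Z$ holds the covariates (age, age², sex,
height, height², weight for FVC only, smoking status, pack-years, asthma,
state of residence, ancestry; FeNO models drop the quadratic terms; a
winter-season flag is available as a sensitivity adjustment). $\beta$ is
estimated by the Lasso; inference comes from the desparsified (debiased)
Lasso, so every taxon receives a coefficient, standard error and p-value —
not only the taxa the penalty happens to select.

## Preprocessing

The chain is `filter → aggregate → winsorize → relative abundance →
standardize`, each step a small, testable function:

* **Filtering.** Samples with fewer than 1000 total reads are dropped, then
  taxa holding less than 0.0005% of the retained grand total, then taxa from
  kingdoms with thin reference-genome coverage (Eukaryota, viruses). Both
  thresholds are strict `<`, so boundary cases are retained, and they are
  applied once, in that order — not iterated to a fixed point.
* **Genus aggregation.** Counts of classified species are summed within each
  genus before any transform, the standard remedy against species-level
  sparsity. Genus is positionally the sixth lineage rank; both `k__`-prefixed
  and bare semicolon-delimited lineages are accepted.
* **Winsorization.** Per taxon, the five largest counts across samples are
  set to the sixth largest, damping extreme sequencing outliers. The
  operation is idempotent and never increases a cell; when the cap ties with
  larger order statistics it is a no-op on the tied cells.
* **Relative abundance.** Each sample's counts are divided by that sample's
  *winsorized* total. The winsorized total is chosen for internal consistency
  (the capped cells and the denominator agree); per-sample totals, not
  per-taxon scalings, are the compositional reading adopted here.
* **Standardization.** $X$ columns and $y$ are centered and scaled to mean 0,
  SD 1 (sample SD, divisor $n-1$; the divisor only rescales all coefficients
  by a common factor, but it must be — and is — the same for $X$ and $y$).
  Constant columns are dropped with a warning and reported with `NA`
  statistics. Covariates are left on their natural scale and are **not**
  penalized: the intercept and $Z$ are projected out of $X$ and $y$
  (Frisch–Waugh residualization) before the penalized fit, which is exactly
  equivalent to leaving $\gamma$ unpenalized. Shrinking confounders would
  undermine adjustment, so this is the only defensible reading.
* **Outcome transforms.** FeNO values below the 5 ppb limit of detection are
  imputed at $\mathrm{LOD}/\sqrt{2} = 3.5$ ppb (rounded to one decimal) and
  all FeNO values are natural-log transformed. Missing outcomes or covariates
  are handled complete-case per outcome, with a logged count.

## The estimator

With the residualized, standardized design $(X_r, y_r)$:

1. **Lasso.** $\hat\beta = \arg\min_b \tfrac{1}{2n}\lVert y_r - X_r b
   \rVert^2 + \lambda \lVert b \rVert_1$, solved by coordinate descent
   (glmnet, convergence threshold $10^{-12}$ for the main fit); $\lambda = 0$
   is solved exactly by least squares. Every returned fit satisfies the KKT
   conditions to $10^{-6}$, which the tests assert.
2. **Penalty selection.** Fivefold cross-validation over 100 log-spaced
   penalties spanning three decades below $\lambda_{\max} = \max_j
   |x_j^\top y_r| / n$; the minimum-CV-error $\lambda$ is used (not the 1-SE
   rule), with the fold partition drawn from the run seed and recorded.
   One $\lambda$ is selected per outcome.
3. **Nodewise regressions.** For each column $j$, the Lasso of $x_j$ on
   $X_{-j}$ yields $\hat\gamma_j$ and $\hat\tau_j^2 = x_j^\top (x_j - X_{-j}
   \hat\gamma_j) / n$; row $j$ of $\hat\Theta$ is $(1, -\hat\gamma_j) /
   \hat\tau_j^2$ placed appropriately. At $\lambda = 0$ (possible when
   $p < n$) this reproduces the exact inverse sample covariance, a unit-tested
   identity.
4. **Debiasing and tests.**
   $\hat b = \hat\beta + \hat\Theta X_r^\top (y_r - X_r \hat\beta) / n$,
   $\;\mathrm{se}_j = \hat\sigma \sqrt{(\hat\Theta \hat\Sigma
   \hat\Theta^\top)_{jj} / n}$ with $\hat\Sigma = X_r^\top X_r / n$, and
   $\hat\sigma^2$ from the Lasso residuals with the degrees-of-freedom
   correction $n - \hat s - q$ ($\hat s$ the support size, $q$ the covariate
   count including the intercept). P-values are two-sided normal. In the
   least-squares limit the whole construction collapses to classical OLS
   estimates and standard errors (up to normal-vs-t p-values), which the
   acceptance tests verify to $10^{-6}$.

Significance is declared at p < 0.05 with no multiplicity correction: the
joint model already adjusts every test for all other taxa, which is the
procedure's point. A Benjamini–Hochberg column is emitted for readers who
want it, but it never changes the `significant` flag.

### Compositional designs and the nodewise penalty floor

Within-sample relative abundances obey an exact sum-to-one constraint, so the
standardized taxon block carries one exact linear dependency: each column can
in principle be predicted perfectly from the rest. Unrestricted nodewise
cross-validation chases that perfect fit, driving $\hat\tau_j^2 \to 0$ —
the precision rows blow up and the optimization crawls. The nodewise CV grid
is therefore floored at `lambda_min_ratio` (default 0.05) times each column's
own $\lambda_{\max}$. For well-conditioned designs the CV optimum lies far
inside this grid and the floor is inert (the Gaussian-design calibration
results below are unchanged by it); for compositional designs it keeps
$\hat\tau_j^2$ bounded away from the singular limit.

`nodewise_theta()` cross-validates each column separately by default. At the
default study scale ($p = 389$) that costs ~50 cross-validation fits per
reported p-value, so `dab()` defaults to `"shared-cv"`: cross-validate ten
randomly chosen columns and share the median penalty across all $p$ nodewise
fits. Under the roughly exchangeable column distributions analyzed here the
two choices give nearly identical $\hat\Theta$; per-column CV remains
available via `nodewise_lambda = "cv"` and is what the fixed-design
simulation studies use.

## The synthetic-data generator

No real dust-metagenome table ships with the package; the generator emulates
the empirical shape of a post-classification, post-decontamination table so
that every downstream stage is testable offline:

* 779 samples × 389 genus-level taxa by default;
* per-sample depths log-normal with `depth_log_mean = 11.17`,
  `depth_log_sd = 1.43`, chosen so the mean depth is ≈ 2×10⁵ reads and the
  minimum across 779 samples is ≈ 975;
* compositions Dirichlet-multinomial with concentration $\alpha_i = 0.22 +
  35\, i^{-2}$: the power-law head sets dominance (top 3 taxa ≈ 30% of all
  reads), the constant baseline sets the zero fraction (≈ 25% of cells).
  Two empirical targets, two knobs; the pair was fixed by a coarse grid
  search before the analysis code was built and is not revisited. Per-taxon
  dispersion is not reported for the real data, so these are tuning choices,
  not facts.
* covariates with marginals matching the study population (age 62 ± 11, 60%
  male, 65/29/6% never/former/current smokers, 38% asthma, 32% NC, 96%
  European ancestry, 23% winter collection; a ~0.26% sprinkle of missing
  pack-years mirrors the two participants the study excluded);
* outcomes generated as a linear model on the *post-preprocessing
  standardized* abundances — so planted coefficients live on exactly the
  scale the inference estimates — plus standardized covariate effects and
  Gaussian noise, then mapped affinely to reporting units (ml, proportion,
  ppb via `exp`; simulated FeNO below 5 ppb is flagged below-LOD, volumes are
  floored at a physiological 200 ml, the ratio is clamped to (0.05, 1] —
  tail-only distortions). When FEV1,
  FVC and their ratio are requested together, FEV1 is derived as FVC × ratio
  so the physiological constraint FEV1 ≤ FVC holds by construction.

What the generator does **not** emulate: read-level error, taxonomy
misassignment, batch effects, spatial/seasonal structure beyond a single
winter flag, and any nonlinear taxon-outcome relationships. Passing tests
therefore demonstrate that the machinery is correct and calibrated under the
stated sampling model — not that the biological findings of any particular
dataset would replicate.

## Alpha diversity

Diversity is a separate branch from the filtered table, computed at the
finest available rank (it is defined over species, not genera): counts are
rarefied **once** — uniform subsampling without replacement, multivariate
hypergeometric — to the minimum sample total (or a user depth), with the
seed recorded; richness is the count of observed taxa and the Shannon index
$H = -\sum_i p_i \ln p_i$ uses natural logs. $e^H$ (the effective number of
species) enters the association models, countering the index's negative
skew; "exponentially transformed" is read as $e^H$ and documented as such.
Associations are ordinary least squares on the outcome's covariate roster.
Differential abundance, by contrast, uses unrarefied counts — winsorization
plus the compositional transform already remove depth effects there.

## Numerical choices and degenerate inputs

* All randomness flows from one run seed through fixed per-operation offsets,
  so operations have independent, reproducible streams; two runs with the
  same seed are byte-identical, including the run manifest (which is why the
  manifest records versions, seeds, hashes and dimensions but deliberately no
  timestamps).
* Filter boundaries are strict `<`; taxa exactly at 0.0005% survive.
* Zero-total samples abort the compositional transform by name; collinear
  taxa abort the nodewise step by name; a non-positive residual degrees of
  freedom aborts debiasing with advice (larger n or stronger penalty).
* Constant taxa after preprocessing are excluded from the design with a
  warning and reported with `NA` statistics rather than dropped silently.

## Simulation studies and their sizes

The three study functions are the package's own evidence of calibration, and
they are what the acceptance suite runs:

* `sim_type1_calibration()` — global null, n = 400, p = 100, 500 replicates.
  Per-taxon type-I error at the 0.05 level should sit in [0.03, 0.07] and
  pooled p-values should pass a KS uniformity check.
* `sim_ci_coverage()` — n = 400, p = 100, 5 planted effects (magnitudes
  0.3–0.5, mixed signs), 500 replicates; 95% intervals should cover in
  [0.92, 0.98] for null and non-null coordinates alike.
* `sim_power()` — the **full pipeline** (counts → preprocessing → `dab()`),
  n = 400, p = 100, three planted standardized effects of magnitude ≥ 0.3,
  200 replicates; detection (p < 0.05, correct sign) should occur in ≥ 90%
  of replicates per effect.

Calibration and coverage condition on one fixed Gaussian design per study:
the nodewise $\hat\Theta$ depends only on $X$, so it is estimated once
(per-column CV) and reused, while the outcome, CV folds and penalty are
redrawn every replicate. This is the standard conditional-on-design view of
debiased-Lasso inference and keeps the studies at desk scale. The power study
redraws the whole count table every replicate and so uses the shared-penalty
nodewise variant.

```{r example, eval = FALSE}
sim <- simulate_dust_study(sim_config(seed = 1))
fit <- dab(sim$counts, sim$meta, outcome = "fev1", seed = 1)
fit
tidy(fit)      # one row per genus: coefficient, se, z, p_value, significant
glance(fit)    # one-row model summary
autoplot(fit)  # coefficient heatmap, stars at p < 0.05
```

## Known limitations

* The debiased-Lasso p-values are asymptotic; at small n with heavy-tailed
  abundances they can drift from nominal (the calibration study is the
  guard).
* The sum-to-one constraint means individual taxon coefficients are
  identified only through regularization; the nodewise penalty floor is a
  pragmatic guardrail, not a removal of the underlying compositional
  non-identifiability.
* Relative abundances cannot speak to absolute microbial load.
* The significance convention (p < 0.05, no multiplicity correction) follows
  the joint-model logic described above; users wanting FDR control should
  filter on the emitted `p_adjust_bh` column instead.
* Cross-sectional association, not causation.
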