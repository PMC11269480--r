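---
title: "Ecoenzymatic stoichiometry vectors: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecoenzymatic stoichiometry vectors: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzlim)
```

## The model

Extracellular enzyme activities (EEAs) proxy the metabolic effort microbes
devote to acquiring carbon, nitrogen and phosphorus. `enzlim` pools the
five assayed activities into acquisition sums — C = BG + CBH, N = NAG +
LAP, P = AP — and expresses relative investment as two proportions,
`x = C/(C+P)` and `y = C/(C+N)`. The point `(x, y)` in the unit square is
summarised as a vector: its length `VL = sqrt(x^2 + y^2)` grows with the
share of effort going to carbon (relative C limitation), and its angle
`VA = degrees(arctan(y/x))` compares P- against N-directed effort. On the
first quadrant an angle above 45° means investment in P acquisition
exceeds investment in N acquisition — phosphorus limitation — and below
45° nitrogen limitation. Spreadsheet-convention formulations of the angle
write the two arguments in the opposite order to most programming
languages; the package pins the convention that makes "above 45° = P
limited" true, and the swap symmetry `VA(x, y) + VA(y, x) = 90` is tested
as an invariant.

Working on raw proportions makes `x`, `y`, `VL`, `VA` and the
classification invariant to uniform rescaling of all five activities, so
assay units never matter. An `ln_transform` option takes natural logs of
the three pooled sums before forming proportions, for comparability with
studies that plot log-converted activity ratios; logs of sub-unit sums
can leave the unit interval, and such samples are marked undefined rather
than clamped. The flag used is recorded in the run manifest.

Numerical edge cases are resolved conservatively: a sample with zero C
acquisition sits at the origin, has no direction, and is excluded from
vector statistics with a logged message (never imputed); angles within
1e-9 of the threshold are classed `BALANCED` because the classification
rule is defined by strict inequalities; the threshold itself (default
45°, the equal-investment diagonal) is a parameter of
`classify_limitation()` constrained to (0, 90).

## Cohort stoichiometry

`stoich_summary()` reports the pooled C:N:P acquisition ratio with C
normalised to 1. The headline ratios are **ratios of cohort means**,
which match how a "mean ratio" across a survey is conventionally quoted
and are robust to individual samples with small C pools; the per-sample
**mean of ratios** is emitted alongside since the two differ under
skewed activity distributions and a reader may want either.

## The synthetic cohort generator

No public dataset accompanies this style of two-region sediment survey,
so the generator is a first-class module that emulates one: `n_sxk = 10`
sites in a shallow, nutrient-rich region (SXK) and `n_lxk = 20` in a
deeper, more dilute one (LXK). Its defaults are the cohort-defining
constants:

* Sediment TC/TN/TP regional means 18.06/1.78/0.73 (SXK) and
  5.43/0.69/0.44 (LXK) g·kg⁻¹; the derived TN:TP means are 2.44 and 1.57.
* Pooled C:N:P acquisition target 1:0.58:1.51 (strong P excess over the
  global ~1:1:1 reference).
* C-acquiring activities three-fold higher, phosphatase four-fold lower
  in SXK ("four times lower" is read as mean(AP|SXK) = mean(AP|LXK)/4);
  N-acquiring activities slightly (×1.3) higher in SXK.
* Dominant phylum mean proportions: bacteria 33.03/11.32/10.45/9.18/7.54%
  (Proteobacteria, Acidobacteria, Chloroflexi, Planctomycetes,
  Actinobacteria), fungi 53.23/33.47/6.06/1.72/0.2% (Ascomycota,
  Basidiomycota, Chytridiomycota, Rozellomycota, Mortierellomycota),
  remainder "Other".

Strictly positive quantities (concentrations, depths, activities) are
lognormal; pH and temperature are normal. Published surveys of this kind
report means without dispersions, so all spreads are one-time generator
choices: a 30% coefficient of variation for lognormal covariates and a
residual log-scale sd of 0.25 for enzymes, typical of right-skewed
activity data. Water TDS and conductivity share a latent correlation of
0.9 (the two track each other almost linearly in lake water).

### Closed-form calibration

Enzyme activities follow
`log A = a(region) + sum(beta_k z_k) + sigma * eps`, where the `z_k` are
the standardised latent drivers behind depth, TDS, water conductivity and
sediment TC. Because `E[exp(mu + L)] = exp(mu + Var(L)/2)` for Gaussian
`L`, the base levels `a(region)` are solved analytically so that (i) the
regional multipliers hold exactly in expectation and (ii) the pooled
expected acquisitions hit the C:N:P target exactly — the calibration is
algebra, not trial-and-error tuning. Within pools, BG:CBH defaults to 2:1
and NAG:LAP to 1:1; CBH shares BG's SXK multiplier since both are
C-cycle enzymes reported jointly elevated.

The driver effects act on the C-acquiring enzymes only
(`beta`: depth −0.4, TDS +0.4, conductivity +0.25, sediment TC +0.35 per
latent sd). Raising C relative to fixed N and P lengthens the vector and,
because P exceeds N nearly everywhere, simultaneously flattens the angle
— so a single mechanism yields the full observed sign pattern: VL
positively related to TDS, sediment TC and conductivity and negatively to
depth, with VA showing the opposite signs. Parameter-recovery tests
regress log BG on the reconstructed latents in a large single-region
cohort and recover each planted beta within two standard errors.

### Communities

Per sample, phylum proportions are Dirichlet with concentration 300
around the configured means — enough overdispersion to be visibly noisy
at 30 sites while keeping survey-mean phylum abundances within a couple
of percentage points of their targets. Within each phylum, OTU relative
abundances follow a cohort-wide stick-breaking profile (Beta(1, 5)
sticks; 40 bacterial / 25 fungal OTUs per phylum) tilted along the
water-conductivity gradient with strength `coupling = 0.4`. Placing the
gradient **inside** phyla leaves phylum-level calibration untouched while
still making Bray–Curtis dissimilarity drift with conductivity, which is
what links community turnover to limitation differences in the Mantel
stage; setting `coupling = 0` severs that link, a property the tests
check. Counts are multinomial at 10,000 (bacteria) / 8,000 (fungi) reads.

What the generator does **not** emulate: spatial autocorrelation among
sites, read-level sequencing error and chimeras, zero inflation beyond
multinomial sampling, seasonal dynamics, and any covariate effect on N-
or P-enzymes beyond the regional contrasts. Tests passing on this cohort
therefore certify the statistical machinery and calibration recovery, not
field realism.

### A deliberate tension

The regional contrasts and the pooled stoichiometry jointly imply that
SXK sites are mostly *nitrogen*-limited: with pooled N fixed at 0.58 C,
phosphatase four-fold lower in SXK and N-enzymes not lower there, SXK's
expected AP falls below its expected N pool. The cohort-wide P-limited
fraction therefore settles near 0.70–0.77 rather than the ~0.9 a survey
with uniformly P-limited regions would show. We kept the quoted regional
contrasts rather than distorting them to force a higher fraction; the
qualitative conclusion (P limitation predominates, overwhelmingly so in
LXK) is unchanged.

## Statistical machinery

Diversity and ordination-adjacent steps delegate to **vegan** (Shannon,
Bray–Curtis, Hellinger, rarefaction) behind the package's interfaces;
closed-form cases (ln 4 for four equal counts, BC = 1/3 for (1,2,3) vs
(3,2,1), unit-norm Hellinger rows) are verified against hand-evaluated
formulas. Rarefaction defaults to the minimum retained sample depth with
a fixed seed — a documented operational stand-in, since "apply
rarefaction sparingly" is not a rule — and the depth used is recorded in
the manifest; diversity on unrarefied counts remains available.
Bray–Curtis is computed on raw counts; Hellinger is exposed as the
standard pre-step for ordination methods outside this package's scope.

The Mantel test is implemented directly (Pearson correlation of lower
triangles; joint row/column permutation of the second matrix; one-tailed
"greater" p with the add-one rule `p = (1 + #{r* >= r}) / (1 + n_perm)`;
default 999 permutations) so that seeding is explicit; `vegan::mantel` is
used in the test suite as an independent cross-check, and a 4-sample case
is compared against exhaustive 24-permutation enumeration. Pearson is
chosen over Spearman on distances, matching the linear-model framing of
the dissimilarity–limitation relationship.

Driver screening uses `stats` fits throughout: `cor.test` with pairwise
deletion for correlations (listwise for regressions), classic one-way
ANOVA (two-group F equals the squared pooled t), and OLS with adjusted
R² `1 − (1 − R²)(n − 1)/(n − p − 1)`. Stepwise selection is **forward by
AIC** from the intercept-only model, ties broken by candidate order —
directions and criteria differ across software, so the choice is pinned
and recorded. Forward-AIC admits a spurious noise candidate with
appreciable probability (roughly `1 − 0.84^k` for k candidates); that is
a property of the criterion, not a defect, and the tests assert the
realistic behaviour (planted strong effects recovered; large all-noise
models rare; the selection never has worse AIC than the intercept-only
model).

Random-forest "relative contribution" rankings are replaced by
**model-agnostic permutation importance** around the selected OLS model:
the mean increase in prediction MSE after permuting one predictor's
column, averaged over `n_rep` shuffles and normalised to percentages of
the summed (positive) increases. This keeps the permute-and-measure
notion of importance while avoiding an opaque ensemble dependency; it is
a methodological substitute, not an RF reimplementation, and chance-level
negative increases are floored at zero before normalisation.

## Problem sizes and determinism

Calibration-recovery checks run at n = 10,000 synthetic sites, where
sampling noise (≈1–2% on pooled ratios) is well inside the ±0.02
acceptance bands, cleanly separating calibration error from sampling
error; sign-recovery checks run at the survey's own n = 30, where the
planted effects still give |r| ≈ 0.6–0.9; the Mantel null calibration
uses 500 replicate pairs at n = 20 with 199 permutations each (p
resolution 1/200 at the 0.05 level). Every stochastic step — simulation,
rarefaction, permutations, importance shuffles — flows from an explicit
integer seed, and `run_pipeline()` writes a manifest with the seed and
per-file checksums so a rerun is verifiably identical.

## Known limitations

* The vector statistics carry no uncertainty intervals; the analysis is
  descriptive per sample.
* Redundancy analysis, structural equation models and read-level
  sequence processing are out of scope; the generator emits OTU tables
  directly.
* Missing values are dropped pairwise (correlations) or listwise
  (regressions) with no imputation.
* The classification threshold is a convention (45° = equal investment),
  not a calibrated boundary.
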