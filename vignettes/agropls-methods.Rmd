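---
title: "Multi-response PLS with VIP selection for farm survey data: methods and design"
author: "agropls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-response PLS with VIP selection for farm survey data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agropls)
```

## The problem this package addresses

On-farm studies of crop performance face an awkward data shape: a few dozen
farms, each described by many noisy, collinear, mixed-type variables —
management choices over several seasons, soil chemistry, landscape context —
and several correlated performance indicators measured on a standard crop.
Classical regression cannot handle more predictors than observations, and
factorial experiments cannot vary dozens of management factors at once.
Projections to latent structures (PLS) is built for exactly this regime: it
relates an explanatory matrix $X$ ($n \times p$) and a response matrix $Y$
($n \times m$) through a small number of shared latent components, tolerating
$p > n$ and strong collinearity.

The package implements the full analysis pipeline for this setting: schema
declaration and validation for the explanatory variables, aggregation of raw
survey answers into analysis variables, NIPALS PLS2 with cross-validated
component selection, variable selection by importance in the projection
(VIP), relative prediction error, a multi-subset model suite comparing
organic and conventional farm groups, and a synthetic-data generator with
known ground truth used to test whether the pipeline recovers what it is
supposed to recover.

## The model

Both matrices are decomposed over $A$ shared score vectors:

$$X = T P' + E, \qquad Y = T Q' + F,$$

where $T$ ($n \times A$) holds the X-scores, $P$ and $Q$ the X- and
Y-loadings, and $E$, $F$ the residuals. Components are extracted one at a
time by the NIPALS algorithm: for each component the inner loop alternates
$w \propto X'u$, $t = Xw$, $q \propto Y't$, $u \propto Yq$ until the Y-score
vector $u$ stabilises; both $X$ and $Y$ are then deflated by the rank-one
contribution of $t$ (classical PLS2 — a single-column $Y$ reduces to PLS1
through the same code). The regression coefficients
$B = W(P'W)^{-1}Q'$ map scaled new observations to scaled predictions.

Deflation makes the structural identities exact by construction: score
vectors are mutually orthogonal and both reconstructions hold to machine
precision regardless of inner-loop precision; what the inner loop determines
is the *direction* of each weight vector. Model quality is tracked as
cumulative explained variation $R^2Y$ (per response and overall, on the
scaled response matrix) and predictive ability $Q^2Y$ from cross-validation.

### Preprocessing

All columns of $X$ and $Y$ are mean-centered and scaled to unit variance
before fitting, the default of the commercial chemometrics software whose
conventions this package follows. This includes 0/1 dummy variables, with a
known caveat: scaling inflates the influence of rare categories. We retain
the convention for comparability and flag it here rather than silently
deviating; `scale_y = FALSE` switches the responses to centering only.
Preprocessing statistics are always computed on the training rows and reused
for prediction — inside cross-validation they are recomputed within each
training fold, so no information about held-out rows leaks into the model.

### Cross-validation and component selection

`crossval_q2()` shuffles the rows once (seeded) and cuts them into $K = 7$
contiguous blocks whose sizes differ by at most one. For each component
count $a$, PRESS$_a$ accumulates squared prediction errors on held-out rows,
on the full-data scaled response scale so it is commensurate with the full
fit's residual sums of squares. Per component,

$$Q^2_a = 1 - \mathrm{PRESS}_a / SS_{a-1},$$

with $SS_{a-1}$ the residual sum of squares after $a-1$ components of the
full fit, and the cumulative value is the multiplicative
$1 - \prod_a (\mathrm{PRESS}_a / SS_{a-1})$ (the simple
$1 - \mathrm{PRESS}_A/SS_0$ variant is also reported). $Q^2$ is never
floored at zero: negative values are informative — the model predicts worse
than the response mean — and the reports preserve them.

`select_components()` keeps the largest $A$ such that every component up to
$A$ has per-component $Q^2$ above the limit (default 0.05, the rule family
of the reference software). At least one component is always retained; a
flag marks the case where even the first fails the rule, since a one
component model is still needed to compute VIP and diagnostics.

Seven folds is the reference software's default and behaves well for
$n$ between 12 and 34: leave-one-out (available as `k = n`) is noticeably
optimistic at these sizes, while fewer folds waste training rows.

### VIP and the filter-and-refit workflow

Variable importance in the projection for variable $j$ over $A$ components:

$$\mathrm{VIP}_j = \sqrt{\; p \cdot \frac{\sum_{a=1}^{A} SSY_a \,
(w_{ja}/\lVert w_a \rVert)^2}{\sum_{a=1}^{A} SSY_a} \;},$$

where $SSY_a$ is the Y-sum-of-squares explained by component $a$. The mean
of the squared VIP scores is exactly 1 — an algebraic identity, tested at
$10^{-10}$ — so at least one variable always scores $\ge 1$ and the
standard "eliminate VIP $< 1$" filter can never empty the variable set.

`vip_filter_refit()` runs exactly two rounds: cross-validate and fit the
full model, eliminate variables *strictly* below the threshold (a score of
exactly 1 is retained), then refit on the survivors with a freshly
cross-validated component count. Two rounds — not iteration to a fixed
point — is the procedure as practised; an `iterate = TRUE` mode exists for
exploration but is off by default.

### Prediction error

Because the response indicators carry different units (t/ha, %, counts per
m²), prediction error is reported relative:

$$\mathrm{RMSRE} = 100 \times \sqrt{\tfrac{1}{N}\sum_{i=1}^{N}
\left(\frac{y_i - \hat y_i}{y_i}\right)^2}\ \%.$$

It is scale-invariant, zero iff the fit is exact, and undefined when any
observed value is zero — hence the strict positivity check on yield and
count indicators at data ingestion.

### Score-plot diagnostics

`hotelling_ellipse()` computes the Hotelling $T^2$ 95% region for a pair of
score vectors: critical value $\frac{2(n-1)}{n-2} F_{0.95}(2, n-2)$, ellipse
semi-axes equal to the score standard deviations times the square root of
the critical value. Farms outside the region are flagged as poorly described
by the model — useful for spotting outlying management profiles.

## The explanatory schema and aggregation

The default schema declares 34 variables: 2 whole-farm descriptors, 1
landscape index, 8 farm-level and 18 field-level management variables
(29 non-soil variables in total), plus 5 soil parameters. Each variable
carries a measurement level, a kind (continuous, dummy, ordinal, percentage,
index), a unit and a closed valid range; validation rejects any value
outside its range and any non-binary dummy.

Raw survey answers are mapped onto these variables by one aggregation rule
each: per-year counts become frequencies (e.g. organic fertilizer
applications over three seasons divided by 3), repeated field assessments
are averaged (weed cover over three visits), practices become 0/1 dummies or
small ordinal scales, and land-use areas become percentages of farm area.
The full questionnaire-to-variable mapping of the original instrument is not
public, so each shipped rule documents its assumption; the rule set is data,
not code, and can be replaced.

Two constructed variables deserve detail:

* **Landscape heterogeneity index.**
  $\mathrm{LHI} = \sin 45^\circ \,(z_1 + z_2)$, where $z_1, z_2$ are
  z-scores of the proportions of semi-natural grassland and field border
  around the field. $\sin 45^\circ = \sqrt2/2$ projects the two
  standardized axes onto their diagonal — a 45° rotation — so joint
  enrichment of both habitat types moves a farm along one gradient. We
  interpret the angle in degrees, not radians: the degree reading produces
  the index magnitudes (roughly $-2$ to $+2$) under which the index is
  conventionally reported, whereas $\sin(45\ \mathrm{rad})$ would be an
  arbitrary constant. The standardization population defaults to all farms
  pooled across regions; per-region statistics can be supplied.

* **Region-median standardization.** Variables that differ between the two
  agro-ecological zones for climatic rather than management reasons
  (sowing date, soil clay content) are replaced by deviations from their
  region median, so each region's median maps to exactly zero. Only the
  location is removed — no rescaling by spread — because the within-region
  variation is the signal of interest.

Missing values are disallowed in the analysis matrix. The package takes the
complete-case contract: imputation or row exclusion is an explicit
pre-processing decision of the analyst, not something the fitting code does
silently.

## The nineteen-model suite

The suite refits the whole workflow on nineteen farm subsets: all farms
(Model 1, $n = 34$ under the default design), organic farms only (Model 2,
$n = 22$), conventional only (Model 3, $n = 12$), six balanced draws of 6
organic + 6 conventional farms per region (Models 4–9, $n = 24$), and ten
draws of 6 organic farms per region (Models 10–19, $n = 12$). The balanced
and organic draws guard against artefacts of the unbalanced group sizes;
their overall $R^2Y$ and $Q^2Y$ are summarized as mean ± SD per replicate
group. Resampling is without replacement within stratum (region × organic/
conventional), and the six balanced draws are six independent replicates.

Seeding is hierarchical: a master seed spawns per-model seeds as
`master * 100 + model_index`, so the suite is bit-reproducible end to end
and appending models never perturbs earlier subsets or folds.

Small resampled subsets raise a practical issue: a dummy variable can be
constant within a subset (it then carries no information and cannot be
unit-variance scaled) or within a cross-validation training fold. The
low-level contracts are strict — `center_scale()` errors on a constant
column and `crossval_q2()` names the degenerate fold — but the suite would
be unusable if a single constant dummy aborted a 19-model run, so
`run_suite()` drops subset-constant columns (recorded in the report) and
uses the tolerant scaling mode (`on_constant = "keep"`: center, scale 1)
inside cross-validation, where a fold-constant column simply contributes
nothing. The strict mode remains the default everywhere else.

## The synthetic-data generator

Because the original farm survey is not public, the generator produces
datasets with the structure the analysis assumes, plus exported ground
truth so recovery can be tested quantitatively.

* **Design.** 34 farms, 17 per region, 6 CF + 5 YOF + 6 OOF per region
  (12 conventional, 22 organic). Two latent factors per farm, independent
  standard normal, with an additive region effect (default 0.5) on factor
  1 so regions separate in score plots without dominating them.
* **Explanatory variables.** A designated *active set* carries the latent
  signal: five core variables active on every farm and seven further
  variables active on organic farms only — organic performance depends on
  more factors than conventional, which is the qualitative pattern the
  method is meant to detect. Active columns are latent signal (unit-norm
  loadings) plus Gaussian noise (SD 0.5); inactive columns are pure noise.
  Every column is then mapped into its declared kind: continuous and
  percentage variables are affinely placed in their schema range and
  clipped, dummies threshold the latent column at its median, ordinals are
  quantile-binned, and region-standardized columns are median-centered per
  region. Time since transition is structural (0 for CF, 1–5 for YOF,
  11–26 for OOF), not latent-driven.
* **Responses.** $Y_{std} = T_0 Q_0' + \varepsilon$ with per-type noise:
  SNR 3 by default for all rows. The contrast configuration lowers the
  conventional rows to SNR 0.5, emulating systems whose performance is
  driven by external inputs rather than the surveyed management factors.
  Standardized responses are mapped to plausible indicator units
  (e.g. grain mass 4.5 ± 0.8 t/ha, ears 650 ± 110 m⁻²) and floored just
  above zero so relative errors stay defined.
* **Design R².** `design_r2()` gives the closed-form expected explained
  variation per response: signal variance is the loading row's quadratic
  form in the factor variances — factor 1 has variance
  $1 + \mathrm{region\_effect}^2$ — divided by signal plus noise variance.
  With no region effect and the SNR parameterization this is
  $\mathrm{snr}/(1+\mathrm{snr})$ for every response. A large-sample test
  checks it against an oracle regression on the true scores.

What the generator does *not* emulate: the real covariance structure among
management variables (e.g. livestock density with organic fertilizer use),
measurement error specific to survey answers, or any particular published
effect sizes. Passing recovery tests therefore shows that the pipeline
finds structure of the designed kind at realistic size and noise — not that
it would reproduce any particular real dataset's numbers.

The recovery properties exercised by the test suite, at the sizes chosen
for them: component-count recovery and active-variable recovery over 100
replicate 34-farm datasets at SNR 3 (the designed two components are
selected in well over 80% of replicates and at least 4 of the 5 core
variables survive the VIP filter in nearly all); the organic-vs-conventional
contrast over 100 replicates of the contrast configuration (the organic-only
model explains more variation than the conventional-only model in ~99%);
convergence of fitted $R^2Y$ to `design_r2()` on a 500-farm,
continuous-active-set configuration; and the large-sample `design_r2()`
oracle at 2 500 farms.

## Numerical choices

* **Inner-loop convergence.** Tolerance $10^{-10}$ on the relative change
  of $u$, cap 10 000 iterations. Power iteration converges linearly at the
  ratio of the two leading eigenvalues of $Y'XX'Y$, which can be
  arbitrarily close to 1 in noise-dominated components; when the cap is
  reached the component is completed exactly by symmetric
  eigendecomposition of that small $m \times m$ matrix — the same fixed
  point, computed directly. This keeps deep components deterministic
  without loosening the tolerance.
* **Sign convention.** Each weight vector's largest-magnitude element is
  made positive (flipping $w, t, p, q, u$ together), so output is
  deterministic across platforms; predictions and all variance measures
  are invariant under these flips.
* **Degenerate inputs.** Constant columns error by name (strict mode);
  an all-zero $X$ and exhausted covariance error with the component index;
  `ncomp` is capped at $\min(n-1, p)$ and cross-validation additionally at
  $n - \lceil n/K \rceil - 1$ so every training fold can support the
  requested components.
* **Ties.** Ordinal quantile-binning uses first-occurrence rank ties;
  fold assignment uses one seeded shuffle then contiguous blocks.

## Known limitations

* The two-round VIP filter is a heuristic: variables marginally below 1 in
  a noisy first fit are lost even if they would score above 1 after
  refitting. The optional iterated mode mitigates but does not solve this.
* $R^2Y$ on subsets with $n \approx 12$ and many candidate variables is
  optimistic; the cross-validated $Q^2Y$ — which the reports always carry
  alongside — is the defensible quantity there, and it is routinely
  negative for weakly structured subsets.
* Unit-variance scaling of rare dummies (see above).
* The aggregation rule set covers the declared schema but encodes
  assumptions where the original questionnaire admitted several answers per
  practice; analysts with richer raw data should supply their own rules.
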