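---
title: "Methods: arctangent pressure–area modelling and group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arctangent pressure-area modelling and group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasofit)
```

## The measurement and the model

In an ex vivo inflation–extension test an excised arterial segment is
mounted at fixed axial length and pressurised quasi-statically at ten
steps from 15 to 300 mmHg (`protocol_pressure_grid()`); at each step the
inner diameter is read three times from separately acquired ultrasound
loops. `vasofit` averages the replicates *at the diameter level* and
converts the mean to a lumen area under a circular-lumen assumption,
`A = π(d/2)²` — the minimal assumption consistent with a single
longitudinal-view diameter per loop.

Areas as a function of pressure follow the arctangent (Langewouters)
relation

$$A(P) = A_m\left\{\tfrac12 + \tfrac1\pi \arctan\frac{P-P_0}{P_1}\right\},$$

a sigmoid with three interpretable parameters: $A_m$ (mm²) the
asymptotic maximal area; $P_0$ (mmHg) the inflection, which is also the
pressure of maximal compliance; $P_1$ (mmHg) the half-width — the offset
at which compliance halves. Differentiation gives the compliance curve
analytically,

$$C_A(P) = \frac{A_m/(\pi P_1)}{1 + \left(\frac{P-P_0}{P_1}\right)^2},$$

a Lorentzian peaking at $C_{max} = A_m/(\pi P_1)$, and distensibility is
the relative version $D_A = C_A / A$. Two analytic facts shape the
implementation:

* $D_A$ has no closed-form argmax; `max_distensibility()` runs a dense
  0.1 mmHg grid search over the measured range followed by local
  refinement with `optimize()`.
* $A_m$ cancels in $C_A/A$: the distensibility curve has only **two**
  free parameters $(P_0, P_1)$. Degrees of freedom in the
  distensibility F-test (below) use 2 parameters per curve accordingly.

## Fitting

`fit_arctangent()` performs bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`). Starting values are data-driven: $A_m^{(0)} =
1.05\times$ the largest observed area; $P_0^{(0)}$ the pressure whose
area is nearest half of that; $P_1^{(0)}$ half the inter-quartile width
of the pressure grid. Bounds — $A_m \in (0, 10\times\max A]$, $P_1 \in
(0, 10^4]$, $P_0 \in [-1000, 1000]$ mmHg — keep the optimiser in the
identifiable regime while letting the compliance peak sit outside the
measured grid, which real stiff vessels produce. The convergence
tolerance is $10^{-10}$ on cost reduction; a non-converged result is
returned flagged, never silently.

Guard rails: a series needs at least 5 distinct pressures (3 parameters
plus 2; rupture-truncated samples below the floor are reported with an
`insufficient_data` status rather than pseudo-fitted), and a series of
constant areas is flagged `insufficient_signal` instead of being given
spurious parameters. $R^2$ is $1 - RSS/TSS$ with TSS about the mean
observed area, the common nonlinear-regression reporting convention; it
is reported for the area fit only, since the derived curves are not
independently fitted per sample.

Ruptured samples keep all pressure points below the rupture pressure;
the rupture pressure itself is carried as metadata (`truncated_at`) and
excluded from the fit grid. Whether "maximal area" should be read as the
fitted asymptote or the largest measured area is a reporting ambiguity;
`process_dataset()` emits both (`Am_mm2` and `max_measured_area_mm2`),
and downstream ANOVA defaults to the fitted $A_m$.

## Comparing whole curves between age groups

`nested_f_test()` asks whether one curve explains all samples at a
location as well as one curve per age group, via the extra-sum-of-squares
construction: fit the model once to all points pooled ($RSS_p$, $p$
parameters) and once per group ($RSS_s$, $pk$ parameters over $k$
groups), then

$$F = \frac{(RSS_p - RSS_s)/(p(k-1))}{RSS_s/(N - pk)} .$$

For the pressure–area curve the points are the observed areas. An F-test
needs data-level residuals, so for compliance and distensibility the
analytic forms are fitted to *empirical* finite-difference points
(`empirical_compliance()`: forward differences at interval midpoints;
distensibility divides by the midpoint-interpolated area) rather than to
residual-free analytically derived curves.

**Error model.** Ultrasound caliper noise scales with the measured
diameter, so area residuals are heteroscedastic with SD proportional to
the area — across a 15–300 mmHg grid the residual variance spans more
than an order of magnitude. An unweighted extra-SS F-test is visibly
anticonservative under such noise. `nested_f_test()` therefore defaults
to a proportional error model: fixed weights $w_i = 1/y_i^2$ computed
from the observed values and shared between the pooled and group fits,
so the models remain exactly nested and the weighted RSS enters the F
ratio. `error_model = "additive"` restores the unweighted test. Two
caveats are documented rather than modelled: residuals are treated as
independent across pressure points within a sample (the within-sample
correlation induced by between-vessel spread makes point-level p-values
optimistic when vessels genuinely vary), and noise-free degenerate input
($RSS_s \le 10^{-12}\,TSS$) short-circuits to "no effect, degenerate"
instead of dividing by ~0.

Separate-group fits also try the pooled solution as a starting value; if
an optimiser wobble still leaves $RSS_p < RSS_s$, the numerator is
clamped at zero — nesting is a mathematical fact the report must not
violate.

For the fitted group curves drawn by `plot_curve_families()` the default
is the pooled per-group fit (one curve to all the group's points); a
mean-of-parameters alternative (`group_method = "mean_params"`) is
provided since either convention is defensible for display.

## Summary metrics and histology inference

Per-sample maxima (maximal area, maximal compliance with its pressure —
clipped to the measured range when $P_0$ falls outside it — and maximal
distensibility with its argmax) are compared with separate univariate
two-way ANOVAs per outcome, age and location fixed, type-III sums of
squares under sum-to-zero contrasts (the convention of mainstream GUI
statistics software, for comparability). Pairwise location contrasts on
estimated marginal means (`emmeans`) are adjusted by the package's own
`bonferroni()` over the full $\binom{k}{2}$ family, and a greedy
compact-letter display reproduces the usual table superscripts.

Histology slides carry five measurements each (image frames for stain
area %, random positions for wall thickness). Aggregation follows the
protocol's order — means first, weighting second: per-layer five-value
means, then the thickness-weighted overall area %

$$\text{overall} = pct_1\frac{t_1}{t_1+t_2} + pct_2\frac{t_2}{t_1+t_2}.$$

This order is *not* equivalent to weighting frame-by-frame and averaging
(a unit test documents a counterexample); the package deliberately
implements the protocol's order. The proximal aorta is single-layer
(weighting bypassed) and its thickness is not assessed, so it is absent
from thickness inference. `histo_anova()` fits, per outcome, a linear
mixed model with age and location fixed and horse as a random intercept
(each horse contributes every location; `lmerTest` Satterthwaite
F-tests). The analysis unit is the horse × location mean, matching the
random-factor structure. If the random intercept is not estimable the
fallback is a fixed-effects ANOVA on the same data, flagged in the
output — never a silent switch.

## The synthetic generator: what it emulates, and what not

`gen_inflation_dataset()` reproduces the study design: 6 young + 14 old
subjects, four mechanically tested locations, the 10-point grid,
triplicate diameters. Per-location × age anchor parameters come from the
study-scale summary table: $A_m$ = the group mean maximal area, $C_{max}$
= the group mean maximal compliance, and $P_1 = A_m/(\pi C_{max})$ backed
out of the peak-compliance identity. $P_0$ defaults to 112.5 mmHg, the
midpoint of the 100–125 mmHg band where equine arteries reach maximal
compliance. Defaults chosen where no source states a value (and
documented as modelling assumptions, not measured facts):

* between-horse SDs — $A_m$ SD taken from the summary table directly,
  $P_1$ SD = 20% of $P_1$, $P_0$ SD = 10 mmHg;
* diameter noise — 2% multiplicative, a plausible ultrasound caliper
  repeatability;
* rupture simulation — off by default; when enabled, 10% of old-group
  samples (the observed ruptures were a minority, almost all old) lose
  their grid points at/above 250 mmHg.

`gen_histology_dataset()` mirrors the histology structure: seven
locations, five frames per slide, a two-layer media always present in
muscular arteries, in 40% of distal aortas and never in the proximal
aorta; layer 1 takes 0.6 of the total thickness; frame-level SD is half
the between-horse SD; both layers share a horse's stain mean so the
thickness weighting is mean-preserving by construction.

What the generator does **not** emulate: within-sample residual
correlation beyond the shared true curve, axial-stretch or viscoelastic
effects, non-circular lumina, drifting calibration, inter-observer
differences, stain-threshold subjectivity, or spatial correlation of
frames within a slide. Passing tests therefore certify the pipeline's
correctness and calibration *under this noise model*, not the field
validity of the biological conclusions.

## Numerical and design choices

* Multi-start fallback (a small ladder of $P_1$ values, plus the pooled
  solution for group fits) protects the Lorentzian and distensibility
  fits, whose loss surfaces are less benign than the area fit's.
* Curve maxima: compliance argmax is analytic ($P_0$, clipped);
  distensibility argmax is grid-plus-refine as above.
* The degeneracy threshold $10^{-12}\cdot TSS$ separates "noise-free"
  from "small residual" scale-freely.
* `bonferroni()` caps at 1 and accepts an explicit family size so the
  adjustment stays correct when only a contrast subset is displayed.
* Significance letters use a greedy insert procedure over the adjusted-p
  matrix; it reproduces standard table letterings for well-separated
  groups but is not a minimal clique cover in adversarial cases.

Validation problem sizes (the package's own choices, balancing Monte
Carlo resolution against laptop-scale runtimes): exact recovery on
randomized parameters ($P_0 \in [40,200]$, $P_1 \in [10,150]$) at
$10^{-6}$ relative tolerance; headline noisy recovery on 200 samples at
the default 2% noise (observed: median $A_m$ error well under the 5%
bound); F-test size over 1000 null replicates judged against the 95%
binomial interval around 0.05; label-permutation agreement on 20 small
datasets; histology power and size over 200 replicates each.

## Known limitations

* Point-level curve comparison ignores within-vessel correlation; with
  real between-animal heterogeneity its p-values overstate evidence.
  A mixed nonlinear model would be the principled upgrade.
* The proportional error model is assumed, not estimated; grossly
  different instruments may need `error_model = "additive"` or bespoke
  weights.
* Summary-metric ANOVA treats fitted parameters as observations,
  propagating no fit uncertainty.
* The generator's anchors are group means of a single study's scale;
  they define a realistic operating point, not a population model.
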