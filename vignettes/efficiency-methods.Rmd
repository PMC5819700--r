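---
title: "Hybrid DEA and panel-data evaluation of health-resource efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid DEA and panel-data evaluation of health-resource efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deapanel)
```

`deapanel` evaluates how efficiently a set of comparable service units —
here community health centers (CHCs) grouped into economic zones —
convert staffing, beds and public financing into patient care.  It
chains two complementary stages: a *data envelopment analysis* (DEA)
stage that benchmarks each unit against the best observed practice in
each year, and a *Cobb-Douglas panel-data* stage that estimates how
output responds to each input over the whole observation window.  A
seeded synthetic generator reproduces the statistical structure such an
analysis assumes, so the entire pipeline runs and is tested without any
administrative micro-data.

## The DEA stage

### Envelopment programs

Each unit $o$ in a period cross-section has inputs $X_o \in
\mathbb{R}^m_{>0}$ and outputs $Y_o \in \mathbb{R}^s_{>0}$.  The
input-oriented CCR (constant-returns) program asks for the largest
equiproportionate input contraction that best practice could support:

$$\min_{\theta,\lambda}\ \theta \quad \text{s.t.}\quad
\sum_j X_j \lambda_j \le \theta X_o,\qquad
\sum_j Y_j \lambda_j \ge Y_o,\qquad \lambda \ge 0 .$$

The BCC (variable-returns) variant adds the convexity constraint
$\sum_j \lambda_j = 1$ and yields *pure technical efficiency*; the ratio
of the two scores is *scale efficiency*.

Radial contraction alone can leave residual input excess or output
shortfall, so a second phase maximises the total slack at the fixed
optimal $\theta^\*$.  Two numerical choices matter here:

* **Two-phase instead of a non-Archimedean $\varepsilon$.**  Folding the
  slacks into the objective with an "infinitesimal" weight is the
  textbook presentation but is numerically treacherous; solving for
  $\theta^\*$ first and then maximising slacks at fixed $\theta^\*$ is
  the standard safe equivalent and also pins down the reference weights
  $\lambda$ used for the scale measure $k = \sum_j \lambda_j$.
* **Slacks are maximised on max-normalised data.**  All data are
  internally rescaled by per-variable maxima before the programs are
  solved.  $\theta$ is invariant to measurement units either way, but a
  raw-unit slack sum would not be: changing beds from counts to
  hundreds would change which slack pattern is "maximal".  The
  normalised objective is scale-free, and slack values are reported back
  in original units.

Classification follows the usual three-way rule: $\theta = 1$ with zero
slack is *DEA efficient*; $\theta = 1$ with positive slack is *weakly
efficient*; $\theta < 1$ is *non-efficient*.  The frontier projection
("ideal value") is $X' = \theta X_o - S^-$, $Y' = Y_o + S^+$, and
re-evaluating a projected point yields $\theta = 1$ with zero slack —
a property the tests exercise as a solver round-trip.  Returns to scale
are read from the slack-maximal CRS weight sum: $k = 1$ (within
$10^{-6}$) is scale-invariant, $k < 1$ increasing, $k > 1$ decreasing.

### The linear-program solver

The envelopment and multiplier programs are small (tens of variables)
but routinely degenerate: at $\theta^\*$ many bases tie, and generic
pivoting can cycle or crash.  The package therefore carries its own
dense two-phase primal simplex with Bland's anti-cycling rule
(`lp_solve()`), which terminates on every input and reports
infeasibility and unboundedness explicitly.  Feasibility/pivot
tolerance is $10^{-9}$; efficiency comparisons use $10^{-6}$.  The test
suite cross-checks $\theta$ and the phase-2 slack optimum against an
independent exhaustive enumeration of basic feasible solutions on
hundreds of random small instances.

Reference weights at degenerate optima are not unique; the package
reports the phase-2 (slack-maximal) solution and documents it as such.

### Cross-efficiency

Self-appraised DEA weights show every unit in its best light.  In the
peer-appraisal matrix, each rater's CCR-optimal weights score all
units; because optimal weights are usually non-unique, the *benevolent*
secondary goal is applied: among the rater's optimal weights, choose
those that maximise the combined weighted output of the other units
(normalised by their combined weighted input) while preserving the
rater's own score.  The diagonal reproduces the CCR scores; column
means give each unit's cross-efficiency.  The aggressive variant and
other secondary goals are deliberately out of scope.

### Malmquist productivity change

Between adjacent periods $t, t+1$ the geometric-mean input-oriented CRS
Malmquist index is

$$MI = \sqrt{\frac{E^t(t{+}1)}{E^t(t)}\cdot
\frac{E^{t+1}(t{+}1)}{E^{t+1}(t)}},$$

where $E^p(q)$ evaluates the unit's period-$q$ data against the
period-$p$ frontier.  The four-factor decomposition follows the
FGNZ convention: efficiency change $EC = E^{t+1}(t{+}1)/E^t(t)$,
technological change $TC = MI/EC$, pure-technical-efficiency change
$PTEC$ from the within-period VRS scores, and scale-efficiency change
$SEC = EC/PTEC$.  The identities $MI = TC \times EC$ and $EC = PTEC
\times SEC$ hold by construction and are asserted per record.  Two
pitfalls are handled explicitly:

* cross-period evaluations may legitimately exceed 1 and are exempt
  from the $\theta \le 1$ invariant;
* cross-period *VRS* programs can be infeasible (a known pathology when
  the evaluated output level is unreachable by the reference convex
  hull).  `dea_solve()` reports `status = "infeasible"` instead of a
  number; the FGNZ decomposition needs only within-period VRS scores,
  so the Malmquist stage itself never hits the pathology.

Zone-level summaries of the multiplicative factors are offered both as
arithmetic and geometric means, clearly labelled, because the two do
not coincide and published regional tables rarely state which was used.

## The variable screen

Three screens reduce a candidate variable list before the DEA stage:

1. **Collinearity filter** — for every pair with $|r| \ge 0.9$ the
   member with the lower coefficient of variation is dropped (ties go
   to the lexicographically earlier name).  Pairs are processed in
   decreasing $|r|$, which makes the outcome independent of column
   order.  The 0.9 default is the package's choice; the screen it
   replaces (an SPSS cluster-analysis shortlisting whose linkage,
   distance and cluster count were never published) is not reproducible.
2. **Explanatory power** — an input survives if a one-regressor fit of
   at least one output on it reaches $R^2 \ge 60\%$, the conventional
   benchmark.  Simple regressions are used deliberately: the screen
   asks whether an input *individually* carries output information.
3. **Dispersion ranking** — coefficients of variation, largest first,
   for reading off the final shortlist.

The full screen is idempotent and invariant to positive rescaling of
any column.  On the default synthetic world the 60% benchmark is
frequently *not* met at the 13-unit study size (see the generator
section); the pipeline then records the screen's verdict but falls back
to the declared variable lists with a warning, rather than aborting the
analysis.

## The panel production stage

All estimation is on natural logs of strictly positive data
(nonpositive records are rejected and named, never offset).  The model
is $\ln Y_{it} = \beta_0 + \beta_1 \ln \text{workers}_{it} + \beta_2
\ln \text{beds}_{it} + \beta_3 \ln \text{financing}_{it} + u_{it}$, in
four forms:

| form | intercepts | slopes | estimator |
|---|---|---|---|
| pooled | common | common | OLS |
| fixed intercept | per unit | common | LSDV $\equiv$ within |
| fixed coefficient | per unit | per unit | joint LSDV $\equiv$ per-unit OLS |
| random effects | common + unit component | common | Swamy–Arora FGLS |

The fixed-coefficient form varies *both* intercepts and slopes — the
most general specification consistent with reporting per-city
coefficient blocks.  $R^2$ is computed as $1 - RSS/TSS$ about the
overall mean for all fixed forms, which makes the nesting inequality
$R^2_{\text{pooled}} \le R^2_{\text{fixed int.}} \le
R^2_{\text{fixed coef.}}$ exact.  Equivalences (within vs dummy
variables; joint vs per-unit fits) are verified to $10^{-10}$/$10^{-8}$
in the tests.

The random-effects comparator uses the standard one-way
error-components moment estimators (within residual variance;
between-regression variance; negative unit-variance estimates truncated
at zero with a warning) and GLS by quasi-demeaning.  The Hausman
contrast $H = d^\top (V_{FE} - V_{RE})^{-1} d$ uses the slope blocks
only; when the covariance difference is not positive definite — which
happens in finite samples — the Moore–Penrose pseudo-inverse over the
positive eigenspace is used and the report flagged.

Poolability is tested with the two covariance-analysis F statistics:
F2 (pooled vs fixed coefficient) and F1 (fixed intercept vs fixed
coefficient), with degrees of freedom always computed from the actual
data dimensions rather than hard-coded to any particular $N, T$.  A
numerically zero unrestricted RSS (noise-free data) makes the
statistics undefined and is reported as an error.

### Panel unit-root tests

The individual-process route is the decision statistic: a per-unit ADF
regression (intercept, or intercept plus trend for trending series —
an explicit configuration choice, not auto-detection; default one
lagged difference) combined across units by Fisher's
$P = -2\sum_i \ln p_i \sim \chi^2_{2N}$.  The common-process route is
reported as the pooled lag-augmented t statistic on per-unit
demeaned/detrended data — a simplified form without the full
small-sample mean/variance corrections, and therefore reported
*without* a p-value.

ADF p-values come from a finite-sample null quantile table simulated at
400 000 replicates per case and series length (grid $T \in \{25, 40,
60, 100, 200, 500\}$, both deterministic cases; generation script and
seed in `data-raw/adf_quantiles.R`), interpolated in the statistic and
in $1/T$, with asymptotic response-surface tail formulas beyond the
tabulated $[0.0005, 0.9995]$ probability range.  The table exists
because asymptotic p-values are visibly oversized at the series lengths
panel work actually uses ($T \approx 60$), and the Fisher combination
amplifies any per-series distortion.

## The synthetic data generator

The generator emulates the three-zone CHC system the analysis targets:

* **Inputs.**  Doctors, nurses, pharmacists, other staff, beds and
  public financing are drawn log-normally per zone, moment-matched to
  the per-zone 2015 mean/SD staffing profiles of the three economic
  zones (southern, middle, northern); the financing profile is the
  package's own realistic choice, as the published staffing tables do
  not cover it.  Draws are truncated below at 1.0 unit.  Counts are
  left continuous: rounding would destroy the exact noise-free
  recovery property the estimator tests rely on.
* **Unit-size factor.**  A persistent unit-level factor carries 60% of
  each input's log variance (configurable).  Real facilities differ
  mainly in overall scale — a large center has more doctors, beds *and*
  funding — and without this joint dispersion the explanatory-power
  screen faces data unlike anything it was designed for.  Per-variable
  means and SDs remain exactly matched.
* **Outputs.**  Outpatient visits, inpatient cases and diagnoses follow
  a Cobb-Douglas law in aggregate health workers (the four staff
  columns summed), beds and financing, with default elasticities
  $(0.3, 0.2, 0.5)$ — decreasing returns to scale with financing
  dominant — and per-output intercepts chosen so output magnitudes are
  realistic for the system (hundreds of thousands of outpatient visits,
  thousands of inpatient cases).  On top sit a unit fixed effect, an
  idiosyncratic normal disturbance (default SD 0.1), and a one-sided
  multiplicative half-normal inefficiency term (default scale 0.15) —
  the standard stochastic-frontier convention.
* **Correlated effects.**  The fixed effect can be tied to the unit
  mean of a chosen log input through a correlation parameter
  (Gaussian-copula style), which is what gives the Hausman test a
  power scenario: at correlation 0.8 the random-effects estimator is
  biased and the test rejects in well over half of replicates at the
  study dimensions.
* **Deflation.**  An optional year-indexed deflator converts nominal
  financing to base-year prices (`deflate_series()` /
  `deflate_panel()`); deflating and re-inflating round-trips to
  machine precision.

What the generator does **not** emulate: serial correlation within
units beyond the persistent size factor, measurement error in counts,
entry/exit of units (panels are balanced by construction, though the
estimators accept unbalanced data), and any particular correlation
pattern among the published staffing tables beyond per-variable
moments.  Tests passing on this world therefore certify the *method
implementation* — solver correctness, estimator algebra, test
calibration — not fidelity to any real administrative data set.

## Problem sizes and runtime choices

The verification suite uses sizes chosen to make Monte-Carlo error
small relative to what is being asserted while keeping the whole suite
in the minutes range: 200 random instances for the DEA-vs-enumeration
equivalence (enumeration cost grows combinatorially, which caps
instance size at 5 units, 3 inputs, 2 outputs); 200 replicates for
estimator recovery at the study dimensions $N = 13$, $T = 8$,
$\sigma = 0.1$; 1000 replicates for the poolability size check (the
statistic is exactly F-distributed under this null, so the band around
5% is an MC-error statement and more replicates sharpen it); 500
replicates for Fisher-ADF size and Hausman power.

## Known limitations

* The simplex is dense and unoptimised; it is comfortable at tens of
  units and would need a revised-simplex or external solver for
  thousands.
* Cross-efficiency implements only the benevolent secondary goal.
* The common-process unit-root statistic is uncorrected and therefore
  descriptive; decisions should use the Fisher route.
* Classical (homoskedastic, non-clustered) covariances throughout; no
  dynamic panels, GMM, spatial effects or cointegration.
* No super-efficiency, SBM/additive models, output orientation, weight
  restrictions, or bootstrap confidence intervals for $\theta$.
* Efficiency scores from cross-period evaluation are reported as
  computed (possibly above 1); only within-period scores are classified.
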