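---
title: "Models, methods, and design choices in tiadose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, methods, and design choices in tiadose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiadose)
```

## The problem

Organ-level internal dosimetry for radiopharmaceutical therapy reduces to
one integral per region: the time-integrated activity (TIA)
$\tilde A = \int_0^\infty A(t)\,dt$, multiplied by a dose factor to give
an absorbed dose in Gy. The integrand is only observed at a few imaging
time points — typically four SPECT scans spread over one to eight days —
so everything before the first scan, between scans, and after the last
scan is model. Different centers make different modelling choices, and
`tiadose` exists to implement those choices explicitly and to measure how
much dose spread they generate.

The integral is split into three intervals:

* **I1**, from injection (time 0) to the first or second time point. With
  near-instantaneous uptake this interval is short and contributes
  little, but it still requires an assumption: a line from the origin, a
  constant at the second point's value, or the fitted model extended
  back.
* **I2**, across the sampled range. Here the data constrain the curve:
  either a fitted exponential model or trapezoidal interpolation.
* **I3**, from the last time point to infinity. Pure extrapolation, and
  empirically the dominant source of between-method spread; guidance in
  the field asks that it contribute less than 20% of the total TIA, and
  `tiadose` flags (strictly) larger tail fractions.

## Model families

Three families cover standard practice. The monoexponential
$A e^{-\lambda t}$ assumes instantaneous uptake and a single washout
phase — appropriate for most healthy organs. The three-parameter
biexponential $A\,(e^{-\lambda_1 t} - e^{-\lambda_2 t})$ is exactly zero
at $t = 0$ and describes an uptake phase ($\lambda_2$, fast) followed by
washout ($\lambda_1$, slow); it is the natural lesion model, and the
reduction to a single amplitude makes it markedly better conditioned on
four points than the four-parameter form
$A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}$. The four-parameter model is
supported because it is used in practice, but fitting four parameters to
four points is an interpolation, not a regression: the package always
attaches an `ill_conditioned_4param` warning, and the back-extrapolated
activity at $t=0$ is checked against the injected activity when known.

All integrals are evaluated analytically, including the improper tails,
which require every decay constant in the integrand to be strictly
positive; a non-positive rate with an infinite upper limit raises a
distinct, catchable condition (`tiadose_divergent_integral`) so that
assembly code can flag a divergent tail instead of crashing. The
degenerate biexponential with $\lambda_1 = \lambda_2$ is defined by the
reparameterized limit $A \lambda t e^{-\lambda t}$, selected when the two
rates agree to within $10^{-9}$ relative; this is a convention for the
degenerate family member (the raw three-parameter form collapses to the
zero curve there), not a continuity claim.

Time is hours post-injection, activity MBq, TIA MBq·h throughout. The
default nuclide is ¹⁷⁷Lu with a physical half-life of 6.6475 d
($\lambda_{phys} = 0.004345\,\mathrm{h^{-1}}$), taken from published
nuclear data and overridable through `nuclide_constants()`, so nothing
else in the package is nuclide-specific.

A triexponential family is deliberately absent: its functional form and
constraints are not pinned down by the practice this package models, and
guessing one would create a method no user could match to their own.

## Fitting

`fit_curve()` minimizes (optionally weighted) squared residuals with
`minpack.lm::nls.lm` — genuine Levenberg–Marquardt, switching to the same
minimizer with box bounds when constraints are active. The contract is
"least-squares minimum respecting bounds", not a particular algorithm.
Control settings are tight (`ftol = ptol = 1e-15`, up to 1000
iterations) so that noiseless synthetic data is recovered to machine-level
accuracy and bounded/unbounded runs agree when the optimum is interior.

Two constraint details matter. First, the optional physical bound: with
`constrain_lambda_physical = TRUE` every decay constant is bounded below
by $\lambda_{phys}$, encoding the physical fact that nothing clears slower
than pure radioactive decay; when the unconstrained optimum violates the
bound the fit returns the rate pinned exactly at $\lambda_{phys}$.
Second, the biexponential ordering: internally the three-parameter model
is optimized as $(A, \lambda_1, \Delta\lambda)$ with
$\Delta\lambda = \lambda_2 - \lambda_1 \ge 0$ as a box bound, so the
uptake rate can never cross below the washout rate.

Initial guesses are deterministic and documented: log-linear regression
on the positive activities for the monoexponential (exact on exact data);
for the biexponential families the washout rate comes from the last two
points, the uptake rate is set ten times faster, and amplitudes are
scaled to the observed peak (or pinned to the first and last points for
the four-parameter form). There are no random restarts by default; a
deterministic perturbed-start ladder is available via `n_restarts`.

Weighting: the `relative` scheme uses $\sigma_i \propto$ the measured
activity, floored at 1% of the peak so zero-activity points cannot get
infinite weight. This is a transparent stand-in for the more elaborate
error models used in SPECT uncertainty work, not a reimplementation of
any of them; user-supplied $\sigma$ vectors are accepted for anything
more specific. Unweighted fitting is the default.

Goodness of fit is reported as $R^2$, $\mathrm{AIC} = n \ln(RSS/n) + 2k$,
and AICc where defined. With $n = k = 4$ the AICc denominator
$n - k - 1$ is negative, so AICc is reported as undefined rather than a
meaningless number — one more reason the four-parameter model on four
points is flagged rather than trusted.

## TIA assembly and the method catalog

A `tia_method()` is a (head, body, tail) rule triple. The default catalog
holds eleven methods spanning the combinations seen in practice:
trapezoid bodies with physical-decay, line-to-zero, or fitted
effective-decay tails; fully model-based mono- and biexponential methods,
constrained and unconstrained; constant-head variants that exclude the
first time point; and the four-parameter model.

Conventions worth stating precisely:

* **Constant head**: the rectangle spans $[0, t_2]$ at the *second*
  point's activity (the first point is excluded, also from any body fit).
  For comparability across methods, the *reported* I1 is the area from 0
  to the first time point only; the remainder of the rectangle is
  reported under I2. The parts always sum exactly to the total.
* **Line-to-zero tail**: the line through the last two measured points
  extended to its zero crossing, integrating the resulting triangle
  ($y_n^2 / (2|s|)$ for slope $s < 0$). A non-negative terminal slope has
  no zero crossing and is flagged (`nondecaying_tail`) with an undefined
  total. Among plausible readings of "linear decay after the last point"
  (extrapolating the last segment vs. a line to a fixed horizon) this is
  the most common one, and it is isolated behind a single rule so a
  different reading is a one-line replacement.
* **Model head**: the fitted model integrated over the head interval,
  with negative excursions (possible for the unconstrained four-parameter
  model) clipped at zero via quadrature and flagged.
* **Effective tail** (`monoexp_last3`): a monoexponential fitted,
  unweighted and unconstrained, to the last three points, integrated
  analytically beyond the last scan.

Two properties of the catalog reproduce known behavior and are enforced
by tests: on washout-phase data whose last-three fitted rate is at least
$\lambda_{phys}$, the physical-decay tail always dominates the fitted
effective tail (physical decay is the conservative, radiation-protection
choice); and model-based and trapezoid-based routes agree within about 2%
when the washout rate is within roughly $3\times\lambda_{phys}$ —
trapezoid overshoot on a convex exponential grows with the rate times the
inter-scan gap, reaching ~20% by $12\times\lambda_{phys}$ on a four-point
schedule, which is precisely why method choice matters.

## Dose conversion

The dose model is deliberately self-dose only:
$AD = \tilde A \times S$, with optional inverse-mass rescaling of the
factor (an approximation that holds for the electron-dominated local dose
of ¹⁷⁷Lu). The shipped factor table is synthetic — realistic in magnitude
(factors scale as $1/\mathrm{mass}$), but not from any phantom library —
and is meant to be replaced by the user's own factors. Cross-organ photon
dose is out of scope; the variability questions this package addresses
live upstream of that term.

Two error-prone steps get dedicated functions. `combine_kidneys()`
implements the mass-weighted average
$(m_L d_L + m_R d_R)/(m_L + m_R)$; plain summation of the two kidney
doses — a documented real-world mistake — always exceeds it.
`apply_decay_correction()` converts between activity conventions:
injection-time-corrected values carry a factor
$e^{+\lambda_{phys} t_i}$ relative to the activity actually present at
the scan. Correction to the start of each SPECT scan is treated as
numerically identical to the uncorrected activity (per-scan duration
offsets are not modelled), which makes the round trip exact and the
"forgot to undo the correction" pitfall an exact pointwise identity — the
property the error-injection machinery relies on.

## Variability statistics

The quartile coefficient of dispersion $(Q_3-Q_1)/(Q_3+Q_1)$ is the
primary spread measure because it is far less outlier-sensitive than the
coefficient of variation, and the observed outliers in multi-center data
are mostly errors, not fitting variability. The quantile convention is
not universal; the default is linear interpolation between order
statistics (`stats::quantile` type 7, the mainstream default), and the
type is exposed because QCD values shift slightly across conventions.
Outlier fences are $Q_1 - 1.5\,\mathrm{IQR}$ to $Q_3 + 1.5\,\mathrm{IQR}$
with *strict* inequality — a value exactly on the fence is not an
outlier. Reports print percentages to one decimal place.

The paired analysis compares, per participant, the dose from their own
fitting (task 4) against the dose from a shared reference TIA (task 5),
normalized by the *cohort mean* of task-5 doses for the region — not the
participant's own value, so one participant's error cannot distort
everyone's denominator. Only participants present in both tasks enter;
regions with fewer than two paired participants are skipped, not
computed. `qcd_difference()` reports QCD(task 4) − QCD(task 5) per
region: the spread attributable to the fitting step.

## The synthetic cohort

The generator emulates the structure of a two-patient, four-time-point
multi-center dosimetry comparison exercise. Patient A images at 3.7, 27.7, 103.1, 124.0 h with
activities decay-corrected to injection time; patient B at 3.7, 32.6,
99.6, 193.3 h corrected to scan start. Ground truth per region is a model
curve, so the exact TIA is known in closed form and every pipeline stage
can be scored against it.

Default kinetics (chosen once, as plausible ¹⁷⁷Lu-DOTATATE values, and
not revisited): patient A has instant-uptake kidneys, spleen, and liver
(monoexponential, washout rates 0.009–0.0145/h, i.e. effective
half-lives of ~48–77 h, all faster than physical decay) and two
liver-contained biexponential lesions sized so the lesions carry ~48% of
the whole-liver TIA — making wrongful lesion inclusion inflate the
healthy-liver TIA by ~93%. Patient B has slow-uptake biexponential
kidneys, two small liver lesions (~6% inflation), and two further
lesions. Noise is multiplicative Gaussian, default 5%, truncated at zero
— a transparent stand-in for SPECT quantification error, pluggable where
a fuller error model is wanted.

A virtual cohort draws, per participant, a method from a frequency table
over the catalog, a software class, and three independent error modes:
`skip_decay_uncorrection` (fit the injection-corrected values as if they
were scan-time activities; inflates every point by exactly
$e^{\lambda_{phys} t_i}$ and every method's TIA with it — only patient A
is affected, since patient B's convention is a no-op),
`include_lesions_in_liver` (the liver VOI swallows the contained
lesions), and `sum_kidneys_unweighted` (total kidney as a plain sum).
Task-5 doses push the true TIA through each participant's dose step, so
conversion-stage errors persist across tasks while fitting errors do not
— mirroring how the two-task design isolates the fitting step. When a
drawn method is infeasible on a drawn series (e.g. a noise-inverted
terminal segment under a line-to-zero tail) that participant simply has
no task-4 submission for the region, as in a real challenge.

A cohort is a pure function of (configuration, seed): same seed, byte
identical output files.

What passing tests on this generator do *not* show: anything about image
formation, VOI segmentation, RTStruct-vs-mask volume differences, or
registration artifacts — all real contributors to multi-center spread
that sit outside the time–activity table this package starts from. The
synthetic kinetics are illustrative, not fitted to any patient's data.

## Problem sizes and numerical tolerances

The test suite verifies closed-form integrals against adaptive quadrature
($10^3$ random draws per family, $10^{-6}$ relative for finite
integrals, $10^{-4}$ against quadrature truncated at 20 half-lives for
improper ones), parameter recovery on noiseless data ($10^{-6}$
relative), the constraint contract on 500 noisy datasets (bound always
respected; interior optima agree with unconstrained fits to $10^{-8}$),
the statistics against a direct sorted-formula oracle ($10^3$ vectors),
interval additivity at $10^{-12}$ relative, the physical-vs-effective
tail ordering on 500 washout series, and cohort-level dispersion across
100 seeds at 24 participants. The Monte-Carlo comparison of the
Levenberg–Marquardt TIA against an independent profiled grid-search
oracle runs 300 replicates. These sizes keep the default suite fast while
leaving the estimates stable; all are trivially scalable upward.

## Interface

The package's interface is its functions — `run_pipeline()` drives
simulate → fit → TIA → dose → variability end to end from a plain list or
YAML configuration, writing CSV tables and a JSON summary stamped with
the seed and a configuration hash — plus `validate_against_reference()`
for field-wise comparison of two result tables, supporting the practice
of benchmarking one implementation against another. CSV is the only
interchange format: imaging formats sit outside the package's scope.

## Known limitations

Voxel-level fitting (and per-voxel model selection) is not implemented;
the package operates on region-level series. The dose model ignores
cross-organ photon dose. The weighting scheme is a stand-in, not a
validated SPECT error model. The synthetic generator's noise is
independent across time points, which understates the correlated
component of real quantification error. And the trapezoid-vs-model 2%
agreement holds only in the organ washout regime (rates within about
$3\times$ physical); faster kinetics on sparse schedules make the routes
diverge, which is a finding, not a defect.
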