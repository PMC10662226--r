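---
title: "Models and methods behind leafPhys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leafPhys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafPhys)
```

# Scope

leafPhys analyses leaf-excision phenotyping experiments on three crop
functional types — tomato (C3 dicot), barley (C3 monocot) and maize (C4
monocot) — in which leaves cut the day before measurement are compared with
leaves left attached to the plant, in the morning (AM) and afternoon (PM).
The package covers four measurement channels and the inference layer that
ties them together:

1. photosynthetic capacity from A/ci gas-exchange response curves,
2. non-photochemical quenching (NPQ) kinetics from pulse fluorometry,
3. hyperspectral leaf reflectance (indices and spectra-wide testing),
4. scalar traits (leaf water potential, ABA, light-saturated gas exchange),

plus a seeded synthetic-data generator that reproduces the full
species x treatment x time x replicate structure, so every stage of the
pipeline can be exercised and validated without instrument data.

# Photosynthetic capacity models

## C3: FvCB with bilinear transition estimation

Net assimilation is the minimum of a Rubisco-limited and an
RuBP-regeneration-limited rate,

$$A = \min\left(V_{cmax}\frac{c_i-\Gamma^*}{c_i+K_m},\;
        J_{max}\frac{c_i-\Gamma^*}{4c_i+8\Gamma^*}\right) - R_d,$$

with $K_m = K_c(1+O/K_o)$. All measurements are taken at one block
temperature (25 °C), so the kinetic constants are fixed scalars — the
community-standard 25 °C values $\Gamma^* = 42.75$, $K_c = 404.9$
µmol mol⁻¹, $K_o = 278.4$, $O = 210$ mmol mol⁻¹ (giving
$K_m \approx 710$ µmol mol⁻¹) — all overridable through
`kineticConstants()`. No temperature response, no mesophyll conductance
(fits are on a $c_i$ basis) and no TPU limitation are modelled.

`fitFvcbBilinear()` estimates $(V_{cmax}, J_{max}, R_d)$ by the bilinear
method: points are sorted by $c_i$, and every split with at least three
points per segment is evaluated; the lower segment gives $(V_{cmax}, R_d)$
by ordinary least squares on $x_1 = (c_i-\Gamma^*)/(c_i+K_m)$, the upper
segment gives $J_{max}$ by least squares of $A + R_d$ on
$x_2 = (c_i-\Gamma^*)/(4c_i+8\Gamma^*)$, and the split minimising the
full-curve SSE against the min() model wins (ties to the smaller index).
The transition $c_i$ is the midpoint of the two points straddling the
selected split.

Two properties of the min() model make the plain split search slightly
suboptimal, so a refinement pass follows. First, points below the
compensation point are RuBP-limited under the min() rule even though they
sit at the low-$c_i$ end of the curve (the 50 µmol mol⁻¹ setpoint falls in
this regime), so a contiguous ci-ordered split misassigns them. Second,
the two-stage estimate does not share $R_d$ between segments. The
refinement therefore iterates, from every admissible split: assign each
point to the branch the current parameters say is limiting, then solve the
joint linear least-squares problem in $(V_{cmax}, J_{max}, R_d)$ for that
assignment. A refinement is kept only when it lowers the SSE, so the
reported fit never does worse than the split search and in our tests it
reaches the least-squares optimum of the min() model: noiseless curves are
recovered to machine precision, and the fitted SSE is never beaten by a
brute-force 50³ lattice search.

Degenerate inputs (no split with positive $V_{cmax}$ and $J_{max}$, e.g. a
flat curve) are returned as explicit failed fits with a warning, never as
silently wrong numbers.

## C4: initial slope and saturating hyperbola

For maize the low-$c_i$ region is governed by PEP carboxylase,

$$A = V_{pmax}\frac{c_i}{c_i+K_p} - R_d,$$

and `fitVpmax()` estimates $V_{pmax}$ from points with
$c_i \le$ `ciCutoff` (default 100 µmol mol⁻¹, capturing the low-CO2
descending steps of the maize measurement sequence). $K_p$ is held fixed
(default 80 µmol mol⁻¹) because the sparse low-$c_i$ design cannot
identify it jointly; the cutoff is configurable because no canonical
point-selection rule exists for this estimator. With $K_p$ fixed the model
is linear in $(V_{pmax}, R_d)$, so the least-squares problem is solved
exactly by ordinary regression — no iteration, no convergence failures.

CO2- and light-saturated assimilation is estimated as the horizontal
asymptote of a four-parameter non-rectangular hyperbola,

$$A(c_i)=\frac{\phi c_i + A_{sat} -
  \sqrt{(\phi c_i + A_{sat})^2-4\theta\phi c_i A_{sat}}}{2\theta}
  + \text{offset},$$

fitted by bounded Levenberg–Marquardt least squares
(`fitNrhAmax()`, via minpack.lm). The reported $A_{max}$ is
$A_{sat}+\text{offset}$ — the asymptote of the fitted function, so the
day-respiration offset is *included* in the reported value; since no
convention is universal here, the choice is stated and the offset is
reported alongside. Initialisation uses the slope of the two lowest-$c_i$
points for $\phi$, $1.1\times\max A$ for $A_{sat}$, $\theta_0 = 0.7$ and
$\min(0, \min A)$ for the offset, with five deterministic jittered
restarts (SSE tolerance $10^{-8}$); deterministic restarts keep fits
reproducible without touching the RNG. $\theta$ is bounded in
(0.01, 0.999) and flagged when pinned at a bound.

# NPQ kinetics

NPQ at each saturating pulse is $(F_m - F_m')/F_m'$ (not clipped;
transiently negative values are legitimate data). Induction under actinic
light follows a saturating exponential and dark relaxation a decaying
exponential with a sustained offset:

$$\mathrm{NPQ}(t) = a\,(1-e^{-bt}) \qquad\text{(induction)},$$
$$\mathrm{NPQ}(t) = a\,e^{-bt} + c \qquad\text{(relaxation)},$$

with relaxation time re-zeroed at light-off, so $c$ is the quenching that
does not relax in the dark. Fits are unweighted bounded least squares with
$a, b \ge 0$, $c$ free in sign, parameter-step tolerance $10^{-10}$ and
three deterministic jittered restarts; $a$ is initialised at the observed
plateau and $b$ by log-linearisation. "Maximum NPQ" is defined as the
maximum *observed* induction-phase NPQ, not the fitted amplitude: it is
robust when induction has not plateaued and equals any transient
overshoot by construction. Traces from different fluorometers carry an
instrument tag and are never pooled.

# Reflectance analysis

Spectra live on a 350–2500 nm grid at 1 nm (2151 wavelengths; the grid is
configurable). Technical replicates (three per leaf in the targeted
protocol) are averaged element-wise before any analysis. The index
registry ships five literature-standard definitions — Datt
$(R_{850}-R_{710})/(R_{850}-R_{680})$, MSI $R_{1599}/R_{819}$, NDVI, PRI
and WI $R_{900}/R_{970}$ — with nearest-grid-point band lookup; the set of
index formulas in routine use varies between groups, so every definition
is overridable and custom expressions can be registered. A zero
denominator yields `NA` with a warning, never a silent infinity.

The spectra-wide test runs an independent one-way ANOVA (excised vs
attached) at every wavelength, separately per time point, and controls the
family-wise error with a Bonferroni threshold of $\alpha/N$ where $N$ is
the number of wavelengths actually tested — never a hard-coded 2151.
Because neighbouring wavelengths covary strongly in real spectra, the
Bonferroni bound is conservative there; on independent-noise null spectra
it is close to exact, which is what the calibration checks verify.
$-\log_{10}p$ is reported for plotting.

# Inference layer

`twoWayRmAnova()` implements the mixed design with a between-subject
treatment factor and a two-level within-subject time factor: treatment is
tested against subjects-within-treatment, time and the interaction against
time x subjects-within-treatment. With only two within-subject levels the
within-stratum tests are computed exactly on per-subject PM−AM
differences (time = test of the unweighted grand mean of group means of
the differences; interaction = treatment effect on the differences). On
balanced data this reproduces the textbook sums-of-squares decomposition
— the test suite checks equality against both an independent brute-force
oracle and `stats::aov` with an `Error()` stratum to $10^{-8}$ — and with
unbalanced groups it gives marginal (Type-III-style) tests. Sphericity
corrections are moot with a two-level within factor and are not offered.
Replicates missing one time point are dropped listwise with a warning;
constant responses raise a classed error rather than returning an
undefined F.

Scalar two-group comparisons default to Welch's two-sample t-test, since
replicate plants are independent; a paired mode (one-sample t on
per-pair differences) is available where measurements are aligned by
replicate. No multiple-testing correction is applied across traits — only
the spectra-wide analysis corrects, mirroring standard practice for this
design. `samplingDateCheck()` applies the same two-group machinery to the
two sampling dates and recommends pooling when no trait shows a date
effect at $\alpha = 0.05$; identical values across dates are treated as
p = 1 (no evidence of a date effect) rather than as a degenerate test.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the package targets:

* **Replicates per treatment**: 10 tomato, 8 barley, 12 maize.
* **CO2 setpoint sequences**: C3
  400, 300, 200, 100, 50, 400, 400, 700, 1000, 1300, 1800 µmol mol⁻¹
  (the repeated 400s retained as distinct logged points); C4 ascending
  400, 600, 800, 1000, 1250 then descending
  400, 300, 250, 200, 100, 75, 25 µmol mol⁻¹.
* **ci from setpoint**: a fixed affine drawdown, $c_i = 0.7\times$
  setpoint (C3) or $0.4\times$ (C4), plus a small Gaussian jitter (SD
  2 µmol mol⁻¹). The fitting operates on $c_i$, so this mapping only needs
  to produce plausible ranges; it is not a stomatal model.
* **Pulse protocol**: 12 induction pulses evenly spaced over 10 min
  (first at light-on, so the induction model passes through zero) and 8
  relaxation pulses over 12 min, denser early when relaxation is fastest
  (0.5, 1, 2, 3, 5, 7, 9, 12 min).
* **Noise model**: additive Gaussian for gas exchange (default SD
  0.3 µmol m⁻² s⁻¹, a typical IRGA stability figure) and spectra (SD 0.01
  reflectance); multiplicative log-normal (σ = 0.02) for fluorescence,
  because fluorescence is strictly positive.
* **Spectra**: a fixed parametric leaf template (low visible reflectance
  with a green bump at 550 nm, logistic red-edge shoulder to a NIR
  plateau, water-absorption dips at 1450/1940 nm, declining SWIR tail),
  per-leaf brightness offsets, and treatment effects as Gaussian bumps on
  excised leaves only; everything clipped to [0, 1].
* **Scalar traits**: additive baseline + treatment + time + interaction
  structure with Gaussian noise — exactly the model the two-way ANOVA
  assumes. Default effect sizes emulate the qualitative findings the
  design targets (afternoon decline in $A_N$ for barley/maize, a −25 %
  gs treatment effect in maize only, a +0.044 MPa excision shift on the
  barley water-potential baseline of −0.237 MPa). The underlying study
  reports only means for water potential and ABA, so the noise SDs are
  free parameters chosen as plausible measurement dispersions; they are
  not calibrated to unpublished raw data.

Random streams are split per leaf and per data type through a
deterministic seed-derivation hash (`childSeed()`), so adding replicates
never perturbs already-generated values and a (design, seed) pair fully
determines every output, byte for byte.

**What passing tests show — and what they do not.** The generator
realises the assumptions of the downstream models exactly: Gaussian
additive noise, the additive effect structure, exact forward models,
independent replicates. Recovery and calibration results therefore
validate the *implementation* (estimators recover their generating
truths; tests hold their nominal error rates under the assumed model).
They do not establish robustness to what real leaves add: non-Gaussian
instrument drift, stomatal patchiness, correlated wavelength noise,
diurnal trends beyond an additive AM/PM shift, or model misspecification
in the biochemistry.

# Pipeline and reproducibility

`runPipeline()` chains simulate/load → A/ci fitting (tomato/barley routed
to the C3 bilinear fit, maize to the C4 pair) → NPQ fitting → spectra
tests and indices → inference, writing canonical CSVs (comma, UTF-8,
header row, doubles at 10 significant digits) so byte-identity across
runs is testable, plus a JSON run report with the file manifest,
per-stage counts, and all warnings (pinned θ, dropped replicates, failed
fits — failed fits are excluded from inference and counted). The simulate
stage generates only the inputs the enabled stages consume, so reduced
configurations stay fast. Configuration is a YAML file validated with
complete violation lists and no silent unknown keys.

# Problem sizes used in validation

The shipped checks run at the design's own sizes: 11-point C3 and
12-point C4 curves, 12 + 8 pulse traces, 2151-wavelength spectra with 8
leaves per group, and replicate counts of 10/8/12. Monte-Carlo components
use 200 simulated curves per noise level for capacity recovery, 100
traces for NPQ recovery, 200 null spectra sets for family-wise error
calibration, 500 null datasets for ANOVA type-I calibration and 100
end-to-end pipeline runs for the detection-pattern check — sizes at which
the binomial uncertainty of each estimated rate is well below the margins
being asserted.

# Known limitations

* No full C4 enzyme-limited/transport-limited intersection model; the C4
  treatment is the initial-slope + saturating-hyperbola pair.
* No light-response (A/Q) fitting, stomatal-limitation analysis, qE/qT/qI
  decomposition of NPQ, or radiative-transfer (PROSPECT-style) spectral
  inversion.
* The mixed-design ANOVA is the classical SS decomposition, not a
  likelihood-based mixed model; replicates missing a time point are
  dropped, not imputed.
* The generator's realism is qualitative (see above); its purpose is
  validation and power exploration, not emulation of any particular
  instrument.
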