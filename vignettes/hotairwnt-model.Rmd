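---
title: "A kinetic model of HOTAIR-regulated Wnt/beta-catenin signalling driving MMP-13"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of HOTAIR-regulated Wnt/beta-catenin signalling driving MMP-13}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HotairWnt)
```

## The biological system

Cartilage is degraded, in osteoarthritis and rheumatoid arthritis alike, by
matrix metalloproteinase 13 (MMP-13), the main collagen-II-cleaving enzyme
secreted by chondrocytes. MMP-13 expression is driven by canonical
Wnt/beta-catenin signalling: when Wnt ligand engages the Frizzled-LRP5/6
co-receptor, Dishevelled is activated, the APC-Axin-GSK3 "destruction
complex" is disassembled, beta-catenin escapes phosphorylation-tagged
degradation, and the nuclear beta-catenin/TCF complex transactivates target
genes, MMP-13 among them. Upstream of all this sits the long non-coding RNA
HOTAIR, which epigenetically silences WIF-1 (Wnt inhibitory factor 1), the
secreted protein that sequesters free Wnt. More HOTAIR therefore means less
WIF-1, more free Wnt, more beta-catenin/TCF, more MMP-13.

`HotairWnt` implements this chain as a deterministic chemical-kinetic
model: 25 molecular species, 37 elementary reactions (reversible binding
steps split into forward/reverse pairs) governed by 42 kinetic parameters
(37 rate constants, the half-saturation constants K3, K8, K27 and the Hill
exponents m3, m27). All concentrations are nanomolar and all times minutes.

Two regulatory steps use saturating rate laws rather than mass action:

* WIF-1 synthesis is Hill-repressed by HOTAIR,
  $v_3 = V_3 K_3^{m_3} / (K_3^{m_3} + [\mathrm{HOTAIR}]^{m_3})$;
* Dishevelled activation is Michaelis-type in inactive Dsh and proportional
  to the active receptor complex,
  $v_8 = k_8 [\mathrm{Wnt{\cdot}Fzl{\cdot}LRP5/6}][\mathrm{Dsh_i}]/(K_8 + [\mathrm{Dsh_i}])$.

A transcriptional negative feedback closes the loop: beta-catenin/TCF
induces synthesis of Axin, the scaffold that rebuilds the destruction
complex that removes beta-catenin. This delayed negative feedback is what
makes the pathway oscillate.

## The MMP-13 regulation step

The model's sources describe step 27 as *activation* of MMP-13 synthesis
by beta-catenin/TCF, and the reported behaviour (MMP-13 falls when Axin
synthesis is boosted 100-fold) requires activation; yet the equation as
printed has the repressive Hill shape. We resolve this in favour of
internal consistency: the default rate law is the activating form

$$v_{27} = V_{27}\,[\mathrm{\beta cat{\cdot}TCF}]^{m_{27}} /
  (K_{27}^{m_{27}} + [\mathrm{\beta cat{\cdot}TCF}]^{m_{27}}),$$

and the literal repressive form remains available via
`mmp13Hill = "printed"` in `evaluateFluxes()`, `simulationSettings()` and
`exportSBML()`, so both readings can be simulated and compared.

## Parameters, initial state, conservation

`defaultParameters()` returns the published kinetic constants;
`paramDescriptions()` lists each with its unit and the process it governs.
The default initial state (`initialState()`) places 10 nM of free Wnt, Fzl
and WIF-1, 100 nM inactive Dsh, 100 nM APC, 50 nM GSK3 and 15 nM TCF, with
every complex and every synthesized species (HOTAIR, Axin, beta-catenin,
MMP-13) starting at zero: they are unbound or unproduced at time zero and
the synthesis reactions populate them. Two choices here were genuinely
open:

* **Initial LRP5/6** is not part of the published value set. We default to
  10 nM, pairing it 1:1 with Frizzled. Because total LRP5/6 is conserved,
  this choice does shift the limit cycle; we checked that the oscillation
  period only moves between about 207 and 215 minutes as LRP5/6(0) ranges
  over 1-30 nM, so no conclusion in this vignette hinges on it. It is
  configurable like every other concentration.
* **The Axin-induction feedback** is implemented literally as
  $k_{24}([\mathrm{\beta cat{\cdot}TCF}] + [\mathrm{\beta cat}])$,
  catalytically (the inducers are not consumed).

Seven moiety totals — Wnt, Fzl, LRP5/6, Dsh, GSK3, APC and TCF, each
summed over the free species and all complexes containing it — have zero
net stoichiometry in every reaction. `conservedTotals()` exposes them, the
test suite verifies the cancellation symbolically through the
stoichiometry matrix, and `checkTrajectory()` uses them as an integration
quality gauge (drift stays below 1e-5 nM over 1000 minutes at default
tolerances).

The right-hand side is assembled two independent ways — stoichiometry
matrix times flux vector (the production path) and a hand-transcribed copy
of the 25 equations (`evaluateRHS(..., method = "direct")`) — and the two
agree to 1e-12 relative error on randomized states. This dual-path check
guards against transcription slips in either representation.

## Numerical integration

Rate constants span 8.22e-5 to 206 per minute, so the system is stiff;
`simulateWnt()` defaults to a BDF solver (deSolve) with absolute tolerance
1e-8 on every variable and relative tolerance 1e-6, reporting on a 1-minute
output grid over 1000 minutes. The horizon covers the ~200-300-minute
transient plus at least three full oscillation cycles; the 1-minute grid
resolves a ~200-minute period far beyond the 1% level needed by the period
estimator. Solver failures raise an error with the solver diagnostic — a
truncated trajectory is never returned silently. Tiny negative round-off
values are clipped to zero only on export; the raw solution is retained in
the `WntTrajectory` object.

One numerical subtlety: a solver only promises the tolerance you request.
At the default rtol of 1e-6, the permitted error on the ~2 nM HOTAIR signal
is itself about 2e-6 nM, so agreement checks against the HOTAIR closed form
$H(t) = 2(1 - e^{-0.1 t})$ with a 1e-6 nM band are run at atol 1e-10 /
rtol 1e-8, where the measured discrepancy (about 1e-7 nM) reflects model
correctness rather than requested accuracy.

## Oscillation features

`summarizeOscillations()` reports, per species, a dynamic regime, the
period, the amplitude and the post-transient mean. The conventions, all
configurable:

* **Transient cut**: features are extracted for t >= 300 min by default
  (the system settles in roughly 200-300 min); `transientEnd = "auto"`
  instead finds the first peak after which cycle-to-cycle peak heights
  vary by less than 1%.
* **Regime**: *oscillatory* needs at least three alternating extrema with
  peak spacings whose coefficient of variation is below 0.2 and a relative
  peak-to-trough of at least 1%; *steady* means relative peak-to-trough
  below 1%; *growing* flags a linear trend moving the level by more than 5%
  of the mean across the window (in either direction — it is a trend
  label); anything else is *undetermined*. All thresholds are relative, so
  classification is invariant to rescaling the series.
* **Period**: mean spacing of post-transient local maxima, each refined by
  a three-point parabola between grid points; exact to well within grid
  resolution on pure sinusoids (tested at periods 30-360 min).
* **Amplitude**: half of max-minus-min over the window trimmed to an
  integer number of cycles (first to last refined peak). Relative
  amplitude *changes* between runs are insensitive to the halving
  convention.

Two classifications of the baseline model sit right at these thresholds
and are worth knowing about. GSK3 genuinely oscillates, but its relative
peak-to-trough on the limit cycle is only about 0.6%, below the 1% steady
cut, so it is reported *steady* at defaults. Free WIF-1 drops from 10 to
about 4.7 nM within minutes and then merely ripples (about 1.9%
peak-to-trough) as the Wnt oscillation breathes through the reversible
WIF-1/Wnt binding — above the 1% cut, so it is reported *oscillatory*
rather than steady. Neither label is wrong so much as a reminder that
threshold classifications of near-threshold signals are fragile; the
numeric amplitude column is the robust quantity.

## Baseline behaviour

With defaults, LRP5/6, APC, Axin, TCF, beta-catenin and MMP-13 settle onto
a sustained limit cycle. The period measured from post-transient Axin
peaks over the standard 1000-minute window is 215 minutes. Measuring
instead from *all* peaks of the run including the startup transient (whose
first cycles are compressed: peaks near t = 107, 171, 299 before the
rhythm locks in) gives mean spacings anywhere between about 168 and 194
minutes — which is our best explanation for the looser "about 180 minutes"
figure sometimes quoted for this system. The package always excludes the
transient, and reports the protocol with the number.

## HOTAIR knockout

`hotairKnockout()` removes HOTAIR by setting its synthesis rate k1 to zero
along with a zero initial pool. Because HOTAIR obeys closed first-order
turnover, this is exactly equivalent to clamping it at zero while keeping
the system autonomous. Downstream consequences, all reproduced by
`runScenario()` + `compareTrajectories()`:

* WIF-1 synthesis is pinned at its maximum V3 = 1 nM/min, so total WIF-1
  grows linearly at exactly 1 nM/min (regime *growing*) — WIF-1 has no
  degradation reaction in this model, a known idealization.
* The core oscillators change only subtly; the largest effect is on
  LRP5/6, nearest the perturbation, whose amplitude rises by about 19%
  over the standard window under the integer-cycle estimator (about 21%
  on the raw half peak-to-trough, and about 27% if the comparison window
  is extended to 2000 minutes — in the knockout the ever-growing WIF-1
  pool keeps sequestering Wnt, so the knockout limit cycle drifts slowly
  and the measured change depends on the horizon).

## Local sensitivity analysis

`fluxSensitivity()` computes the scaled local sensitivity of each of the
37 reaction fluxes to each of the 42 parameters — 1554 entries. The
protocol, recorded in the result object:

* **Perturbation**: central finite differences at ±1% of the parameter
  value (the Hill exponents are perturbed multiplicatively like any other
  parameter; the rate laws accept non-integer exponents). Halving delta to
  0.5% moves entries of meaningful magnitude (|S| > 0.5) by under 2%,
  confirming the finite-difference error is controlled; relative
  convergence is not meaningful for entries near zero, which is why the
  convergence test applies a magnitude floor.
* **Output**: reaction fluxes, not state variables — the screening
  question is how many *reactions* a parameter touches.
* **Scaling**: S(t) = (relative flux change) / (relative parameter
  change), evaluated against the baseline flux at each output time; times
  where the baseline flux is below 1e-9 nM/min are excluded, and entries
  whose baseline flux stays below that floor across the whole window are
  masked rather than reported as huge ratios.
* **Aggregation**: the default takes the largest-magnitude S(t) over the
  post-transient window t in [300, 1000] min, keeping its sign (negative
  means the flux falls as the parameter rises). `"mean"` and `"end"`
  (end-time value) are shipped alternatives. On an oscillator, local
  sensitivities grow along the window because a perturbed period
  accumulates phase shift, so the max rule is generous and the mean rule
  (where oscillatory contributions cancel) is conservative; there is no
  canonical choice, which is why the rule is recorded with every result.

`screenParameters()` counts, per parameter, the fluxes with |S| above 2
and ranks parameters by that count (ties broken by largest |S|, then
name). Under the default protocol the ranking is headed by k24 (induced
Axin synthesis), followed by k16 (release of phosphorylated beta-catenin)
and, further down, k19 (Axin degradation) — the Axin-coupled rates
dominate the network, which is the screening's scientific conclusion. The
absolute counts are protocol-dependent in exactly the way described
above: the default max rule screens 21 of 42 parameters at |S| > 2 (k24
touching 23 of 37 reactions), the end-time rule 19, and the mean rule
only 4. Published counts for this screening (11 parameters; 18/15/14
reactions for k24/k16/k19) evidently used a normalization that is not
fully specified; none of the three shipped rules reproduces it, so we
report our protocol alongside every number rather than matching counts we
cannot derive.

## Perturbation scans

`foldChangeScan()` rescales one parameter at a time (fold 1 is
bit-identical to the baseline) and attaches per-species summaries;
`axinScanPresets()` ships the three canonical 100-fold scans around the
basal values: k16 in {0.005, 0.5, 50}, k19 in {0.00167, 0.167, 16.7}, k24
in {0.0002, 0.02, 2} (all per minute). Reproduced behaviour:

* k24 at 100-fold above *or* below basal abolishes the oscillations of
  the six core species within the standard window. The two directions
  fail differently: at k24 = 2 the system collapses to a genuine steady
  state; at k24 = 0.0002 the feedback is so weak that the period
  stretches roughly tenfold with tiny amplitude, so no full cycle fits
  the observation window. Both are honestly "oscillations gone" at the
  reporting horizon.
* k19 at 100-fold above or below basal leaves MMP-13 non-oscillatory.
* At k24 = 2 (Axin synthesis boosted), the post-transient MMP-13 mean
  falls below baseline — the model's core therapeutic prediction, that
  raising Axin suppresses the collagenase — and it requires the
  activating MMP-13 rate law; the printed repressive form inverts it.

## What the tests do and do not show

The test suite builds every fixture in code: randomized non-negative
states for the dual-path and conservation properties, pure and
trend-contaminated sinusoids for the estimators, a birth-death toy
(dX/dt = a - bX, equilibrium flux bX* = a, so S = 1 for a and 0 for b)
for the sensitivity engine, and short model runs for everything else.
Problem sizes were chosen to keep the default suite under a few minutes:
1000 random states for the dual-path check, 85 stiff 1000-minute
integrations for the full sensitivity matrix, single runs elsewhere.

These are all *internal* validations plus reproductions of published
model behaviour. They show the network is transcribed consistently, the
integrator converges, and the feature extraction is unbiased on signals
with known ground truth. They do not show the model describes real
chondrocytes: the kinetic constants are literature-assembled rather than
fitted, WIF-1 lacks turnover, the lumped transcription steps hide delays,
and concentrations are well-mixed cell averages. Known limitations, in
short: no stochasticity (concentrations are assumed large), no parameter
estimation, no spatial structure, no bifurcation-point continuation —
regime changes are detected by simulation at fixed parameter values.
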