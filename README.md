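# HotairWnt

Deterministic kinetic modelling of the lncRNA-HOTAIR-regulated
Wnt/beta-catenin signalling pathway and its collagenase readout MMP-13 in
chondrocytes.

## The problem

MMP-13 is the matrix metalloproteinase chiefly responsible for the
irreversible collagen-II degradation seen in osteoarthritic and rheumatoid
cartilage. Its expression is driven by Wnt/beta-catenin signalling, which
is in turn de-repressed by the long non-coding RNA HOTAIR (HOTAIR silences
WIF-1, the secreted factor that sequesters free Wnt). Understanding — and
perturbing — this chain quantitatively requires a dynamic model, not a
wiring diagram.

`HotairWnt` implements the pathway as a mass-action/Hill ODE system:

- **25 species** (nM): HOTAIR, WIF-1, Wnt, the receptor module
  (Fzl, LRP5/6 and their complexes), Dishevelled (inactive/active), the
  APC–Axin–GSK3 destruction complex in phosphorylated and unphosphorylated
  forms, beta-catenin and its complexes, TCF, and MMP-13;
- **37 reactions** (reversible binding steps split into forward/reverse)
  governed by **42 parameters** — 37 rate constants, the half-saturation
  constants $K_3, K_8, K_{27}$ and Hill exponents $m_3, m_{27}$;
- **7 conserved moieties** (total Wnt, Fzl, LRP5/6, Dsh, GSK3, APC, TCF),
  used as built-in integration quality checks;
- WIF-1 synthesis Hill-repressed by HOTAIR,
  $v_3 = V_3 K_3^{m_3}/(K_3^{m_3} + [\mathrm{HOTAIR}]^{m_3})$, and MMP-13
  synthesis Hill-activated by beta-catenin·TCF;
- a transcriptional negative feedback, $v_{24} = k_{24}([\beta\mathrm{cat{\cdot}TCF}] + [\beta\mathrm{cat}])$,
  inducing synthesis of Axin — the loop that makes the pathway oscillate.

On top of the simulator the package provides limit-cycle feature
extraction (regime / period / amplitude), a 37 × 42 scaled local
sensitivity analysis of every reaction flux with |S| > 2 screening,
perturbation scenarios (HOTAIR knockout, 100-fold parameter scans), a YAML
configuration format, SBML Level 3 export, and a CLI
(`inst/cli/hotairwnt.R`).

## Worked example

```r
library(HotairWnt)

tr <- simulateWnt()   # Table defaults, stiff solver, 1000 min, 1-min grid
summarizeOscillations(tr, c("Axin", "LRP56", "Bcat", "MMP13", "WIF1"))
#>   species      regime transient_end period_min amplitude_nM mean_nM
#> 1    Axin oscillatory           300      215.0      0.12601  0.3379
#> 2   LRP56 oscillatory           300      215.2      0.26294  3.9320
#> 3    Bcat oscillatory           300      215.1      0.74994  1.1985
#> 4   MMP13 oscillatory           300      215.1      0.40865  1.7241
#> 5    WIF1 oscillatory           300      215.2      0.04179  4.5837
```

The Axin negative-feedback loop sustains a limit cycle with a ~215-minute
period (measured from post-transient peaks; the first cycles of the
transient are faster). Beta-catenin swings by ±0.75 nM around a 1.2 nM
mean and MMP-13 follows it. WIF-1 settles within minutes to ~4.6 nM and
then only ripples by ~2% — near the classifier's steady/oscillatory
boundary.

Removing HOTAIR (synthesis off, zero initial pool) releases WIF-1
synthesis to its maximum 1 nM/min and mostly perturbs the receptor level:

```r
ko <- runScenario(hotairKnockout())
compareTrajectories(tr, ko, c("LRP56", "MMP13"))
#>   species  regime_ref  regime_var amplitude_ref amplitude_var amplitude_change_pct
#> 1   LRP56 oscillatory oscillatory         0.263         0.313                18.97
#> 2   MMP13 oscillatory oscillatory         0.409         0.397                -2.73
```

LRP5/6, closest to the perturbation, gains ~19% oscillation amplitude
over the standard window while the downstream species barely move.

Sensitivity screening (1% central differences of all 37 flux trajectories
with respect to all 42 parameters, max |S(t)| over t ∈ [300, 1000] min):

```r
fs <- fluxSensitivity()          # ~30 s: 85 stiff 1000-min integrations
head(screenParameters(fs), 3)
#>   parameter nAffected  maxAbsS rank
#> 1       k24        23 28.25364    1
#> 2       k16        23 27.15204    2
#> 3       k12        22 23.98158    3
```

The Axin-coupled rates dominate: k24 (induced Axin synthesis) affects the
most reactions, ahead of k16 and k19 — which motivates Axin as the
pathway's intervention point. Consistently, `foldChangeScan(paramName =
"k24", folds = c(0.01, 1, 100))` shows the oscillations of all core
species collapsing at both scan extremes, and at k24 = 2 /min the
post-transient MMP-13 mean falls from 1.72 to 1.00 nM.

## Layout

- `R/` — network definition (species, rate laws, stoichiometry,
  conserved moieties), simulator, oscillation features, sensitivity
  analysis, scenarios, config/SBML/CLI;
- `tests/testthat/` — unit and property tests (all fixtures generated in
  code) plus `test-acceptance.R`;
- `scripts/acceptance.R` — headline-number reproduction;
- `vignettes/hotairwnt-model.Rmd` — the model, its assumptions, numerical
  choices and limitations.
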