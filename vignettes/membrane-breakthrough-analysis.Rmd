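---
title: "Methods: dynamic adsorption analysis for membrane-bed chromatography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic adsorption analysis for membrane-bed chromatography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memchrom)
```

## The problem

In membrane-bed (and fixed-bed) chromatography a protein solution at constant
inlet concentration $C_0$ is pumped through a stack of adsorptive membrane
layers. The outlet concentration $C_t$ starts near zero, rises sigmoidally as
binding sites fill, and approaches $C_0$ at bed exhaustion. The recorded
$C_t/C_0$ versus time trace — the *breakthrough curve* — is the primary
experimental object of dynamic adsorption studies; the motivating system for
this package is lysozyme capture on tris(hydroxymethyl)aminomethane-
functionalized polyacrylonitrile nanofiber membranes, where capacities run to
hundreds of mg per gram of adsorbent and fronts are minutes wide.

memchrom implements the complete analysis chain for such data: the
performance-indicator panel, conversion to dynamic uptake curves, linearized
kinetic-model fits, the four classical breakthrough-curve models with error
statistics and ranking, BDST scale-up across bed depths, and a synthetic-data
generator with known ground truth so that every stage is testable without
access to raw instrument traces.

## Units and bed geometry

Internal computation uses minutes, mL, mg (protein), g (adsorbent) and cm.
Bed height $Z$ is accepted in $\mu$m at the boundary (the natural unit for
nanofiber stacks, 115 $\mu$m per layer in the reference system) and converted
where needed. The bed volume is purely geometric, $V_M = A \cdot Z$
(0.04255 mL for $A = 3.7\,\mathrm{cm}^2$, $Z = 115\,\mu$m); the linear
velocity is $v = F/A$ in cm/min. The adsorbent mass $W$ counts the functional
nanofiber material only — inert support fabric is excluded, because all
capacities are expressed per gram of adsorbent and only this convention
reproduces internally consistent indicator panels ($DBC = C_0 V_b / W$
against published values). Multi-layer beds scale $Z$ and $W$ proportionally.

A note on the reference system's bed volume: one published passage implies
$V_M \approx 3.39\times10^{-2}$ mL while the layer-scaling arithmetic uses
0.04255 mL. The two cannot be reconciled (the porosity correction
$\varepsilon V_M$ gives 0.0356, not 0.0339); this package uses the geometric
$V_M = A Z$ throughout, which is the only choice consistent with the
published bed-volume ratios and volumetric capacities.

## The indicator panel

With $t_b$ and $t_e$ the times at 10% and 90% breakthrough (located by
fitting the two-parameter logistic front
$c(t) = 1/(1+e^{k(t^*-t)})$ by nonlinear least squares and inverting it;
linear interpolation between bracketing samples is available as a fallback):

* $V_b = F t_b$ — volume processed at breakthrough (mL);
* $BV = V_b / V_M$ — bed volumes processed;
* $DBC = C_0 V_b / W$ — dynamic binding capacity (mg/g). This product form
  assumes negligible breakthrough before $t_b$ (a sharp front); the uptake
  integral evaluated at $t_b$ is available via `dbc_method = "integral"` for
  diffuse fronts;
* $EBC$ — equilibrium binding capacity, the uptake integral at bed
  exhaustion. We integrate to the last sample with $c \ge 0.99$; if the curve
  never gets there the final sample is used and the result flagged
  (`exhausted = FALSE`), since a truncated integral understates capacity;
* $MAER = W / V_b$ — adsorbent exhaustion rate (g/mL), lower is better;
* $HMTZ = Z (t_e - t_b) / t_e$ — mass-transfer-zone length ($\mu$m). This
  form, rather than the also-seen $Z(1 - t_b/t_e)$ rearrangements with
  stoichiometric times, was frozen only after verifying it reproduces all
  twelve published HMTZ values of the reference system exactly;
* $MBU = 100 \cdot DBC / EBC$ — bed utilization (%);
* $P = DBC / t_b$ — productivity (mg per minute per g);
* $\tau = \varepsilon V_M / F$ — hydraulic residence time;
* $J = V/(A t) = F/A$ — permeation flux, reported in L/(m²·h). No pressure
  term enters the defining relation, so the per-bar normalization sometimes
  attached to this quantity is not computed.

`indicators_from_times()` computes every cell derivable from printed
$(t_{0.1}, t_{0.9}, C_0, F, Z)$ inputs alone, which is how the acceptance
suite reproduces the published indicator table to printed precision.

## Uptake curves and kinetic models

The dynamic uptake curve is
$q_t = \frac{F}{W}\int_0^t \big(C_0 - C(s)\big)\,ds$, evaluated by the
trapezoidal rule on the sample grid (refinement drift $\le 0.5\%$ on
noiseless logistic data is a tested invariant). Four linearized kinetic
models are fitted by ordinary least squares:

| model | linear form | parameters |
|---|---|---|
| pseudo-first-order | $\ln(q_1 - q_t)$ vs $t$ | $k_1$ (1/min), $q_1$ (mg/g) |
| pseudo-second-order | $t/q_t$ vs $t$ | $k_2$ (g/(mg·min)), $q_2$ (mg/g) |
| Elovich | $q_t$ vs $\ln t$ | $\alpha$ (mg/(g·min)), $\beta$ (g/mg) |
| intraparticle diffusion | $q_t$ vs $\sqrt t$, piecewise | $k_i$ (mg/(g·min$^{0.5}$)), $I$ (mg/g) per stage |

Notes on choices that were genuinely open:

* The PSO linearization is sometimes printed with a minus sign on the $t/q_2$
  term; that form cannot produce positive parameters from monotone uptake
  data, so the standard $t/q_t = 1/(k_2 q_2^2) + t/q_2$ is used.
* PFO needs the equilibrium capacity inside the logarithm. When no
  independent estimate exists we default to $1.02 \cdot \max q_t$ (standard
  practice); points at or above it are dropped and counted.
* The intraparticle (Weber–Morris) plot of protein-on-membrane data is
  typically multi-linear — boundary-layer film diffusion, then intraparticle
  diffusion, then equilibrium. `fit_ipd()` segments by exhaustive search
  over admissible breakpoints (at least 3 points per stage, 1–3 stages)
  minimizing the total residual sum of squares, using prefix sums so the
  search is $O(n^2)$ with $O(1)$ per-segment regressions. No published
  method exists for the segmentation; exhaustive RSS minimization is the
  reproducible choice.
* $R^2$ is the squared Pearson correlation of each linearized regression —
  the convention under which linearized-fit studies report goodness of fit.

## Breakthrough-curve models

With $c = C_t/C_0$:

* **Bohart–Adams** $\ln c = k_{BA} C_0 t - k_{BA} N_o Z / v$: an early-front
  exponential. Fitted by default over the whole available front
  ($c \in (0.001, 0.999)$), which is deliberately unfavorable — the model is
  only physical before exhaustion, and the full-front fit reproduces the
  characteristically poor $R^2$ and inflated $N_o$ seen when this model is
  applied to sigmoidal protein-breakthrough data. A restricted early-front
  window (e.g. $c < 0.15$) is exposed for faithful use.
* **Thomas** $\ln(1/c - 1) = k_T q_e W / F - k_T C_0 t$.
* **Yoon–Nelson** $\ln(c/(1-c)) = k_{YN} t - k_{YN} t_{0.5}$.
* **BDST** (single depth) $t = Q_o Z/(C_0 v) - \ln(1/c-1)/(k_{BDST} C_0)$.

Thomas and Yoon–Nelson regress the same response up to sign
($k_{YN} = k_T C_0$, $t_{0.5} = q_e W/(C_0 F)$), and BDST is the inverse
regression of the same line, so the three $R^2$ values coincide to machine
precision on shared data — a tested identity that also explains why
published tables show identical $R^2$ columns for the three models while
their capacity estimates drift apart as $R^2$ falls below 1 (the inverse
regression slope carries a factor $r^2$).

**Fitting window.** The logistic-family fits use points with
$c \in (0.05, 0.95)$ by default. This is a deliberate package design choice:
the linearized response $\mathrm{logit}(c)$ amplifies additive concentration
noise by $1/(c(1-c))$, which diverges at the window edges, and the physical
truncation of $c$ at 0 biases whichever extreme points survive a wider
window. Empirically (noise s.d. 0.02, 100 seeds), widening the window to
$(0.01, 0.99)$ inflates the median $k_{YN}$ recovery error from ~7% to ~44%
while the 5–95% window keeps median $t_{0.5}$ recovery within 0.5%. Any
window can be passed explicitly.

**Error statistic.** $E(\%) = 100\,|x_{exp} - x_{cal}| / x_{cal}$, with the
model-calculated value in the denominator. Both denominator conventions
circulate; this one was frozen after verifying it reproduces the published
error table of the reference system across all four model blocks (the
$x_{exp}$ denominator fails by tens of points on the worst rows). The
experimental comparators are $q_e^{exp} = EBC$,
$t_{0.5}^{exp}$ = the observed 50% crossing, and
$N_o^{exp} = Q_o^{exp} = EBC \cdot W / V_M$. `rank_models()` sorts fits by
$E$ ascending with $R^2$ as tie-break; on noisy logistic data the expected
ordering Yoon–Nelson $\ge$ BDST $\approx$ Thomas $>$ Bohart–Adams is a
tested property.

**Scale-up.** `bdst_scaleup()` regresses the service time at a target
fraction on bed height across beds differing only in depth, returning the
BDST line $t = aZ + b$, a service-time predictor for new depths, and the
volumetric capacity implied by the slope.

## The synthetic generator: what it does and does not emulate

`synthetic_spec()` / `generate_breakthrough()` produce curves from the
closed forms of the models above: logistic fronts for Yoon–Nelson/Thomas,
the clamped exponential for Bohart–Adams. Defaults state a world matching
the reference system: $C_0$ 0.5–2 mg/mL, $F$ 0.1–1 mL/min, 1–5 layers
(115 $\mu$m and 0.015 g per layer, $A = 3.7\,\mathrm{cm}^2$,
$\varepsilon = 0.8367$), capacities 200–1000 mg/g. The sampling grid spans
the front plus its saturated tail ($t_{0.5} + 12/k$) with at least 30
samples inside the 5–95% window, since linearized fits need dense front
coverage. Noise is additive Gaussian on $c$, truncated to $[0, 1.05]$
(mirroring the reader's overshoot tolerance); the default s.d. of 0.01 for
the standard fixture set represents a well-behaved UV detector at ~1% of
$C_0$. The 12-condition standard set (`standard_condition_specs()`,
`make_fixtures()`) uses the published capacities and front widths of the
reference system as ground truth, with pH entering only through capacity
and a label — pH appears in no model equation, so no mechanistic pH model
is attempted.

What the generator does **not** emulate: asymmetric or tailing fronts from
axial dispersion, flow maldistribution across stacked layers, slow
saturation tails, baseline drift, or correlated detector noise. A green
parameter-recovery test therefore establishes that the estimators are
correct and stable for sigmoidal fronts with independent additive noise —
not that any particular mechanistic model is true of a real membrane, and
not that real (often asymmetric) curves will show the small error
percentages seen on synthetic logistic data.

## Numerical details and degenerate inputs

* Crossing times: `nls` logistic fit started from the linearized regression;
  if `nls` fails the linearized estimate is used. Curves that never reach
  the requested fraction raise a "never reaches" error naming the observed
  maximum.
* Log-domain guards: $c \le 0$ and $c \ge 1$ points are excluded from the
  linearizations and counted in `n_dropped`; $q_t \ge q_e$ points likewise
  for PFO; $t = 0$ for Elovich. Fits with fewer than 3 usable points raise
  insufficient-data errors; wrong-signed slopes (falling curves, constant
  uptake) raise degenerate-fit errors rather than returning nonsense
  parameters.
* `c_ratio` values in $(1, 1.05]$ are retained with a warning (detector
  overshoot); values above 1.05 are rejected.
* Reruns of `run_pipeline()` under the same configuration are bit-identical;
  every random draw flows through the spec seed.

## Known limitations

Only linearized fits are provided as defaults (matching how this literature
reports parameters); a nonlinear refit of the logistic front is used
internally for crossing times but not exposed as a general fitting route.
The Bohart–Adams clamp at $c = 1$ makes its synthetic curves non-smooth at
the clamp point. Elution, regeneration and pressure-drop phenomena are out
of scope.
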