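# memchrom

Dynamic adsorption analysis for membrane-bed chromatography from
breakthrough curves.

## What it is for

In membrane-bed (and fixed-bed) protein chromatography, feed at constant
inlet concentration C₀ flows through a stack of adsorptive membrane layers
and the normalized outlet concentration C/C₀ is recorded over time. That
sigmoidal trace — the breakthrough curve — carries everything a process
engineer needs about the bed's dynamic binding behavior. memchrom is for
people who design or characterize such adsorbers (the motivating system is
lysozyme capture on Tris-functionalized polyacrylonitrile nanofiber
membranes) and implements the full standard analysis chain:

- **Performance indicators** at the 10%/90% breakthrough points:
  dynamic binding capacity `DBC = C₀·V_b/W`, equilibrium binding capacity
  `EBC = (F/W)·∫(C₀ − C)dt`, mass-transfer-zone length
  `HMTZ = Z·(t₀.₉ − t₀.₁)/t₀.₉`, adsorbent exhaustion rate `MAER = W/V_b`,
  bed utilization `MBU = 100·DBC/EBC`, bed volumes `BV = V_b/V_M`,
  productivity `P = DBC/t_b`, residence time `τ = ε·V_M/F`, flux `J = F/A`.
- **Kinetics**: breakthrough→uptake conversion (trapezoidal integral) and
  linearized pseudo-first-order, pseudo-second-order, Elovich and
  multi-stage intraparticle-diffusion (Weber–Morris) fits with automatic
  breakpoint search.
- **Breakthrough models**: linearized Bohart–Adams, Thomas, Yoon–Nelson and
  single-depth BDST fits with R², percent error
  `E = 100·|x_exp − x_cal|/x_cal`, model ranking, curve prediction, and
  BDST scale-up across bed depths.
- **Synthetic data**: closed-form curve generation (logistic and
  Bohart–Adams fronts) with seeded truncated-Gaussian noise and a standard
  12-condition fixture set with ground truth, so every estimator is
  validated by parameter recovery.

See `vignettes/membrane-breakthrough-analysis.Rmd` for the model
assumptions, unit conventions and design decisions.

## Worked example

Generate a noisy synthetic curve for a one-layer bed (Z = 115 μm,
A = 3.7 cm², W = 0.015 g, ε = 0.8367) at C₀ = 2 mg/mL, F = 1 mL/min with a
Thomas-model ground truth of q_e = 769.65 mg/g:

```r
library(memchrom)
bed   <- bed_spec(Z = 115, A = 3.7, epsilon = 0.8367, W = 0.015)
spec  <- synthetic_spec("thomas", params = list(k_T = 1.16, q_e = 769.65),
                        C0 = 2, F_mL = 1, bed = bed, noise_sd = 0.01, seed = 42)
curve <- generate_breakthrough(spec)
performance_indicators(curve)
#> Breakthrough indicators:
#>   t_b = 4.817 min, t_e = 6.718 min, V_b = 4.817 mL, BV = 113.21
#>   DBC = 642.30 mg/g, EBC = 768.07 mg/g, MBU = 83.63 %
#>   MAER = 0.00311 g/mL, HMTZ = 32.54 um, P = 133.33 mg/(min g)
#>   tau_res = 0.0356 min, J = 162.2 L/(m^2 h)
```

The bed breaks through at t_b ≈ 4.8 min having bound 642 mg of protein per
gram of adsorbent — 84% of its equilibrium capacity (768 mg/g, within 0.2%
of the generating truth), with the adsorption front occupying 33 of the
115 μm of bed height. Fit and rank the four breakthrough models:

```r
fits <- list(fit_thomas(curve), fit_bohart_adams(curve),
             fit_yoon_nelson(curve), fit_bdst(curve))
rank_models(fits)
#>          model        E_pct        r2
#> 3  yoon_nelson  0.003860472 0.9966699
#> 4         bdst  0.121689680 0.9966699
#> 1       thomas  0.122500797 0.9966699
#> 2 bohart_adams 33.484881039 0.7608981
```

Yoon–Nelson, BDST and Thomas share one regression line (identical R²,
recovering q_e = 769.0 mg/g vs the true 769.65), while the early-front
Bohart–Adams model misfits the full sigmoid — the ordering
YN > BDST ≈ Thomas > Bohart–Adams expected for this kind of data.

The full pipeline (indicators + kinetics + models + ranking for a directory
of curves, or the built-in 12-condition synthetic set) runs as

```r
run_pipeline(run_config(outdir = "report", seed = 1))
```

or from the shell via `exec/memchrom
<metrics|kinetics|models|run|fixtures>`.

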