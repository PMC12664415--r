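# phenolkin

Kinetic, mass-transfer and thermodynamic modelling of solid–liquid
extraction curves of phenolic compounds — the analysis chain applied to
ultrasound-assisted extraction (UAE) of total phenolics from plant
material such as strawberry guava leaves, and to its conventional
shaking (CSE) control.

Given time courses $C_t$ (mg GAE per g dry weight) at several
temperatures, the package fits:

* **Pseudo-second-order kinetics** $dC_t/dt = k(C_s - C_t)^2$, via the
  exact linearization $t/C_t = 1/(kC_s^2) + t/C_s$, giving the
  saturation concentration $C_s$, rate constant $k$ and initial rate
  $h = kC_s^2$;
* **Arrhenius** temperature dependence of $k$ ($E_a$, $k_0$);
* **Effective diffusivity** $D_e$ from Crank's series solution for a
  sphere, $y = \frac{6}{\pi^2}\sum n^{-2}\exp(-n^2\pi^2 D_e t/R^2)$,
  fitted by constrained nonlinear least squares on the unaccomplished
  ratio $y = (C_\infty - C_t)/(C_\infty - C_0)$, with a
  residual-resampling **bootstrap** SE and 95 % percentile CI;
* **External mass transfer** $K_T$ from
  $\ln\!\big(C_s/(C_s-C_t)\big) = (K_T/L_c)\,t$ and the **Biot number**
  $Bi = K_T L/D_e$ (diameter convention $L = 2R$ by default; $Bi > 50$
  means internal-diffusion-limited);
* **Thermodynamics**: $K_{eq} = C_s/(C_{max}-C_s)$, Van't Hoff
  regression for $\Delta H^\circ, \Delta S^\circ$, and the Gibbs series
  $\Delta G^\circ = \Delta H^\circ - T\Delta S^\circ$;
* **Assay helpers**: Folin–Ciocalteu / AlCl₃ standard-curve calibration
  and DPPH % inhibition.

A seeded synthetic-data module generates triplicate study-like curves
(30–70 °C, 10–80 min, noise SD 1 mg/g, truth at published magnitudes) so
the whole chain is testable without external data.

## Worked example

```r
library(phenolkin)

ds  <- generate_uae_cse_pair(synthetic_spec(seed = 7))       # UAE + CSE arms
cfg <- study_config(bootstrap_B = 200, n_terms = c(10), seed = 7)
bundle <- run_study(ds, cfg)

bundle$kinetics_table[bundle$kinetics_table$method == "UAE", ]
#>    method temperature     cs   cs_sd          k       k_sd      h r_squared
#> 6     UAE          30 151.52 0.54621 0.00083782 1.1313e-05 19.235   0.99637
#> 7     UAE          40 153.29 0.75998 0.00100144 4.2374e-05 23.532   0.99730
#> 8     UAE          50 159.64 1.00411 0.00122790 9.4174e-05 31.291   0.99776
#> 9     UAE          60 157.92 1.49371 0.00101334 8.4719e-05 25.270   0.99614
#> 10    UAE          70 154.81 0.66683 0.00099086 1.9895e-05 23.748   0.99697

bundle$comparison_table
#>   parameter        UAE        CSE percent_change temperature
#> 1        cs 1.5964e+02 1.4313e+02         11.530          50
#> 2         k 1.2279e-03 7.9836e-04         53.803          50
#> 3        de 1.2780e-12 8.0561e-13         58.640          50
#> 4        kt 2.9682e-08 2.3926e-08         24.055          50
```

Reading this: the fitted saturation concentration peaks at 50 °C
(159.6 mg GAE/g, recovering the generator truth of 159.15 within the
replicate SD), the rate constant and effective diffusivity peak there
too, and every parameter is larger for the ultrasound arm than for the
shaking control — the expected intensification signature. Each row of
`cs`/`k` is the mean ± SD of per-replicate fits; `r_squared`/`mse`/`rmse`
are on the concentration scale.

Individual stages are plain functions: `fit_pso_linearized()`,
`fit_arrhenius()`, `unaccomplished_ratio()` → `fit_de()` →
`bootstrap_de()`, `fit_kt()` → `biot_number()` →
`classify_rate_limit()`, `equilibrium_constant()` → `vant_hoff_fit()` →
`gibbs_energy()`. `read_curves()`/`write_curves()` handle long-format
CSV/TSV with a configurable column dialect; `write_report_bundle()`
emits the four report tables as CSV plus a JSON bundle with full
provenance. A thin CLI (`inst/cli/phenolkin.R`) wraps
`simulate` / `run-all` / `compare`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the package's published reference tables and its own
`biot_number()`, the Biot numbers at 30 °C and 50 °C under the
particle-diameter length convention, and writes them as JSON.
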