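# phagestrat

Bacteria–phage–nutrient chemostat dynamics under different phage infection
strategies.

## The problem

How can many bacterial species coexist on few resources? One classical
answer is top-down control by bacteriophages. `phagestrat` is a simulation
tool for exploring that mechanism: two bacterial species (a fast and a slow
grower) compete for one limiting nutrient in a chemostat, each infected by
its own phage. The phage can follow one of three strategies, distinguished
solely by how the lysis (phage induction) rate `s` depends on total host
density `h = B + I`:

| strategy | lysis law | biology |
|---|---|---|
| lytic | `s = s_max` | constant induction, hosts never reproduce once infected |
| Piggyback-the-Winner (PtW) | `s = s_max / ((h·r)² + H)` | lysogeny when hosts are *abundant* |
| Piggyback-the-Loser (PtL) | `s = s_max · h² / (h² + SH)` | lysogeny when hosts are *rare* |

A density-dependent switching point (lysis rate 0.0033/h) toggles
infected-cell growth between the lysogenic (growing) and lytic
(non-growing) life cycle. Lysed cells release a fraction `n` of their
biovolume as phage and recycle the rest (`1 − n`) into the dissolved
nutrient pool — the **viral shunt**. Resource variability enters as a
sinusoidal modulation of the chemostat turnover rate with relative
amplitude `a < 1` and period `T`.

On top of the simulator sits an analysis layer that produces the objects
such studies report: bifurcation scans over nutrient supply `N0`,
persistence-state classification (codes 0–4 counting surviving community
states), two-dimensional amplitude×supply and period×supply sweeps, and
bisection estimates of extinction thresholds.

The model, its parameters and every numerical choice are documented in the
methods vignette (`vignettes/phage-strategies.Rmd`).

## Worked example

```r
library(phagestrat)

# where the temperate strategies cross the lysogenic/lytic switch
switch_density("ptl", phage_params())   # 0.2010076  (2.01e6 particles/mL)
switch_density("ptw", phage_params())   # 19.89975   (1.99e8 particles/mL)

# five simulated years of Piggyback-the-Loser at supply N0 = 2
traj <- run_simulation(simulation_spec("ptl", phage_params(N0 = 2)))
tail(as.data.frame(traj), 1)
#>       time_h     B1     B2     I1     I2     P1     P2      N
#> 43801  43800 1.0094 1.0472 0.3542 0.1364 0.0084 0.0026 0.7177

classify_persistence(traj)
#> <persistence_state> code 4 | B1 inf1 B2 inf2

# the phage-free control: competitive exclusion of the slow grower
classify_persistence(run_simulation(simulation_spec("none",
                                                    phage_params(N0 = 2))))
#> <persistence_state> code 1 | B1
```

Densities are normalized biovolume (abundance / half-saturation abundance
of 1e7 particles/mL; phages additionally scaled by the biovolume ratio
3.14e-4). With the phage present all four community states persist
(code 4); without it the slow grower is competitively excluded (code 1) —
the phage rescues coexistence.

Scans and sweeps work the same way:

```r
bd <- bifurcation_scan("lytic", phage_params(), N0_grid = seq(1, 10, 0.5))
coexistence_onset(bd)          # smallest N0 with bacterial coexistence
sw <- sweep_2d("ptl", phage_params(), axis = "amplitude",
               axis_grid = seq(0, 0.99, length.out = 15),
               N0_grid = seq(0.6, 8, length.out = 15))
print(sw)                      # matrix of persistence codes
```

## Command line

Bundled scenario presets (time series, bifurcation scans, fluctuation
sweeps, sensitivity variants) can be run from a shell:

```sh
inst/scripts/phagestrat presets                 # list the 42 presets
inst/scripts/phagestrat run fig3_ptl --command timeseries --out out/
inst/scripts/phagestrat run fig5_ptw_amplitude --command sweep --out out/
```

Scenario configs are YAML; `load_config()`/`save_config()` round-trip
exactly, unknown keys are rejected, and grids outside the reference ranges
require `--allow-extrapolation`. Outputs are plain CSV/TSV plus a
`manifest.json` run record, and repeated runs are byte-identical.

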