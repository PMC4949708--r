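# axdi — axon diameter index estimation from PGSE diffusion MRI

`axdi` estimates the **axon diameter index** of white matter from
multi-shell pulsed-gradient spin-echo (PGSE) diffusion MRI, and provides
the simulation and statistics tooling needed to validate such estimates
against microscopy. It is aimed at microstructure-imaging researchers who
want a self-contained, testable implementation of the
cylinder–zeppelin–ball–dot white-matter model and its two standard
fitting routes.

Because perpendicular signal attenuation in a restricted cylinder grows
roughly as diameter to the fourth power, a voxel reports a tail-weighted
summary of its diameter distribution rather than the mean:

    alpha_wide  = (<a^6> / <a^2>)^(1/4)      (wide-pulse limit)
    alpha_short = (<a^4> / <a^2>)^(1/2)      (short-pulse limit)

with `< >` the mean over axons. The package implements:

* **Protocols** — PGSE shell/protocol containers with b, q, diffusion-time
  arithmetic, the built-in optimised ex vivo three-shell (Gmax 300 mT/m)
  and five-shell (Gmax 1350 mT/m, b up to ~105,000 s/mm²) schemes,
  shell subsetting, and Camino / FSL(+timing sidecar) scheme I/O.
* **Signal models** — Gaussian-phase-distribution cylinder (series over
  Bessel-derivative roots), its wide-pulse closed form, tortuosity
  zeppelin, ball, dot, and the composite four-compartment voxel signal.
* **Dictionary fitter** — per-voxel atom dictionary (60 diameters ×
  13 tortuosity zeppelins + ball + dot) with exact per-shell Rician bias
  offsets baked into the atoms, solved by non-negative least squares;
  the index is the weight-weighted mean over the cylinder atoms.
* **Three-stage fitter** — grid search, bounded Nelder–Mead refinement,
  and Metropolis–Hastings sampling under a Rician likelihood.
* **Diameter statistics** — `adi_wide`/`adi_short`, summary tables for
  microscopy diameter samples, and the ROI sensitivity/stability metrics
  `|alpha_EM - mean|` and `sd(alpha)`.
* **PGSE sensitivity analysis** — smallest detectable diameter per shell
  from the noise-floor criterion `1 - S(d) >= 1/SNR`.
* **Synthetic data** — voxels/ROIs with gamma or discrete diameter
  distributions, Watson orientation dispersion, and per-shell Rician
  noise, always emitted alongside their ground truth.

## Worked example

Simulate one corpus-callosum-like voxel on the five-shell protocol and
fit it back:

```r
library(axdi)
p5 <- builtin_protocol("five_shell")

spec <- substrate_spec(
  diameter_dist = list(type = "gamma", shape = 25, scale = 0.12),  # mean 3 um
  v_intra = 0.7, v_extra = 0.2, v_iso = 0.05, v_dot = 0.05,
  orientation = c(1, 0, 0), snr = 20, seed = 42)
vox <- generate_voxel(spec, p5)
round(c(alpha_wide = vox$truth$alpha_wide, mean_diameter = vox$truth$mean_diameter), 3)
#>    alpha_wide mean_diameter
#>         3.366         2.983

fit_voxel_dictionary(vox$signal, p5, orientation = c(1, 0, 0),
                     snr = shell_snr(20, p5))
#> axdi dictionary fit: alpha = 2.967 um
#>   fractions: intra 0.624  extra 0.369  iso 0.000  dot 0.007
#>   residual norm: 0.908
```

The fitted index (2.97 μm) sits near the tail-weighted truth (3.37 μm),
not the arithmetic mean — that weighting is exactly what makes
`alpha_wide` the right microscopy comparator. Supplying the known
per-shell SNR uses the simulation's noise condition; passing nothing
estimates it per voxel from the shell mean/SD, the convention used on
real data (see the vignette for its bias).

The detectability analysis shows why sub-micron axons are invisible to
this acquisition:

```r
protocol_sensitivity_report(p5, D = 0.6e-9, snr_list = c(5, 10, 20))$best
#>   snr best_threshold_um
#> 1   5              1.94
#> 2  10              1.60
#> 3  20              1.34
```

Only axons above ~1.3–1.9 μm attenuate the strongest shell's signal by
more than the noise floor, so a voxel whose true index is below that
(most of a mouse corpus callosum) cannot be resolved — the physical basis
of the overestimation seen in vivo.

Microscopy-style diameter tables go through the same statistics:

```r
em <- sample_diameters(substrate_spec(seed = 7), n = 20000)
round(summarize_diameters(em)$stats[, c("mean", "sd", "median", "alpha_wide")], 3)
#>    mean   sd median alpha_wide
#> 1 0.559 0.27  0.516      1.004
```

A thin command-line front end over the same functions is installed at
`inst/cli/axdi.R` (subcommands `protocol`, `simulate`, `fit-dict`,
`fit-mcmc`, `adi`, `sensitivity`).

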