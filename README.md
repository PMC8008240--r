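# logdiffuse

Multimodal diffusion spectra from single-particle tracking data, via the
logarithmic measure of diffusion.

## The problem

Single-particle/single-molecule tracking of biological systems routinely
yields *mixed* Brownian data: several molecular species, or one species
visiting different environments, diffuse with distinct coefficients in the
same sample, and the tracks carry no label saying which is which. Ensemble
mean-squared-displacement (MSD) analysis averages the modes away, and
per-track MSD fitting needs long tracks. This package is for
experimentalists and modelers who need the *spectrum* of diffusion
coefficients — how many modes, at which D, in what proportions — from
plain trajectory tables, including very small data sets of short tracks.

## The method

Every consecutive step of a track in `n_d` dimensions over interval Δt is
reduced to its **diffusion element**

    S = |Δr|² / (2 n_d Δt),      η = log10(S).

For a Brownian mode with per-axis step variance σ² = 2DΔt, the squared
step is a scaled chi-square variable, and η has the exact density

    H(η) = Σ_k α_k · ln(10)/Γ(n_d/2) · x_k^(n_d/2) · exp(−x_k),
    x_k = n_d Δt 10^η / σ_k²,

an N-term mixture whose k-th component peaks **exactly at
η = log10(D_k)**, in any dimension. Distinct diffusive modes therefore
appear as distinct spectral peaks of the η histogram: often they can be
read off without any fitting (`peak_diffusion(eta_p)` = `10^eta_p`), and
a least-squares fit of H(η) (`fit_logmeasure()`) returns weights and
coefficients when quantitative estimates are needed. The package also
provides:

- the natural-domain chi-square mixture and its maximum-likelihood fit
  (`density_Z()`, `fit_direct_F()`);
- the exact second derivative of the bimodal density and bisection for
  the **critical mode separation** and **critical mixing fraction** at
  which a second spectral feature appears or vanishes
  (`d2H_bimodal()`, `critical_separation()`, `critical_alpha()`);
- residual-ratio model selection between 1- and 2-mode fits with
  threshold ε (`select_modality()`, `detection_experiment()`);
- MSD baselines and frame-based/individual-based ensemble averages
  (`msd_curve()`, `d_from_msd()`, `d_frame_based()`,
  `d_individual_based()`, `population_error()`);
- rotational (1D angular) variants throughout
  (`angular_displacements()`);
- Kullback–Leibler checks that the log-domain representation loses no
  information (`kl_domain_comparison()`);
- two validated data generators: ideal multimodal Brownian walks
  (`simulate_ideal()`) and a Brownian-dynamics model of cross-linked
  rigid filament bundles with anisotropic drag, WCA sterics and harmonic
  tethers (`run_filament_sim()`), whose bundle-size-dependent mobility
  creates multimodality from interactions rather than by construction.

See the methods vignette (`vignettes/logmeasure-methods.Rmd`) for the
model, assumptions, numerical choices and limitations.

## Worked example

Generate an equal mixture of fast (1.8×10⁻³ µm²/s) and slow
(6.5×10⁻⁵ µm²/s) tracks, transform, and fit a two-mode spectrum:

```r
library(logdiffuse)
spec <- mixture_spec(D = c(1.8e-3, 6.5e-5), alpha = c(0.5, 0.5),
                     n_d = 2, dt = 2.5, n_steps = 50, n_tracks = 2000,
                     seed = 42)
trajs <- simulate_ideal(spec)
el <- diffusion_elements(displacements(trajs))
fit <- fit_logmeasure(el, n_modes = 2)
fit
#> Log-measure fit (least squares on eta histogram), 2 mode(s)
#>       alpha         D
#> mode1 0.511 1.800e-03
#> mode2 0.489 6.508e-05
#> RMS residual per fitting point: 0.003296 over 71 bins
```

Both coefficients and the mixing fraction are recovered to within a
percent or two of the generating values at 10⁵ displacements. The peaks
of the fitted density sit at `log10(D)` of each mode:

```r
find_peaks(fit$model)
#> [1] -4.143082 -2.744627      # 10^(-2.74) = 1.8e-3, 10^(-4.14) = 7.2e-5
```

(the slow peak is pulled slightly off `log10(6.5e-5) = -4.19` by overlap
with the fast mode's tail — reading peaks is a quick look; the fit is the
estimator). Model selection prefers two modes decisively:

```r
select_modality(el, epsilon = 0.95)
#> Residual-ratio model selection: chose 2 mode(s)
#>   R1 = 0.1789, R2 = 0.003296, R2/R1 = 0.01842, epsilon = 0.95
```

How far apart must modes be to show up at all? For a fast mode with
σ₁ = 0.096 µm at Δt = 2.5 s and equal mixing, the second spectral
feature first appears when the slow mode's σ₂ drops to

```r
critical_separation(sigma1 = 0.096, alpha = 0.5, dt = 2.5)
#> $sigma2_crit 0.04786   # um; emerging inflection at eta = -2.739
```

i.e. slow-mode D below ~4.6×10⁻⁴ µm²/s. And the drag formulas for the
reference filament (L = 1 µm, d = 25 nm, ζ = 1 Pa·s, T = 300 K) give the
free-filament coefficient the simulations are validated against:

```r
drag_coefficients()$D_com
#> [1] 0.001823813           # um^2/s
```

## Command line

A thin wrapper over the same functions ships in
`inst/scripts/logdiffuse`:

```sh
logdiffuse spectrum --input traj.csv --dt 2.5 --dims 2 --out spectrum.tsv
logdiffuse fit --input traj.csv --dt 2.5 --dims 2 --modes 2 --out fit.json
logdiffuse simulate-ideal --config mixture.yaml --out traj.csv
```

Trajectory files are plain CSV with header `particle,frame,t,x,y[,theta]`
(µm, s, rad); other column layouts can be mapped in
`read_trajectories()`.

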