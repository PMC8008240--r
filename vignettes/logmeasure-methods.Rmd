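---
title: "The logarithmic measure of diffusion: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The logarithmic measure of diffusion: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logdiffuse)
```

## The problem

Single-particle tracking of biomolecules frequently produces *mixed*
Brownian data: several molecular species, or one species switching between
environments, diffuse with different coefficients in the same field of
view, and nothing in the images labels which track belongs to which mode.
Ensemble mean-squared-displacement (MSD) analysis averages the modes away.
This package implements a transform-and-fit analysis in which the modes
separate spectrally instead.

## The transform and its exact densities

For each consecutive step of a track in $n_d$ dimensions over interval
$\Delta t$, define the **diffusion element**

$$S = \frac{|\Delta \mathbf r|^2}{2 n_d \Delta t},$$

a single-step random variable with the units of a diffusion coefficient,
and its logarithm $\eta = \log_{10} S$. For a Brownian mode with per-axis
displacement variance $\sigma^2 = 2 D \Delta t$, the summed squared
components $Z = \sum_i \Delta x_i^2$ are $\sigma^2 \chi^2_{n_d}$
distributed, and the logarithmic change of variables gives the closed
form implemented by `density_eta()`:

$$H(\eta) = \sum_k \alpha_k \frac{\ln 10}{\Gamma(n_d/2)}
  x_k^{n_d/2} e^{-x_k}, \qquad
  x_k = \frac{n_d \Delta t\, 10^{\eta}}{\sigma_k^2},$$

for a mixture with weights $\alpha_k$. Two properties carry the whole
method:

* each mode's contribution peaks **exactly** at $\eta_p = \log_{10} D_k$,
  independent of $n_d$ — so peaks in the $\eta$ histogram can be read off
  as diffusion coefficients (`peak_diffusion()`), often without fitting;
* the family is closed under mixtures, so an $N$-mode population is an
  $N$-term sum with $2N-1$ free parameters.

For $n_d = 2$ the per-mode form reduces to
$\lambda\, 10^\eta e^{-2\Delta t 10^\eta/\sigma^2}$ with
$\lambda = 2\ln(10)\Delta t/\sigma^2$. For rotational data ($n_d = 1$,
$S_\theta = d\theta^2/2\Delta t$) the same protocol yields
$\lambda_\theta 10^{\eta/2} e^{-\Delta t 10^{\eta}/\sigma^2}$ with
$\lambda_\theta = \ln(10)\sqrt{\Delta t/(\pi\sigma^2)}$. We use this
re-derived prefactor — it is the unique one that normalizes to 1 and
agrees with the general-$n_d$ form; published typesettings of the 1D case
are frequently garbled by markup. The natural-domain density
(`density_Z()`) is the matching Gamma$(n_d/2,\,2\sigma_k^2)$ mixture,
evaluated through `stats::dgamma`.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `dt` (s) | data-defined | analysis interval; for state-switching systems it must exceed the dwell times, and for wrapped angles it must keep $|d\theta| \le \pi/2$ |
| `bin_width` ($\eta$ units) | 0.1 | histogram bin width; fitted coefficients are stable below 0.5 (a warning guards larger values, and `bin_width_sweep()` measures the dependence) |
| `n_starts` | 5 | multi-start optimizer seeds (spectrum peaks, $\eta$ quantiles, a collapsed one-mode start, deterministic jitters); best residual wins, ties to the first |
| `epsilon` | 0.95 | model-selection threshold on $R_2/R_1$ (see below) |

Zero displacements have $\eta = -\infty$; they are measure-zero under the
continuous model but real in discretized data, so they are excluded from
the histogram and reported in `n_zero` rather than silently dropped.

## Fitting

`fit_logmeasure()` minimizes the unweighted sum of squared differences
between $H(\eta)$ at occupied bin centers and the normalized bin
densities. Unweighted least squares is the minimal reading of how such
histogram fits are usually done; the maximum-likelihood route on the raw
natural-domain samples is provided separately (`fit_direct_F()`, whose
monomodal optimum is the closed form $\hat\sigma^2 = \overline{Z}/n_d$).
Positivity and simplex constraints are enforced by an unconstrained
reparameterization (log variances, softmax weights); Nelder–Mead followed
by a BFGS polish. A fit needs at least $2N+1$ occupied bins. Fits whose
modes sit closer than 0.05 decades are flagged as collapsed — below the
critical separation (next section) the components are not identifiable.
The fit object reports the RMS residual per fitting point;
`robustness_and_sensitivity()` recomputes it under fractional
perturbations $D = D_0(1+\delta)$ and summarizes the curvature at
$\delta = 0$, which is the meaningful sensitivity measure in the
noise-dominated small-track regime.

## When is a second mode visible?

`d2H_bimodal()` evaluates the exact second derivative of the two-mode 2D
density (cross-validated against numerical differentiation to $10^{-6}$
relative). Counting its sign changes on a dense grid
($\eta \in [\mu - 6, \mu + 3]$ at step $10^{-3}$, where $\mu$ is the fast
mode's $\log_{10} D$; exact zeros from tail underflow are ignored)
classifies the density shape: two inflection points for an effectively
monomodal shape, four when a second spectral feature exists.
`critical_separation()` and `critical_alpha()` bisect (tolerance
$10^{-4}$) for the parameter at which the extra pair appears or vanishes.
The grid step out-resolves the two-decimal precision at which such
critical values are usually quoted. Note the inflection pair appears
*before* a second local maximum does: just past critical the slow mode is
a shoulder, not yet a peak.

For the reference filament parameters the package computes a critical
slow-mode SD of 0.0479 µm (for $\sigma_1 = 0.096$ µm, $\alpha = 1/2$,
$\Delta t = 2.5$ s) with the new inflection at $\eta = -2.74$, and a
critical mixing fraction of 0.922 for the mode pair
($1.8\times10^{-3}$, $6.5\times10^{-5}$) µm²/s — matching the
two-significant-figure values quoted for this system (0.048, $-2.73$,
$\approx 0.925$).

## Model selection

`select_modality()` fits both the one- and two-mode densities to the same
spectrum and forms the residual ratio $R_2/R_1$. The two-mode model is
selected when $R_2/R_1 \le \epsilon$: the second mode must *improve* the
residual by at least the factor $\epsilon$. Because the two-mode family
nests the one-mode family and the two-mode optimizer is started from the
one-mode optimum, $R_2 \le R_1$ up to numerical noise, so $\epsilon = 1$
means no filtering and essentially always selects two modes; decreasing
$\epsilon$ filters increasingly aggressively, and the detection rate is
non-decreasing in $\epsilon$ by construction. (The threshold inequality
is sometimes prose-described in the opposite direction in the literature;
the direction implemented here is the one consistent with detection rates
that rise from 0% to ~100% as $\epsilon \to 1$.) On pooled samples as
small as one fast plus one slow 5-frame track (8 displacements) the
two-mode fit needs a coarser histogram; `detection_experiment()` uses
$\Delta\eta = 0.2$ and 3 starts there, a documented choice since no
small-sample binning protocol is standard. If the pooled spectrum cannot
support a two-mode fit at all (fewer than 5 occupied bins), the outcome
falls back to one mode with a flag — this, not fit failure, accounts for
the few percent of non-detections at $\epsilon = 1$.

## MSD baselines

`msd_curve()` (internal averaging), `d_from_msd()` (free-intercept linear
regression over lags up to $\tilde N \Delta t$, presets `full` and
`fifth`), and the ensemble averages `d_frame_based()` (pooled mean of all
elements — exactly the mean of $S$) and `d_individual_based()`
(per-particle means first) provide the standard comparisons. When track
length correlates with mode (slow particles tracked longer), step
weighting pulls $D_{FB}$ toward the long-lived mode and the two averages
split — the inequality is a useful nonuniformity diagnostic; which side
is larger follows from the weighting arithmetic, with $D_{IB} > D_{FB}$
when the slower particles carry more steps. `population_error()`
reproduces the characteristic error scalings: per-track histogram-fit
errors decay as $1/\sqrt{N_T}$ while full-MSD regression errors are flat
in track length.

## The ideal generator

`simulate_ideal()` draws IID zero-mean Gaussian steps with per-axis
variance $2 D_k \Delta t$; each track keeps one mode for its whole life
(a population mixture — state switching is deliberately out of scope,
and would anyway require $\Delta t$ above the transition times for this
analysis to apply). Rotational tracks accumulate a wrapped 1D angle, with
a warning when the per-step SD exceeds $\pi/6$, since wrapping then
biases $d\theta$. Per-track RNG substreams are derived from the master
seed by a two-round Lehmer scramble ($a = 48271$, $m = 2^{31}-1$, exact
in doubles), so enlarging a population never reshuffles existing tracks
and derived sub-experiments cannot collide with each other's streams.

What the generator does *not* emulate: localization error, motion blur,
finite-exposure effects, state switching, and anomalous (non-Gaussian or
correlated) displacements. Tests passing on this generator therefore
validate the transform, densities, fitting and selection machinery under
the model's own assumptions — they do not certify behavior on data whose
displacement statistics violate Gaussianity.

## The filament-bundle simulator

To validate against data whose nonuniformity *emerges from interactions*
rather than construction, `run_filament_sim()` integrates 2D Brownian
dynamics of rigid rods (length $L = 1$ µm, diameter $d = 25$ nm) with
slender-body drag
$\gamma_\parallel = 2\pi\zeta L/\ln(L/d)$,
$\gamma_\perp = 2\gamma_\parallel$,
$\gamma_r = \pi\zeta L^3/(3\ln(L/d))$ in a $\zeta = 1$ Pa·s solvent at
300 K ($k_BT = 4.1419\times10^{-3}$ pN·µm; units pN, µm, s throughout).
Pairs interact sterically through a WCA potential ($\epsilon = 1\,k_BT$,
Lennard-Jones distance $d$) acting along the line of closest approach
between the segments, and bundles are held by permanent harmonic
cross-links ($\kappa = 0.3$ pN/nm, rest length $d_0 = 80$ nm, kinesin-5
scale) at fixed arc-length sites, formed at initialization and never
broken. Forward Euler with fluctuation–dissipation-consistent Gaussian
kicks; periodic minimum-image box.

Numerical choices worth stating:

* **Friction tensor convention.** Printed rod equations of motion
  sometimes assign $\gamma_\perp$ to the filament axis
  ($\Gamma = \gamma_\perp \hat u\hat u + \gamma_\parallel(I - \hat u\hat u)$),
  the transpose of the conventional rod assignment. Both are implemented
  behind `friction = "printed"` / `"conventional"`; the free
  center-of-mass coefficient $(D_\parallel + D_\perp)/2$ — the quantity
  all headline results use — is identical under either.
* **Overlap cap.** WCA forces are evaluated with separations floored at
  $0.5\,d$ (capped at ~$6.5\times10^4$ pN and logged). A much smaller
  floor produces forces so astronomically large that double-precision
  accumulation loses the pairwise balance of every other interaction.
* **Neighbor search.** Candidate pairs are pruned exactly by
  minimum-image center distance against $L + 2^{1/6}d$. At the package's
  desk scale (tens of filaments) this $O(N^2)$ prune is exact, simple and
  fast; a cell list would pay off only far beyond that.
* **Zero-distance contacts.** Crossing segments (distance exactly 0) get
  the capped force directed perpendicular to the first filament's axis.
* **Scale.** The shipped configurations integrate $10^4$–$10^5$ steps of
  $10^{-4}$ s for 1–20 filaments (bond relaxation time
  $\gamma/\kappa \approx 6\times10^{-3}$ s $\gg$ dt), enough to show the
  free-filament fluctuation–dissipation checks and, for a bonded dimer,
  the qualitative three-regime MSD (diffusive, bond-dominated
  subdiffusive, collective diffusive at a reduced coefficient). Campaign
  scales (thousands of seconds at microsecond steps) are configuration
  changes, not code changes, but are far outside an interactive session.
* **Rotational ground truth.** Direct evaluation of the drag formulas
  gives $D_r = 1.46\times10^{-2}$ rad²/s for the reference filament; a
  value of 0.0135 is sometimes quoted for the same parameters (and
  $10^{-1.88} = 0.0132$, not 0.0135). The package reports the formula
  value and treats the quoted one as approximate; none of the acceptance
  quantities depend on it.

## Information content

`kl_domain_comparison()` verifies that representing data on the
logarithmic domain loses nothing: the KL divergence between a bimodal
density and its moment-matched monomodal surrogate
($\sigma_m^2 = \sum_k \alpha_k\sigma_k^2$, `monomodal_surrogate()`) is
identical in the displacement domain and the $\eta$ domain, because the
squaring-then-log chain is measurable and applied to both densities, and
the symmetric densities are blind to the sign lost by squaring.
Quadrature runs over $[\mu_{slow} - 16,\ \mu_{fast} + 6]$ on the $\eta$
axis — the 1D density decays only as $10^{\eta/2}$ on the left, so the
truncation must sit that far out to keep the tail error below $10^{-8}$.
For the rotational example with $\sigma_1 = 0.18$, $\sigma_{30} = 0.04$
rad at $\alpha = 1/2$ the surrogate SD is 0.130 rad (the mixture second
moment); a figure caption quoting 0.25 rad for these numbers is not
reproducible from them.

## Problem sizes used by the shipped tests

Chosen as the package's own desk-scale study conditions: $10^5$
displacements for two-mode recovery (both coefficients within a few
percent); 3000 tracks per length for the $1/\sqrt{N_T}$ error-scaling law
over $N_T \in \{5, 10, 20, 50, 100\}$; 200 repetitions of the paired
5-frame detection experiment; $3\times10^4$ BD steps for the dimer MSD
regimes; a 60-seed goodness-of-fit battery for the generator.

## Known limitations

No measurement-error model (localization noise, motion blur); no
anomalous-diffusion fitting (the theory rests on Gaussian displacements);
no state switching within tracks; model selection implemented for
$N \in \{1, 2\}$ (the densities themselves support any $N$); rotational
analysis limited by wrapping to effective intervals with
$|d\theta| \le \pi/2$.
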