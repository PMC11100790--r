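---
title: "Methods: quantifying a fluorogenic, red-shifting glycan probe"
author: "glycoprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying a fluorogenic, red-shifting glycan probe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoprobe)
```

# Scope and model

`glycoprobe` implements the quantitative analysis stack for a turn-on,
red-shifting glycan-binding fluorophore: a dye that is weakly fluorescent
free in solution and becomes brighter — with red-shifted absorbance and
emission — upon reversible boronic-acid/diol binding to glycans. Six
analysis stages share one synthetic-data generator with recorded ground
truth, so every estimator in the package can be exercised against known
parameters. The `analysis/` scripts at the repository root run the stages in
order and write their tables under `results/`.

## Two-state photophysics

The dye is modeled as a two-state system (`two_state_dye`): each state
carries a peak molar extinction $\varepsilon$, a quantum yield $\Phi$, an
absorbance spectrum $A(\lambda)$ stored for a reference condition (5 µM dye,
1 cm path; Beer–Lambert scaling applies elsewhere), and an emission spectrum
in arbitrary units. The detected signal of a state under settings
$(\lambda_{ex}, [\lambda_1, \lambda_2])$ is

$$ S = \Phi\,\bigl(1 - 10^{-A(\lambda_{ex})}\bigr)
       \int_{\lambda_1}^{\lambda_2} E(\lambda)\, d\lambda , $$

the product of a wavelength-specific excitation coefficient and the band
integral of the emission spectrum. The proportionality constant of the
excitation coefficient is set to 1: every quantity derived from it
(renormalized spectra, contrast) is a ratio in which the constant cancels. A
bound/unbound mixture with bound fraction $f$ is linear:
$I(f) = f S_{bound} + (1-f) S_{unbound}$, and the fluorogenic contrast is
$\Delta F/F = (S_{bound} - S_{unbound})/S_{unbound}$.

Numerical choices: spectra are interpolated linearly between grid points and
never extrapolated (queries outside the stored range are an error —
extrapolating measured photophysics invents data); band integrals use the
trapezoidal rule on the stored grid with interpolated band edges, and a
longpass band integrates to the last stored wavelength.

## Binding kinetics

Under pseudo-first-order conditions (dye in large excess over its change in
free concentration), approach to equilibrium is single-exponential,

$$ I(t) = I_{max}\bigl(1 - e^{-k_{obs}(t - t_0)}\bigr) + b ,
   \qquad k_{obs} = k_{on} C + k_{off}, $$

with the model clamped to $b$ for $t < t_0$; the delay absorbs the arbitrary
moment of dye addition. `fit_binding_timelapse()` estimates
$(I_{max}, k_{obs}, t_0, b)$ by Levenberg–Marquardt least squares
(`minpack.lm`). Initialization is deterministic — background from the trace
floor, amplitude from the range, rate from the log-linearized tail slope,
onset from the 5% crossing — with a multistart over
$\{0.3, 1, 3\} \times k_{obs,0}$ so that fits are reproducible without a
global optimizer. Bounds ($k_{obs} \in (10^{-7}, 1)$ s$^{-1}$,
$t_0 \in [0, t_{max}/2]$, $I_{max} > 0$) encode hour-scale binding. Flat
traces (range below $10^{-9}$ of the mean) are rejected as unidentifiable
rather than fitted.

`fit_rate_line()` regresses $k_{obs}$ on concentration: the slope is
$k_{on}$, the intercept $k_{off}$, and $K_D = k_{off}/k_{on}$ (stored
redundantly and asserted bit-for-bit). The regression is unweighted by
default, with inverse-variance weighting available; 95% intervals use the t
distribution on the regression standard errors. A nonpositive fitted
intercept flags $K_D$ as unavailable with a warning instead of reporting a
negative affinity. With the reference constants
$k_{on} = 12.8\ \mathrm{M^{-1} s^{-1}}$ and
$k_{off} = 6.77\times10^{-4}\ \mathrm{s^{-1}}$, $K_D = 52.9$ µM, and at 5 µM
dye $k_{obs} = 7.41\times10^{-4}\ \mathrm{s^{-1}}$, giving a delay-free
half-rise of $\ln 2 / k_{obs} = 935$ s $\approx$ 15.6 min and 90% of signal
at 51.8 min.

The default simulated experiment uses concentrations
$\{2.5, 5, 10, 20\}$ µM, 181 frames over 3 h (1 frame/min), and Gaussian
noise of 2% of $I_{max}$. The four concentrations are a package choice (a
plausible two-octave design bracketing 5 µM); $k_{obs}$ spans only
$\sim$30% across them because $k_{off}$ dominates, which is exactly why the
recovered slope is the noisiest quantity of the pipeline and why the
acceptance analysis reports the median over 20 replicate experiments.

## Hyperspectral excitation-scan mapping

An excitation scan steps $\lambda_{ex}$ over 500–566 nm in 2 nm increments
with fixed 575–630 nm detection, so each pixel carries an excitation
spectrum. Because the bound state is red-shifted, the wavelength of maximal
response discriminates bound from free dye. `spectral_peak_map()` bins the
cube spatially (block mean over $b \times b$ blocks, default $b = 2$,
trailing partial blocks dropped) and then takes the per-pixel argmax over
the sampled grid. No sub-grid interpolation is performed — the instrument
grid is 2 nm, and interpolating would invent precision. Ties break toward
the lowest wavelength, so flat noise-floor pixels read maximally blue and
are visually distinct; an optional intensity floor can mask them entirely
(default 0). Binning before argmax (rather than after) is the
variance-reducing order and the one adopted.

## FLIM phasor analysis

Per-pixel photon-arrival histograms are transformed to first-harmonic
phasor coordinates with bin midpoints $t_k$ and
$\omega = 2\pi f_{rep}$:

$$ g = \frac{\sum_k c_k \cos(\omega t_k)}{\sum_k c_k}, \qquad
   s = \frac{\sum_k c_k \sin(\omega t_k)}{\sum_k c_k}. $$

Mono-exponential decays of lifetime $\tau$ lie on the universal semicircle
$g^2 + s^2 = g$ at $g = 1/(1 + (\omega\tau)^2)$, and mixtures lie on the
chord between their components at the count-weighted fraction — the
properties the test suite asserts analytically ($10^{-12}$) and for binned
noiseless decays ($10^{-3}$, limited by midpoint quadrature). No
instrument-response deconvolution is applied; gates are circles in $(g, s)$
space, which suffices to separate the 2 ns (free) and 3.5 ns (bound)
populations — at 5000 photons/pixel, radius-0.05 gates assign $\ge 98\%$ of
pixels correctly. The default repetition rate is 80 MHz (Ti:Sapphire); the
simulator draws per-pixel multinomial counts from exact wrapped-exponential
bin probabilities, so lifetimes commensurate with the 12.5 ns period are
handled without bias, and it warns only when a lifetime exceeds the period
itself.

## Glycan-array quantification

The array layout is 100 glycans × 4 replicate spots plus two sets of 4
negative-control spots. Per spot, signal is the disk mean and local
background the median of a surrounding annulus (median rather than mean to
resist bleed from neighboring spots); the corrected signal is their
difference, which cancels any image-wide additive offset. Within-array
normalization divides by the array-wise mean of corrected values, canceling
multiplicative gain drift between arrays; the normalizer is a package
choice, as is pooling the eight control spots into one reference group.

Detection uses the strict rule corrected mean $> 2\times$ the local
background SD. Significance uses a Welch (unequal-variance) t statistic per
glycan against the pooled controls, with family-wise adjustment by a
Dunnett-type maximum statistic: the adjusted p of glycan $i$ is the null
probability that $\max_j |T_j|$ exceeds $|t_i|$. Because every comparison
shares one control group the statistics are correlated, and with unequal
variances no closed form exists, so the joint null is evaluated by seeded
parametric Monte Carlo with plug-in group SDs (default $10^5$ draws);
adjusted p-values are floored at the raw Welch p so adjustment can only
increase them. The family-wise error study in the acceptance suite runs
2000 global-null experiments at 4000 draws each — at that design the
binomial error of the FWER estimate ($\approx 0.5$ percentage points)
dominates the Monte Carlo depth per experiment, so deeper per-experiment
sampling would not sharpen the study.

## Photostability

`bleaching_metric()` reports the relative change between the means of the
first and last 5% of frames (windows of at least 3 frames) and the
trace-mean-normalized least-squares slope per hour; both are invariant to
multiplicative rescaling. "No loss" is operationalized as relative change
$\ge -1\%$ over the acquisition. Note the windowed metric spans window
centers rather than the full $0 \to T$ interval, so against the closed form
$1 - e^{-k_b T}$ it reads up to $\sim$1.6 percentage points shallow at 50%
loss; tests compare at 0.02 absolute.

The generator's exchange model is the minimal embodiment of the
replenishment mechanism: with exchange off, bound dye bleaches as
$e^{-k_b t}$; with exchange on, each frame bleaches fraction
$q = 1 - e^{-k_b \Delta t}$ of the bound dye, which instantly re-equilibrates
with an unbleached-rich free pool `free_pool_excess` times the bound
population, so the fluorescent fraction decays by $(1 - q/(1+E))$ per frame.
With $E \ge 100$ a 9.6 h, 1 frame/min acquisition loses under 1%.

# The synthetic-data generator

The generator defines the study conditions; its defaults are fixed, not
tuning knobs:

- **Dye model** (`make_default_dye()`): Gaussian bands with the bound state
  red-shifted 13 nm (absorbance) and 14 nm (emission);
  $\varepsilon = 8\times10^4 \to 1\times10^5\ \mathrm{M^{-1}cm^{-1}}$ and
  $\Phi = 0.60 \to 0.85$ (both increase on binding). The bound emission
  amplitude is calibrated in closed form so that $\Delta F/F$ at 561 nm
  excitation / 575 nm longpass equals the configured target (default 7.3)
  exactly. The main absorbance band uses $\sigma = 6$ nm so that the 2 nm
  excitation-scan grid cleanly resolves the region peaks (548 nm unbound vs
  560 nm bound-rich) at the 5% noise level; a 10%-amplitude blue shoulder
  (55 nm offset, $\sigma = 25$ nm) gives the band the blue tail through
  which a 488 nm line still excites the dye, as real rhodamines do. Real
  dye bands are broader and asymmetric; what passing tests show is that the
  estimators recover a known two-state model, not that this model is a
  spectroscopic fit to any particular dye.
- **Kinetics**: $k_{on} = 12.8\ \mathrm{M^{-1}s^{-1}}$,
  $k_{off} = 6.77\times10^{-4}\ \mathrm{s^{-1}}$, $I_{max} = 100$,
  $t_0 = 60$ s, $b = 10$, 2% Gaussian noise.
- **Scenes**: disjoint labeled regions with per-region bound fraction and
  brightness; intensity noise is Gaussian with SD proportional to the local
  noiseless signal (2% default, truncated at zero), emulating a
  detector-gain regime; FLIM photons are multinomial (shot-noise) draws.
- **Arrays**: 98 binder glycans with amplitudes drawn uniformly between 5
  and 25 noise SDs, 2 non-binders and 8 control spots at zero — the
  structural analogue of a broad-specificity probe on a commercial
  100-glycan array (the published raw images are unavailable, so this is a
  structure-matched stand-in, not a reproduction).
- **Photostability**: $k_b = 10^{-5}\ \mathrm{s^{-1}}$ (a clearly visible
  29% loss in 9.6 h without exchange), free-pool excess 100, trace noise
  0.5% of the initial intensity — an ROI-mean trace averages many pixels,
  so its frame-to-frame noise sits well below the 2% per-pixel level.

Every generator is deterministic under its seed (`with_seed()` restores the
caller's RNG state) and records seed and ground truth with its output.

# Problem sizes and determinism

The bundled analyses and tests use deliberately compact problem sizes —
64×64 spectral scenes, 32×32 FLIM scenes at 5000 photons/pixel, 181-frame
timelapses, 20-replicate kinetics studies, 2000-experiment FWER studies —
sizes at which every stochastic acceptance property holds with comfortable
margin while the whole suite remains quick to re-run. All randomness flows
through explicit seeds; re-running any stage with the same configuration
and seed reproduces its numeric outputs exactly.

# Known limitations

- The photophysics model has no solvatochromism, pH dependence of the
  boronic acids, or two-photon cross-sections; absorbance scaling assumes
  the Beer–Lambert regime.
- Kinetics fits assume a single exponential (one effective site class); no
  diffusion-limited corrections or spatially resolved $k_{obs}$ maps.
- The phasor stage omits IRF calibration and multi-harmonic analysis;
  free-form gates are approximated as circles.
- Array spot geometry comes from the layout configuration; there is no
  automatic grid registration or morphology QC.
- The synthetic scenes have no optical PSF, scattering, or tissue
  morphology; conclusions about estimator correctness transfer to real data
  only insofar as the stated noise models do.
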