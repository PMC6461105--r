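---
title: "Two-state conformational equilibrium analysis of single-molecule traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state conformational equilibrium analysis of single-molecule traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smeq)
```

## The measurement and the model

Many protein kinases are switched on and off by the orientation of their
activation loop. In the single-molecule assay this package analyses, two
dyes are attached to the kinase domain (one on the loop, one on the
N-lobe) such that the inactive loop conformation brings them within
quenching contact and the active conformation separates them: each
surface-tethered molecule blinks between a low- and a high-intensity
level as its loop interconverts. A camera records the intensity at 80 ms
per frame for 500 frames per molecule, and hundreds of molecules are
pooled per condition.

The package models this as a two-state continuous-time Markov (telegraph)
process. The inactive state is left at rate $k_\mathrm{active}$
(inactive $\to$ active) and re-entered at rate $k_\mathrm{inactive}$
(active $\to$ inactive); dwell times in each state are exponential and
the stationary inactive fraction is
$k_\mathrm{inactive}/(k_\mathrm{active}+k_\mathrm{inactive})$. Everything
downstream — histogram fitting, dwell kinetics, thermodynamics, the
conformational-selection binding algebra — is built on this two-state
picture, which the two-construct inversion experiment supports: a
reporter with the opposite intensity polarity yields the mirror-image
histogram and the same populations, so only two major conformations are
populated.

## The synthetic-data generator

`simulate_ensemble()` draws, per molecule, a telegraph path
(`sample_state_path()`, initial state from the stationary distribution —
molecules are observed at equilibrium) and integrates it into frames
(`integrate_to_frames()`). Two features matter:

* **Exact frame integration.** A frame's noiseless level is the
  time-weighted mixture of the two state intensities within the frame,
  computed by exact integration of the piecewise-constant path (the
  cumulative inactive time is piecewise linear, so interpolating it at
  the frame edges is exact). Conformational switches therefore happen
  *within* a frame, as in the experiment, not between frames.
* **Mode-preserving log-normal noise.** Each frame's intensity is drawn
  from a log-normal whose mode equals the frame level, with log-scale
  shape interpolated between the two state shapes by occupancy. This is
  the same distribution family the histogram model fits.

Defaults, chosen once as a realistic rendering of the assay: frame
interval 0.08 s, 500 frames per molecule, emission modes 30 and 90 a.u.
(a resolved 3:1 ratio), shapes 0.2, baseline 0, no photobleaching or
blinking (the experiment suppresses both with an oxygen-scavenger/Trolox
buffer). One seeded generator drives a whole ensemble and the seed is
recorded in the output metadata, so ensembles are reproducible
bit-for-bit.

What the generator does **not** emulate: camera physics (EM gain, pixel
noise, PSF), surface-tethering artefacts, photophysics
(bleaching/blinking), baseline drift, and heterogeneity between
molecules. Tests that pass on synthetic data therefore validate the
estimators under the model's assumptions; they do not certify performance
on raw videos, which additionally need spot finding and background
subtraction (out of scope here).

## Histogram model and population extraction

`fit_two_lognormals()` fits the pooled intensity histogram to the sum of
two log-normal components. Each component is parameterized by its
**mode** $m$ (the peak position, which is what one reads off a histogram)
and log-scale shape $s$; in the usual (meanlog, sdlog) parameterization
this is $\mu = \log m + s^2$, $\sigma = s$, and the median of the
component is $m\,e^{s^2}$. The default objective is least squares on the
binned counts — mirroring common practice with histogram fitting software
— with each bin's expectation computed from the bin-integrated component
probability (not density $\times$ width), which keeps the fit honest for
coarse bins. A mixture maximum-likelihood option on the raw intensities
(`method = "mle"`) is provided; on clean data the two agree (asserted in
tests).

Numerical choices:

* Binning: Freedman–Diaconis by default; fitted populations shift by
  less than one percentage point under ±25% bin-width changes (asserted
  in tests).
* Initialization: modes at the 20th/80th percentiles of the pooled
  intensity, shapes 0.2, equal areas — robust for bimodal data.
* Areas are the fitted component totals divided by the pooled frame
  count, and are **not** renormalized to sum to one; the published
  population pairs do not sum to 100 either.
* Degeneracy: if the fitted modes are unresolved (log separation less
  than half the summed shapes — two components splitting one peak), the
  fit collapses to a single log-normal, reported by convention as the
  high component with zero low-side area, flagged with a warning. Which
  conformation a lone peak represents is not identifiable from the data
  alone.

`populations_from_fit()` maps areas to conformations by construct
polarity: for the quench reporter (inactive = low intensity) the low peak
is the inactive population; for the inverted construct the mapping swaps.
Standard errors come from the fit covariance.

**Known bias.** At $k \approx 2\ \mathrm{s^{-1}}$ and 80 ms frames,
roughly 15% of frames contain a transition and sit between the peaks; the
two-component fit absorbs them asymmetrically (toward the high peak in
log space). This biases the low-peak area by about $-3$ percentage points
at equal populations, antisymmetrically in polarity — so the two
constructs bracket the truth and their mean recovers it (asserted in
tests). The same physics affects the real experiment; the published
two-construct agreement (52 vs 51% inactive) is consistent with a bias of
this size.

## Dwell-time kinetics

State assignment uses a reproducible threshold: the intensity between the
fitted modes where the two weighted component densities are equal
(`threshold_from_fit()`; geometric-mean fallback if they never cross).
Because the transition amplitude far exceeds the noise, any reasonable
threshold gives the same dwells; the density crossing simply removes the
manual step.

`extract_dwells()` converts maximal same-state runs into durations
(multiples of the frame interval; one-frame dwells are retained). Runs
touching either end of a trace are censored and excluded from fitting —
the standard unbiased treatment. `fit_single_exponential()` estimates the
exit rate either by the exponential MLE $k = 1/\bar t$ with analytic
standard error $k/\sqrt n$ (default: exact and assumption-matched) or by
least squares of $A e^{-kt}$ on the dwell histogram (bin width one frame,
starting at the shortest observed dwell — durations below one frame are
unobservable and an empty leading bin would bias the decay).

No dead-time/missed-event correction is applied: at 80 ms frames and
$k \approx 2\ \mathrm{s^{-1}}$, dwells shorter than about half a frame
are occasionally merged, biasing the fitted $k_\mathrm{active}$ low by
roughly 10% in simulation — documented here and bounded in tests (within
15% of truth at 500 molecules).

The reverse rate follows by detailed balance,
$k_\mathrm{inactive} = k_\mathrm{active} K_\mathrm{eq}$, and residence
times are reciprocal exit rates.

## Thermodynamics and the independence cycle

With $K_\mathrm{eq} = [\mathrm{inactive}]/[\mathrm{active}]$ computed
from the *unrounded* population ratio,
$\Delta G_\mathrm{inactive-active} = -RT\ln K_\mathrm{eq}$ at
$T = 298.15$ K ($R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$).
Population errors propagate in quadrature of relative errors; displayed
$K_\mathrm{eq}$ errors carry a floor of 0.1 (one display unit — the
published table prints ±0.1 where quadrature gives ±0.014), while stored
values keep full precision.

The ligand effect is $\Delta\Delta G_\mathrm{ligand} =
\Delta G_\mathrm{eq,apo} - \Delta G_\mathrm{eq,ligand}$ and the
phosphorylation effect analogously;
`independence_check()` verifies the experimental finding that the former
is independent of phosphorylation state (deviation ≤ 0.3 kcal mol$^{-1}$
per ligand), which licenses the composition
$\Delta G_\mathrm{eq} = \Delta G_\mathrm{eq,apo,unphos} -
\Delta\Delta G_\mathrm{phos} - \Delta\Delta G_\mathrm{ligand}$
(`compose_free_energy()`).

A print-precision caveat: the published $K_\mathrm{eq}$/$\Delta G$
columns were evidently computed from unrounded fitted areas. Recomputing
from the printed (rounded) populations reproduces 34 of the 40 printed
values exactly at one decimal and the remaining three cells
(43/57 → 0.75, printed 0.7; 64/36 → $\Delta G$ −0.34, printed −0.4;
83/13 → 6.38, printed 6.3) within one display unit. `thermo_table()`
returns full precision; its documentation records the caveat.

## Conformational-selection binding

Ligand discrimination is $D = K_\mathrm{d,inactive}/K_\mathrm{d,active}
= K_\mathrm{eq,apo}/K_\mathrm{eq,ligand}$ at saturating ligand; the
discrimination required to reach a target inactive fraction $f$ is
$K_\mathrm{eq,start}/\big(f/(1-f)\big)$ (`required_discrimination()`).
Display convention for the reproduction of the published table: fold
preference rounded to the nearest integer and discrimination printed as
the reciprocal of the *printed* fold to three decimals — this is the
published footnote ("fold preference = 1/ligand discrimination") applied
at print precision, and it reproduces every printed cell (direct
three-decimal rounding of the unrounded discrimination differs in one
cell, 0.126 vs 0.125). Unrounded values are always retained. The
unphosphorylated+TPX2 row is reproduced only from the *inverse* of the
measured ratio (56/46 rather than 46/56), an apparent inversion in the
published table; `reproduce_table2()` emits that row in both conventions
with a flag.

In the trace-ligand limit the apparent dissociation constant over both
conformations is

$$K_\mathrm{d,overall} =
\frac{1 + K_\mathrm{eq,free}}{1/K_\mathrm{d,active} +
K_\mathrm{eq,free}/K_\mathrm{d,inactive}},$$

the population-weighted harmonic combination of the conformation-specific
constants. This closed form is verified in tests against an independent
numerical oracle that solves the four-species balance
(A, I, A·L, I·L) and bisects for the half-saturation ligand
concentration. `kd_surface()` evaluates it on a log-spaced grid (default
1 nM–10 µM, 50 points per axis): the surface is monotone along both axes
and symmetric under axis swap when $K_\mathrm{eq} = 1$.

`contour_gap_distances()` inverts the closed form to give the
axis-parallel reductions in $K_\mathrm{d}$ needed to reach a target
contour. Because the surface falls to zero along either axis, every
contour below an uphill point is reachable along both axes; the
infinite-distance flag exists only as a defensive guard.
`equidistant_line()` traces the locus where the two reductions are equal
(distances measured linearly in concentration, since that is how the
published analysis phrases them; the metric tag is recorded in the
result). The surface is homogeneous of degree one in the concentration
variables, so curves sampled at heights proportional to the contour value
are rescaled copies of one another; the meaningful sense in which tighter
contours "approach the diagonal" is at fixed surface height, and that is
how the property is asserted (pass a common `levels` vector for a
decreasing contour sequence; the deviation
$|\log(K_\mathrm{d,inactive}/K_\mathrm{d,active})|$ at each level then
decreases monotonically). `plateau_mask()` returns the logarithmic
sensitivities $S_\mathrm{active} + S_\mathrm{inactive} = 1$; a region is
a plateau with respect to one axis when that axis's sensitivity is small,
and the joint mask (both below threshold) is non-empty only for
thresholds above 0.5.

## Reporter design numbers

`fret_efficiency()` implements $E = 1/(1+(r/R_0)^6)$; with the modelled
mean dye distances (45 Å active, 18 Å inactive) and $R_0 = 62$ Å for a
conventional FRET pair, both conformations would give high FRET (87% and
99.94% ≈ 100%), which is why the quench reporter — switching over a
16–21 Å residue-distance band (`quench_classification()`) — is the more
discriminating readout for this loop.

## Problem sizes and reproducibility

The test suite and worked examples use ensembles of 40–500 molecules at
500 frames; parameter-recovery checks use 300–500 molecules (about 1–2 s
each to simulate and fit), with tolerances of 3–4 percentage points on
populations and 15% on rates as stated above. All randomness flows from
explicit integer seeds; rerunning any pipeline with the same
configuration reproduces results exactly.

## Known limitations

* Populations inherit the ~3 pp mixed-frame bias discussed above;
  two-construct averaging cancels it.
* No hidden-Markov inference: thresholding suffices at this
  signal-to-noise ratio, but would not for overlapping peaks.
* No missed-event correction in the dwell analysis (~10% rate bias at
  the default frame rate).
* The binding layer is equilibrium-only: no kinetic (on/off-rate)
  models, no ligand depletion, no fitting of dose–response data.
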