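---
title: "Tracking cellular water during tissue drying: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking cellular water during tissue drying: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxdry)
```

## The measurement and the model

Plant tissue holds water in distinct compartments: intracellular water (ICW)
in the vacuole and cytoplasm, free water (FW) in the intercellular spaces,
and a small tightly bound fraction in the cell walls. In a proton NMR
echo-train experiment each compartment relaxes with its own transverse time
constant, so the measured magnitude decay is a discrete multi-exponential,

$$Z(t) \;=\; \sum_{i} M_i \, e^{-t/T_2^{\,i}},$$

with the slow pool (long $T_2$, order 100 ms in fresh tissue) read as ICW
and the fast pool (short $T_2$, order 30 ms) as FW. `relaxdry` fits this
model to echo-train decays, converts amplitudes to compartment percentages,
follows those percentages over drying time, and flags cell-rupture events —
abrupt transfers of ICW to the free pool when membranes fail under thermal
stress. A separate image branch binarises micro-CT style slices of the cell
wall lattice by maximum-entropy thresholding, the structural counterpart of
the relaxometric story.

Two deliberate scope limits: only discrete-component fitting is offered (no
regularised inversion to a continuous $T_2$ spectrum), and only
two-component fits have a compartment reading — the tightly bound cell-wall
pool is a few percent of total water and is not resolvable in this regime,
so a three-component fit raises an error rather than inventing a label for
its middle pool.

## How many components?

The classic bench rule is visual: plot $\ln Z$ against $t$; each
well-separated exponential contributes a distinct linear regime.
`estimate_component_count()` formalises this: the ln-signal is segmented
into $k = 1,2,3$ contiguous linear pieces by exact dynamic programming, $k$
is chosen by BIC, and adjacent segments whose slopes agree within 25% are
counted as one regime. Two numerical guards matter:

* the BIC's residual term is floored at a quantisation-scale value, so
  noiseless data (RSS numerically zero for every $k$) resolve by the
  parameter penalty instead of $-\infty$;
* the 25% slope-merge sets the method's resolution. A minor component that
  bends the log-slope by only a few percent — $T_2$ ratio below roughly 3
  with a small minor fraction — reads as a single regime on noiseless data,
  exactly as it would to the eye. Noisy realistic acquisitions of such
  truths typically still read as two regimes, and the fitting step is in
  any case run with $k = 2$ for compartment analysis.

## Fitting: variable projection with a deterministic multi-start

`fit_multiexponential()` minimises the linear-scale sum of squares. The
model is partially linear, which the search exploits:

1. amplitudes are profiled out by non-negative linear least squares on a
   log-spaced grid of $T_2$ combinations spanning the echo window;
2. the best grid cells (`n_starts`, default 4) are refined by
   Levenberg–Marquardt in $\log T_2$ with amplitudes still profiled;
3. each candidate gets a full-parameter polish under box constraints
   (amplitudes $\ge 0$, $T_2 \in [0.1, 10^4]$ ms).

For $k \ge 2$ one extra start is seeded from the best $(k-1)$-component fit
plus a zero-amplitude component, which makes the minimised residual
provably non-increasing in $k$. The procedure uses no random numbers, so
fits are reproducible by construction. Fitted $T_2$ values that cross
during optimisation are re-sorted into the canonical descending order
("long" is always index 1); values that agree within $10^{-6}$ relative are
merged and flagged `collapsed`, meaning the data support fewer components
than requested. Noise-floor samples — including negative ones under
additive noise — are retained by the fit (they carry information on the
linear scale) but dropped from the log-plot.

We verified on the reference parameter sets that the grid+LM search finds
the global minimum: Levenberg–Marquardt polished *from the truth* converges
to the same optimum the search returns, including in realisations where
that optimum sits far from the truth. At low curve SNR such far minima are
a property of the likelihood, not of the optimizer: with a $T_2$ ratio near
2.8 the fraction estimate is weakly identified, and no estimator of a
single noisy trace can do better. This is why the acquisition emulation
below averages over a region of interest.

## Signal-to-noise: definition, gate, and the ROI-mean convention

SNR is defined as mean(signal ROI) / sd(noise ROI), the common
magnitude-image convention with the noise region placed outside the sample
(`compute_snr()`). Fits are accepted when the curve's SNR reaches the gate,
default **5.17**, the validated sufficiency threshold for a stable
four-parameter bi-exponential fit; ties accept, and rejected fits are kept
with `accepted = FALSE` rather than deleted (`gate_by_snr()`).

The synthetic acquisition mirrors how such data are actually produced. SNR
is a *pixel-level* quantity, but the decay that is fitted is the *mean over
a region of interest*: the generator adds curve noise of standard deviation
$\sigma_{\text{pixel}} / \sqrt{\text{roi\_pixels}}$ with
$\sigma_{\text{pixel}} = Z(t_1) / \text{SNR}$, and separately emits
pixel-level signal and noise ROIs so that `compute_snr()` on them
round-trips the nominal SNR. The default `roi_pixels = 800` is a geometry
estimate fixed once: an 18 mm sample cross-section at 468 µm pixels spans
roughly 1150 pixels, and two manually drawn regions covering most of the
interior total about 800. Each reported series point is additionally the
mean of 3 replicate measurements, matching the convention that one tabled
measurement is the mean of three tests. Under these conditions the fresh
composition (88/12 split, $T_2$ 90.7/32.8 ms) is recovered with a median
fraction error of about 3.5 pp at the gate SNR — the acceptance suite
asserts $\le 5$ pp — and well under 1 pp at SNR 20.

The noise model is additive Gaussian by default (analytic, unbiased, the
right reference for estimator tests); a Rician option simulates the
magnitude of a complex Gaussian per pixel before ROI averaging. At the
gate SNR and above the Rician bias is small, which is the usual
justification for fitting magnitude data without bias correction; the
Gaussian default keeps that approximation out of the estimator tests.

One subtlety surfaces when probing behaviour *exactly at* the gate: an
unbiased SNR estimate of data whose true SNR equals the gate falls below it
by coin flip, so half the measurements are rejected as gate sampling noise.
`measure_drying_series(gate_on = "nominal")` gates on the acquisition's
true SNR for such experiments; the default (`"measured"`) keeps the
analyst-facing behaviour.

## Drying series and rupture detection

`generate_drying_series()` plants a ground-truth ICW trajectory: a stable
baseline, an abrupt drop of `drop_pp` at each rupture time, a partial
rebound toward baseline between ruptures (evaporation removes the freed
water, so the *relative* ICW share recovers), and seeded Gaussian
fluctuations elsewhere. Every time point also yields decay-simulation specs
whose amplitude fractions equal the truth, so the full chain
simulate → fit → gate → fractions → events closes end to end.

`detect_rupture_events()` records an event at every point sitting at least
`min_drop_pp` percentage points below the previous retained point. The
default threshold of **15 pp** is chosen to separate genuine rupture drops
(≥ ~22 pp in the reference series at 60–70 °C) from the minor fluctuations
(≤ ~6 pp) of non-rupturing 45 °C drying, and events are timestamped at the
post-drop measurement — the first time the drop is observable on the 30-min
sampling grid, which places the reference 60 °C drops at 90, 180, 270 and
360 min even though the underlying ruptures began one interval earlier.
Low-SNR points are excluded before detection, never interpolated:
interpolation could either fabricate a drop or smooth one away.

The preset protocols (`reference_protocol()`) encode the study's
qualitative temperature contrast as generator defaults, fixed once: no
ruptures and ±2 pp fluctuations at 45 °C; ruptures first observable at
90 min at 60 °C; earlier (60 min) and denser ruptures at 70 °C; drops of
30 pp (twice the detection threshold) and 1 pp fluctuations at the
rupturing temperatures, with a 0.5–0.6 per-step rebound.

```{r}
ev <- detect_rupture_events(reference_icw_series(60), min_drop_pp = 15)
ev
```

## Image branch: maximum-entropy segmentation

`entropy_threshold()` implements the Kapur criterion — the intensity cut
maximising the summed Shannon entropies of the two histogram classes —
by exhaustive scan of all 255 cuts, so the implementation *is* the
brute-force argmax the tests compare against (the test re-derives the
objective independently). Empty histogram bins contribute zero entropy
($0 \log 0 := 0$); cuts leaving an empty class are excluded; ties break to
the lowest maximising threshold. Thresholds are computed per slice.

Source descriptions of binarisation conventions are often self-
contradictory (a label of 1 "below" a grey value, yet the solid matrix
"appears white"). This package fixes the physical convention: X-rays are
reflected by the solid matrix, so **bright pixels are cell wall** — the
mask assigns 1 to intensities at or above the threshold, and
`wall_fraction` is the solid share of the slice.
`wall_fraction_profile()` reduces a mask to per-row solid fractions with
row 1 as the drying surface, quantifying breakage progressing inward.

The phantom generator renders a square cell lattice (period 24 px, 3 px
walls by default) with Gaussian intensity noise; `broken_fraction` erases
whole wall segments with probability graded linearly from twice its value
at the surface row to zero at the far edge. Noiseless phantoms segment to
the exact planted mask; at intensity noise of ~12 grey levels the Kapur
threshold lands close to the large (lumen) mode and the wall fraction is
recovered within a few percentage points, with the depth profile cleanly
resolving surface-weighted breakage.

## What the synthetic data do and do not show

The generators emulate the *structure* of the study conditions: the
1000-echo, 10-ms acquisition grid, the pixel-SNR/ROI-mean noise convention,
triplicate measurements, sawtooth ICW trajectories, and lattice-like wall
imagery. Passing tests therefore demonstrate that the estimators recover
known truths under that structure. They do not show: robustness to the
continuous $T_2$ distributions of real tissue (real pools are broadened,
not discrete); drift of $T_2$ constants with drying (the reference table's
long $T_2$ triples by the end of drying, while the generator holds the pair
fixed at 95/30 ms); temperature-dependent SNR; Rician bias at very low SNR;
or the irregular, anisotropic geometry of real cellular tissue as opposed
to a square lattice. The in-vivo temperature-field results of the original
study depend on a heat-transfer model outside this package's scope and are
not emulated.

## Numerical choices and test problem sizes

* $T_2$ bounds $[0.1, 10^4]$ ms; amplitudes non-negative; VARPRO grid of 10
  log-spaced candidates per axis between $t_1/3$ and $2 t_{\max}$.
* LM convergence tolerance $10^{-10}$ on the relative residual change;
  200 iterations per stage.
* Component merge tolerance $10^{-6}$ relative in $T_2$; bound-contact
  flag at 0.1%.
* Ln-plot segmentation: minimum segment length 4 points, BIC penalty
  $(3k-1)\log n$, RSS floor $n (10^{-6} \Delta)^2$ with $\Delta$ the
  ln-signal range, slope-merge tolerance 25%; echo trains beyond 1500
  points are thinned before the DP.
* Degenerate inputs: constant signals fit with $T_2$ driven to the upper
  bound and are flagged; all-non-positive signals are a log-plot error;
  single-intensity images are a histogram error.
* Test problem sizes, chosen to exercise the study regime at desk scale:
  50 random models for round-trip and oracle checks, 100 seeds for the
  gate-SNR recovery distribution, 20 seeded protocols (14 time points,
  1–3 replicates) for end-to-end closure, 64–256 px phantoms for the image
  branch.

## Known limitations

Fraction estimates at the gate SNR are heavy-tailed — the median error is
a few pp but the 90th percentile can exceed 15 pp for weakly separated
truths, which is precisely why the SNR gate exists and why series points
average replicates. The rupture detector is a thresholded first difference:
it cannot separate two ruptures inside one sampling interval, and a
rejected post-drop point delays an event to the next retained measurement,
where rebound may carry it back over the threshold. The component-count
rule inherits the visual method's resolution limit described above. The
Kapur threshold is computed per slice and can sit inside the dominant mode
for strongly imbalanced histograms; the wall-fraction error this induces is
small but systematic at high intensity noise.
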