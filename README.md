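# relaxdry

Water-compartment analysis of proton NMR T₂ relaxation during tissue
drying, with a synthetic-data bench for validating every stage against
known ground truth.

Plant tissue stores most of its water inside cells (intracellular water,
ICW) and a smaller share in the intercellular spaces (free water, FW). In
an echo-train NMR experiment these pools relax at different rates, so the
magnitude signal decays as a discrete multi-exponential

    Z(t) = Σᵢ Mᵢ · exp(−t / T₂ⁱ),

with the long-T₂ amplitude fraction read as ICW% and the short-T₂ fraction
as FW% (they sum to 100 by construction). Followed over drying time, the
ICW% series is diagnostic of how water leaves the tissue: it stays flat
when membranes hold (slow, cell-to-cell transport) and shows a sawtooth of
abrupt drops when heat ruptures cell membranes and dumps intracellular
water into the free pool. `relaxdry` implements the full analysis:

* **Decay fitting** — variable-projection nonlinear least squares for 1–3
  exponential components, deterministic multi-start, canonical
  descending-T₂ ordering (`fit_multiexponential`), plus a piecewise-linear
  ln-signal rule for choosing the component count
  (`estimate_component_count`).
* **Quality gating** — ROI-based SNR (`compute_snr`) and an acceptance
  gate at SNR 5.17 (`gate_by_snr`).
* **Compartment series and rupture detection** — amplitude fractions
  (`assign_compartments`), series assembly that excludes rejected fits
  (`build_series`), drop-threshold event detection
  (`detect_rupture_events`, default 15 pp), and per-temperature comparison
  (`compare_series`).
* **Micro-CT style segmentation** — Kapur maximum-entropy thresholding
  (`entropy_threshold`), bright-equals-solid binarisation
  (`segment_image`), and depth profiles of wall fraction
  (`wall_fraction_profile`).
* **Synthetic data** — seed-deterministic generators for decay
  acquisitions (`generate_decay`), drying protocols with planted ruptures
  (`generate_drying_series`, `reference_protocol`), and cell-lattice
  phantom images (`generate_phantom`).
* **Orchestration** — `run_pipeline()` runs simulate → fit → gate →
  series → events (→ segmentation) and writes JSON/CSV reports with seed
  and config-hash provenance.

A reference table of published bi-exponential decompositions of apple
tissue drying at 45/60/70 °C ships with the package
(`apple_t2_reference()`, `reference_icw_series()`) and serves as the
fixture for round-trip and detection checks.

## Worked example

Fit a clean 1000-echo acquisition synthesized from the fresh-tissue
reference row and read off the water split:

```r
library(relaxdry)

truth <- multiexp_model(c(88.10, 11.97), c(90.67, 32.76))  # %, ms
curve <- generate_decay(decay_sim_spec(truth))              # snr = Inf
fit   <- gate_by_snr(fit_multiexponential(curve, k = 2),
                     snr = compute_snr(curve$meta$signal_roi,
                                       curve$meta$noise_roi))
fit
#> <t2_fit> k = 2, R^2 = 1.0000, SSR = 1.168e-28
#> <multiexp_model>
#>   long   M = 88.1, T2 = 90.67 ms
#>   short  M = 11.97, T2 = 32.76 ms
#>   SNR = Inf -> accepted
assign_compartments(fit)
#> icw_pct  fw_pct
#> 88.03837 11.96163
```

The fitted constants reproduce the generating values exactly, and 88% of
the signal is intracellular water. Rupture detection on the reference
60 °C series:

```r
detect_rupture_events(reference_icw_series(60), min_drop_pp = 15)
#>   time_min drop_pp
#> 1       90   33.20
#> 2      180   24.99
#> 3      270   22.73
#> 4      360   56.91
```

Four membrane-rupture events, first observable at 90 min — each an
ICW% collapse of 22 pp or more within one 30-min sampling step. The same
rule finds no events in the 45 °C series, where membranes stay intact.

The numbered scripts under `analysis/` run the full narrative (simulate
example decays, fit them, run the three-temperature drying analysis,
segment phantoms) and leave their tables under `results/`:

```sh
Rscript analysis/01_simulate_decays.R
Rscript analysis/02_fit_relaxation.R
Rscript analysis/03_drying_series.R
Rscript analysis/04_segmentation.R
```

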