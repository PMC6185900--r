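## Run `code` under a temporary RNG state seeded with `seed`, restoring the
## caller's state afterwards, so generators are seed-deterministic without
## clobbering the session RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a simulated decay acquisition
#'
#' Describes one synthetic echo-train measurement: the ground-truth
#' relaxation model, the acquisition grid, and the noise regime. The noise
#' regime mirrors how such data are actually acquired and analysed: SNR is a
#' pixel-level quantity (mean signal-region intensity over the standard
#' deviation of a noise region outside the sample), while the decay that is
#' fitted is the mean over a signal region of `roi_pixels` pixels, whose
#' noise is reduced by `sqrt(roi_pixels)` relative to a single pixel. Set
#' `roi_pixels = 1` for raw single-trace noise.
#'
#' @param model ground truth [multiexp_model()].
#' @param n_echoes number of echoes (default 1000).
#' @param echo_spacing_ms echo spacing in ms (default 10).
#' @param snr pixel-level signal-to-noise ratio referenced to the first-echo
#'   signal; `Inf` (default) for a noiseless curve.
#' @param noise_model `"gaussian"` (additive, analytic reference) or
#'   `"rician"` (magnitude of a complex Gaussian, the physical model for
#'   magnitude data; positively biased at low SNR).
#' @param roi_pixels number of pixels averaged into the fitted decay
#'   (default 800, a whole-sample region at the emulated geometry).
#' @param seed integer RNG seed.
#' @return object of class `decay_sim_spec`.
#' @export
decay_sim_spec <- function(model, n_echoes = 1000, echo_spacing_ms = 10,
                           snr = Inf, noise_model = c("gaussian", "rician"),
                           roi_pixels = 800, seed = 1L) {
  if (!inherits(model, "multiexp_model"))
    stop("`model` must be a multiexp_model", call. = FALSE)
  if (n_echoes < 4) stop("`n_echoes` must be >= 4", call. = FALSE)
  if (echo_spacing_ms <= 0) stop("`echo_spacing_ms` must be > 0", call. = FALSE)
  if (!is.numeric(snr) || snr <= 0) stop("`snr` must be > 0", call. = FALSE)
  if (roi_pixels < 1) stop("`roi_pixels` must be >= 1", call. = FALSE)
  structure(list(model = model, n_echoes = as.integer(n_echoes),
                 echo_spacing_ms = echo_spacing_ms, snr = snr,
                 noise_model = match.arg(noise_model),
                 roi_pixels = as.integer(roi_pixels), seed = as.integer(seed)),
            class = "decay_sim_spec")
}

#' Generate a synthetic decay curve
#'
#' Samples the ground-truth model on the echo grid and adds seeded noise at
#' the pixel SNR of the spec (see [decay_sim_spec()] for the noise
#' convention). With `snr = Inf` the signal equals the model values exactly.
#' The returned curve carries, in `meta`, the truth model, the pixel noise
#' standard deviation, and two pixel-level regions of interest mirroring the
#' acquisition: `signal_roi` (first-echo pixel intensities inside the
#' sample) and `noise_roi` (pixels outside the sample), so that
#' [compute_snr()] on them recovers the nominal SNR up to sampling error.
#'
#' @param spec a [decay_sim_spec()].
#' @return a [decay_curve()].
#' @export
generate_decay <- function(spec) {
  if (!inherits(spec, "decay_sim_spec"))
    stop("`spec` must be a decay_sim_spec", call. = FALSE)
  times <- spec$echo_spacing_ms * seq_len(spec$n_echoes)
  clean <- evaluate_model(spec$model, times)
  n_roi <- max(64L, spec$roi_pixels)
  if (!is.finite(spec$snr)) {
    meta <- list(truth = spec$model, noise_sd_pixel = 0, snr_nominal = Inf,
                 roi_pixels = spec$roi_pixels,
                 signal_roi = rep(clean[1], n_roi), noise_roi = rep(0, n_roi),
                 noise_model = spec$noise_model, seed = spec$seed)
    return(decay_curve(times, clean, meta))
  }
  sd_pix <- clean[1] / spec$snr
  with_seed(spec$seed, {
    if (spec$noise_model == "gaussian") {
      signal <- clean + stats::rnorm(length(clean),
                                     sd = sd_pix / sqrt(spec$roi_pixels))
      signal_roi <- clean[1] + stats::rnorm(n_roi, sd = sd_pix)
      noise_roi <- stats::rnorm(n_roi, sd = sd_pix)
    } else {
      ## magnitude of complex Gaussian per pixel, averaged over the ROI
      g1 <- matrix(stats::rnorm(spec$roi_pixels * length(clean), sd = sd_pix),
                   spec$roi_pixels)
      g2 <- matrix(stats::rnorm(spec$roi_pixels * length(clean), sd = sd_pix),
                   spec$roi_pixels)
      signal <- colMeans(sqrt(sweep(g1, 2, clean, "+")^2 + g2^2))
      signal_roi <- sqrt((clean[1] + stats::rnorm(n_roi, sd = sd_pix))^2 +
                           stats::rnorm(n_roi, sd = sd_pix)^2)
      noise_roi <- sqrt(stats::rnorm(n_roi, sd = sd_pix)^2 +
                          stats::rnorm(n_roi, sd = sd_pix)^2)
    }
    meta <- list(truth = spec$model, noise_sd_pixel = sd_pix,
                 snr_nominal = spec$snr, roi_pixels = spec$roi_pixels,
                 signal_roi = signal_roi, noise_roi = noise_roi,
                 noise_model = spec$noise_model, seed = spec$seed)
    decay_curve(times, signal, meta)
  })
}

#' Specification of a drying protocol with planted ruptures
#'
#' Ground-truth recipe for an intracellular-water trajectory over drying
#' time: a stable baseline, abrupt planted drops at the rupture times, a
#' partial rebound toward baseline between ruptures (free water evaporates,
#' so the *relative* ICW share recovers), and small seeded fluctuations
#' elsewhere.
#'
#' @param temperature_c drying temperature label in Celsius.
#' @param sample_times measurement times in minutes, strictly increasing
#'   (default every 30 min from 30 to 420).
#' @param baseline_icw_pct ICW percentage before any rupture (default 88,
#'   a fresh-tissue value).
#' @param rupture_times subset of `sample_times` at which a drop is planted
#'   (empty for a non-rupturing, low-temperature protocol).
#' @param drop_pp drop size(s) in percentage points, scalar or one per
#'   rupture (default 30).
#' @param recovery_rate per-step fractional rebound toward baseline between
#'   ruptures, in `[0, 1]` (default 0.5).
#' @param fluctuation_sd standard deviation (pp) of the seeded point-to-point
#'   fluctuations (default 1).
#' @param t2_long_ms,t2_short_ms ground-truth relaxation constants of the
#'   two compartments (defaults 95 and 30 ms, matching the magnitude of the
#'   reference long/short columns).
#' @param seed integer RNG seed for the trajectory fluctuations.
#' @return object of class `drying_sim_spec`.
#' @export
drying_sim_spec <- function(temperature_c, sample_times = seq(30, 420, by = 30),
                            baseline_icw_pct = 88, rupture_times = numeric(),
                            drop_pp = 30, recovery_rate = 0.5,
                            fluctuation_sd = 1, t2_long_ms = 95,
                            t2_short_ms = 30, seed = 1L) {
  if (any(diff(sample_times) <= 0))
    stop("`sample_times` must be strictly increasing", call. = FALSE)
  if (!all(rupture_times %in% sample_times))
    stop("`rupture_times` must be a subset of `sample_times`", call. = FALSE)
  if (length(drop_pp) == 1) drop_pp <- rep(drop_pp, length(rupture_times))
  if (length(drop_pp) != length(rupture_times))
    stop("`drop_pp` must be scalar or one value per rupture", call. = FALSE)
  if (length(rupture_times) && any(drop_pp <= 0))
    stop("rupture drops must be positive", call. = FALSE)
  if (baseline_icw_pct < 0 || baseline_icw_pct > 100)
    stop("`baseline_icw_pct` must lie in [0, 100]", call. = FALSE)
  if (recovery_rate < 0 || recovery_rate > 1)
    stop("`recovery_rate` must lie in [0, 1]", call. = FALSE)
  if (t2_long_ms <= t2_short_ms)
    stop("`t2_long_ms` must exceed `t2_short_ms`", call. = FALSE)
  structure(list(temperature_c = temperature_c, sample_times = sample_times,
                 baseline_icw_pct = baseline_icw_pct,
                 rupture_times = rupture_times, drop_pp = drop_pp,
                 recovery_rate = recovery_rate,
                 fluctuation_sd = fluctuation_sd, t2_long_ms = t2_long_ms,
                 t2_short_ms = t2_short_ms, seed = as.integer(seed)),
            class = "drying_sim_spec")
}

#' Generate a drying series with planted ruptures
#'
#' Builds the ground-truth ICW trajectory of a [drying_sim_spec()] and, for
#' each time point, a [decay_sim_spec()] whose amplitude fractions equal the
#' truth at that point, so the full pipeline (fit, fraction assignment,
#' series assembly, rupture detection) can run end to end against known
#' ground truth. Per-time decay seeds are derived from the protocol seed and
#' the replicate index, keeping everything reproducible.
#'
#' @param spec a [drying_sim_spec()].
#' @param n_echoes,echo_spacing_ms,snr,noise_model,roi_pixels acquisition
#'   settings forwarded to each [decay_sim_spec()].
#' @param replicates decay measurements per time point (default 3; replicate
#'   fractions are averaged downstream, matching the convention that one
#'   reported measurement is the mean of 3 tests).
#' @return list with `truth` (a [compartment_series()]),
#'   `decay_specs` (list over time points, each a list of `replicates`
#'   [decay_sim_spec()]s) and `spec`.
#' @export
generate_drying_series <- function(spec, n_echoes = 1000,
                                   echo_spacing_ms = 10, snr = Inf,
                                   noise_model = "gaussian",
                                   roi_pixels = 800, replicates = 3) {
  if (!inherits(spec, "drying_sim_spec"))
    stop("`spec` must be a drying_sim_spec", call. = FALSE)
  tms <- spec$sample_times
  icw <- numeric(length(tms))
  with_seed(spec$seed, {
    fl <- function() if (spec$fluctuation_sd > 0)
      stats::rnorm(1, sd = spec$fluctuation_sd) else 0
    icw[1] <- spec$baseline_icw_pct + fl()
    for (i in seq_along(tms)[-1]) {
      ri <- match(tms[i], spec$rupture_times)
      if (!is.na(ri)) {
        icw[i] <- icw[i - 1] - spec$drop_pp[ri]
        if (icw[i] < 0)
          stop("planted drop of ", spec$drop_pp[ri],
               " pp exceeds current ICW (", round(icw[i - 1], 2), "%) at t = ",
               tms[i], " min", call. = FALSE)
      } else {
        icw[i] <- icw[i - 1] +
          spec$recovery_rate * (spec$baseline_icw_pct - icw[i - 1]) + fl()
      }
      icw[i] <- min(max(icw[i], 0), 100)
    }
    icw[1] <- min(max(icw[1], 0), 100)
  })
  truth <- compartment_series(tms, icw, spec$temperature_c)
  dspecs <- lapply(seq_along(tms), function(i) {
    lapply(seq_len(replicates), function(r) {
      decay_sim_spec(
        multiexp_model(c(icw[i], 100 - icw[i]) + 1e-9,  # guard zero amplitude
                       c(spec$t2_long_ms, spec$t2_short_ms)),
        n_echoes = n_echoes, echo_spacing_ms = echo_spacing_ms, snr = snr,
        noise_model = noise_model, roi_pixels = roi_pixels,
        seed = spec$seed + 1000L * i + r)
    })
  })
  list(truth = truth, decay_specs = dspecs, spec = spec)
}

#' Preset drying protocols at the three study temperatures
#'
#' Convenience constructors of [drying_sim_spec()]s emulating the qualitative
#' behaviour observed at each drying temperature: no ruptures at 45 degC
#' (minor fluctuations only); four ruptures at 60 degC first visible at 90
#' min; earlier and denser ruptures at 70 degC, first visible at 60 min.
#' Drops of 30 pp and a detection threshold of 15 pp keep planted events
#' twice the threshold and fluctuations well below half of it.
#'
#' @param temperature_c one of 45, 60, 70.
#' @param seed RNG seed forwarded to the spec.
#' @return a [drying_sim_spec()].
#' @export
reference_protocol <- function(temperature_c, seed = 1L) {
  if (temperature_c == 45)
    drying_sim_spec(45, baseline_icw_pct = 82, rupture_times = numeric(),
                    fluctuation_sd = 2, recovery_rate = 0.2, seed = seed)
  else if (temperature_c == 60)
    drying_sim_spec(60, baseline_icw_pct = 88,
                    rupture_times = c(90, 180, 270, 360), drop_pp = 30,
                    recovery_rate = 0.6, fluctuation_sd = 1, seed = seed)
  else if (temperature_c == 70)
    drying_sim_spec(70, baseline_icw_pct = 85,
                    rupture_times = c(60, 150, 240, 300), drop_pp = 30,
                    recovery_rate = 0.6, fluctuation_sd = 1, seed = seed)
  else stop("no preset protocol at ", temperature_c, " degC", call. = FALSE)
}

#' Specification of a cell-lattice phantom image
#'
#' Recipe for a synthetic micro-CT style slice: a square lattice of cells
#' with bright walls (solid matrix reflects X-rays) over a dark lumen, plus
#' optional wall breakage concentrated toward one edge, emulating rupture
#' progressing inward from the drying surface (row 1).
#'
#' @param size image side length in pixels (square image, default 256).
#' @param cell_diameter_px lattice period in pixels (default 24).
#' @param wall_thickness_px wall strip thickness in pixels (default 3,
#'   must satisfy `cell_diameter_px >= 2 * wall_thickness_px`).
#' @param wall_intensity,lumen_intensity mean 8-bit intensities of wall and
#'   lumen pixels (defaults 200 and 60).
#' @param intensity_sd Gaussian intensity noise sd (default 10; 0 for a
#'   noiseless two-level image).
#' @param broken_fraction average fraction of wall segments erased, graded
#'   from twice this value at the surface row to zero at the far edge
#'   (default 0).
#' @param resolution_um physical pixel size (default 6).
#' @param seed RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 256, cell_diameter_px = 24,
                         wall_thickness_px = 3, wall_intensity = 200,
                         lumen_intensity = 60, intensity_sd = 10,
                         broken_fraction = 0, resolution_um = 6, seed = 1L) {
  if (wall_thickness_px < 1) stop("wall thickness must be >= 1 px", call. = FALSE)
  if (cell_diameter_px < 2 * wall_thickness_px)
    stop("cell diameter must be at least twice the wall thickness",
         call. = FALSE)
  if (wall_intensity < 0 || wall_intensity > 255 ||
      lumen_intensity < 0 || lumen_intensity > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  if (broken_fraction < 0 || broken_fraction > 1)
    stop("`broken_fraction` must lie in [0, 1]", call. = FALSE)
  structure(list(size = as.integer(size),
                 cell_diameter_px = as.integer(cell_diameter_px),
                 wall_thickness_px = as.integer(wall_thickness_px),
                 wall_intensity = wall_intensity,
                 lumen_intensity = lumen_intensity,
                 intensity_sd = intensity_sd,
                 broken_fraction = broken_fraction,
                 resolution_um = resolution_um, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a cell-lattice phantom image with ground truth
#'
#' Renders the lattice of a [phantom_spec()] and returns both the grayscale
#' image and the true wall mask. Wall breakage erases whole wall segments
#' (the strip bordering one lattice cell) with a probability that decreases
#' linearly with depth from the surface row, so shallow rows lose more wall
#' than deep ones; erased segments take lumen intensity and leave the truth
#' mask.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [gray_image()]) and `truth_mask` (0/1
#'   integer matrix of surviving wall pixels).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  n <- spec$size; d <- spec$cell_diameter_px; w <- spec$wall_thickness_px
  pos <- (seq_len(n) - 1L) %% d
  is_wall_line <- pos < w
  wall <- outer(is_wall_line, is_wall_line, "|")  # rows OR cols on a wall line
  with_seed(spec$seed, {
    if (spec$broken_fraction > 0) {
      ## erase per wall segment: horizontal strips (per cell column) and
      ## vertical strips (per cell row), graded by depth of the segment
      cell_of <- function(i) (i - 1L) %/% d
      nr_cells <- cell_of(n) + 1L
      erase <- matrix(FALSE, n, n)
      p_at <- function(center_row)
        min(1, max(0, 2 * spec$broken_fraction * (1 - center_row / n)))
      for (ci in seq_len(nr_cells) - 1L) {
        for (cj in seq_len(nr_cells) - 1L) {
          rows_h <- which(cell_of(seq_len(n)) == ci & is_wall_line)
          cols_h <- which(cell_of(seq_len(n)) == cj & !is_wall_line)
          if (length(rows_h) && length(cols_h) &&
              stats::runif(1) < p_at(mean(rows_h)))
            erase[rows_h, cols_h] <- TRUE
          rows_v <- which(cell_of(seq_len(n)) == ci & !is_wall_line)
          cols_v <- which(cell_of(seq_len(n)) == cj & is_wall_line)
          if (length(rows_v) && length(cols_v) &&
              stats::runif(1) < p_at(mean(rows_v)))
            erase[rows_v, cols_v] <- TRUE
        }
      }
      wall <- wall & !erase
    }
    px <- ifelse(wall, spec$wall_intensity, spec$lumen_intensity)
    if (spec$intensity_sd > 0)
      px <- px + stats::rnorm(length(px), sd = spec$intensity_sd)
    px <- matrix(pmin(pmax(round(px), 0), 255), n, n)
    list(image = gray_image(px, spec$resolution_um),
         truth_mask = wall + 0L)
  })
}
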