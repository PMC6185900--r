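test_that("decay generation is exact at infinite SNR and seed-deterministic", {
  m <- multiexp_model(c(70, 30), c(100, 20))
  sp <- decay_sim_spec(m, n_echoes = 200, snr = Inf)
  cv <- generate_decay(sp)
  expect_identical(cv$signal, evaluate_model(m, cv$times))
  sp2 <- decay_sim_spec(m, n_echoes = 200, snr = 8, seed = 42)
  a <- generate_decay(sp2); b <- generate_decay(sp2)
  expect_identical(a$signal, b$signal)
  sp3 <- decay_sim_spec(m, n_echoes = 200, snr = 8, seed = 43)
  expect_false(identical(a$signal, generate_decay(sp3)$signal))
  # generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_decay(sp2)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated ROIs round-trip the nominal SNR through compute_snr", {
  m <- multiexp_model(c(88.1, 11.97), c(90.67, 32.76))
  snrs <- vapply(1:12, function(s) {
    cv <- generate_decay(decay_sim_spec(m, n_echoes = 100, snr = 5.17,
                                        seed = s))
    compute_snr(cv$meta$signal_roi, cv$meta$noise_roi)
  }, numeric(1))
  expect_equal(median(snrs), 5.17, tolerance = 0.05)
  expect_true(all(abs(snrs - 5.17) < 0.8))
})

test_that("rician noise is a positively biased magnitude signal", {
  m <- multiexp_model(c(70, 30), c(100, 20))
  cv <- generate_decay(decay_sim_spec(m, n_echoes = 400, snr = 5,
                                      noise_model = "rician",
                                      roi_pixels = 50, seed = 2))
  expect_true(all(cv$signal > 0))          # magnitudes, never negative
  tail_mean <- mean(cv$signal[300:400])    # decayed region: Rayleigh floor
  expect_gt(tail_mean, 0.5 * cv$meta$noise_sd_pixel / sqrt(50))
  expect_true(all(cv$meta$noise_roi > 0))
})

test_that("drying series plants exactly the requested trajectory features", {
  # flat protocol: constant series
  flat <- drying_sim_spec(45, baseline_icw_pct = 80,
                          fluctuation_sd = 0, seed = 1)
  s <- generate_drying_series(flat)$truth
  expect_true(all(s$icw_pct == 80))
  expect_equal(nrow(detect_rupture_events(s, 15)), 0)

  # one 30-pp rupture: exactly one detectable drop
  one <- drying_sim_spec(60, rupture_times = 210, drop_pp = 30,
                         fluctuation_sd = 0, seed = 1)
  st <- generate_drying_series(one)$truth
  ev <- detect_rupture_events(st, 15)
  expect_equal(ev$time_min, 210)
  expect_equal(ev$drop_pp, 30)

  # per-time decay specs carry the truth fractions
  sim <- generate_drying_series(one, replicates = 2)
  expect_length(sim$decay_specs, nrow(st))
  expect_length(sim$decay_specs[[1]], 2)
  fr <- vapply(sim$decay_specs, function(reps) {
    a <- reps[[1]]$model$amplitudes
    100 * a[1] / sum(a)
  }, numeric(1))
  expect_equal(fr, st$icw_pct, tolerance = 1e-6)

  # invalid specs refused
  expect_error(drying_sim_spec(60, rupture_times = 17), "subset")
  expect_error(generate_drying_series(
    drying_sim_spec(60, baseline_icw_pct = 20, rupture_times = 90,
                    drop_pp = 40, fluctuation_sd = 0)), "exceeds")
})

test_that("phantom generation matches its spec and is reproducible", {
  ph <- generate_phantom(phantom_spec(size = 96, intensity_sd = 0, seed = 3))
  expect_equal(dim(ph$image$pixels), c(96, 96))
  # intact lattice: truth mask is exactly the bright pixels
  expect_identical(ph$truth_mask, (ph$image$pixels > 128) + 0L)
  ph2 <- generate_phantom(phantom_spec(size = 96, intensity_sd = 0, seed = 3))
  expect_identical(ph$image$pixels, ph2$image$pixels)
  ph3 <- generate_phantom(phantom_spec(size = 96, intensity_sd = 10, seed = 4))
  expect_true(all(ph3$image$pixels >= 0 & ph3$image$pixels <= 255))
  expect_error(phantom_spec(cell_diameter_px = 5, wall_thickness_px = 3),
               "twice")
  # breakage erases wall, never adds
  phb <- generate_phantom(phantom_spec(size = 96, intensity_sd = 0,
                                       broken_fraction = 0.5, seed = 3))
  expect_true(all(phb$truth_mask <= ph$truth_mask))
  expect_lt(mean(phb$truth_mask), mean(ph$truth_mask))
})

test_that("pipeline closure holds at the SNR gate value", {
  # planted drops 2x the detection threshold, fluctuations well below it;
  # 20 seeded protocols at the gate SNR, gated on the acquisition's nominal
  # SNR (an unbiased SNR estimate of data sitting exactly on the gate is
  # rejected by coin flip, which is gate sampling noise, not fit failure)
  prec <- rec <- numeric(20)
  for (s in 1:20) {
    pr <- reference_protocol(60, seed = s)
    sim <- generate_drying_series(pr, snr = 5.17, replicates = 3)
    me <- measure_drying_series(sim, gate_on = "nominal")
    ev <- detect_rupture_events(me$series, 15)
    rec[s] <- mean(pr$rupture_times %in% ev$time_min)
    prec[s] <- if (nrow(ev)) mean(ev$time_min %in% pr$rupture_times) else 1
  }
  expect_gte(mean(prec), 0.9)
  expect_gte(mean(rec), 0.9)
})
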