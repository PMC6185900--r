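fake_fit <- function(amplitudes, t2, accepted = TRUE) {
  structure(list(model = multiexp_model(amplitudes, t2), r_squared = 1,
                 residual_norm = 0, snr = if (is.na(accepted)) NA_real_ else 10,
                 accepted = accepted, k = length(t2), collapsed = FALSE,
                 t2_at_bound = FALSE),
            class = "t2_fit")
}

test_that("compartment assignment is the long-amplitude fraction", {
  expect_equal(assign_compartments(fake_fit(c(3, 1), c(90, 30))),
               c(icw_pct = 75, fw_pct = 25))
  expect_equal(assign_compartments(fake_fit(c(1, 1), c(90, 30))),
               c(icw_pct = 50, fw_pct = 50))
  # the long label follows T2, not input order
  expect_equal(assign_compartments(fake_fit(c(1, 3), c(30, 90)))[["icw_pct"]],
               75)
  # fractions always sum to exactly 100
  set.seed(1)
  for (i in 1:20) {
    p <- assign_compartments(fake_fit(runif(2, 1, 100), c(100, 25)))
    expect_identical(sum(p), 100)
  }
})

test_that("compartment assignment rejects non-bi-exponential fits", {
  expect_error(assign_compartments(fake_fit(5, 90)), "exactly 2")
  expect_error(assign_compartments(fake_fit(c(3, 2, 1), c(300, 90, 10))),
               "exactly 2")
  collapsed <- fake_fit(c(3, 1), c(90, 30))
  collapsed$collapsed <- TRUE
  expect_error(assign_compartments(collapsed), "collapsed")
})

test_that("compartment_series enforces its invariants", {
  s <- compartment_series(c(30, 60, 90), c(88, 80, 45), 60)
  expect_equal(s$fw_pct, 100 - s$icw_pct)
  expect_equal(attr(s, "temperature_c"), 60)
  expect_error(compartment_series(c(30, 30, 60), c(1, 2, 3)), "increasing")
  expect_error(compartment_series(c(30, 60), c(88, 101)), "\\[0, 100\\]")
})

test_that("build_series keeps accepted fits in time order, drops the rest", {
  cfg <- fit_config()
  fits <- list(gate_by_snr(fake_fit(c(88, 12), c(95, 30)), 10, cfg),
               gate_by_snr(fake_fit(c(80, 20), c(95, 30)), 10, cfg),
               gate_by_snr(fake_fit(c(45, 55), c(95, 30)), 10, cfg))
  s <- build_series(fits, c(30, 60, 90), 60)
  expect_equal(nrow(s), 3)
  expect_equal(s$icw_pct, c(88, 80, 45))

  fits[[2]] <- gate_by_snr(fits[[2]], 2, cfg)   # below the gate
  s2 <- build_series(fits, c(30, 60, 90), 60)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$time_min, c(30, 90))
  expect_equal(attr(s2, "n_rejected"), 1L)

  fits[[3]] <- gate_by_snr(fits[[3]], 2, cfg)
  expect_error(build_series(fits, c(30, 60, 90), 60), "fewer than 2")
  ungated <- list(fake_fit(c(1, 1), c(90, 30), accepted = NA),
                  fake_fit(c(1, 1), c(90, 30), accepted = NA))
  expect_error(build_series(ungated, c(30, 60)), "gated")
})

test_that("rupture detection matches the exhaustive drop-scan oracle", {
  tm <- seq(30, 180, by = 30)
  s <- compartment_series(tm, c(88, 87, 45, 69, 78, 53), 60)
  ev <- detect_rupture_events(s, 15)
  expect_equal(ev$time_min, c(90, 180))     # third and sixth points
  expect_equal(ev$drop_pp, c(42, 25))
  # property: agreement with the scan oracle across random sawtooth series
  set.seed(23)
  for (i in 1:25) {
    icw <- pmin(pmax(cumsum(rnorm(12, 0, 12)) + 60, 0), 100)
    tmr <- seq(30, by = 30, length.out = 12)
    sr <- compartment_series(tmr, icw)
    thr <- sample(c(0, 5, 15, 30), 1)
    expect_equal(detect_rupture_events(sr, thr)$time_min,
                 scan_oracle(tmr, icw, thr))
  }
})

test_that("rupture detection honours threshold extremes", {
  tm <- seq(30, 180, by = 30)
  s <- compartment_series(tm, c(88, 87, 45, 69, 78, 53), 60)
  expect_equal(nrow(detect_rupture_events(s, Inf)), 0)
  # threshold 0: every strictly decreasing step
  ev0 <- detect_rupture_events(s, 1e-12)
  expect_equal(ev0$time_min, c(60, 90, 180))
  const <- compartment_series(tm, rep(80, 6), 45)
  expect_equal(nrow(detect_rupture_events(const, 15)), 0)
  expect_error(detect_rupture_events(compartment_series(c(1, 2), c(5, 5)), 1),
               "at least 3")
})

test_that("the 60 degC reference column yields the documented drop times", {
  ev <- detect_rupture_events(reference_icw_series(60), 15)
  expect_equal(ev$time_min, c(90, 180, 270, 360))
  # and the 45 degC protocol shows no events at all
  expect_equal(nrow(detect_rupture_events(reference_icw_series(45), 15)), 0)
})

test_that("compare_series summarises event timing across temperatures", {
  s45 <- reference_icw_series(45)
  s60 <- reference_icw_series(60)
  tab <- compare_series(list(s45, s60, s60))
  expect_equal(tab$n_events, c(0, 4, 4))
  expect_equal(tab$first_event_min, c(NA, 90, 90))
  expect_identical(tab[2, ], tab[3, ], ignore_attr = TRUE)
  expect_equal(tab$final_icw_pct[2], 5.12)
  # generator ground truth: hotter protocol ruptures first
  sim60 <- generate_drying_series(reference_protocol(60, seed = 2))
  sim70 <- generate_drying_series(reference_protocol(70, seed = 2))
  tab2 <- compare_series(list(sim60$truth, sim70$truth))
  expect_lt(tab2$first_event_min[2], tab2$first_event_min[1])
  expect_error(compare_series(list(s45)), "at least 2")
})
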