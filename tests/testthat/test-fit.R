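test_that("noiseless mono-exponential fit is exact with R^2 = 1", {
  t <- echo_grid(300)
  cv <- decay_curve(t, evaluate_model(multiexp_model(75, 140), t))
  f <- fit_multiexponential(cv, 1)
  expect_equal(f$model$amplitudes, 75, tolerance = 1e-8)
  expect_equal(f$model$t2, 140, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
})

test_that("noiseless two-component round trip recovers parameters to < 0.5%", {
  t <- echo_grid()
  set.seed(7)
  worst <- 0
  for (i in 1:50) {
    m <- rand_model2(min_ratio = 2.5, min_minor = 0.05)
    f <- fit_multiexponential(decay_curve(t, evaluate_model(m, t)), 2)
    rel <- max(abs(c(f$model$amplitudes, f$model$t2) /
                     c(m$amplitudes, m$t2) - 1))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 0.005)
})

test_that("adding a component never increases the minimised residual", {
  set.seed(11)
  t <- echo_grid(400)
  for (s in 1:5) {
    m <- rand_model2()
    cv <- generate_decay(decay_sim_spec(m, n_echoes = 400, snr = 10,
                                        roi_pixels = 50, seed = s))
    f1 <- fit_multiexponential(cv, 1)
    f2 <- fit_multiexponential(cv, 2)
    f3 <- fit_multiexponential(cv, 3)
    expect_lte(f2$residual_norm, f1$residual_norm + 1e-9)
    expect_lte(f3$residual_norm, f2$residual_norm + 1e-9)
  }
})

test_that("fit is invariant to uniform signal rescaling", {
  t <- echo_grid(500)
  cv <- generate_decay(decay_sim_spec(
    multiexp_model(c(70, 30), c(100, 20)), n_echoes = 500, snr = 30,
    seed = 3))
  f <- fit_multiexponential(cv, 2)
  f_scaled <- fit_multiexponential(decay_curve(cv$times, 1000 * cv$signal), 2)
  expect_equal(f_scaled$model$amplitudes, 1000 * f$model$amplitudes,
               tolerance = 1e-4)
  expect_equal(f_scaled$model$t2, f$model$t2, tolerance = 1e-4)
  expect_equal(f_scaled$r_squared, f$r_squared, tolerance = 1e-8)
})

test_that("degenerate constant signal fits with T2 at the bound, flagged", {
  cv <- decay_curve(echo_grid(50), rep(10, 50))
  f <- fit_multiexponential(cv, 1)
  expect_true(f$t2_at_bound)
  expect_equal(f$model$amplitudes, 10, tolerance = 0.05)
})

test_that("component count follows the distinct-linear-regime rule", {
  t <- echo_grid()
  k_of <- function(m) estimate_component_count(
    decay_curve(t, evaluate_model(m, t)))
  expect_equal(k_of(multiexp_model(100, 100)), 1)
  expect_equal(k_of(multiexp_model(c(60, 40), c(100, 20))), 2)
  expect_equal(k_of(multiexp_model(c(50, 50), c(1000, 10))), 2)
  expect_equal(k_of(multiexp_model(c(40, 30, 30), c(1000, 100, 10))), 3)
  # constant signal: single zero-slope regime
  expect_equal(estimate_component_count(decay_curve(echo_grid(50),
                                                    rep(5, 50))), 1)
  # realistic noisy acquisitions of the fresh-sample model read as 2
  m <- multiexp_model(c(88.10, 11.97), c(90.67, 32.76))
  ks <- vapply(1:5, function(s) estimate_component_count(
    generate_decay(decay_sim_spec(m, snr = 20, seed = s))), numeric(1))
  expect_true(all(ks == 2))
})

test_that("component count respects max_components and short curves", {
  t <- echo_grid()
  cv <- decay_curve(t, evaluate_model(multiexp_model(c(50, 50),
                                                     c(1000, 10)), t))
  expect_equal(estimate_component_count(cv, fit_config(max_components = 1)), 1)
  short <- decay_curve(1:6, exp(-(1:6) / 2))
  expect_warning(k <- estimate_component_count(short), "capping")
  expect_lte(k, 1)
})

test_that("compute_snr is mean(signal)/sd(noise) with an Inf sentinel", {
  noise <- rnorm(200)
  noise <- (noise - mean(noise)) / sd(noise) * 10   # sample sd exactly 10
  expect_equal(compute_snr(rep(51.7, 25), noise), 5.17)
  roi <- c(4, 6, 5, 7, 3)
  expect_equal(compute_snr(roi, roi), mean(roi) / sd(roi))
  expect_identical(compute_snr(c(1, 2), rep(3, 10)), Inf)
  expect_error(compute_snr(numeric(), 1:5), "non-empty")
})

test_that("SNR gate accepts ties and keeps rejected fits", {
  t <- echo_grid(100)
  f <- fit_multiexponential(
    decay_curve(t, evaluate_model(multiexp_model(c(70, 30), c(100, 20)), t)),
    2)
  expect_true(gate_by_snr(f, 5.17)$accepted)
  expect_false(gate_by_snr(f, 5.16)$accepted)
  expect_false(gate_by_snr(f, 0)$accepted)
  rejected <- gate_by_snr(f, 1)
  expect_s3_class(rejected, "t2_fit")          # retained, not deleted
  expect_equal(rejected$model$t2, f$model$t2)  # model untouched
  expect_true(gate_by_snr(f, 3, fit_config(snr_gate = 2))$accepted)
})
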