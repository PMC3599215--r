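test_that("monoexponential forward model evaluates the exponential decay", {
  expect_equal(mono_signal(b = 800, si0 = 1, adc = 0), 1)
  expect_equal(mono_signal(b = 800, si0 = 1, adc = 1.0e-3), exp(-0.8))
  # cohort-median ADC at the maximal b value; frozen forward evaluation
  expect_equal(mono_signal(b = 800, si0 = 1000, adc = 1.04e-3),
               435.17805926635674, tolerance = 1e-12)
  # strictly decreasing in b for positive adc
  s <- mono_signal(b = c(0, 50, 100, 250, 800), si0 = 10, adc = 1e-3)
  expect_true(all(diff(s) < 0))
})

test_that("biexponential forward model and its degenerate limits", {
  tr <- median_truth()
  # normalisation at b = 0
  expect_equal(biexp_signal(0, tr$si0, tr$d, tr$d_star, tr$fp), tr$si0)
  # frozen hand evaluation at cohort-median parameters, b = 50
  expect_equal(biexp_signal(50, 1, 0.84e-3, 11.9e-3, 0.16),
               0.89370062621973967, tolerance = 1e-12)
  # fp = 0 collapses to the monoexponential model at machine precision
  b <- seq(0, 1500, by = 50)
  expect_equal(biexp_signal(b, 7, 1.0e-3, 30e-3, 0),
               mono_signal(b, 7, 1.0e-3), tolerance = 1e-15)
  # d_star = d collapses likewise for any fp
  expect_equal(biexp_signal(b, 7, 1.0e-3, 1.0e-3, 0.4),
               mono_signal(b, 7, 1.0e-3), tolerance = 1e-15)
})

test_that("parameter constructors enforce their invariants", {
  expect_silent(ivim_params(1000, 0.84e-3, 11.9e-3, 0.16))
  expect_error(ivim_params(0, 1e-3, 1e-2, 0.1), "si0")
  expect_error(ivim_params(1, 2e-3, 1e-3, 0.1), "d_star")
  expect_error(ivim_params(1, 1e-3, 1e-2, 1.3), "fp")
  expect_silent(mono_params(1, -1e-4)) # noise-dominated voxels allowed
  expect_error(mono_params(1, Inf), "finite")
})

test_that("two-point ADC inverts the monoexponential model", {
  expect_equal(two_point_adc(1, 0, exp(-0.8), 800), 1.0e-3)
  expect_equal(two_point_adc(5, 100, 5, 800), 0)
  expect_error(two_point_adc(-1, 0, 1, 800), class = "ivimsim_domain_error")
  expect_error(two_point_adc(1, 800, 1, 100), class = "ivimsim_domain_error")

  # round-trip identity over random monoexponential parameters
  withr::with_seed(42, {
    for (i in 1:200) {
      si0 <- runif(1, 1, 2000)
      adc <- runif(1, -0.5e-3, 3e-3)
      ba <- runif(1, 0, 400)
      bb <- ba + runif(1, 10, 800)
      rec <- two_point_adc(mono_signal(ba, si0, adc), ba,
                           mono_signal(bb, si0, adc), bb)
      expect_equal(rec, adc, tolerance = 1e-12)
    }
  })
})

test_that("log-signal chord slope decreases as the b interval shifts right", {
  # log-convexity of the two-compartment sum: for fp > 0 and d_star > d the
  # chord ADC over a later interval is strictly smaller, and every chord
  # stays above the limiting slope d
  withr::with_seed(7, {
    for (i in 1:50) {
      d <- runif(1, 0.2e-3, 1.6e-3)
      d_star <- runif(1, 4.3e-3, 72.1e-3)
      fp <- runif(1, 0.05, 0.55)
      ivals <- list(c(0, 50), c(0, 100), c(0, 250), c(50, 250), c(100, 400),
                    c(250, 800), c(400, 1000))
      slopes <- vapply(ivals, function(iv)
        oracle_chord_adc(iv[1], iv[2], 1, d, d_star, fp), numeric(1))
      expect_true(all(diff(slopes) < 0))
      expect_true(all(slopes > d))
    }
  })
})

test_that("limiting log-signal slope at large b is the tissue coefficient", {
  tr <- median_truth()
  slope_far <- oracle_chord_adc(4000, 5000, tr$si0, tr$d, tr$d_star, tr$fp)
  expect_equal(slope_far, tr$d, tolerance = 1e-6)
})

test_that("noiseless chord ADC over low b exceeds the high-b chord", {
  tr <- median_truth()
  low <- oracle_chord_adc(0, 50, tr$si0, tr$d, tr$d_star, tr$fp)
  high <- oracle_chord_adc(250, 800, tr$si0, tr$d, tr$d_star, tr$fp)
  expect_gt(low, high)
  # frozen oracle values at the cohort medians
  expect_equal(low, 2.2476885978078599e-3, tolerance = 1e-12)
  expect_equal(high, 0.86163037677006562e-3, tolerance = 1e-12)
})
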