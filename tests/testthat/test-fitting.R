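test_that("mono fit recovers generating parameters on noiseless data", {
  b <- acquisition_b()
  s <- mono_signal(b, si0 = 500, adc = 1.3e-3)
  fit <- fit_mono(tibble::tibble(b_value = b, signal = s))
  expect_true(fit$converged)
  expect_equal(fit$si0, 500, tolerance = 1e-9)
  expect_equal(fit$adc, 1.3e-3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$chi_squared, 1e-20)
  expect_equal(tidy(fit)$term, c("si0", "adc"))
  expect_equal(glance(fit)$n_points, 5L)
})

test_that("two-b-value mono fits equal the closed-form chord ADC", {
  withr::with_seed(101, {
    for (i in 1:50) {
      si0 <- runif(1, 10, 2000)
      adc <- runif(1, 0.1e-3, 3e-3)
      ba <- runif(1, 0, 300); bb <- ba + runif(1, 50, 700)
      s <- mono_signal(c(ba, bb), si0, adc) *
        exp(rnorm(2, 0, 0.05)) # multiplicative perturbation keeps s > 0
      fit <- fit_mono(s, b_values = c(ba, bb))
      oracle <- two_point_adc(s[1], ba, s[2], bb)
      expect_equal(fit$adc, oracle, tolerance = 1e-9)
    }
  })
  # flat signal gives zero ADC
  expect_equal(fit_mono(c(7, 7), b_values = c(0, 800))$adc, 0)
})

test_that("degraded voxels yield converged = FALSE, never an error", {
  fit <- fit_mono(c(0, 0, 0), b_values = c(0, 100, 800))
  expect_false(fit$converged)
  expect_error(fit_mono(5, b_values = 0), class = "ivimsim_config_error")
})

test_that("biexp fit recovers cohort-median truth on the 5-point acquisition", {
  ser <- median_truth_series()
  tr <- median_truth()
  fit <- fit_biexp(ser)
  expect_true(fit$converged)
  expect_equal(fit$d, tr$d, tolerance = 1e-4)
  expect_equal(fit$d_star, tr$d_star, tolerance = 1e-4)
  expect_equal(fit$fp, tr$fp, tolerance = 1e-4)
  expect_equal(fit$si0, tr$si0, tolerance = 1e-4)
})

test_that("biexp fit degenerates correctly when there is no perfusion", {
  b <- acquisition_b()
  s <- mono_signal(b, 800, 1.1e-3)
  bi <- fit_biexp(tibble::tibble(b_value = b, signal = s))
  mo <- fit_mono(tibble::tibble(b_value = b, signal = s))
  expect_lt(abs(bi$d - mo$adc) / mo$adc, 1e-6)
  expect_lt(bi$fp, 1e-6)
})

test_that("biexp fit refuses fewer than four distinct b values", {
  expect_error(fit_biexp(c(1, 0.9, 0.5), b_values = c(0, 100, 800)),
               class = "ivimsim_config_error")
})

test_that("segmented initialisation lands near the truth", {
  # pure mono series: no perfusion compartment to back-extrapolate
  b <- acquisition_b()
  ini <- segmented_init(tibble::tibble(b_value = b,
                                       signal = mono_signal(b, 100, 1e-3)))
  expect_lt(ini$fp, 1e-8)
  expect_false(ini$fallback)
  # cohort-median series: d seeded within 10 % of truth (high-b chord)
  ini2 <- segmented_init(median_truth_series(), b_threshold = 250)
  expect_lt(abs(ini2$d - median_truth()$d) / median_truth()$d, 0.10)
  # all b below the threshold: documented fallback, flagged
  ini3 <- segmented_init(tibble::tibble(b_value = c(0, 50, 100),
                                        signal = c(1, 0.95, 0.9)),
                         b_threshold = 250)
  expect_true(ini3$fallback)
})

test_that("goodness of fit follows the stated conventions", {
  obs <- c(10, 8, 5, 2)
  expect_equal(goodness_of_fit(obs, obs),
               list(r_squared = 1, chi_squared = 0))
  # model predicting the mean: correlation undefined, chi^2 = normalised TSS
  g <- goodness_of_fit(obs, rep(mean(obs), 4))
  expect_true(is.na(g$r_squared))
  expect_equal(g$chi_squared, sum((obs - mean(obs))^2) / obs[1]^2)
  # model misspecification is detectable: mono fit of a biexp series
  fit <- fit_mono(median_truth_series())
  expect_lt(fit$r_squared, 1 - 1e-6)
  expect_gt(fit$chi_squared, 0)
})

test_that("QC filtering passes good fits and excludes noise-dominated blocks", {
  b <- acquisition_b()
  good <- purrr::map(1:6, ~ glance(fit_mono(
    mono_signal(b, 100, runif(1, 0.5e-3, 2e-3)), b_values = b)))
  bad <- withr::with_seed(8, purrr::map(1:6, ~ glance(fit_mono(
    abs(rnorm(5, 0, 5)) + 0.1, b_values = b))))
  fits <- dplyr::bind_rows(c(good, bad)) |>
    dplyr::mutate(voxel_id = dplyr::row_number(),
                  truly_bad = dplyr::row_number() > 6)
  filtered <- qc_filter(fits, qc_thresholds(r2_min = 0.98, chi2_max = 0.05))
  expect_true(all(filtered$qc_pass[!filtered$truly_bad]))
  expect_true(all(!filtered$qc_pass[filtered$truly_bad]))
  # vacuous thresholds keep every converged fit
  vac <- qc_filter(fits, qc_thresholds(r2_min = 0, chi2_max = Inf))
  expect_true(all(vac$qc_pass[vac$converged & !is.na(vac$r_squared)]))
  expect_error(qc_thresholds(r2_min = 1.2), "r2_min")
})
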