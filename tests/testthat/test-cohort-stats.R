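uniform_maps <- function(values, scheme_id = "B0", model = "mono") {
  # minimal maps table: one lesion, one voxel per value, all passing QC
  tibble::tibble(
    voxel_id = seq_along(values), lesion = 1L,
    scheme_id = scheme_id, model = model, n_points = 5L,
    si0 = 1000, adc = ifelse(model == "mono", values, NA_real_),
    d = ifelse(model == "biexp", values, NA_real_),
    d_star = NA_real_, fp = NA_real_,
    r_squared = 1, chi_squared = 0, converged = TRUE, qc_pass = TRUE
  )
}

test_that("ROI summaries reduce QC-passing voxels to the stated statistics", {
  m <- uniform_maps(c(1e-3, 2e-3, 10e-3))
  s <- summarize_roi(m)
  expect_equal(s$median, 2e-3)
  expect_equal(s$mean, 13e-3 / 3, tolerance = 1e-12)
  expect_equal(s$n_voxels_used, 3L)
  # constant field: median = mean = v, sd = 0
  s2 <- summarize_roi(uniform_maps(rep(5e-4, 4)))
  expect_equal(s2$median, 5e-4)
  expect_equal(s2$sd, 0)
  # QC-failing voxels are excluded from the statistics
  m$qc_pass[3] <- FALSE
  s3 <- summarize_roi(m)
  expect_equal(s3$median, 1.5e-3)
  expect_equal(s3$n_voxels_used, 2L)
  # no passing voxels: flagged unusable with a warning
  m$qc_pass <- FALSE
  expect_warning(s4 <- summarize_roi(m), "unusable")
  expect_false(s4$usable)
})

test_that("percent deviation and its reciprocal identity", {
  expect_equal(deviation(1.04, 1.04), 0)
  expect_equal(deviation(1.09, 1.04), 100 * 0.05 / 1.04)
  a <- 1.273; b <- 0.861
  expect_equal((1 + deviation(a, b) / 100) * (1 + deviation(b, a) / 100), 1,
               tolerance = 1e-15)
  expect_warning(d0 <- deviation(1, 0), "zero reference")
  expect_true(is.na(d0))
})

test_that("paired signed-rank test follows the stated conventions", {
  x <- 1:24 / 10
  expect_equal(paired_compare(x, x), 1)
  # constant positive shift, n = 24, no ties: smallest attainable two-sided p
  expect_equal(paired_compare(x + 1, x), 2 / 2^24, tolerance = 1e-12)
  expect_error(paired_compare(1:3, 2:4), class = "ivimsim_config_error")
})

test_that("signed-rank p-values match full enumeration for small n", {
  withr::with_seed(55, {
    for (n in c(6, 9, 12)) {
      for (rep in 1:5) {
        x <- rnorm(n); y <- x + rnorm(n, 0.3, 0.7)
        expect_equal(paired_compare(x, y), oracle_signed_rank_p(x, y),
                     tolerance = 1e-12,
                     info = sprintf("n=%d rep=%d", n, rep))
      }
    }
  })
})

test_that("rank correlation handles monotone, reversed and constant input", {
  x <- c(3, 1, 7, 5, 9, 2)
  expect_equal(rank_correlation(x, exp(x))$rho, 1)
  expect_equal(rank_correlation(x, -x)$rho, -1)
  expect_true(is.na(rank_correlation(rep(1, 6), x)$rho))
})

test_that("deviation matrix honours reciprocity and the zero diagonal", {
  ph <- generate_phantom(phantom_spec(n_lesions = 8, noise_model = "none",
                                      seed = 31))
  maps <- compute_maps(ph, builtin_schemes()[c(2, 7, 14), ]) # B1, B6, biexp
  sums <- summarize_roi(maps)
  dm <- deviation_matrix(sums, c("B1", "B6", "B0_biexp"))
  expect_equal(diag(dm$deviations), rep(0, 3), ignore_attr = TRUE)
  for (i in 1:3) for (j in 1:3) {
    expect_equal((1 + dm$deviations[i, j] / 100) *
                   (1 + dm$deviations[j, i] / 100), 1, tolerance = 1e-12)
  }
  # flow-sensitive ADC_B1 exceeds both the high-b ADC_B6 and the biexp D
  expect_gt(dm$deviations["B1", "B0_biexp"], 0)
  expect_gt(dm$deviations["B1", "B6"], 0)
  # per-lesion aggregation is available and also reciprocal on its diagonal
  dm2 <- deviation_matrix(sums, c("B1", "B6"), method = "per_lesion")
  expect_equal(diag(dm2$deviations), rep(0, 2), ignore_attr = TRUE)
  tid <- tidy(dm)
  expect_equal(nrow(tid), 9L)
})

test_that("cohort report renders descriptives in reporting units", {
  ph <- generate_phantom(phantom_spec(n_lesions = 8, noise_model = "none",
                                      seed = 31))
  maps <- compute_maps(ph)
  # multi-point mono fits on high-perfusion lesions fail strict QC by design
  expect_warning(sums <- summarize_roi(maps), "unusable")
  rep <- cohort_report(sums, maps = maps)
  desc <- rep$descriptives
  expect_equal(sum(desc$parameter == "adc"), 13L)
  expect_equal(sum(desc$parameter == "d"), 1L)
  expect_true(all(desc$unit[desc$parameter %in% c("adc", "d", "d_star")] ==
                    "x10^-3 mm^2/s"))
  expect_true(all(desc$unit[desc$parameter == "fp"] == "dimensionless"))
  # diffusivities are rendered on the 1e-3 scale
  expect_true(all(desc$median[desc$parameter == "adc"] > 0.1 &
                    desc$median[desc$parameter == "adc"] < 10))
  # range brackets the median and is non-degenerate when lesions differ
  expect_true(all(desc$min <= desc$median & desc$median <= desc$max))
  multi <- desc$n_lesions >= 2
  expect_true(all(desc$min[multi] < desc$max[multi]))
  expect_s3_class(rep$correlations, "tbl_df")
  expect_true(!is.null(rep$qc))
  # single scheme: descriptives only, no deviation matrix (B1 is a two-point
  # fit, so it is exact and all lesions survive QC)
  rep1 <- cohort_report(dplyr::filter(sums, scheme_id == "B1"), "B1")
  expect_null(rep1$deviations)
  expect_equal(nrow(rep1$descriptives), 1L)
})

test_that("cohort report writes machine-readable tables", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(n_lesions = 6, noise_model = "none",
                                      seed = 2))
  maps <- compute_maps(ph, builtin_schemes()[c(1, 2, 14), ])
  rep <- suppressWarnings(
    cohort_report(summarize_roi(maps),
                  scheme_ids = c("B0", "B1", "B0_biexp"), maps = maps))
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("descriptives.csv",
                                               "deviations.csv",
                                               "report.json")))))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_true(all(c("descriptives", "deviations") %in% names(js)))
})
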