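test_that("noise scale is definitional and vanishes in the high-SNR limit", {
  expect_equal(1 / noise_spec(20)$snr, 0.05)
  set.seed(1)
  clean <- predict_signal("full", gm_params(), trace_scheme())
  noisy <- add_noise(clean, noise_spec(1e12))
  expect_equal(noisy, clean, tolerance = 1e-9)
  expect_error(noise_spec(0), "positive")
  expect_error(noise_spec(-3), "positive")
})

test_that("rician noise on an empty channel has the Rayleigh mean", {
  set.seed(2)
  sigma <- 0.05
  x <- add_noise(rep(0, 20000), noise_spec(1 / sigma, "rician"))
  expect_equal(mean(x), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("averaging-equivalent SNR follows the square-root law", {
  expect_equal(equivalent_snr(50, 9), 150)
  expect_equal(equivalent_snr(50, 1), 50)
  expect_equal(equivalent_snr(50, 1000), 1581.139, tolerance = 1e-6)
  expect_error(equivalent_snr(50, 0), ">= 1")
})

test_that("the recovery study is seed-deterministic and degenerate cases are flagged", {
  gm <- tissue_truth_table()[1, ]
  a <- run_recovery_study(gm, snr_levels = 30, n_reps = 5, fitters = "simultaneous",
                          seed = 99)
  b <- run_recovery_study(gm, snr_levels = 30, n_reps = 5, fitters = "simultaneous",
                          seed = 99)
  expect_identical(a$summary, b$summary)
  expect_identical(a$estimates, b$estimates)

  one <- run_recovery_study(gm, snr_levels = 30, n_reps = 1, fitters = "simultaneous",
                            seed = 1)
  expect_true(all(is.na(one$summary$sd)))
  expect_true(all(is.nan(one$summary$cv)))
  expect_error(run_recovery_study(gm[0, ], n_reps = 10), "empty")
})

test_that("near-noiseless recovery is essentially exact", {
  rs <- run_recovery_study(tissue_truth_table()[1, ], snr_levels = 1e6,
                           n_reps = 5, fitters = "simultaneous", seed = 3,
                           keep_estimates = FALSE)
  expect_true(all(rs$summary$rel_err < 0.5))
})

test_that("precision improves with SNR for the Gaussian-regime parameters", {
  rs <- run_recovery_study(tissue_truth_table()[1, ], snr_levels = c(20, 60),
                           n_reps = 150, fitters = "simultaneous", seed = 4,
                           keep_estimates = FALSE)
  s <- rs$summary
  for (p in c("d_app", "k_app")) {
    cv20 <- s$cv[s$snr == 20 & s$parameter == p]
    cv60 <- s$cv[s$snr == 60 & s$parameter == p]
    expect_lt(cv60, cv20)
  }
})

test_that("gaussian and rician summaries agree at moderate-to-high SNR", {
  gm <- tissue_truth_table()[1, ]
  g <- run_recovery_study(gm, snr_levels = 40, n_reps = 200,
                          fitters = "simultaneous", noise_model = "gaussian",
                          seed = 8, keep_estimates = FALSE)
  r <- run_recovery_study(gm, snr_levels = 40, n_reps = 200,
                          fitters = "simultaneous", noise_model = "rician",
                          seed = 8, keep_estimates = FALSE)
  m <- dplyr::inner_join(g$summary, r$summary,
                         by = c("tissue", "snr", "fitter", "parameter"),
                         suffix = c("_g", "_r"))
  # means differ by less than 2 Monte-Carlo standard errors of the mean
  mc_se <- m$sd_g / sqrt(m$n_reps_g)
  expect_true(all(abs(m$mean_g - m$mean_r) < 2 * mc_se + 2 * m$sd_r / sqrt(m$n_reps_r)))
})

test_that("paired fitter comparison behaves under null and shift alternatives", {
  set.seed(5)
  a <- tibble::tibble(f = rnorm(50), d_star = rnorm(50), d_app = rnorm(50),
                      k_app = rnorm(50))
  w <- capture_warnings(same <- compare_fitters(a, a))
  expect_length(w, 4)  # one all-zero-differences warning per parameter
  expect_match(w, "zero", all = TRUE)
  expect_true(all(same$p_value == 1))

  shifted <- dplyr::mutate(a, f = f + 10, d_star = d_star + 10,
                           d_app = d_app + 10, k_app = k_app + 10)
  res <- compare_fitters(a, shifted)
  expect_true(all(res$p_value < 0.05))
  expect_error(compare_fitters(a, a[1:10, ]), "equal length")
})

test_that("recovery tables tidy and plot", {
  rs <- run_recovery_study(tissue_truth_table()[1, ], snr_levels = c(20, 40),
                           n_reps = 8, fitters = "simultaneous", seed = 6)
  expect_s3_class(tidy(rs), "tbl_df")
  expect_true(all(c("cv", "bias", "rel_err") %in% names(tidy(rs))))
  expect_s3_class(autoplot(rs), "ggplot")
})
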