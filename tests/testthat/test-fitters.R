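test_that("two-point slope matches the closed-form hand computation", {
  d <- clean_gm_decay()
  # independent oracle: the two-point log slope between b = 500 and b = 1000
  s500 <- d$signal[d$b == 500]
  s1000 <- d$signal[d$b == 1000]
  expected <- (log(s500) - log(s1000)) / 500
  ft <- fit_sequential(d, config = fit_config(two_point = TRUE))
  expect_equal(ft$params[["d_app"]], expected, tolerance = 1e-10)
  # the slope estimate underestimates the generating d_app (kurtosis curvature)
  expect_lt(ft$params[["d_app"]], 1.12e-3)
})

test_that("sequential fit is exact on its own model class", {
  b <- trace_scheme()
  d <- signal_decay(b, predict_signal("mono", list(d_app = 1e-3), b))
  ft <- fit_sequential(d)
  expect_equal(ft$params[["d_app"]], 1e-3, tolerance = 1e-8)
  expect_equal(ft$params[["f"]], 0, tolerance = 1e-8)
  expect_equal(ft$params[["k_app"]], 0, tolerance = 1e-4)
})

test_that("a zero signal inside the slope window fails softly", {
  d <- clean_gm_decay()
  d$signal[d$b == 700] <- 0
  ft <- fit_sequential(d)
  expect_false(ft$converged)
  expect_true(anyNA(ft$params))
})

test_that("simultaneous fit recovers noiseless truths to high accuracy", {
  b <- trace_scheme()
  gm <- gm_params()
  d <- signal_decay(b, predict_signal("full", gm, b))
  ft <- fit_simultaneous(d)
  truth <- unlist(gm)
  expect_true(all(abs(ft$params - truth) / truth < 0.01))
  expect_true(ft$converged)
})

test_that("an f = 0 truth is recovered at the boundary", {
  b <- trace_scheme()
  p <- list(f = 0, d_star = 0.01, d_app = 1.3e-3, k_app = 0.9)
  d <- signal_decay(b, predict_signal("full", p, b))
  ft <- fit_simultaneous(d)
  expect_lte(ft$params[["f"]], 0.005)
  expect_equal(ft$params[["d_app"]], p$d_app, tolerance = 0.01)
})

test_that("out-of-bounds starts are clipped and the result respects the box", {
  d <- clean_gm_decay()
  init <- c(f = 0.9, d_star = 0.2, d_app = 5e-3, k_app = 10)
  ft <- fit_simultaneous(d, init = init)
  bd <- param_bounds()
  expect_true(all(ft$params >= bd$lower & ft$params <= bd$upper))
  expect_true(ft$converged)
})

test_that("both fitters respect the bounds on pure noise", {
  set.seed(42)
  b <- trace_scheme()
  bd <- param_bounds()
  cfg <- fit_config()
  for (i in 1:25) {
    sig <- abs(rnorm(length(b), 0.5, 0.3))
    sig[as.numeric(b) == 0] <- max(sig)
    d <- signal_decay(b, sig)
    for (ft in list(tryCatch(fit_sequential(d, bd, cfg), error = function(e) NULL),
                    tryCatch(fit_simultaneous(d, bd, cfg), error = function(e) NULL))) {
      if (is.null(ft) || anyNA(ft$params)) next
      expect_true(all(ft$params >= bd$lower - 1e-12))
      expect_true(all(ft$params <= bd$upper + 1e-12))
    }
  }
})

test_that("sequential d_app is biased low on kurtotic signals, simultaneous is not", {
  set.seed(7)
  truths <- random_interior_truths(20)
  truths <- truths[truths$k_app > 0.3 & truths$f > 0.02, ]
  b <- trace_scheme()
  for (i in seq_len(nrow(truths))) {
    p <- as.list(truths[i, -1])
    d <- signal_decay(b, predict_signal("full", p, b))
    sq <- fit_sequential(d)
    sm <- fit_simultaneous(d)
    expect_lt(sq$params[["d_app"]], p$d_app)
    expect_equal(sm$params[["d_app"]], p$d_app, tolerance = 0.01)
  }
})

test_that("fits are deterministic given identical inputs", {
  d <- clean_gm_decay()
  set.seed(1)
  noisy <- signal_decay(d$b, add_noise(d$signal, noise_spec(30)))
  a <- fit_simultaneous(noisy)
  b2 <- fit_simultaneous(noisy)
  expect_identical(a$params, b2$params)
  expect_identical(a$rss, b2$rss)
  s1 <- fit_sequential(noisy)
  s2 <- fit_sequential(noisy)
  expect_identical(s1$params, s2$params)
})

test_that("fit preconditions are enforced", {
  b <- b_scheme(c(0, 500, 1000))
  d <- signal_decay(b, c(1, 0.6, 0.4))
  expect_error(fit_sequential(d), "at least 4")
  expect_error(fit_simultaneous(d), "free parameters|spanning")
  d16 <- clean_gm_decay()
  expect_error(fit_sequential(dplyr::rename(d16, bees = b)), "columns")
  flat <- signal_decay(trace_scheme(), rep(1, 16))
  expect_false(fit_simultaneous(flat)$converged)
})

test_that("tidy and glance expose the fit in broom shape", {
  ft <- fit_simultaneous(clean_gm_decay())
  td <- tidy(ft)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("parameter", "estimate", "lower", "upper", "clipped", "free"))
  expect_equal(nrow(td), 4)
  gl <- glance(ft)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("rss", "rmse", "aicc", "converged") %in% names(gl)))
  expect_s3_class(autoplot(ft), "ggplot")
})
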