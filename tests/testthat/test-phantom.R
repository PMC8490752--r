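test_that("mask thresholds follow the rule truth table", {
  fa <- array(c(0.2, 0.30, 0.05, 0.04, 0.29, 0.95, 0.10, 0.5), c(2, 2, 2))
  wm <- array(1L, c(2, 2, 2))
  sp <- split_wm_by_fa(wm, fa)
  expect_equal(as.vector(sp$wm_low_fa), as.integer(c(1, 0, 0, 0, 1, 0, 1, 0)))
  expect_equal(as.vector(sp$wm_high_fa), as.integer(c(0, 1, 0, 0, 0, 1, 0, 1)))

  up <- array(2, c(2, 2, 1))
  ref <- array(0L, c(2, 2, 1))
  ref[1, 1, 1] <- 1L                     # reference mean = 2
  up[2, 1, 1] <- 3.2                     # exactly 1.6x -> included
  up[1, 2, 1] <- 3.1                     # 1.55x -> excluded
  tum <- tumour_from_uptake(up, ref)
  expect_equal(tum[2, 1, 1], 1L)
  expect_equal(tum[1, 2, 1], 0L)
  # uniform map: nothing reaches 1.6x its own mean
  expect_true(all(tumour_from_uptake(array(5, c(2, 2, 1)), ref) == 0L))
  expect_error(tumour_from_uptake(up, array(0L, c(2, 2, 1))), "empty")
})

test_that("overlap resolution applies pathology priority and is idempotent", {
  d <- c(3, 3, 1)
  z <- function() array(0L, d)
  gm <- z(); wl <- z(); wh <- z(); oe <- z(); tu <- z()
  tu[1, 1, 1] <- 1L; oe[1, 1, 1] <- 1L        # tumour beats oedema
  gm[2, 1, 1] <- 1L; wl[2, 1, 1] <- 1L        # ambiguous healthy: dropped
  gm[3, 1, 1] <- 1L                           # clean GM voxel
  oe[1, 2, 1] <- 1L; gm[1, 2, 1] <- 1L        # healthy vs oedema: oedema kept
  res <- resolve_mask_overlaps(mask_set(gm, wl, wh, oe, tu))
  expect_equal(res$tumour[1, 1, 1], 1L)
  expect_equal(res$oedema[1, 1, 1], 0L)
  expect_equal(res$gm[2, 1, 1] + res$wm_low_fa[2, 1, 1], 0L)
  expect_equal(res$gm[3, 1, 1], 1L)
  expect_equal(res$oedema[1, 2, 1], 1L)
  expect_equal(res$gm[1, 2, 1], 0L)

  # pairwise disjoint output
  total <- res$gm + res$wm_low_fa + res$wm_high_fa + res$oedema + res$tumour
  expect_true(all(total <= 1L))
  # idempotent; tumour never loses voxels
  again <- resolve_mask_overlaps(res)
  expect_identical(unclass(again)[1:5], unclass(res)[1:5])
  expect_true(sum(res$tumour) == sum(tu))

  # already-disjoint input is unchanged
  clean <- mask_set(gm = z(), wl, wh, oe = z(), tu)
  expect_identical(unclass(resolve_mask_overlaps(clean))[1:5], unclass(clean)[1:5])
})

test_that("phantom geometry, s0 and seeding behave as configured", {
  cfg <- phantom_config(snr = NULL)
  ph <- generate_phantom(cfg)
  b0 <- ph$dwi$data[, , , 1]
  inside <- ph$masks$gm > 0
  expect_true(all(b0[inside] == 1))          # s0 exactly at b = 0, no noise
  expect_true(all(b0[1:6, 1:6, ] == 0))      # air frame for corner estimation

  # same seed, same data; different seeds differ only through noise
  a <- generate_phantom(phantom_config(snr = 30), seed = 1)
  b <- generate_phantom(phantom_config(snr = 30), seed = 1)
  c2 <- generate_phantom(phantom_config(snr = 30), seed = 2)
  expect_identical(a$dwi$data, b$dwi$data)
  expect_false(identical(a$dwi$data, c2$dwi$data))
  expect_identical(a$truth, c2$truth)

  expect_error(phantom_config(layout = list(GM = list(x = 1:40, y = 1:40, z = 1:4))),
               "every tissue")
})

test_that("corner patches measure the configured SNR", {
  ph <- generate_phantom(phantom_config(snr = 50, noise_model = "rician"), seed = 7)
  corners <- c(ph$dwi$data[1:5, 1:5, , 1], ph$dwi$data[36:40, 1:5, , 1],
               ph$dwi$data[1:5, 36:40, , 1], ph$dwi$data[36:40, 36:40, , 1])
  # signal-free magnitudes are Rayleigh with mean sigma * sqrt(pi/2)
  sigma_hat <- mean(corners) / sqrt(pi / 2)
  expect_equal(1 / sigma_hat, 50, tolerance = 0.1)
})

test_that("noiseless phantom recovery returns the generating table per class", {
  ph <- generate_phantom(phantom_config(snr = NULL))
  truth <- ph$config$truth
  for (i in seq_len(nrow(truth))) {
    m <- switch(truth$tissue[i], "GM" = ph$masks$gm, "WM-lowFA" = ph$masks$wm_low_fa,
                "WM-highFA" = ph$masks$wm_high_fa, "Oedema" = ph$masks$oedema,
                "Tumour" = ph$masks$tumour)
    rf <- fit_roi(ph$dwi, m, models = "full", sequential_full = FALSE)
    est <- rf$fits$full$params
    for (p in c("f", "d_star", "d_app", "k_app")) {
      expect_equal(est[[p]], truth[[p]][i], tolerance = 0.01,
                   label = paste(truth$tissue[i], p))
    }
  }
})

test_that("within-class jitter stays inside the fit bounds", {
  cfg <- phantom_config(snr = NULL, jitter_sd = c(d_app = 2e-4, k_app = 0.2))
  ph <- generate_phantom(cfg, seed = 13)
  bd <- param_bounds()
  d_app_map <- ph$truth$d_app
  vals <- d_app_map[!is.nan(d_app_map)]
  expect_true(all(vals >= bd$lower[["d_app"]] & vals <= bd$upper[["d_app"]]))
  expect_gt(stats::sd(vals), 0)
})
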