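make_noise_dwi <- function(nx = 12, ny = 12, nz = 2, seed = 3, sd = 1, mean = 10) {
  set.seed(seed)
  b <- trace_scheme()
  dwi_volume(array(pmax(rnorm(nx * ny * nz * length(b), mean, sd), 0),
                   c(nx, ny, nz, length(b))), b)
}

test_that("retaining all components reconstructs the input", {
  dwi <- make_noise_dwi()
  out <- denoise_pca(dwi, method = "fixed", value = 16)
  expect_equal(out$dwi$data, dwi$data, tolerance = 1e-10)
  expect_equal(out$report$n_retained, 16)
})

test_that("a noiseless multi-class phantom has low numerical rank", {
  ph <- generate_phantom(phantom_config(snr = NULL))
  out <- denoise_pca(ph$dwi, method = "mp")
  expect_lte(out$report$n_retained, 6)
  expect_equal(out$dwi$data, ph$dwi$data, tolerance = 1e-6)
  expect_true(all(diff(out$report$singular_values) <= 1e-9))
})

test_that("pure-noise volumes are aggressively truncated", {
  dwi <- make_noise_dwi(mean = 0, sd = 1)
  out <- denoise_pca(dwi, method = "mp")
  expect_lte(out$report$n_retained, 3)
  v_in <- var(as.vector(dwi$data))
  resid_var <- var(as.vector(dwi$data - out$dwi$data))
  expect_gt(resid_var, 0.5 * v_in)  # most of the iid noise is removed
})

test_that("PCA denoising is idempotent at a fixed threshold", {
  ph <- generate_phantom(phantom_config(snr = 40), seed = 9)
  tissue <- with(ph$masks, gm | wm_low_fa | wm_high_fa | oedema | tumour)
  once <- denoise_pca(ph$dwi, method = "fixed", value = 6, mask = tissue)
  twice <- denoise_pca(once$dwi, method = "fixed", value = 6, mask = tissue)
  expect_equal(twice$dwi$data, once$dwi$data, tolerance = 1e-8)
})

test_that("denoising requires enough voxels and volumes", {
  b <- b_scheme(c(0, 100))
  expect_error(denoise_pca(dwi_volume(array(1, c(2, 2, 1, 2)), b)), "at least 3")
  b16 <- trace_scheme()
  tiny <- dwi_volume(array(1, c(2, 2, 1, 16)), b16)
  expect_error(denoise_pca(tiny), "fewer voxels")
})

test_that("noise-floor subtraction follows corner arithmetic", {
  b <- trace_scheme()
  # constant image equal to its own floor vanishes
  dwi <- dwi_volume(array(10, c(12, 12, 2, length(b))), b)
  expect_true(all(remove_noise_floor(dwi, 3)$data == 0))

  # object 100 over a floor of 4 ends at 96; floor region clamps at 0
  data <- array(4, c(20, 20, 2, length(b)))
  data[8:13, 8:13, , ] <- 100
  dwi <- dwi_volume(data, b)
  out <- remove_noise_floor(dwi, 5)
  expect_equal(out$data[10, 10, 1, 1], 96)
  expect_equal(out$data[1, 1, 1, 1], 0)
  expect_true(all(out$data >= 0))

  expect_error(remove_noise_floor(dwi, 11), "half")
})

test_that("gaussian smoothing preserves constants, mass and the FWHM relation", {
  b <- trace_scheme()
  dwi <- dwi_volume(array(7, c(8, 8, 4, length(b))), b)
  expect_equal(gaussian_smooth(dwi)$data, dwi$data, tolerance = 1e-12)

  # unit impulse spreads into a normalised kernel
  data <- array(0, c(9, 9, 9, length(b)))
  data[5, 5, 5, ] <- 1
  sm <- gaussian_smooth(dwi_volume(data, b))
  expect_equal(sum(sm$data[, , , 1]), 1, tolerance = 1e-10)
  expect_true(sm$data[5, 5, 5, 1] > sm$data[4, 5, 5, 1])

  # sigma = fwhm / (2 sqrt(2 log 2))
  expect_equal(1.5 / (2 * sqrt(2 * log(2))), 0.63700, tolerance = 1e-4)

  # volume mean is preserved within kernel-truncation tolerance on smooth content
  ph <- generate_phantom(phantom_config(snr = 40), seed = 2)
  sm2 <- gaussian_smooth(ph$dwi)
  m0 <- mean(ph$dwi$data[, , , 1])
  expect_equal(mean(sm2$data[, , , 1]), m0, tolerance = 0.02)
})

test_that("floor subtraction perturbs high-SNR kurtosis less than low-SNR kurtosis", {
  k_shift <- function(snr) {
    ph <- generate_phantom(phantom_config(snr = snr, noise_model = "rician"), seed = 21)
    raw <- fit_roi(ph$dwi, ph$masks$gm, models = "full", sequential_full = FALSE)
    flo <- fit_roi(remove_noise_floor(ph$dwi), ph$masks$gm,
                   models = "full", sequential_full = FALSE)
    abs(flo$fits$full$params[["k_app"]] - raw$fits$full$params[["k_app"]])
  }
  expect_lt(k_shift(60), k_shift(12))
})
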