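#' PCA denoising of a 4-D diffusion volume
#'
#' Recasts the volume as a (voxels x b-volumes) matrix, takes the singular
#' value decomposition of the column-centred matrix, zeroes every component
#' whose singular value falls below a threshold and reconstructs. Three
#' threshold rules are available:
#'
#' * `"mp"` (default): the Marchenko-Pastur bulk edge estimated from the lower
#'   singular-value spectrum — for each candidate signal rank p the noise
#'   variance is the mean of the remaining eigenvalues and the edge is
#'   `sigma^2 * (1 + sqrt((N - p) / M))^2`; the smallest p whose next
#'   eigenvalue sits below the edge is retained.
#' * `"fraction"`: retain components with `sv >= value * sv[1]`.
#' * `"fixed"`: retain exactly `value` components.
#'
#' @param dwi A [dwi_volume()] with at least 3 b-volumes.
#' @param method Threshold rule, see above.
#' @param value Fraction (for `"fraction"`, default 0.05) or component count
#'   (for `"fixed"`).
#' @param mask Optional 3-D array; only voxels with mask > 0 enter (and are
#'   rewritten by) the decomposition.
#'
#' @return List with `dwi` (denoised volume) and `report` (list with
#'   `singular_values`, `n_retained`, `threshold`, `method`).
#' @export
denoise_pca <- function(dwi, method = c("mp", "fraction", "fixed"),
                        value = NULL, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  method <- match.arg(method)
  nvol <- dim(dwi$data)[4]
  if (nvol < 3) stop("PCA denoising needs at least 3 b-volumes", call. = FALSE)
  mat <- matrix(dwi$data, ncol = nvol)
  rows <- if (is.null(mask)) seq_len(nrow(mat)) else which(as.vector(mask > 0))
  x <- mat[rows, , drop = FALSE]
  m <- nrow(x)
  if (m < nvol) stop("fewer voxels (", m, ") than volumes (", nvol, ")", call. = FALSE)

  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  lambda <- sv$d^2 / m

  keep <- switch(method,
    mp = {
      p <- nvol - 1
      zero_floor <- 1e-12 * lambda[1]  # numerical zeros of rank-deficient input
      for (cand in 0:(nvol - 1)) {
        tail_mean <- mean(lambda[(cand + 1):nvol])
        edge <- tail_mean * (1 + sqrt((nvol - cand) / m))^2
        if (lambda[cand + 1] <= max(edge, zero_floor)) {
          p <- cand
          break
        }
      }
      max(p, 1)
    },
    fraction = {
      alpha <- value %||% 0.05
      max(sum(sv$d >= alpha * sv$d[1]), 1)
    },
    fixed = {
      if (is.null(value)) stop("method = 'fixed' needs `value`", call. = FALSE)
      min(max(as.integer(value), 1), nvol)
    }
  )
  threshold <- if (keep < nvol) sv$d[keep + 1] else 0

  d_trunc <- sv$d
  d_trunc[seq_len(nvol) > keep] <- 0
  recon <- sv$u %*% (d_trunc * t(sv$v))
  recon <- sweep(recon, 2, mu, `+`)
  recon[recon < 0] <- 0
  mat[rows, ] <- recon
  out <- dwi
  out$data <- array(mat, dim = dim(dwi$data))
  list(dwi = out,
       report = list(singular_values = sv$d, n_retained = keep,
                     threshold = threshold, method = method))
}

corner_patch_index <- function(nx, ny, corner_size) {
  cs <- corner_size
  xs <- c(seq_len(cs), nx - cs + seq_len(cs))
  ys <- c(seq_len(cs), ny - cs + seq_len(cs))
  list(lo = seq_len(cs), hix = nx - cs + seq_len(cs), hiy = ny - cs + seq_len(cs))
}

#' Noise-floor subtraction from image corners
#'
#' Estimates the magnitude noise floor of each b-volume as the mean signal in
#' the four in-plane corner patches (air in a brain EPI field of view, over
#' all slices), subtracts that scalar from the volume and clamps the result at
#' zero.
#'
#' @param dwi A [dwi_volume()].
#' @param corner_size Side length of each square corner patch in voxels
#'   (default 5).
#'
#' @return A [dwi_volume()] with the floor removed.
#' @export
remove_noise_floor <- function(dwi, corner_size = 5) {
  stopifnot(inherits(dwi, "dwi_volume"))
  d <- dim(dwi$data)
  if (corner_size > floor(min(d[1], d[2]) / 2)) {
    stop("corner_size exceeds half the in-plane matrix", call. = FALSE)
  }
  ix <- corner_patch_index(d[1], d[2], corner_size)
  out <- dwi
  for (v in seq_len(d[4])) {
    vol <- dwi$data[, , , v, drop = FALSE]
    corners <- c(vol[ix$lo, ix$lo, , ], vol[ix$hix, ix$lo, , ],
                 vol[ix$lo, ix$hiy, , ], vol[ix$hix, ix$hiy, , ])
    floor_v <- mean(corners)
    out$data[, , , v] <- pmax(dwi$data[, , , v] - floor_v, 0)
  }
  out
}

gaussian_kernel_1d <- function(fwhm, len) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  h <- (len - 1) / 2
  k <- exp(-((-h):h)^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution along margin `along` with replicate padding
convolve_axis <- function(vol, kern, along) {
  h <- (length(kern) - 1) / 2
  idx_of <- function(i, n) pmin(pmax(i, 1), n)
  n <- dim(vol)[along]
  out <- array(0, dim(vol))
  for (o in -h:h) {
    shifted <- idx_of(seq_len(n) + o, n)
    sl <- switch(along,
                 vol[shifted, , , drop = FALSE],
                 vol[, shifted, , drop = FALSE],
                 vol[, , shifted, drop = FALSE])
    out <- out + kern[o + h + 1] * sl
  }
  out
}

#' Gaussian smoothing of each b-volume
#'
#' Convolves every 3-D volume with a separable, normalised, truncated Gaussian
#' kernel. `sigma = fwhm / (2 * sqrt(2 * log(2)))` (about `fwhm / 2.3548`)
#' voxels.
#'
#' @param dwi A [dwi_volume()].
#' @param fwhm Full width at half maximum in voxels (default 1.5).
#' @param kernel Kernel shape, odd sides (default `c(3, 3, 3)`).
#'
#' @return A smoothed [dwi_volume()].
#' @export
gaussian_smooth <- function(dwi, fwhm = 1.5, kernel = c(3, 3, 3)) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (fwhm <= 0) stop("fwhm must be positive", call. = FALSE)
  if (any(kernel %% 2 != 1)) stop("kernel sides must be odd", call. = FALSE)
  d <- dim(dwi$data)
  if (any(kernel > d[1:3])) stop("kernel does not fit inside the volume", call. = FALSE)
  out <- dwi
  for (v in seq_len(d[4])) {
    vol <- array(dwi$data[, , , v], d[1:3])
    for (ax in 1:3) {
      vol <- convolve_axis(vol, gaussian_kernel_1d(fwhm, kernel[ax]), ax)
    }
    out$data[, , , v] <- vol
  }
  out
}
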