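#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats kmeans quantile sd var median glm binomial coef predict
#'   pchisq pnorm qnorm rnorm runif rbinom cor complete.cases shapiro.test
#'   t.test wilcox.test chisq.test as.formula setNames
#' @importFrom utils head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Mirror (reflect-about-edge-centre) index folding for out-of-range indices.
mirror_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- ((i - 1L) %% p + p) %% p
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

index_axis <- function(arr, idx, axis) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# 1D convolution along one axis of a 3D array with mirror padding.
# `origin` is the kernel tap aligned with the output voxel.
conv_axis <- function(arr, kernel, axis, origin = (length(kernel) + 1L) %/% 2L) {
  dims <- dim(arr)
  n <- dims[axis]
  out <- array(0, dims)
  for (t in seq_along(kernel)) {
    if (kernel[t] == 0) next
    idx <- mirror_idx(seq_len(n) + (t - origin), n)
    out <- out + kernel[t] * index_axis(arr, idx, axis)
  }
  out
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  x <- (-r):r
  w <- exp(-x^2 / (2 * sigma_vox^2))
  w / sum(w)
}

# Separable Gaussian smoothing, sigma in mm, spacing-aware.
gaussian_smooth <- function(arr, sigma_mm, spacing) {
  for (ax in 1:3) {
    arr <- conv_axis(arr, gaussian_kernel(sigma_mm / spacing[ax]), ax)
  }
  arr
}

# Smooth standard-normal random field: white noise blurred with a Gaussian,
# rescaled to unit variance. Used for lobulated phantom boundaries and for
# reader-variability mask perturbation.
smooth_noise_field <- function(dims, sigma_vox = 2) {
  arr <- array(rnorm(prod(dims)), dims)
  for (ax in 1:3) arr <- conv_axis(arr, gaussian_kernel(sigma_vox), ax)
  s <- sd(arr)
  if (s < .Machine$double.eps) return(array(0, dims))
  (arr - mean(arr)) / s
}

# Coiflet-1 analysis filters (6 taps). The high-pass is the quadrature
# mirror of the low-pass; its taps sum to 0 so constant images map to
# (numerically) zero detail sub-bands.
coif1_filters <- function() {
  lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
          0.852572020212255, 0.337897662457809, -0.072732619512854)
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  list(lo = lo / sqrt(2), hi = hi / sqrt(2))
}

#' Derive the filtered image set for feature extraction
#'
#' Produces the 12 intensity image types on which non-shape radiomic
#' features are computed: the original image, the 8 sub-bands of a one-level
#' stationary (undecimated) 3D coiflet-1 wavelet decomposition
#' (`LLL` ... `HHH`, all at original resolution), and scale-normalised
#' Laplacian-of-Gaussian responses at physical scales sigma = 1, 2, 3 mm.
#'
#' @param volume A windowed, resampled `ct_volume`.
#' @param wavelet Logical, include the 8 wavelet sub-bands.
#' @param log_sigmas_mm Numeric vector of LoG scales in mm (may be empty).
#' @return Named list of 3D arrays; names are the filter tags used in
#'   feature names (`original`, `wavelet_LLH`, `log_sigma_2_mm`, ...).
#' @examples
#' v <- ct_volume(array(rnorm(6^3), c(6, 6, 6)), spacing = 1)
#' names(derive_images(v))
#' @export
derive_images <- function(volume, wavelet = TRUE, log_sigmas_mm = c(1, 2, 3)) {
  stopifnot(inherits(volume, "ct_volume"))
  arr <- volume$values
  if (min(dim(arr)) < 4) stop("volume smaller than the filter support (need >= 4 voxels per axis)")
  out <- list(original = arr)

  if (wavelet) {
    f <- coif1_filters()
    for (cx in c("L", "H")) {
      ax_x <- conv_axis(arr, if (cx == "L") f$lo else f$hi, 1)
      for (cy in c("L", "H")) {
        ax_xy <- conv_axis(ax_x, if (cy == "L") f$lo else f$hi, 2)
        for (cz in c("L", "H")) {
          sub <- conv_axis(ax_xy, if (cz == "L") f$lo else f$hi, 3)
          out[[paste0("wavelet_", cx, cy, cz)]] <- sub
        }
      }
    }
  }

  lap_kernels <- lapply(volume$spacing, function(s) c(1, -2, 1) / s^2)
  for (s in log_sigmas_mm) {
    sm <- gaussian_smooth(arr, s, volume$spacing)
    lap <- conv_axis(sm, lap_kernels[[1]], 1) +
      conv_axis(sm, lap_kernels[[2]], 2) +
      conv_axis(sm, lap_kernels[[3]], 3)
    out[[sprintf("log_sigma_%g_mm", s)]] <- s^2 * lap
  }
  out
}
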