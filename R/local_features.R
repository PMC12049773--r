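#' Names of the 19 voxel-level local features
#'
#' First-order statistics of the moving-window intensity sample around each
#' tumor voxel, in the fixed order used by [local_feature_map()]. The
#' histogram features (`entropy`, `uniformity`) use 16 fixed bins spanning
#' the display window `[-125, 175]` HU so that they are comparable across
#' voxels and patients.
#'
#' @return Character vector of length 19.
#' @export
local_feature_names <- function() {
  c("mean", "median", "min", "max", "range", "variance",
    "coefficient_of_variation", "skewness", "kurtosis", "energy",
    "entropy", "uniformity", "rms", "mean_absolute_deviation",
    "interquartile_range", "p10", "p25", "p75", "p90")
}

#' Voxel-wise local feature map
#'
#' For every voxel inside the tumor mask, collects the intensities of a
#' `window^3` neighbourhood (mirror-padded at the image boundary, not masked)
#' and computes 19 first-order statistics, yielding a 19-dimensional feature
#' vector per voxel. These per-voxel vectors are the input to habitat
#' clustering; standardisation happens at clustering time, not here.
#'
#' @param volume A windowed `ct_volume`.
#' @param mask The tumor `mask_volume`, aligned to `volume`.
#' @param window Odd window edge length in voxels (>= 3); default 5.
#' @param entropy_bins Number of fixed histogram bins for entropy and
#'   uniformity; default 16.
#' @param entropy_range Intensity range covered by the histogram bins;
#'   default the display window `c(-125, 175)`.
#' @return A `voxel_feature_map`: list with `vectors` (n_voxels x 19 matrix),
#'   `feature_names`, `voxel_index` (n_voxels x 3 integer matrix of grid
#'   coordinates), `dims`, `spacing`, `origin`, `phase`.
#' @examples
#' v <- ct_volume(array(rnorm(7^3, 50, 10), c(7, 7, 7)), spacing = 1)
#' m <- array(0L, c(7, 7, 7)); m[3:5, 3:5, 3:5] <- 1L
#' fm <- local_feature_map(v, mask_volume(m, spacing = 1))
#' dim(fm$vectors)
#' @export
local_feature_map <- function(volume, mask, window = 5, entropy_bins = 16,
                              entropy_range = c(-125, 175)) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "mask_volume"))
  assert_same_grid(volume, mask)
  if (window < 3 || window %% 2 == 0) stop("`window` must be odd and >= 3")
  vox <- which(mask$labels == 1L, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("tumor mask is empty")

  dims <- dim(volume$values)
  h <- (window - 1L) %/% 2L
  offs <- as.matrix(expand.grid(dx = -h:h, dy = -h:h, dz = -h:h))
  n <- nrow(vox)
  V <- matrix(0, n, nrow(offs))
  for (j in seq_len(nrow(offs))) {
    xi <- mirror_idx(vox[, 1] + offs[j, 1], dims[1])
    yi <- mirror_idx(vox[, 2] + offs[j, 2], dims[2])
    zi <- mirror_idx(vox[, 3] + offs[j, 3], dims[3])
    V[, j] <- volume$values[cbind(xi, yi, zi)]
  }

  m <- nrow(offs)
  mu <- rowMeans(V)
  cent <- V - mu
  m2 <- rowMeans(cent^2)
  m3 <- rowMeans(cent^3)
  m4 <- rowMeans(cent^4)
  s <- sqrt(m2)
  qs <- apply(V, 1, quantile, probs = c(0.1, 0.25, 0.5, 0.75, 0.9),
              names = FALSE, type = 7)
  vmin <- apply(V, 1, min)
  vmax <- apply(V, 1, max)

  # Fixed-bin histogram probabilities for entropy / uniformity.
  bw <- diff(entropy_range) / entropy_bins
  B <- pmin(pmax(floor((V - entropy_range[1]) / bw) + 1, 1), entropy_bins)
  ent <- numeric(n); unif <- numeric(n)
  for (b in seq_len(entropy_bins)) {
    p <- rowSums(B == b) / m
    nz <- p > 0
    ent[nz] <- ent[nz] - p[nz] * log2(p[nz])
    unif <- unif + p^2
  }

  zero_sd <- s < 1e-12
  skew <- ifelse(zero_sd, 0, m3 / s^3)
  kurt <- ifelse(zero_sd, 0, m4 / m2^2)
  cv <- ifelse(abs(mu) < 1e-12 | zero_sd, 0, s / abs(mu))

  F <- cbind(
    mean = mu, median = qs[3, ], min = vmin, max = vmax, range = vmax - vmin,
    variance = m2, coefficient_of_variation = cv, skewness = skew,
    kurtosis = kurt, energy = rowSums(V^2), entropy = ent, uniformity = unif,
    rms = sqrt(rowMeans(V^2)), mean_absolute_deviation = rowMeans(abs(cent)),
    interquartile_range = qs[4, ] - qs[2, ], p10 = qs[1, ], p25 = qs[2, ],
    p75 = qs[4, ], p90 = qs[5, ]
  )
  colnames(F) <- local_feature_names()
  structure(
    list(vectors = F, feature_names = local_feature_names(),
         voxel_index = vox, dims = dims, spacing = volume$spacing,
         origin = volume$origin, phase = volume$phase),
    class = "voxel_feature_map"
  )
}
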