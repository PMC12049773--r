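# First-order (intensity histogram) features of a region sample.
# 18 features; histogram features use the extraction bin width.
first_order_features <- function(x, bin_width, voxel_volume) {
  n <- length(x)
  mu <- mean(x)
  cent <- x - mu
  m2 <- mean(cent^2)
  m3 <- mean(cent^3)
  m4 <- mean(cent^4)
  s <- sqrt(m2)
  qs <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)

  g <- floor((x - min(x)) / bin_width) + 1
  p <- tabulate(g, max(g)) / n
  p <- p[p > 0]

  inner <- x[x >= qs[1] & x <= qs[5]]
  rmad <- if (length(inner) > 0) mean(abs(inner - mean(inner))) else 0

  c(energy = sum(x^2),
    total_energy = voxel_volume * sum(x^2),
    entropy = -sum(p * log2(p)),
    minimum = min(x),
    p10 = qs[1],
    p90 = qs[5],
    maximum = max(x),
    mean = mu,
    median = qs[3],
    interquartile_range = qs[4] - qs[2],
    range = max(x) - min(x),
    mean_absolute_deviation = mean(abs(cent)),
    robust_mean_absolute_deviation = rmad,
    root_mean_squared = sqrt(mean(x^2)),
    skewness = if (s > 1e-12) m3 / s^3 else 0,
    kurtosis = if (s > 1e-12) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2))
}

first_order_names <- function() {
  c("energy", "total_energy", "entropy", "minimum", "p10", "p90", "maximum",
    "mean", "median", "interquartile_range", "range",
    "mean_absolute_deviation", "robust_mean_absolute_deviation",
    "root_mean_squared", "skewness", "kurtosis", "variance", "uniformity")
}

# 14 shape descriptors from the binary mask only (physical units).
# Surface area uses the coarea estimator: the integral of the gradient
# magnitude of the Gaussian-smoothed occupancy, which is unbiased for
# smooth interfaces and avoids the ~1.5x bias of voxel-face counting.
shape_features <- function(mask) {
  sp <- mask$spacing
  voxvol <- prod(sp)
  idx <- which(mask$labels == 1L, arr.ind = TRUE)
  n <- nrow(idx)
  V <- n * voxvol

  A <- surface_area_coarea(mask)
  sphericity <- (36 * pi * V^2)^(1 / 3) / A

  phys <- sweep(idx, 2, sp, "*")
  if (n > 1) {
    ev <- eigen(stats::cov(phys), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])

  max_diam <- max_diameter(mask, phys)

  c(volume_mm3 = V,
    surface_area_mm2 = A,
    surface_volume_ratio = A / V,
    sphericity = sphericity,
    compactness1 = V / (sqrt(pi) * A^1.5),
    compactness2 = 36 * pi * V^2 / A^3,
    spherical_disproportion = 1 / sphericity,
    maximum_3d_diameter = max_diam,
    major_axis_length = major,
    minor_axis_length = minor,
    least_axis_length = least,
    elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0,
    equivalent_sphere_diameter = 2 * (3 * V / (4 * pi))^(1 / 3))
}

shape_names <- function() {
  c("volume_mm3", "surface_area_mm2", "surface_volume_ratio", "sphericity",
    "compactness1", "compactness2", "spherical_disproportion",
    "maximum_3d_diameter", "major_axis_length", "minor_axis_length",
    "least_axis_length", "elongation", "flatness",
    "equivalent_sphere_diameter")
}

surface_area_coarea <- function(mask, sigma_vox = 1) {
  m <- array(as.numeric(mask$labels), dim(mask$labels))
  k <- gaussian_kernel(sigma_vox)
  for (ax in 1:3) m <- conv_axis(m, k, ax)
  sp <- mask$spacing
  gx <- conv_axis(m, c(1, 0, -1) / (2 * sp[1]), 1)
  gy <- conv_axis(m, c(1, 0, -1) / (2 * sp[2]), 2)
  gz <- conv_axis(m, c(1, 0, -1) / (2 * sp[3]), 3)
  sum(sqrt(gx^2 + gy^2 + gz^2)) * prod(sp)
}

# Shift a label array by `off` voxels along `ax`; out-of-image positions
# read as background (0).
shift_zero <- function(lab, ax, off) {
  dims <- dim(lab)
  n <- dims[ax]
  idx <- pmin(pmax(seq_len(n) + off, 1L), n)
  out <- index_axis(lab, idx, ax)
  oob <- which(seq_len(n) + off < 1L | seq_len(n) + off > n)
  if (length(oob)) {
    if (ax == 1) out[oob, , ] <- 0L
    else if (ax == 2) out[, oob, ] <- 0L
    else out[, , oob] <- 0L
  }
  out
}

# Largest pairwise distance between boundary voxel centres. Boundary =
# mask voxels with a face-adjacent background (or image-edge) voxel.
# Deterministically subsampled above 2500 boundary voxels.
max_diameter <- function(mask, phys_all) {
  lab <- mask$labels
  inside <- lab == 1L
  boundary <- inside &
    (shift_zero(lab, 1, -1) == 0L | shift_zero(lab, 1, 1) == 0L |
     shift_zero(lab, 2, -1) == 0L | shift_zero(lab, 2, 1) == 0L |
     shift_zero(lab, 3, -1) == 0L | shift_zero(lab, 3, 1) == 0L)
  pts <- which(boundary, arr.ind = TRUE)
  if (nrow(pts) == 0) pts <- which(inside, arr.ind = TRUE)
  phys <- sweep(pts, 2, mask$spacing, "*")
  if (nrow(phys) > 2500) {
    phys <- phys[seq(1, nrow(phys), length.out = 2500), , drop = FALSE]
  }
  if (nrow(phys) == 1) return(0)
  d2max <- 0
  chunk <- 500L
  for (s in seq(1, nrow(phys), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(phys))
    block <- phys[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(phys^2), "+") -
      2 * block %*% t(phys)
    d2max <- max(d2max, max(d2))
  }
  sqrt(max(d2max, 0))
}
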