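# Texture feature families on a discretized region grid.
#
# All families operate on `G`: an integer array over the region bounding
# box, holding the discretized gray level (1..Ng) inside the region and NA
# outside, with 26-connectivity realised through the 13 unique 3D offsets
# and their negatives.

offsets_13 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), ]
  # keep one representative per +/- pair
  keep <- apply(offs, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  offs[keep, , drop = FALSE]
}

# Discretize region intensities with a fixed bin width (gray level 1..Ng).
discretize_region <- function(values, mask, bin_width) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  sub_v <- values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_m <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub_v) <- hi - lo + 1L
  dim(sub_m) <- hi - lo + 1L
  x <- sub_v[sub_m == 1L]
  g <- as.integer(floor((x - min(x)) / bin_width) + 1)
  G <- array(NA_integer_, dim(sub_m))
  G[sub_m == 1L] <- g
  list(G = G, Ng = max(g), n = length(g))
}

# In-bounds source indices along one axis for an offset d (empty if the
# offset exceeds the axis length).
axis_range <- function(n, d) {
  lo <- max(1L, 1L - d)
  hi <- min(n, n - d)
  if (lo > hi) integer(0) else lo:hi
}

# Aligned sub-array pair for an offset; returns in-bounds index ranges.
shift_pairs <- function(G, d) {
  dims <- dim(G)
  src <- lapply(1:3, function(a) axis_range(dims[a], d[a]))
  dst <- lapply(1:3, function(a) src[[a]] + d[a])
  a_vals <- G[src[[1]], src[[2]], src[[3]], drop = FALSE]
  b_vals <- G[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
  ok <- !is.na(a_vals) & !is.na(b_vals)
  list(a = a_vals[ok], b = b_vals[ok])
}

# ---- GLCM ------------------------------------------------------------------

glcm_matrix <- function(G, Ng) {
  P <- matrix(0, Ng, Ng)
  for (i in seq_len(nrow(offsets_13()))) {
    d <- offsets_13()[i, ]
    pr <- shift_pairs(G, d)
    if (length(pr$a) == 0) next
    tab <- table(factor(pr$a, seq_len(Ng)), factor(pr$b, seq_len(Ng)))
    P <- P + tab + t(tab)
  }
  if (sum(P) == 0) P[1, 1] <- 1
  P / sum(P)
}

glcm_features <- function(G, Ng) {
  P <- glcm_matrix(G, Ng)
  i <- row(P); j <- col(P)
  eps <- 2.2e-16
  px <- rowSums(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)

  kd <- abs(i - j)
  p_diff <- vapply(0:(Ng - 1), function(k) sum(P[kd == k]), 0)
  ks <- i + j
  p_sum <- vapply(2:(2 * Ng), function(k) sum(P[ks == k]), 0)
  da <- sum((0:(Ng - 1)) * p_diff)

  H <- -sum(P * log2(P + eps))
  pxy <- outer(px, px)
  HXY1 <- -sum(P * log2(pxy + eps))
  HXY2 <- -sum(pxy * log2(pxy + eps))
  HX <- -sum(px * log2(px + eps))
  imc1 <- if (HX > eps) (H - HXY1) / HX else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - H)), 0))

  corr <- if (sig2 > eps) (sum(i * j * P) - mu^2) / sig2 else 1

  c(autocorrelation = sum(i * j * P),
    joint_average = mu,
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(p_diff * log2(p_diff + eps)),
    difference_variance = sum(((0:(Ng - 1)) - da)^2 * p_diff),
    joint_energy = sum(P^2),
    joint_entropy = H,
    imc1 = imc1,
    imc2 = imc2,
    idm = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + ((i - j) / Ng)^2)),
    id = sum(P / (1 + kd)),
    idn = sum(P / (1 + kd / Ng)),
    inverse_variance = sum(P[kd > 0] / kd[kd > 0]^2),
    maximum_probability = max(P),
    sum_entropy = -sum(p_sum * log2(p_sum + eps)),
    sum_squares = sig2)
}

# ---- GLRLM -----------------------------------------------------------------

glrlm_runs <- function(G) {
  coords <- which(!is.na(G), arr.ind = TRUE)
  gvals <- G[coords]
  offs <- offsets_13()
  C <- max(dim(G)) + 2L
  glev_all <- integer(0); len_all <- integer(0)
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    a <- which(d != 0)[1]
    t <- coords[, a] * sign(d[a])
    start <- coords - outer(t, d)
    key <- (start[, 1] + C) + (start[, 2] + C) * (3 * C) +
      (start[, 3] + C) * (3 * C)^2
    o <- order(key, t)
    k <- key[o]; tt <- t[o]; gg <- gvals[o]
    n <- length(k)
    newrun <- c(TRUE, k[-1] != k[-n] | tt[-1] != tt[-n] + 1L | gg[-1] != gg[-n])
    runid <- cumsum(newrun)
    len_all <- c(len_all, tabulate(runid))
    glev_all <- c(glev_all, gg[newrun])
  }
  list(g = glev_all, len = len_all)
}

glrlm_features <- function(G, Ng, n_voxels) {
  runs <- glrlm_runs(G)
  Lmax <- max(runs$len)
  P <- as.matrix(table(factor(runs$g, seq_len(Ng)),
                       factor(runs$len, seq_len(Lmax))))
  srlm_features(P, Ng, n_voxels * nrow(offsets_13()), prefix = "run",
                size_name = "length")
}

# Shared run-length / size-zone feature arithmetic on a (gray x size)
# count matrix. `n_total` is the denominator of the percentage feature.
srlm_features <- function(P, Ng, n_total, prefix, size_name) {
  Nr <- sum(P)
  p <- P / Nr
  i <- row(P); j <- col(P)
  eps <- 2.2e-16
  pg <- rowSums(P); pl <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)

  vals <- c(
    sum(P / col(P)^2) / Nr,                 # short/small emphasis
    sum(P * col(P)^2) / Nr,                 # long/large emphasis
    sum(pg^2) / Nr,                         # gray level non-uniformity
    sum(pg^2) / Nr^2,                       # ... normalized
    sum(pl^2) / Nr,                         # size non-uniformity
    sum(pl^2) / Nr^2,                       # ... normalized
    Nr / n_total,                           # percentage
    sum((i - mu_i)^2 * p),                  # gray level variance
    sum((j - mu_j)^2 * p),                  # size variance
    -sum(p * log2(p + eps)),                # entropy
    sum(P / row(P)^2) / Nr,                 # low gray level emphasis
    sum(P * row(P)^2) / Nr,                 # high gray level emphasis
    sum(P / (row(P)^2 * col(P)^2)) / Nr,    # short+low
    sum(P * row(P)^2 / col(P)^2) / Nr,      # short+high
    sum(P * col(P)^2 / row(P)^2) / Nr,      # long+low
    sum(P * (row(P) * col(P))^2) / Nr       # long+high
  )
  short_tag <- if (prefix == "run") "short_run" else "small_area"
  long_tag <- if (prefix == "run") "long_run" else "large_area"
  names(vals) <- c(
    paste0(short_tag, "_emphasis"), paste0(long_tag, "_emphasis"),
    "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
    paste0(prefix, "_", size_name, "_nonuniformity"),
    paste0(prefix, "_", size_name, "_nonuniformity_normalized"),
    paste0(prefix, "_percentage"), "gray_level_variance",
    paste0(prefix, "_variance"), paste0(prefix, "_entropy"),
    "low_gray_level_emphasis", "high_gray_level_emphasis",
    paste0(short_tag, "_low_gray_level_emphasis"),
    paste0(short_tag, "_high_gray_level_emphasis"),
    paste0(long_tag, "_low_gray_level_emphasis"),
    paste0(long_tag, "_high_gray_level_emphasis"))
  vals
}

# ---- GLSZM -----------------------------------------------------------------

glszm_features <- function(G, Ng, n_voxels) {
  coords <- which(!is.na(G), arr.ind = TRUE)
  gvals <- G[coords]
  id_arr <- array(0L, dim(G))
  id_arr[coords] <- seq_len(nrow(coords))
  edges <- list()
  offs <- offsets_13()
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    dims <- dim(G)
    src <- lapply(1:3, function(a) axis_range(dims[a], d[a]))
    dst <- lapply(1:3, function(a) src[[a]] + d[a])
    ga <- G[src[[1]], src[[2]], src[[3]], drop = FALSE]
    gb <- G[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    ia <- id_arr[src[[1]], src[[2]], src[[3]], drop = FALSE]
    ib <- id_arr[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    ok <- !is.na(ga) & !is.na(gb) & ga == gb
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(ia[ok], ib[ok])
  }
  n <- nrow(coords)
  if (length(edges) > 0) {
    el <- do.call(rbind, edges)
    gr <- igraph::make_empty_graph(n, directed = FALSE)
    gr <- igraph::add_edges(gr, t(el))
    memb <- igraph::components(gr)$membership
  } else {
    memb <- seq_len(n)
  }
  zone_size <- as.integer(table(memb))
  zone_gray <- gvals[!duplicated(memb)][order(unique(memb))]
  # order zones consistently: gray of each component id 1..max
  zone_gray <- vapply(seq_along(zone_size),
                      function(z) gvals[match(z, memb)], 0L)
  Smax <- max(zone_size)
  P <- as.matrix(table(factor(zone_gray, seq_len(Ng)),
                       factor(zone_size, seq_len(Smax))))
  srlm_features(P, Ng, n_voxels, prefix = "zone", size_name = "size")
}

# ---- GLDM ------------------------------------------------------------------

gldm_features <- function(G, Ng, alpha = 0) {
  offs <- offsets_13()
  dep <- array(0L, dim(G))
  for (r in seq_len(nrow(offs))) {
    for (sgn in c(1, -1)) {
      d <- sgn * offs[r, ]
      dims <- dim(G)
      src <- lapply(1:3, function(a) {
        if (d[a] >= 0) seq_len(dims[a] - d[a]) else seq(1 - d[a], dims[a])
      })
      dst <- lapply(1:3, function(a) src[[a]] + d[a])
      ga <- G[src[[1]], src[[2]], src[[3]], drop = FALSE]
      gb <- G[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
      ok <- !is.na(ga) & !is.na(gb) & abs(ga - gb) <= alpha
      dep[src[[1]], src[[2]], src[[3]]] <-
        as.vector(dep[src[[1]], src[[2]], src[[3]], drop = FALSE]) +
        as.integer(ok)
    }
  }
  in_reg <- !is.na(G)
  g <- G[in_reg]
  dcount <- dep[in_reg] + 1L
  Dmax <- max(dcount)
  P <- as.matrix(table(factor(g, seq_len(Ng)), factor(dcount, seq_len(Dmax))))
  Nz <- sum(P)
  p <- P / Nz
  i <- row(P); j <- col(P)
  eps <- 2.2e-16
  pg <- rowSums(P); pd <- colSums(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(small_dependence_emphasis = sum(P / col(P)^2) / Nz,
    large_dependence_emphasis = sum(P * col(P)^2) / Nz,
    gray_level_nonuniformity = sum(pg^2) / Nz,
    dependence_nonuniformity = sum(pd^2) / Nz,
    dependence_nonuniformity_normalized = sum(pd^2) / Nz^2,
    gray_level_variance = sum((i - mu_i)^2 * p),
    dependence_variance = sum((j - mu_j)^2 * p),
    dependence_entropy = -sum(p * log2(p + eps)),
    low_gray_level_emphasis = sum(P / row(P)^2) / Nz,
    high_gray_level_emphasis = sum(P * row(P)^2) / Nz,
    small_dependence_low_gray_level_emphasis = sum(P / (row(P)^2 * col(P)^2)) / Nz,
    small_dependence_high_gray_level_emphasis = sum(P * row(P)^2 / col(P)^2) / Nz,
    large_dependence_low_gray_level_emphasis = sum(P * col(P)^2 / row(P)^2) / Nz,
    large_dependence_high_gray_level_emphasis = sum(P * (row(P) * col(P))^2) / Nz)
}

# ---- NGTDM -----------------------------------------------------------------

ngtdm_features <- function(G, Ng) {
  offs <- offsets_13()
  nb_sum <- array(0, dim(G))
  nb_cnt <- array(0L, dim(G))
  Gz <- G; Gz[is.na(Gz)] <- 0L
  in_reg <- !is.na(G)
  for (r in seq_len(nrow(offs))) {
    for (sgn in c(1, -1)) {
      d <- sgn * offs[r, ]
      dims <- dim(G)
      src <- lapply(1:3, function(a) {
        if (d[a] >= 0) seq_len(dims[a] - d[a]) else seq(1 - d[a], dims[a])
      })
      dst <- lapply(1:3, function(a) src[[a]] + d[a])
      gb <- Gz[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
      mb <- in_reg[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
      gb[!mb] <- 0L
      nb_sum[src[[1]], src[[2]], src[[3]]] <-
        as.vector(nb_sum[src[[1]], src[[2]], src[[3]], drop = FALSE]) +
        as.vector(gb)
      nb_cnt[src[[1]], src[[2]], src[[3]]] <-
        as.vector(nb_cnt[src[[1]], src[[2]], src[[3]], drop = FALSE]) +
        as.integer(mb)
    }
  }
  use <- in_reg & nb_cnt > 0
  g <- G[use]
  avg <- nb_sum[use] / nb_cnt[use]
  N <- length(g)
  s <- vapply(seq_len(Ng), function(lev) sum(abs(g[g == lev] - avg[g == lev])), 0)
  n_i <- tabulate(g, Ng)
  p_i <- n_i / N
  present <- which(n_i > 0)
  Ngp <- length(present)

  coarse_den <- sum(p_i * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6

  if (Ngp > 1) {
    pij <- outer(p_i[present], p_i[present])
    dij2 <- outer(present, present, function(a, b) (a - b)^2)
    contrast <- sum(pij * dij2) / (Ngp * (Ngp - 1)) * sum(s) / N
    busy_den <- sum(abs(outer(present * p_i[present], present * p_i[present], "-")))
    busyness <- if (busy_den > 0) sum(p_i * s) / busy_den else 0
    cplx <- 0; stren <- 0
    for (ii in present) for (jj in present) {
      if (ii == jj) next
      cplx <- cplx + abs(ii - jj) * (p_i[ii] * s[ii] + p_i[jj] * s[jj]) /
        (p_i[ii] + p_i[jj])
      stren <- stren + (p_i[ii] + p_i[jj]) * (ii - jj)^2
    }
    complexity <- cplx / N
    strength <- if (sum(s) > 0) stren / sum(s) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}
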