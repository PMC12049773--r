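test_that("local feature maps are 19-dimensional with documented degeneracies", {
  p <- tiny_phantom(seed = 2, grid = 20, radius = 7)
  fm <- local_feature_map(window_hu(p$phases[[1]]), p$tumor_mask_reader1)
  expect_equal(ncol(fm$vectors), 19L)
  expect_equal(fm$feature_names, local_feature_names())
  expect_equal(nrow(fm$vectors), sum(p$tumor_mask_reader1$labels))
  expect_true(all(is.finite(fm$vectors)))

  # constant volume: entropy and variance vanish everywhere
  v <- ct_volume(array(50, c(9, 9, 9)), spacing = 1)
  m <- ball_mask(3, 9)
  fmc <- local_feature_map(v, m)
  expect_true(all(fmc$vectors[, "entropy"] == 0))
  expect_true(all(fmc$vectors[, "variance"] == 0))
  expect_true(all(fmc$vectors[, "uniformity"] == 1))

  # single in-mask voxel still yields one vector from the padded window
  m1 <- mask_volume(array(c(rep(0L, 40), 1L, rep(0L, 9^3 - 41)), c(9, 9, 9)),
                    spacing = 1)
  v1 <- ct_volume(array(rnorm(9^3), c(9, 9, 9)), spacing = 1)
  fm1 <- local_feature_map(v1, m1)
  expect_equal(dim(fm1$vectors), c(1L, 19L))
})

test_that("window mean matches a brute-force mirrored-window average", {
  set.seed(8)
  v <- ct_volume(array(rnorm(14^3, 20, 30), c(14, 14, 14)), spacing = 1)
  m <- ball_mask(5, 14)
  fm <- local_feature_map(v, m)
  mirror <- function(i, n) {
    p <- 2 * n - 2
    j <- ((i - 1) %% p + p) %% p
    ifelse(j >= n, p - j, j) + 1
  }
  idx <- sample(nrow(fm$vectors), 10)
  for (r in idx) {
    vox <- fm$voxel_index[r, ]
    vals <- numeric(0)
    for (dx in -2:2) for (dy in -2:2) for (dz in -2:2) {
      vals <- c(vals, v$values[mirror(vox[1] + dx, 14),
                               mirror(vox[2] + dy, 14),
                               mirror(vox[3] + dz, 14)])
    }
    expect_equal(fm$vectors[r, "mean"], mean(vals), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(fm$vectors[r, "p25"],
                 unname(quantile(vals, 0.25)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("the CH index equals the from-scratch scatter decomposition", {
  # two obvious pairs-of-3: hand-computable scatter ratio
  x <- cbind(c(0, 0.1, -0.1, 10, 10.1, 9.9), rep(0, 6))
  lab <- c(1, 1, 1, 2, 2, 2)
  tot <- sum(sweep(x, 2, colMeans(x))^2)
  W <- sum(sweep(x[1:3, ], 2, colMeans(x[1:3, ]))^2) +
    sum(sweep(x[4:6, ], 2, colMeans(x[4:6, ]))^2)
  B <- tot - W
  expect_equal(ch_index(x, lab), (B / 1) / (W / 4), tolerance = 1e-10)

  # random instances: CH equals total-minus-within decomposition to 1e-8
  for (s in 1:5) {
    set.seed(s)
    n <- sample(20:200, 1)
    xs <- matrix(rnorm(n * 4), n, 4)
    ls <- sample(1:4, n, replace = TRUE)
    k <- length(unique(ls))
    if (k < 2) next
    tot <- sum(sweep(xs, 2, colMeans(xs))^2)
    W <- sum(vapply(unique(ls), function(cl) {
      xi <- xs[ls == cl, , drop = FALSE]
      sum(sweep(xi, 2, colMeans(xi))^2)
    }, 0))
    expect_equal(ch_index(xs, ls), ((tot - W) / (k - 1)) / (W / (n - k)),
                 tolerance = 1e-8)
  }

  # degenerate: as many clusters as points -> undefined
  expect_true(is.na(ch_index(matrix(rnorm(6), 3, 2), 1:3)))
})

test_that("CH selection recovers the planted habitat count and excludes tiny maps", {
  maps <- list()
  for (i in 1:4) {
    p <- tiny_phantom(seed = 30 + i, n_phases = 2, grid = 22, radius = 8)
    for (ph in names(p$phases)) {
      maps[[length(maps) + 1]] <-
        local_feature_map(window_hu(p$phases[[ph]]), p$tumor_mask_reader1)
    }
  }
  sel <- select_k_by_ch(maps, k_range = 3:6, seed = 4)
  expect_equal(sel$k_star, 3L)
  expect_true(all(sel$per_phase$k_star == 3L))
  expect_true(all(is.finite(sel$scores$ch)))

  # a map with too few voxels is excluded with a warning
  small <- maps[[1]]
  keep <- 1:5
  small$vectors <- small$vectors[keep, , drop = FALSE]
  small$voxel_index <- small$voxel_index[keep, , drop = FALSE]
  expect_warning(select_k_by_ch(c(maps[1], list(small)), k_range = 3:6,
                                seed = 4), "excluded")
})

test_that("habitat clustering recovers a planted two-cluster VOI deterministically", {
  # planted partition: two intensity populations, far apart
  set.seed(9)
  arr <- array(rnorm(24^3, 0, 5), c(24, 24, 24))
  arr[13:24, , ] <- arr[13:24, , ] + 100
  v <- ct_volume(arr, spacing = 1)
  m <- mask_volume(array(1L, c(24, 24, 24)), spacing = 1)
  truth <- array(1L, c(24, 24, 24)); truth[13:24, , ] <- 2L
  fm <- local_feature_map(v, m)
  hm <- cluster_habitats(fm, 2, seed = 3)
  agree <- max(mean(hm$labels == truth), mean(hm$labels == 3L - truth))
  expect_gte(agree, 0.95)

  hm2 <- cluster_habitats(fm, 2, seed = 3)
  expect_identical(hm$labels, hm2$labels)

  # labels ordered by ascending windowed-intensity mean
  expect_lt(mean(v$values[hm$labels == 1L]), mean(v$values[hm$labels == 2L]))

  # identical feature vectors: collapses to a single label
  vc <- ct_volume(array(7, c(9, 9, 9)), spacing = 1)
  fmc <- local_feature_map(vc, ball_mask(3, 9))
  hc <- cluster_habitats(fmc, 3, seed = 1)
  expect_equal(hc$k, 1L)
})

test_that("knn gap filling dissolves tiny clusters and preserves the partition", {
  p <- tiny_phantom(seed = 14, grid = 20, radius = 7)
  fm <- local_feature_map(window_hu(p$phases[[1]]), p$tumor_mask_reader1)
  hm <- cluster_habitats(fm, 3, seed = 2)

  # no cluster below threshold: identity
  expect_identical(knn_fill(hm, min_voxels = 1)$labels, hm$labels)

  # stray voxel: plant a single label-3 voxel inside a label-1 block
  lab <- array(0L, c(9, 9, 9))
  lab[3:7, 3:7, 3:7] <- 1L
  lab[5, 5, 5] <- 3L
  lab[2, 2, 2] <- 2L; lab[2, 2, 3] <- 2L; lab[2, 3, 2] <- 2L
  lab[3, 2, 2] <- 2L; lab[2, 3, 3] <- 2L
  hm3 <- habitatct:::new_habitat_map(lab, 3L, "plain", c(1, 1, 1), c(0, 0, 0))
  filled <- knn_fill(hm3, min_voxels = 3, k_neighbors = 5)
  expect_equal(filled$labels[5, 5, 5], 1L)
  # partition invariant: same voxel set, consecutive labels, none empty
  expect_true(all((filled$labels > 0) == (lab > 0)))
  expect_setequal(unique(filled$labels[filled$labels > 0]), seq_len(filled$k))

  # equidistant tie breaks toward the smaller label
  lab2 <- array(0L, c(7, 7, 7))
  lab2[2, 4, 4] <- 2L; lab2[2, 4, 5] <- 2L; lab2[2, 5, 4] <- 2L
  lab2[6, 4, 4] <- 3L; lab2[6, 4, 5] <- 3L; lab2[6, 5, 4] <- 3L
  lab2[4, 4, 4] <- 1L  # lone voxel equidistant to both clusters
  hm4 <- habitatct:::new_habitat_map(lab2, 3L, "plain", c(1, 1, 1), c(0, 0, 0))
  filled2 <- knn_fill(hm4, min_voxels = 2, k_neighbors = 2)
  # lone label-1 voxel dissolved; its 2 nearest neighbours are one voxel of
  # each surviving cluster (equal distance) -> vote ties -> smaller label
  expect_equal(filled2$labels[4, 4, 4], 1L)  # relabelled: 2 -> 1 after renumbering

  # everything below threshold is an error
  expect_error(knn_fill(hm3, min_voxels = 1000), "degenerate")
})
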