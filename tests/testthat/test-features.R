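test_that("the filtered image set has 12 members with the expected responses", {
  p <- tiny_phantom(seed = 4, grid = 20, radius = 7)
  imgs <- derive_images(window_hu(p$phases[[1]]))
  expect_length(imgs, 12L)
  expect_equal(sum(grepl("^wavelet_", names(imgs))), 8L)
  expect_equal(sum(grepl("^log_sigma_", names(imgs))), 3L)

  # constant image: detail sub-bands and LoG responses vanish
  const <- ct_volume(array(80, c(10, 10, 10)), spacing = 1)
  imc <- derive_images(const)
  for (nm in names(imc)) {
    if (nm == "original" || nm == "wavelet_LLL") next
    expect_lt(max(abs(imc[[nm]])), 1e-8)
  }
  expect_equal(imc$wavelet_LLL, imc$original, tolerance = 1e-8)

  # impulse: LoG response matches the closed-form scale-normalised kernel
  arr <- array(0, c(21, 21, 21)); arr[11, 11, 11] <- 1
  imp <- derive_images(ct_volume(arr, spacing = 1), wavelet = FALSE,
                       log_sigmas_mm = 2)[["log_sigma_2_mm"]]
  s <- 2
  log_kernel <- function(x, y, z) {
    r2 <- x^2 + y^2 + z^2
    s^2 * (r2 / s^4 - 3 / s^2) * exp(-r2 / (2 * s^2)) / (2 * pi * s^2)^1.5
  }
  for (off in list(c(0, 0, 0), c(2, 0, 0), c(0, 0, 4))) {
    got <- imp[11 + off[1], 11 + off[2], 11 + off[3]]
    want <- log_kernel(off[1], off[2], off[3])
    expect_equal(got, want, tolerance = 0.1)
  }

  expect_error(derive_images(ct_volume(array(0, c(2, 2, 2)), 1)), "support")
})

test_that("first-order features match direct formulas", {
  set.seed(12)
  x <- rnorm(400, 30, 40)
  fo <- habitatct:::first_order_features(x, bin_width = 25, voxel_volume = 2)
  expect_length(fo, 18L)
  expect_equal(fo[["mean"]], mean(x))
  expect_equal(fo[["variance"]], mean((x - mean(x))^2))
  expect_equal(fo[["energy"]], sum(x^2))
  expect_equal(fo[["total_energy"]], 2 * sum(x^2))
  expect_equal(fo[["root_mean_squared"]], sqrt(mean(x^2)))
  expect_equal(fo[["p10"]], unname(quantile(x, 0.1)))
  g <- floor((x - min(x)) / 25) + 1
  pb <- tabulate(g) / length(x); pb <- pb[pb > 0]
  expect_equal(fo[["entropy"]], -sum(pb * log2(pb)))
  expect_equal(fo[["uniformity"]], sum(pb^2))
})

test_that("GLCM counts equal hand enumeration on a toy grid", {
  # 4x4x1 grid with 2 gray levels
  vals <- array(c(1, 1, 2, 2,
                  1, 1, 2, 2,
                  1, 2, 1, 2,
                  2, 2, 2, 1) * 25, c(4, 4, 1))
  mask <- array(1L, c(4, 4, 1))
  dg <- habitatct:::discretize_region(vals, mask, bin_width = 25)
  expect_equal(dg$Ng, 2L)
  P <- habitatct:::glcm_matrix(dg$G, dg$Ng)

  # brute force: every ordered neighbour pair within 26-connectivity
  cnt <- matrix(0, 2, 2)
  coords <- which(mask == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(coords))) for (j in seq_len(nrow(coords))) {
    if (i == j) next
    d <- coords[j, ] - coords[i, ]
    if (all(abs(d) <= 1)) {
      cnt[dg$G[coords[i, , drop = FALSE]], dg$G[coords[j, , drop = FALSE]]] <-
        cnt[dg$G[coords[i, , drop = FALSE]], dg$G[coords[j, , drop = FALSE]]] + 1
    }
  }
  expect_equal(P, cnt / sum(cnt), ignore_attr = TRUE, tolerance = 1e-12)

  feats <- habitatct:::glcm_features(dg$G, dg$Ng)
  i <- row(cnt); j <- col(cnt); pn <- cnt / sum(cnt)
  expect_equal(feats[["contrast"]], sum((i - j)^2 * pn))
  expect_equal(feats[["joint_entropy"]],
               -sum(pn[pn > 0] * log2(pn[pn > 0])), tolerance = 1e-6)
})

test_that("the full region vector honours the printed inventory", {
  p <- tiny_phantom(seed = 5, grid = 20, radius = 7)
  imgs <- derive_images(window_hu(p$phases[[1]]))
  v <- extract_region_features(imgs, p$tumor_mask_reader1)
  expect_length(v, 1106L)
  expect_equal(sum(grepl("__first_order__", names(v))), 216L)
  expect_equal(sum(grepl("__shape__", names(v))), 14L)
  expect_equal(sum(grepl("__glcm__", names(v))), 22L * 12L)
  expect_true(all(is.finite(v)))
  # names agree with the declared template
  expect_identical(names(v),
                   habitatct:::feature_name_template(extraction_config(),
                                                     names(imgs)))

  # constant region: zero first-order entropy, zero GLCM contrast
  const <- list(original = array(12, c(10, 10, 10)))
  m <- ball_mask(3.5, 10)
  vc <- extract_region_features(const, m,
                                extraction_config(wavelet = FALSE,
                                                  log_sigmas_mm = NULL))
  expect_equal(vc[["original__first_order__entropy"]], 0)
  expect_equal(vc[["original__glcm__contrast"]], 0)

  # sub-2-voxel regions are flagged as degenerate
  m1 <- mask_volume(array(c(1L, rep(0L, 999)), c(10, 10, 10)), 1)
  expect_error(extract_region_features(const, m1), class = "habitatct_degenerate_region")
})

test_that("a digital ball approaches sphericity 1 and axis-permutation invariance holds", {
  m <- ball_mask(9, 24, spacing = 1)
  sh <- habitatct:::shape_features(m)
  expect_lt(abs(sh[["sphericity"]] - 1), 0.05)
  expect_equal(sh[["volume_mm3"]], sum(m$labels))
  expect_lt(abs(sh[["surface_area_mm2"]] - 4 * pi * 9^2) / (4 * pi * 9^2), 0.05)
  expect_lt(abs(sh[["maximum_3d_diameter"]] - 18) / 18, 0.1)
  expect_equal(sh[["elongation"]], 1, tolerance = 0.05)

  # permuting the axes of an isotropic region leaves the vector unchanged
  set.seed(3)
  arr <- array(rnorm(14^3, 50, 20), c(14, 14, 14))
  mm <- ball_mask(5, 14)
  cfg <- extraction_config(wavelet = FALSE, log_sigmas_mm = NULL)
  v1 <- extract_region_features(list(original = arr), mm, cfg)
  v2 <- extract_region_features(list(original = aperm(arr, c(2, 3, 1))),
                                mask_volume(aperm(mm$labels, c(2, 3, 1)), 1),
                                cfg)
  expect_equal(v1[grepl("first_order", names(v1))],
               v2[grepl("first_order", names(v2))], tolerance = 1e-10)
  expect_equal(v1[grepl("shape", names(v1))],
               v2[grepl("shape", names(v2))], tolerance = 1e-6)
  expect_equal(v1[grepl("glcm|glrlm|glszm|gldm|ngtdm", names(v1))],
               v2[grepl("glcm|glrlm|glszm|gldm|ngtdm", names(v2))],
               tolerance = 1e-10)
})

test_that("cohort tables have the documented widths and impute degenerate habitats", {
  pats <- list(P1 = tiny_phantom(seed = 21, grid = 18, radius = 6.5),
               P2 = tiny_phantom(seed = 22, grid = 18, radius = 6.5))
  rings <- lapply(pats, function(p) list(ring2 = dilate_ring(p$tumor_mask_reader1, 2)))
  habs <- lapply(pats, function(p) {
    fm <- local_feature_map(window_hu(p$phases[[1]]), p$tumor_mask_reader1)
    knn_fill(cluster_habitats(fm, 3, seed = 1))
  })
  cfg <- extraction_config(wavelet = FALSE, log_sigmas_mm = NULL)
  # 1 filter -> 14 + 91 = 105 features per region
  tabs <- build_feature_tables(pats, habitats = habs, rings = rings,
                               config = cfg)
  expect_equal(ncol(tabs$radiomics) - 1L, 105L)
  expect_equal(ncol(tabs$peri$ring2) - 1L, 105L)
  expect_equal(ncol(tabs$ith) - 1L, 3L * 105L)
  expect_equal(nrow(tabs$ith), 2L)

  # a habitat map with a missing subregion triggers cohort-median imputation
  habs2 <- habs
  lab <- habs2$P1$labels
  lab[lab == 3L] <- 2L
  habs2$P1 <- habitatct:::new_habitat_map(lab, 2L, "plain",
                                          habs2$P1$spacing, habs2$P1$origin)
  expect_message(
    tabs2 <- build_feature_tables(pats, habitats = habs2, config = cfg,
                                  tables = "ith"),
    "imputing")
  expect_false(anyNA(tabs2$ith))
  expect_equal(ncol(tabs2$ith) - 1L, 315L)

  expect_error(build_feature_tables(pats, config = cfg, tables = "ith"),
               "habitats")
})
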