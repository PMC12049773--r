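#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion,
#' `CH = (B / (k - 1)) / (W / (n - k))`, where `B` and `W` are the traces of
#' the between- and within-cluster scatter matrices. Used to select the
#' habitat count.
#'
#' @param x Numeric matrix (observations x features).
#' @param labels Integer cluster assignment of each row.
#' @return The CH score (scalar); `NA` if undefined (`k < 2` or `k >= n`).
#' @export
ch_index <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  g_mean <- colMeans(x)
  W <- 0; B <- 0
  for (cl in unique(labels)) {
    xi <- x[labels == cl, , drop = FALSE]
    ci <- colMeans(xi)
    W <- W + sum(sweep(xi, 2, ci)^2)
    B <- B + nrow(xi) * sum((ci - g_mean)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# z-score columns using their own mean/sd; zero-variance columns map to 0.
zscore_cols <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s < 1e-12] <- 1
  sweep(sweep(x, 2, mu), 2, s, "/")
}

run_kmeans <- function(x, k, seed, nstart = 10, iter_max = 300) {
  with_seed(seed, {
    fit <- tryCatch(
      kmeans(x, centers = k, nstart = nstart, iter.max = iter_max),
      error = function(e) kmeans(x, centers = k, nstart = nstart,
                                 iter.max = iter_max, algorithm = "Lloyd")
    )
    fit
  })
}

#' Cluster tumor voxels into habitats
#'
#' Runs K-means (multiple restarts) on the z-scored per-voxel local feature
#' vectors of one patient/phase and returns an integer habitat map. Labels
#' are renumbered `1..k` by ascending cluster mean of the windowed-intensity
#' `mean` feature, so label 1 is always the least-enhancing (e.g. necrotic)
#' habitat and label semantics are consistent across patients.
#'
#' @param map A `voxel_feature_map` from [local_feature_map()].
#' @param k Number of habitats.
#' @param seed Integer seed; the clustering is deterministic given the seed.
#' @param nstart Number of random restarts (default 10).
#' @return A `habitat_map`: integer label grid (0 outside the tumor), with
#'   fields `k`, `phase`, `spacing`, `origin`.
#' @export
cluster_habitats <- function(map, k, seed = 1, nstart = 10) {
  stopifnot(inherits(map, "voxel_feature_map"))
  n <- nrow(map$vectors)
  if (n <= k) stop("need more voxels than clusters")
  z <- zscore_cols(map$vectors)
  if (all(abs(z) < 1e-12)) {
    lab <- rep(1L, n)
    k_eff <- 1L
  } else {
    fit <- run_kmeans(z, k, seed)
    lab <- fit$cluster
    k_eff <- k
  }
  # Consistent semantics: order labels by mean windowed intensity.
  mean_feat <- map$vectors[, "mean"]
  ord <- order(vapply(seq_len(k_eff),
                      function(cl) mean(mean_feat[lab == cl]), 0))
  relab <- integer(k_eff); relab[ord] <- seq_len(k_eff)
  lab <- relab[lab]

  labels <- array(0L, map$dims)
  labels[map$voxel_index] <- lab
  new_habitat_map(labels, k_eff, map$phase, map$spacing, map$origin)
}

new_habitat_map <- function(labels, k, phase, spacing, origin) {
  structure(list(labels = labels, k = as.integer(k), phase = phase,
                 spacing = spacing, origin = origin),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("<habitat_map> k = %d, %s voxels, sizes: %s\n", x$k,
              paste(dim(x$labels), collapse = "x"),
              paste(tabulate(x$labels[x$labels > 0], x$k), collapse = ", ")))
  invisible(x)
}

#' Select the habitat count by the Calinski-Harabasz criterion
#'
#' For every patient/phase feature map and every candidate `k`, clusters the
#' z-scored voxel vectors and records the CH score; the selected `k_star` is
#' the argmax of the mean CH across patients, per phase. When phases
#' disagree, the argmax of the overall (all-phase) mean is used.
#'
#' @param maps List of `voxel_feature_map` objects (any mix of patients and
#'   phases).
#' @param k_range Candidate cluster counts; default `3:10`.
#' @param seed Integer seed.
#' @param nstart Restarts per K-means run.
#' @return A `cluster_selection`: list with `scores` (tibble: map id, phase,
#'   k, ch), `per_phase` (tibble: phase, k_star), and `k_star`.
#' @export
select_k_by_ch <- function(maps, k_range = 3:10, seed = 1, nstart = 10) {
  stopifnot(length(maps) >= 1)
  rows <- list()
  for (i in seq_along(maps)) {
    map <- maps[[i]]
    n <- nrow(map$vectors)
    if (n <= max(k_range)) {
      warning(sprintf("map %d has %d voxels (<= max k); excluded", i, n))
      next
    }
    z <- zscore_cols(map$vectors)
    for (k in k_range) {
      fit <- run_kmeans(z, k, seed + 1000L * k + i)
      ch <- ch_index(z, fit$cluster)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        map_id = i, phase = map$phase, k = k, ch = ch)
    }
  }
  if (length(rows) == 0) stop("no map had enough voxels for CH selection")
  scores <- dplyr::bind_rows(rows)

  per_phase <- scores |>
    dplyr::group_by(.data$phase, .data$k) |>
    dplyr::summarise(mean_ch = mean(.data$ch, na.rm = TRUE), .groups = "drop_last") |>
    dplyr::slice_max(.data$mean_ch, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(phase = "phase", k_star = "k")

  if (length(unique(per_phase$k_star)) == 1) {
    k_star <- per_phase$k_star[1]
  } else {
    overall <- scores |>
      dplyr::group_by(.data$k) |>
      dplyr::summarise(mean_ch = mean(.data$ch, na.rm = TRUE))
    k_star <- overall$k[which.max(overall$mean_ch)]
  }
  structure(list(scores = scores, per_phase = per_phase,
                 k_star = as.integer(k_star), k_range = k_range),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("<cluster_selection> k_star = %d over k in {%s}\n", x$k_star,
              paste(range(x$k_range), collapse = "..")))
  print(x$per_phase)
  invisible(x)
}

#' Dissolve tiny habitat clusters and fill label gaps
#'
#' Clusters smaller than `min_voxels` are dissolved; their voxels (and any
#' unlabeled in-mask voxels) are reassigned to the majority label among
#' their `k_neighbors` nearest labeled voxels in physical distance, ties
#' broken toward the smaller label index. Remaining labels are renumbered
#' consecutively so the output still partitions the tumor mask.
#'
#' @param habitat A `habitat_map`.
#' @param min_voxels Minimum cluster size kept; default 5.
#' @param k_neighbors Neighbour count for the majority vote; default 5.
#' @return A `habitat_map` whose labels partition the same voxel set.
#' @export
knn_fill <- function(habitat, min_voxels = 5, k_neighbors = 5) {
  stopifnot(inherits(habitat, "habitat_map"))
  lab <- habitat$labels
  in_mask <- lab > 0L
  sizes <- tabulate(lab[in_mask], habitat$k)
  keep <- which(sizes >= min_voxels)
  if (length(keep) == 0) stop("all clusters fall below `min_voxels`; clustering is degenerate")

  dissolve <- lab > 0L & !(lab %in% keep)
  if (any(dissolve)) {
    src <- which(in_mask & !dissolve, arr.ind = TRUE)
    dst <- which(dissolve, arr.ind = TRUE)
    src_lab <- lab[src]
    sp <- habitat$spacing
    src_phys <- sweep(src, 2, sp, "*")
    dst_phys <- sweep(dst, 2, sp, "*")
    for (i in seq_len(nrow(dst))) {
      d2 <- colSums((t(src_phys) - dst_phys[i, ])^2)
      nn <- order(d2)[seq_len(min(k_neighbors, length(d2)))]
      votes <- table(src_lab[nn])
      # which.max on a table returns the first (smallest label) maximum.
      lab[dst[i, 1], dst[i, 2], dst[i, 3]] <-
        as.integer(names(votes)[which.max(votes)])
    }
  }
  present <- sort(unique(lab[lab > 0L]))
  relab <- integer(max(present)); relab[present] <- seq_along(present)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  new_habitat_map(lab, length(present), habitat$phase, habitat$spacing,
                  habitat$origin)
}

# Extract one habitat subregion as a binary mask.
habitat_submask <- function(habitat, label) {
  mask_volume(array(as.integer(habitat$labels == label), dim(habitat$labels)),
              spacing = habitat$spacing, origin = habitat$origin)
}
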