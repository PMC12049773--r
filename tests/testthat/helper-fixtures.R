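# Small fixtures built in code; kept cheap so the suite stays desk-scale.

tiny_phantom <- function(seed = 1, grade = "low", n_phases = 1, grid = 24,
                         spacing = 2, radius = 8.5, ...) {
  generate_phantom(
    phantom_config(grid_shape = rep(grid, 3), spacing_mm = spacing,
                   tumor_radius_mm = radius, n_phases = n_phases,
                   seed = seed, ...),
    grade = grade)
}

# digital ball: voxels whose centre lies within r_vox voxels of the grid centre
ball_mask <- function(r_vox, n, spacing = 1) {
  ax <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  mask_volume(array(as.integer(d2 <= r_vox^2), c(n, n, n)), spacing = spacing)
}

rand_table <- function(n, p, seed = 1, prefix = "f") {
  x <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  colnames(x) <- paste0(prefix, seq_len(p))
  tibble::as_tibble(x)
}

# labels from a logistic model on the first columns of `tab`
planted_labels <- function(tab, beta, seed = 1, intercept = -0.5) {
  x <- as.matrix(tab)[, seq_along(beta), drop = FALSE]
  withr::with_seed(seed, rbinom(nrow(x), 1, stats::plogis(intercept + x %*% beta)))
}
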