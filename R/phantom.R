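#' Phantom configuration
#'
#' Parameters of the single-tumor multi-phase CT phantom: a soft-tissue body
#' ellipsoid containing a lobulated, roughly spherical tumor partitioned
#' into three concentric-but-blobby habitats (1 = hypoenhancing/necrotic
#' core, 2 = intermediate, 3 = enhancing rim), plus a peritumoral
#' enhancement gradient that decays with distance from the tumor surface.
#'
#' Default intensities emulate a hypervascular renal tumor across the four
#' contrast phases (non-contrast, corticomedullary, parenchymal, excretory):
#' strong rim enhancement in the corticomedullary phase, washout later, and
#' a core that stays near water density throughout. High-grade tumors get a
#' larger necrotic-core fraction (`+core_fraction_boost`) and rougher
#' texture (`texture_multiplier` on the per-habitat noise SD); tumor size is
#' not grade-dependent, so the grade signal is carried by habitat
#' composition and texture rather than volume.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param spacing_mm Voxel size in mm (scalar or length-3).
#' @param n_phases Number of contrast phases generated (1-4); default 4.
#' @param tumor_radius_mm Mean tumor radius in mm.
#' @param habitat_fractions Volume fractions of habitats 1-3 (core,
#'   intermediate, rim) for a low-grade tumor; must sum to 1.
#' @param habitat_means_hu `n_phases x 3` matrix of mean HU per phase and
#'   habitat (columns = habitats 1-3).
#' @param habitat_texture_sd Length-3 noise SD (HU) per habitat.
#' @param rim_gradient_hu_per_mm Slope of the peritumoral enhancement added
#'   to body voxels within 5 mm of the tumor surface.
#' @param body_hu Mean body soft-tissue HU per phase.
#' @param body_noise_sd Body noise SD in HU.
#' @param lobulation Relative amplitude of the random low-order angular
#'   perturbation of the tumor radius.
#' @param reader2_perturb_mm Boundary displacement scale of the simulated
#'   second reader's mask.
#' @param core_fraction_boost Added to the core fraction for high grade.
#' @param texture_multiplier Texture SD multiplier for high grade.
#' @param patient_effects Between-patient random-effect scales, the
#'   biological/technical variability that keeps any fixed grade effect
#'   from being perfectly separable: `global_offset_sd` (HU, a common
#'   intensity offset across the whole body, e.g. calibration/enhancement
#'   differences), `habitat_mean_sd` (HU, independent per-habitat mean
#'   jitter), `fraction_logit_sd` (multiplicative log-normal jitter of the
#'   habitat volume fractions before renormalisation), `texture_sd_lognorm`
#'   (log-normal jitter of the texture SDs).
#' @param seed Integer seed; the phantom is a pure function of the config.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(40, 40, 40),
                           spacing_mm = c(1.5, 1.5, 1.5),
                           n_phases = 4,
                           tumor_radius_mm = 12,
                           habitat_fractions = c(0.2, 0.3, 0.5),
                           habitat_means_hu = default_habitat_means(),
                           habitat_texture_sd = c(8, 12, 12),
                           rim_gradient_hu_per_mm = 8,
                           body_hu = c(40, 70, 90, 75),
                           body_noise_sd = 8,
                           lobulation = 0.08,
                           reader2_perturb_mm = 1,
                           core_fraction_boost = 0.15,
                           texture_multiplier = 1.5,
                           patient_effects = list(global_offset_sd = 10,
                                                  habitat_mean_sd = 8,
                                                  fraction_logit_sd = 0.25,
                                                  texture_sd_lognorm = 0.2),
                           seed = 1) {
  spacing_mm <- if (length(spacing_mm) == 1) rep(spacing_mm, 3) else spacing_mm
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  if (n_phases < 1 || n_phases > 4) stop("n_phases must be in 1..4")
  if (abs(sum(habitat_fractions) - 1) > 1e-9 || any(habitat_fractions < 0)) {
    stop("habitat_fractions must be nonnegative and sum to 1")
  }
  habitat_means_hu <- as.matrix(habitat_means_hu)
  stopifnot(ncol(habitat_means_hu) == 3, nrow(habitat_means_hu) >= n_phases)
  structure(
    list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
         n_phases = as.integer(n_phases), tumor_radius_mm = tumor_radius_mm,
         habitat_fractions = habitat_fractions,
         habitat_means_hu = habitat_means_hu,
         habitat_texture_sd = habitat_texture_sd,
         rim_gradient_hu_per_mm = rim_gradient_hu_per_mm,
         body_hu = body_hu, body_noise_sd = body_noise_sd,
         lobulation = lobulation, reader2_perturb_mm = reader2_perturb_mm,
         core_fraction_boost = core_fraction_boost,
         texture_multiplier = texture_multiplier,
         patient_effects = patient_effects, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Rows: plain, cortical, parenchymal, excretory. Columns: habitats 1-3
# (core, intermediate, rim). Hypervascular rim, near-water core.
default_habitat_means <- function() {
  rbind(plain       = c(20, 35, 40),
        cortical    = c(25, 80, 120),
        parenchymal = c(30, 70, 100),
        excretory   = c(30, 60, 80))
}

#' Generate one synthetic multi-phase CT patient
#'
#' Builds the phantom described by [phantom_config()] for one patient:
#' `n_phases` co-registered `ct_volume`s, two reader tumor masks (the second
#' obtained by [perturb_mask()]), and the ground-truth `habitat_map`.
#' Intensities outside the body are air (-1000 HU). Deterministic given the
#' config seed.
#'
#' @param config A `phantom_config`.
#' @param grade `"low"` or `"high"` (or 0/1).
#' @param patient_id Identifier string.
#' @return A `synthetic_patient` list: `patient_id`, `phases` (named list of
#'   `ct_volume`), `tumor_mask_reader1`, `tumor_mask_reader2`,
#'   `habitat_truth`, `grade`.
#' @examples
#' p <- generate_phantom(phantom_config(grid_shape = c(24, 24, 24),
#'                                      spacing_mm = 2, tumor_radius_mm = 8,
#'                                      n_phases = 1), grade = "low")
#' table(p$habitat_truth$labels[p$habitat_truth$labels > 0])
#' @export
generate_phantom <- function(config, grade = "low", patient_id = "P001") {
  stopifnot(inherits(config, "phantom_config"))
  grade <- normalize_grade(grade)
  dims <- config$grid_shape
  sp <- config$spacing_mm
  half_extent <- dims * sp / 2
  if (config$tumor_radius_mm <= 0) stop("tumor_radius_mm must be > 0 (empty tumor mask)")
  if (config$tumor_radius_mm * (1 + config$lobulation + 0.05) >= min(half_extent)) {
    stop("tumor does not fit inside the grid; enlarge grid_shape or shrink tumor_radius_mm")
  }

  with_seed(config$seed, {
    ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - (dims[a] + 1) / 2)) * sp[a])
    X <- array(ax[[1]], dims)
    Y <- array(rep(ax[[2]], each = dims[1]), dims)
    Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)

    body_semi <- half_extent * 0.95
    body <- (X / body_semi[1])^2 + (Y / body_semi[2])^2 + (Z / body_semi[3])^2 <= 1

    r <- sqrt(X^2 + Y^2 + Z^2)
    eps <- .Machine$double.eps
    ux <- X / pmax(r, eps); uy <- Y / pmax(r, eps); uz <- Z / pmax(r, eps)
    # Low-order angular perturbation -> lobulated boundary.
    a <- rnorm(8)
    g <- a[1] * ux + a[2] * uy + a[3] * uz + a[4] * ux * uy + a[5] * ux * uz +
      a[6] * uy * uz + a[7] * (ux^2 - uy^2) + a[8] * (2 * uz^2 - ux^2 - uy^2) / 2
    g <- g / max(abs(range(g)), 1)
    R_dir <- config$tumor_radius_mm * (1 + config$lobulation * g)
    tumor <- r <= R_dir & body
    if (!any(tumor)) stop("tumor mask is empty at this resolution")

    # Patient-level random effects: no two patients of a grade are
    # statistically identical.
    pe <- config$patient_effects
    offset_hu <- rnorm(1, sd = pe$global_offset_sd)
    hab_jitter <- rnorm(3, sd = pe$habitat_mean_sd)
    tex_jitter <- exp(rnorm(1, sd = pe$texture_sd_lognorm))
    frac_jitter <- exp(rnorm(3, sd = pe$fraction_logit_sd))

    # Habitat partition: normalized radius + smooth blob noise, thresholded
    # at volume-fraction radii (core innermost).
    frac <- config$habitat_fractions
    if (grade == "high") {
      f1 <- min(frac[1] + config$core_fraction_boost, 0.9)
      rest <- frac[2:3] * (1 - f1) / max(sum(frac[2:3]), eps)
      frac <- c(f1, rest)
    }
    frac <- frac * frac_jitter
    frac <- frac / sum(frac)
    u <- r / R_dir + 0.06 * smooth_noise_field(dims, sigma_vox = 2)
    t1 <- frac[1]^(1 / 3)
    t2 <- (frac[1] + frac[2])^(1 / 3)
    hab <- array(0L, dims)
    hab[tumor] <- ifelse(u[tumor] < t1, 1L, ifelse(u[tumor] < t2, 2L, 3L))
    if (length(unique(hab[tumor])) < 3) {
      u0 <- r / R_dir
      hab[tumor] <- ifelse(u0[tumor] < t1, 1L, ifelse(u0[tumor] < t2, 2L, 3L))
    }

    # Peritumoral enhancement gradient, decaying over 5 mm from the surface.
    d_surface <- pmax(r - R_dir, 0)
    rim_boost <- config$rim_gradient_hu_per_mm * pmax(5 - d_surface, 0) *
      (!tumor) * body

    tex_sd <- config$habitat_texture_sd * tex_jitter
    if (grade == "high") tex_sd <- tex_sd * config$texture_multiplier
    phases <- list()
    for (ph in seq_len(config$n_phases)) {
      vol <- array(-1000, dims)
      vol[body] <- config$body_hu[ph] + offset_hu +
        rnorm(sum(body), sd = config$body_noise_sd)
      vol <- vol + rim_boost * (ph > 1)  # no contrast boost on the plain phase
      for (h in 1:3) {
        idx <- hab == h
        vol[idx] <- config$habitat_means_hu[ph, h] + offset_hu + hab_jitter[h] +
          rnorm(sum(idx), sd = tex_sd[h])
      }
      phases[[ct_phases()[ph]]] <- ct_volume(vol, spacing = sp, phase = ct_phases()[ph])
    }

    mask1 <- mask_volume(array(as.integer(tumor), dims), spacing = sp)
    mask2 <- perturb_mask(mask1, config$reader2_perturb_mm,
                          seed = config$seed + 77003L)
    structure(
      list(patient_id = patient_id, phases = phases,
           tumor_mask_reader1 = mask1, tumor_mask_reader2 = mask2,
           habitat_truth = new_habitat_map(hab, 3L, "all", sp, c(0, 0, 0)),
           grade = grade),
      class = "synthetic_patient"
    )
  })
}

normalize_grade <- function(grade) {
  if (is.numeric(grade)) grade <- ifelse(grade > 0, "high", "low")
  match.arg(grade, c("low", "high"))
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> %s, grade %s, %d phase(s), %d tumor voxels\n",
              x$patient_id, x$grade, length(x$phases),
              sum(x$tumor_mask_reader1$labels)))
  invisible(x)
}

#' Randomly perturb a mask boundary
#'
#' Simulates inter-reader segmentation variability: the mask is re-thresholded
#' at `signed_distance <= magnitude_mm * eta`, where `eta` is a smooth
#' standard-normal random field, producing correlated boundary erosion and
#' dilation with displacement scale `magnitude_mm`. Magnitude 0 returns the
#' input unchanged; the Dice overlap with the input decreases as the
#' magnitude grows. If a draw empties the mask the magnitude is halved and
#' redrawn (3 attempts) before failing.
#'
#' @param mask A nonempty `mask_volume`.
#' @param magnitude_mm Displacement scale in mm (>= 0).
#' @param seed Integer seed.
#' @return A `mask_volume` on the same grid.
#' @export
perturb_mask <- function(mask, magnitude_mm, seed = 1) {
  stopifnot(inherits(mask, "mask_volume"))
  if (sum(mask$labels) == 0) stop("mask is empty")
  if (magnitude_mm < 0) stop("magnitude_mm must be >= 0")
  if (magnitude_mm == 0) return(mask)
  sdist <- distance_transform(mask, signed = TRUE)
  with_seed(seed, {
    mag <- magnitude_mm
    for (attempt in 1:4) {
      eta <- smooth_noise_field(dim(mask$labels), sigma_vox = 2)
      new_lab <- (sdist <= mag * eta)
      out <- mask_volume(array(as.integer(new_lab), dim(mask$labels)),
                         spacing = mask$spacing, origin = mask$origin)
      # a boundary perturbation must keep the bulk of the mask; an empty or
      # nearly-disjoint result means the magnitude dwarfs the mask
      if (any(new_lab) && dice(mask, out) > 0.2) return(out)
      mag <- mag / 2
    }
    stop("perturbation destroyed the mask even after reducing the magnitude; ",
         "use a smaller `magnitude_mm` relative to the mask size")
  })
}

#' Dice overlap of two masks
#'
#' @param a,b `mask_volume`s on the same grid.
#' @return Dice coefficient between 0 and 1.
#' @export
dice <- function(a, b) {
  assert_same_grid(a, b)
  inter <- sum(a$labels & b$labels)
  2 * inter / (sum(a$labels) + sum(b$labels))
}
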