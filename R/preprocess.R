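#' Resample a volume to a fixed physical resolution
#'
#' All inputs are conformed to a common isotropic grid before any
#' millimetre-defined operation (peritumoral dilation radii, 3D texture
#' kernels). Intensity volumes are interpolated with a separable natural
#' cubic spline along each axis; masks use nearest-neighbour lookup so they
#' remain strictly binary. The resampled grid covers the same physical
#' extent as the input to within one voxel.
#'
#' @param volume A `ct_volume` or `mask_volume`.
#' @param target_spacing_mm Numeric length-3 (or scalar), the output voxel
#'   size in mm; default 1 mm isotropic.
#' @return An object of the same class as `volume` on the new grid.
#' @examples
#' v <- ct_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 5))
#' r <- resample_fixed(v, c(1, 1, 1))
#' dim(r$values)
#' @export
resample_fixed <- function(volume, target_spacing_mm = c(1, 1, 1)) {
  target <- as.numeric(target_spacing_mm)
  if (length(target) == 1) target <- rep(target, 3)
  if (any(!is.finite(target)) || any(target <= 0)) {
    stop("target spacing must be finite and strictly positive")
  }
  is_mask <- inherits(volume, "mask_volume")
  arr <- if (is_mask) volume$labels else volume$values
  old_sp <- volume$spacing
  dims <- dim(arr)
  if (all(abs(old_sp - target) < 1e-9)) return(volume)

  new_dims <- pmax(1L, as.integer(round(dims * old_sp / target)))
  for (ax in 1:3) {
    if (new_dims[ax] == dims[ax] && abs(old_sp[ax] - target[ax]) < 1e-9) next
    arr <- resample_axis(arr, ax, old_sp[ax], new_dims[ax], target[ax],
                         nearest = is_mask)
  }
  if (is_mask) {
    mask_volume(arr, spacing = target, origin = volume$origin)
  } else {
    ct_volume(arr, spacing = target, origin = volume$origin,
              phase = volume$phase)
  }
}

# Resample one axis. Voxel-center convention: center of voxel i sits at
# (i - 1) * spacing. Nearest: index lookup; smooth: natural cubic spline.
resample_axis <- function(arr, axis, old_spacing, new_n, new_spacing,
                          nearest = FALSE) {
  dims <- dim(arr)
  old_n <- dims[axis]
  new_x <- (seq_len(new_n) - 1) * new_spacing
  old_x <- (seq_len(old_n) - 1) * old_spacing

  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = old_n)
  if (nearest) {
    idx <- pmin(pmax(round(new_x / old_spacing) + 1, 1), old_n)
    out <- m[idx, , drop = FALSE]
  } else if (old_n == 1) {
    out <- m[rep(1L, new_n), , drop = FALSE]
  } else {
    out <- apply(m, 2, function(y) {
      stats::spline(old_x, y, xout = pmin(pmax(new_x, old_x[1]), old_x[old_n]),
                    method = "natural")$y
    })
    out <- matrix(out, nrow = new_n)
  }
  new_dims <- dims
  new_dims[axis] <- new_n
  aperm(array(out, new_dims[perm]), order(perm))
}

#' Clip intensities to a display window
#'
#' Applies the HU display window used throughout the pipeline: values are
#' clipped to `[level - width/2, level + width/2]`, i.e. `[-125, 175]` HU at
#' the default width 300 / level 25. The operation is idempotent.
#'
#' @param volume A `ct_volume`.
#' @param window_width Window width in HU (> 0); default 300.
#' @param window_level Window level (center) in HU; default 25.
#' @return A `ct_volume` with clipped intensities.
#' @examples
#' v <- ct_volume(array(c(-1000, 500, 25, 0), c(1, 2, 2)), spacing = 1)
#' range(window_hu(v)$values)
#' @export
window_hu <- function(volume, window_width = 300, window_level = 25) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!is.finite(window_width) || window_width <= 0) {
    stop("`window_width` must be positive")
  }
  lo <- window_level - window_width / 2
  hi <- window_level + window_width / 2
  volume$values <- pmin(pmax(volume$values, lo), hi)
  volume
}
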