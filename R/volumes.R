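#' CT volume objects
#'
#' A `ct_volume` is a 3D scalar grid in Hounsfield units (HU) together with
#' its physical voxel spacing (mm), origin (mm) and acquisition phase. A
#' `mask_volume` is a binary label grid aligned to the same physical grid
#' (tumor ROI, peritumoral ring, or any other region of interest).
#'
#' @param values 3D numeric array of intensities in HU.
#' @param spacing Numeric length-3, voxel size per axis in mm (strictly
#'   positive).
#' @param origin Numeric length-3, physical offset of the first voxel in mm.
#' @param phase Contrast phase, one of `"plain"` (non-contrast),
#'   `"cortical"` (corticomedullary), `"parenchymal"`, `"excretory"`.
#'
#' @return An object of class `ct_volume` (resp. `mask_volume`).
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(v$values)
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0), phase = "plain") {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be finite and strictly positive on every axis")
  }
  if (any(!is.finite(values))) stop("`values` must be finite")
  phase <- match.arg(phase, ct_phases())
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         phase = phase),
    class = "ct_volume"
  )
}

#' @rdname ct_volume
#' @param labels 3D array coercible to binary 0/1.
#' @export
mask_volume <- function(labels, spacing, origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  stopifnot(length(dim(labels)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be finite and strictly positive on every axis")
  }
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(0L, 1L))) stop("mask labels must be 0/1")
  structure(
    list(labels = labels, spacing = spacing, origin = as.numeric(origin)),
    class = "mask_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s phase, %s voxels @ %s mm, HU range [%.1f, %.1f]\n",
              x$phase, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s voxels @ %s mm, %d foreground\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              sum(x$labels)))
  invisible(x)
}

ct_phases <- function() c("plain", "cortical", "parenchymal", "excretory")

# Grids match when shape and physical geometry agree to float tolerance.
same_grid <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "ct_volume")) dim(a$values) else dim(a$labels)
  db <- if (inherits(b, "ct_volume")) dim(b$values) else dim(b$labels)
  identical(da, db) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

assert_same_grid <- function(a, b) {
  if (!same_grid(a, b)) {
    stop("volume and mask are not aligned on the same physical grid")
  }
  invisible(TRUE)
}

#' Read or write a volume as NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' carry voxel spacing and origin through the round trip.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param phase Phase tag to attach on read (not stored in the NIfTI header).
#' @param mask Logical; read as a binary `mask_volume` instead of a
#'   `ct_volume`.
#' @return `read_volume()` returns a `ct_volume` or `mask_volume`;
#'   `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path, phase = "plain", mask = FALSE) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  sp <- RNifti::pixdim(img)[1:3]
  orig <- as.numeric(RNifti::origin(img))
  if (length(orig) < 3 || any(!is.finite(orig))) orig <- c(0, 0, 0)
  if (mask) {
    mask_volume(round(vals), spacing = sp, origin = orig)
  } else {
    ct_volume(vals, spacing = sp, origin = orig, phase = phase)
  }
}

#' @rdname read_volume
#' @param volume A `ct_volume` or `mask_volume`.
#' @export
write_volume <- function(volume, path) {
  vals <- if (inherits(volume, "mask_volume")) volume$labels else volume$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
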