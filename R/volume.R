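#' 3D image volume with physical spacing
#'
#' A minimal container for a 3D scalar grid on a regular lattice: an array of
#' intensities plus voxel spacing (mm per axis) and a physical origin (the
#' centre of voxel `[1,1,1]`, in mm). Axis order is array order (x, y, z with
#' z the slice axis).
#'
#' @param voxels numeric 3D array of intensities; all values must be finite.
#' @param spacing numeric length-3, mm per axis, strictly positive.
#' @param origin numeric length-3, mm.
#' @return An `image_volume` object.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!all(is.finite(voxels))) stop("all intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive values (mm)", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' Binary region-of-interest mask
#'
#' A 0/1 array on the same lattice as its companion [image_volume()].
#'
#' @param voxels 0/1 (or logical) 3D array; must contain at least one
#'   foreground voxel.
#' @param spacing,origin as in [image_volume()].
#' @return An `roi_mask` object.
#' @export
roi_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  if (sum(v) == 0L) stop("ROI mask has no foreground voxels", call. = FALSE)
  obj <- image_volume(v, spacing, origin)
  class(obj) <- c("roi_mask", "image_volume")
  obj
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    class(x)[1], d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  if (inherits(x, "roi_mask")) {
    cat(sprintf("  foreground voxels: %d\n", sum(x$voxels)))
  } else {
    cat(sprintf(
      "  intensity range: [%.4g, %.4g]\n",
      min(x$voxels), max(x$voxels)
    ))
  }
  invisible(x)
}

.check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$voxels))) {
    stop("volume and mask have different grid shapes", call. = FALSE)
  }
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9) {
    stop("volume and mask have different spacings", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} that carry the voxel spacing through the
#' NIfTI `pixdim` field.
#'
#' @param x an [image_volume()] or [roi_mask()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_nifti` returns `path` invisibly; `read_nifti_volume` and
#'   `read_nifti_mask` return an `image_volume` / `roi_mask`.
#' @export
write_nifti <- function(x, path) {
  stopifnot(inherits(x, "image_volume"))
  img <- RNifti::asNifti(x$voxels)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)), spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname write_nifti
#' @export
read_nifti_mask <- function(path) {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.integer(img > 0.5), dim = dim(img)), spacing = RNifti::pixdim(img)[1:3])
}

# physical coordinates (mm) of the voxel centres of a mask's foreground
.mask_coords <- function(mask) {
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}
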