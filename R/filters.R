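#' Laplacian-of-Gaussian derived image
#'
#' Band-pass filters a volume with the Laplacian of a Gaussian of width
#' `sigma_mm` (in physical units; converted per axis through the voxel
#' spacing). The response is the plain Laplacian of the Gaussian-smoothed
#' image, so a quadratic field `a * (x^2 + y^2 + z^2)` maps to `6 a` in the
#' interior and constants map to zero.
#'
#' @param volume an [image_volume()].
#' @param sigma_mm Gaussian width in mm (default 5).
#' @return An `image_volume` with the filter response.
#' @export
apply_log_filter <- function(volume, sigma_mm = 5) {
  stopifnot(inherits(volume, "image_volume"), sigma_mm > 0)
  sp <- volume$spacing
  a <- volume$voxels
  out <- array(0, dim = dim(a))
  for (d2ax in 1:3) {
    part <- a
    for (ax in 1:3) {
      if (ax == d2ax) {
        k <- .gaussian_d2_kernel(sigma_mm, sp[ax])
      } else {
        k <- .gaussian_kernel(sigma_mm / sp[ax])
      }
      part <- .conv_axis(part, k, ax, "reflect")
    }
    out <- out + part
  }
  image_volume(out, volume$spacing, volume$origin)
}

# Coiflet-1 orthonormal decomposition filters (6 taps); the high-pass is the
# quadrature mirror of the low-pass.
.COIF1_LO <- c(
  -0.015655728135465,
  -0.072732619512854,
  0.384864846864203,
  0.852572020212255,
  0.337897662457809,
  -0.072732619512854
)
.COIF1_HI <- rev(.COIF1_LO) * c(1, -1, 1, -1, 1, -1)

#' Single-level undecimated 3D wavelet decomposition
#'
#' Applies a low- (`L`) or high-pass (`H`) wavelet filter along each of the
#' three axes, producing the 8 sub-band images `HHH, HHL, HLH, HLL, LHH,
#' LHL, LLH, LLL` (letter order = axis order), each with the same shape as
#' the input. The transform is undecimated with periodic boundary handling,
#' so for an orthonormal family the total sub-band energy is exactly 8 times
#' the input energy.
#'
#' @param volume an [image_volume()].
#' @param family wavelet family; currently `"coif1"` (the common default of
#'   radiomics extraction platforms).
#' @return A named list of 8 `image_volume` objects.
#' @export
wavelet_decompose <- function(volume, family = "coif1") {
  stopifnot(inherits(volume, "image_volume"))
  family <- match.arg(family, "coif1")
  lo <- .COIF1_LO
  hi <- .COIF1_HI
  if (any(dim(volume$voxels) < length(lo))) {
    stop(
      "volume smaller than the wavelet filter length (", length(lo),
      ") along some axis", call. = FALSE
    )
  }
  bands <- c("HHH", "HHL", "HLH", "HLL", "LHH", "LHL", "LLH", "LLL")
  out <- vector("list", 8L)
  names(out) <- bands
  for (b in bands) {
    letters3 <- strsplit(b, "")[[1]]
    a <- volume$voxels
    for (ax in 1:3) {
      k <- if (letters3[ax] == "L") lo else hi
      a <- .conv_axis(a, k, ax, "periodic", center = 3L)
    }
    out[[b]] <- image_volume(a, volume$spacing, volume$origin)
  }
  out
}
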