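# Separable FIR filtering along one axis of a 3D array.
#
# Kernels are short relative to the grid, so the filter is applied as a dense
# n x n banded operator per axis (n <= a few hundred), which keeps everything
# vectorised in BLAS.

.fold_index <- function(idx, n, boundary) {
  switch(boundary,
    reflect = {
      # whole-sample reflection about both ends (..3,2,1,2,3.. at the left)
      p <- 2L * (n - 1L)
      m <- (idx - 1L) %% p
      m <- ifelse(m >= n, p - m, m)
      m + 1L
    },
    periodic = ((idx - 1L) %% n) + 1L,
    zero = ifelse(idx >= 1L & idx <= n, idx, NA_integer_),
    stop("unknown boundary: ", boundary)
  )
}

# n x n matrix applying the 1D convolution with 'kernel' (centre index
# 'center') under the given boundary handling
.conv_matrix <- function(n, kernel, center, boundary) {
  K <- matrix(0, n, n)
  out <- seq_len(n)
  for (t in seq_along(kernel)) {
    src <- .fold_index(out + t - center, n, boundary)
    keep <- !is.na(src)
    K[cbind(out[keep], src[keep])] <- K[cbind(out[keep], src[keep])] + kernel[t]
  }
  K
}

# apply 1D kernel along one axis of a 3D array
.conv_axis <- function(a, kernel, axis, boundary = "reflect",
                       center = (length(kernel) + 1L) / 2L) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  K <- .conv_matrix(d[axis], kernel, center, boundary)
  res <- K %*% m
  aperm(array(res, dim = d[perm]), order(perm))
}

# sampled Gaussian kernel (sum-normalised) for sigma expressed in voxels
.gaussian_kernel <- function(sigma_vox, radius = max(1L, ceiling(4 * sigma_vox))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# sampled second derivative of a Gaussian, in physical units:
# d2/dx2 exp(-x^2/(2 s^2)) / (s sqrt(2 pi)), sampled at x = j * spacing and
# weighted by the sample spacing (midpoint quadrature)
.gaussian_d2_kernel <- function(sigma_mm, spacing_mm,
                                radius = max(2L, ceiling(4 * sigma_mm / spacing_mm))) {
  x <- seq(-radius, radius) * spacing_mm
  g <- exp(-x^2 / (2 * sigma_mm^2)) / (sigma_mm * sqrt(2 * pi))
  k <- g * (x^2 - sigma_mm^2) / sigma_mm^4 * spacing_mm
  # enforce zero DC response so constant regions map exactly to zero
  k - sum(k) / length(k)
}

# isotropic (in mm) Gaussian smoothing of a 3D array
.smooth_gaussian <- function(a, sigma_mm, spacing, boundary = "reflect") {
  out <- a
  for (ax in 1:3) {
    sv <- sigma_mm / spacing[ax]
    if (sv > 1e-8) out <- .conv_axis(out, .gaussian_kernel(sv), ax, boundary)
  }
  out
}
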