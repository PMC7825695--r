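#' Bias-field correction
#'
#' Removes smooth multiplicative intensity inhomogeneity ("bias field") from
#' an MRI volume. The default `smooth-divide` method estimates the field in
#' the log-intensity domain by iteratively refined wide Gaussian smoothing
#' (a single smoothing pass attenuates the field at its own wavelength;
#' repeating `est <- est + smooth(logv - est)` drives the pass-band transfer
#' to 1 while texture-scale structure stays suppressed) and divides it out.
#' `delegate-n4` hands the volume to an external N4 implementation
#' (SimpleITK via the `python` on `PATH`) when one is available. In both
#' cases the output is rescaled so its mean intensity (over `mask` if given,
#' else the whole volume) equals the input's.
#'
#' @param volume an [image_volume()] with strictly positive intensities.
#' @param method `"smooth-divide"` (default) or `"delegate-n4"`.
#' @param sigma_mm width (mm) of the log-domain Gaussian field estimator.
#' @param iterations refinement passes of the smooth-divide estimator.
#' @param mask optional [roi_mask()]; if given, the mean preserved is the
#'   ROI mean.
#' @return A corrected `image_volume`.
#' @export
correct_bias_field <- function(volume, method = c("smooth-divide", "delegate-n4"),
                               sigma_mm = 25, iterations = 20, mask = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(volume, "image_volume"))
  if (min(volume$voxels) <= 0) {
    stop(
      "bias correction operates in the log domain and requires strictly ",
      "positive intensities; shift the volume by an offset first",
      call. = FALSE
    )
  }
  if (!is.null(mask)) .check_aligned(volume, mask)
  sel <- if (is.null(mask)) TRUE else mask$voxels == 1L

  if (method == "smooth-divide") {
    lv <- log(volume$voxels)
    est <- array(0, dim = dim(lv))
    for (k in seq_len(iterations)) {
      est <- est + .smooth_gaussian(lv - est, sigma_mm, volume$spacing)
    }
    out <- volume$voxels / exp(est)
  } else {
    out <- .delegate_n4(volume)
  }
  out <- out * mean(volume$voxels[sel]) / mean(out[sel])
  image_volume(out, volume$spacing, volume$origin)
}

.delegate_n4 <- function(volume) {
  py <- Sys.which("python")
  if (!nzchar(py)) {
    stop("delegate-n4 requires a 'python' with SimpleITK on PATH", call. = FALSE)
  }
  tin <- tempfile(fileext = ".nii.gz")
  tout <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(tin, tout)), add = TRUE)
  write_nifti(volume, tin)
  code <- sprintf(
    "import SimpleITK as sitk; img = sitk.ReadImage(%s, sitk.sitkFloat64); out = sitk.N4BiasFieldCorrection(img); sitk.WriteImage(out, %s)",
    deparse(tin), deparse(tout)
  )
  status <- system2(py, c("-c", shQuote(code)), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(tout)) {
    stop("external N4 correction failed (is SimpleITK installed?)", call. = FALSE)
  }
  read_nifti_volume(tout)$voxels
}

#' Histogram matching by quantile landmarks
#'
#' Normalises a volume's intensity distribution to a reference volume through
#' a monotone piecewise-linear map fitted at `n_landmarks` equally spaced
#' quantiles, the standard landmark scheme for multi-scanner MRI
#' harmonisation.
#'
#' @param volume,reference [image_volume()] objects.
#' @param n_landmarks number of quantile landmarks (default 64).
#' @return The remapped `image_volume`.
#' @export
match_histogram <- function(volume, reference, n_landmarks = 64) {
  stopifnot(inherits(volume, "image_volume"), inherits(reference, "image_volume"))
  stopifnot(n_landmarks >= 2)
  if (diff(range(reference$voxels)) == 0) {
    stop("reference volume is constant: quantile map undefined", call. = FALSE)
  }
  probs <- seq(0, 1, length.out = n_landmarks)
  vq <- stats::quantile(volume$voxels, probs, names = FALSE, type = 7)
  rq <- stats::quantile(reference$voxels, probs, names = FALSE, type = 7)
  # collapse duplicated input landmarks (flat stretches of the histogram)
  keep <- !duplicated(vq)
  vq <- vq[keep]
  rq <- rq[keep]
  if (length(vq) < 2) {
    # volume is constant: map everything to the median of the reference
    out <- array(rq[1], dim = dim(volume$voxels))
  } else {
    out <- stats::approx(vq, rq, xout = as.vector(volume$voxels), rule = 2)$y
    out <- array(out, dim = dim(volume$voxels))
  }
  image_volume(out, volume$spacing, volume$origin)
}

# ---- cubic B-spline interpolation (Unser prefilter + tensor evaluation) ----

# causal/anticausal recursive prefilter for the cubic B-spline, applied along
# the rows of an n x m matrix
.bspline_prefilter_mat <- function(s) {
  n <- nrow(s)
  if (n == 1L) return(s)
  z <- sqrt(3) - 2
  horizon <- ceiling(log(1e-15) / log(abs(z)))
  cp <- s
  # mirror-symmetric initialisation of the causal pass; fold indices past
  # the end so short axes keep the full precision horizon
  init <- s[1, , drop = FALSE]
  zk <- 1
  for (k in 2:horizon) {
    zk <- zk * z
    init <- init + zk * s[.fold_index(k, n, "reflect"), , drop = FALSE]
  }
  cp[1, ] <- init
  for (k in 2:n) cp[k, ] <- s[k, ] + z * cp[k - 1, ]
  cn <- cp
  cn[n, ] <- (z / (z^2 - 1)) * (cp[n, ] + z * cp[n - 1, ])
  for (k in (n - 1):1) cn[k, ] <- z * (cn[k + 1, ] - cp[k, ])
  6 * cn
}

# cubic B-spline kernel
.bspline3 <- function(t) {
  at <- abs(t)
  ifelse(at < 1, (4 - 6 * at^2 + 3 * at^3) / 6,
    ifelse(at < 2, (2 - at)^3 / 6, 0)
  )
}

# n_new x n_old matrix evaluating the cubic spline (given its coefficients)
# at continuous 1-based index positions x
.bspline_eval_matrix <- function(x, n_old) {
  W <- matrix(0, length(x), n_old)
  i0 <- floor(x)
  for (o in -1:2) {
    j <- i0 + o
    w <- .bspline3(x - j)
    jf <- .fold_index(as.integer(j), n_old, "reflect")
    W[cbind(seq_along(x), jf)] <- W[cbind(seq_along(x), jf)] + w
  }
  W
}

# apply a per-axis linear operator W (rows = new size) along one axis
.apply_axis_op <- function(a, W, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- W %*% matrix(ap, nrow = d[axis])
  dnew <- d[perm]
  dnew[1] <- nrow(W)
  aperm(array(m, dim = dnew), order(perm))
}

#' Resample a volume and its mask to a target voxel size
#'
#' Interpolates the intensity volume with cubic B-splines (exact on linear
#' ramps, interpolating at the original voxel centres) and the mask with
#' nearest neighbours, onto a grid with exactly the requested spacing and the
#' same origin.
#'
#' @param volume an [image_volume()].
#' @param mask an aligned [roi_mask()].
#' @param target_spacing numeric length-3, mm (default `c(2, 2, 2)`).
#' @return A list with elements `volume` and `mask` on the new grid.
#' @export
resample_volume <- function(volume, mask, target_spacing = c(2, 2, 2)) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  .check_aligned(volume, mask)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0)) {
    stop("target spacing must be 3 positive values (mm)", call. = FALSE)
  }
  d <- dim(volume$voxels)
  nnew <- pmax(1L, as.integer(round(d * volume$spacing / target_spacing)))

  # B-spline coefficients: prefilter each axis in turn
  coef <- volume$voxels
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(coef, perm)
    m <- .bspline_prefilter_mat(matrix(ap, nrow = d[ax]))
    coef <- aperm(array(m, dim = d[perm]), order(perm))
  }

  out <- coef
  mout <- mask$voxels
  for (ax in 1:3) {
    x <- ((seq_len(nnew[ax]) - 1) * target_spacing[ax]) / volume$spacing[ax] + 1
    W <- .bspline_eval_matrix(x, d[ax])
    out <- .apply_axis_op(out, W, ax)
    # nearest-neighbour operator for the mask
    src <- pmin(pmax(as.integer(round(x)), 1L), d[ax])
    Wn <- matrix(0, nnew[ax], d[ax])
    Wn[cbind(seq_len(nnew[ax]), src)] <- 1
    mout <- .apply_axis_op(mout, Wn, ax)
  }
  mout <- array(as.integer(mout > 0.5), dim = nnew)
  if (sum(mout) == 0L) {
    stop("ROI mask vanished after resampling to the requested spacing", call. = FALSE)
  }
  list(
    volume = image_volume(out, target_spacing, volume$origin),
    mask = roi_mask(mout, target_spacing, volume$origin)
  )
}
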