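#' First-order intensity statistics
#'
#' The 18 first-order features of IBSI-style radiomics, computed over the
#' ROI intensities. Entropy and uniformity are computed on intensities
#' discretized with `bin_width`; all moments are population (biased)
#' moments; kurtosis is non-excess. A zero-variance ROI yields skewness and
#' kurtosis 0 by convention.
#'
#' @param volume an [image_volume()].
#' @param mask an aligned [roi_mask()].
#' @param bin_width discretization bin width for entropy/uniformity.
#' @return A named numeric vector of length 18.
#' @export
compute_first_order <- function(volume, mask, bin_width = 25) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  .check_aligned(volume, mask)
  x <- volume$voxels[mask$voxels == 1L]
  n <- length(x)
  voxvol <- prod(volume$spacing)
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  lv <- floor((x - min(x)) / bin_width) + 1
  p <- tabulate(lv) / n
  p <- p[p > 0]
  inrob <- x >= q[1] & x <= q[5]
  c(
    Energy = sum(x^2),
    TotalEnergy = voxvol * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(x[inrob] - mean(x[inrob]))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}
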