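# Texture feature sets computed from the texture matrices. All follow the
# IBSI definitions with the conventions noted in the roxygen blocks; division
# guards use .EPS-style conventions that are unit-tested.

.glcm_features_one <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  p <- P / tot
  i <- row(p)
  j <- col(p)
  px <- rowSums(p) # == colSums by symmetry
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  sig <- sqrt(sig2)

  kd <- 0:(ng - 1) # |i - j|
  pd <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * ng) # i + j
  ps <- vapply(ks, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(kd * pd)

  nz <- p > 0
  hxy <- -sum(p[nz] * log2(p[nz]))
  pxy <- px[i] * px[j]
  hxy1 <- -sum(p[nz] * log2(pxy[nz] + .EPS))
  nzm <- pxy > 0
  hxy2 <- -sum(pxy[nzm] * log2(pxy[nzm]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))

  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  mcc <- 1
  pres <- which(px > 0)
  if (length(pres) > 1) {
    pp <- p[pres, pres, drop = FALSE]
    Q <- (pp / px[pres]) %*% t(pp / px[pres])
    lam <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, lam[2]))
  }

  c(
    Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    SumSquares = sig2
  )
}

#' Gray-level co-occurrence features
#'
#' The 24 GLCM features, computed per direction on the symmetrised,
#' normalised co-occurrence matrix and averaged over the 13 unique 3D
#' directions. With a single gray level, correlation and MCC are 1 by
#' convention.
#'
#' @param disc a discretized image as returned by [discretize()].
#' @param distance co-occurrence distance in voxels (default 1).
#' @return A named numeric vector of length 24.
#' @export
compute_glcm_features <- function(disc, distance = 1L) {
  feats <- lapply(seq_len(nrow(.DIRECTIONS_13)), function(r) {
    P <- glcm_matrix(disc$levels, disc$ng, .DIRECTIONS_13[r, ], distance)
    if (sum(P) == 0) return(NULL)
    .glcm_features_one(P)
  })
  feats <- feats[!vapply(feats, is.null, logical(1))]
  Reduce(`+`, feats) / length(feats)
}

.rlm_style_features <- function(P, np, prefix_short, prefix_long, run_word) {
  nr <- sum(P)
  i <- row(P)
  j <- col(P)
  p <- P / nr
  mug <- sum(i * p)
  mur <- sum(j * p)
  nz <- p > 0
  out <- c(
    sum(P / col(P)^2) / nr,
    sum(P * col(P)^2) / nr,
    sum(rowSums(P)^2) / nr,
    sum(rowSums(P)^2) / nr^2,
    sum(colSums(P)^2) / nr,
    sum(colSums(P)^2) / nr^2,
    nr / np,
    sum((i - mug)^2 * p),
    sum((j - mur)^2 * p),
    -sum(p[nz] * log2(p[nz])),
    sum(P / row(P)^2) / nr,
    sum(P * row(P)^2) / nr,
    sum(P / (row(P)^2 * col(P)^2)) / nr,
    sum(P * row(P)^2 / col(P)^2) / nr,
    sum(P * col(P)^2 / row(P)^2) / nr,
    sum(P * row(P)^2 * col(P)^2) / nr
  )
  names(out) <- c(
    paste0(prefix_short, "Emphasis"),
    paste0(prefix_long, "Emphasis"),
    "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized",
    paste0(run_word, "NonUniformity"),
    paste0(run_word, "NonUniformityNormalized"),
    paste0(run_word, "Percentage"),
    "GrayLevelVariance",
    paste0(run_word, "Variance"),
    paste0(run_word, "Entropy"),
    "LowGrayLevelEmphasis",
    "HighGrayLevelEmphasis",
    paste0(prefix_short, "LowGrayLevelEmphasis"),
    paste0(prefix_short, "HighGrayLevelEmphasis"),
    paste0(prefix_long, "LowGrayLevelEmphasis"),
    paste0(prefix_long, "HighGrayLevelEmphasis")
  )
  out
}

#' Gray-level run-length features
#'
#' The 16 GLRLM features, computed per direction and averaged over the 13
#' unique 3D directions.
#'
#' @inheritParams compute_glcm_features
#' @return A named numeric vector of length 16.
#' @export
compute_glrlm_features <- function(disc) {
  np <- sum(disc$levels > 0L)
  feats <- lapply(seq_len(nrow(.DIRECTIONS_13)), function(r) {
    P <- glrlm_matrix(disc$levels, disc$ng, .DIRECTIONS_13[r, ])
    .rlm_style_features(P, np, "ShortRun", "LongRun", "RunLength")
  })
  out <- Reduce(`+`, feats) / length(feats)
  # conventional GLRLM spellings
  names(out) <- sub("^RunLengthVariance$", "RunVariance", names(out))
  names(out) <- sub("^RunLengthEntropy$", "RunEntropy", names(out))
  names(out) <- sub("^RunLengthPercentage$", "RunPercentage", names(out))
  names(out) <- sub("^LowGrayLevelEmphasis$", "LowGrayLevelRunEmphasis", names(out))
  names(out) <- sub("^HighGrayLevelEmphasis$", "HighGrayLevelRunEmphasis", names(out))
  out
}

#' Gray-level size-zone features
#'
#' The 16 GLSZM features over 26-connected equal-level zones.
#'
#' @inheritParams compute_glcm_features
#' @return A named numeric vector of length 16.
#' @export
compute_glszm_features <- function(disc) {
  np <- sum(disc$levels > 0L)
  P <- glszm_matrix(disc$levels, disc$ng)
  out <- .rlm_style_features(P, np, "SmallArea", "LargeArea", "Zone")
  names(out) <- sub("^ZoneNonUniformity", "SizeZoneNonUniformity", names(out))
  names(out) <- sub("^LowGrayLevelEmphasis$", "LowGrayLevelZoneEmphasis", names(out))
  names(out) <- sub("^HighGrayLevelEmphasis$", "HighGrayLevelZoneEmphasis", names(out))
  out
}

#' Gray-level dependence features
#'
#' The 14 GLDM features; the dependence of a voxel is its number of
#' equal-level 26-neighbours (tolerance alpha = 0) and is indexed from 1
#' (dependence d maps to column d + 1).
#'
#' @inheritParams compute_glcm_features
#' @return A named numeric vector of length 14.
#' @export
compute_gldm_features <- function(disc) {
  P <- gldm_matrix(disc$levels, disc$ng)
  nz <- sum(P)
  i <- row(P)
  j <- col(P)
  p <- P / nz
  mug <- sum(i * p)
  mud <- sum(j * p)
  pnz <- p > 0
  c(
    SmallDependenceEmphasis = sum(P / col(P)^2) / nz,
    LargeDependenceEmphasis = sum(P * col(P)^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    GrayLevelVariance = sum((i - mug)^2 * p),
    DependenceVariance = sum((j - mud)^2 * p),
    DependenceEntropy = -sum(p[pnz] * log2(p[pnz])),
    LowGrayLevelEmphasis = sum(P / row(P)^2) / nz,
    HighGrayLevelEmphasis = sum(P * row(P)^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (row(P)^2 * col(P)^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * row(P)^2 / col(P)^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * col(P)^2 / row(P)^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * row(P)^2 * col(P)^2) / nz
  )
}

#' Neighbouring gray-tone difference features
#'
#' Coarseness, contrast, busyness, complexity and strength. Degenerate
#' cases follow fixed conventions: a fully uniform ROI has zero summed
#' differences, so coarseness is capped at 1e6 and contrast, busyness and
#' strength return 0.
#'
#' @inheritParams compute_glcm_features
#' @return A named numeric vector of length 5.
#' @export
compute_ngtdm_features <- function(disc) {
  tb <- ngtdm_table(disc$levels, disc$ng)
  pres <- tb$p > 0
  pv <- tb$p[pres]
  sv <- tb$s[pres]
  iv <- tb$level[pres]
  npv <- sum(tb$n)
  ngp <- sum(pres)
  ps <- sum(pv * sv)

  coarseness <- if (ps > 0) 1 / ps else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(pv, pv) * outer(iv, iv, "-")^2) / (ngp * (ngp - 1)) * sum(sv) / npv
  } else {
    0
  }
  ipd <- outer(iv * pv, iv * pv, "-")
  busy_den <- sum(abs(ipd))
  busyness <- if (busy_den > 0) ps / busy_den else 0
  complexity <- sum(
    abs(outer(iv, iv, "-")) * (outer(pv * sv, pv * sv, "+")) / outer(pv, pv, "+")
  ) / npv
  strength <- if (sum(sv) > 0) {
    sum(outer(pv, pv, "+") * outer(iv, iv, "-")^2) / sum(sv)
  } else {
    0
  }
  c(
    Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength
  )
}
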