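# Gray-level discretization and the five 3D texture matrices
# (GLCM / GLRLM / GLSZM / GLDM / NGTDM).
#
# Internal representation: an integer array of gray levels, 1..Ng inside the
# ROI and 0 outside, so out-of-mask voxels break runs/zones naturally.

# the 13 unique 3D direction pairs (first non-zero component +1)
.DIRECTIONS_13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

#' Fixed-bin-width gray-level discretization
#'
#' Bins ROI intensities with `level = floor((x - min) / bin_width) + 1`,
#' anchored at the ROI minimum, the fixed-bin-width scheme of IBSI-style
#' extraction. Voxels outside the mask get level 0.
#'
#' @param volume an [image_volume()].
#' @param mask an aligned [roi_mask()].
#' @param bin_width bin width in intensity units (default 25).
#' @return A list with `levels` (integer array), `ng` (number of gray
#'   levels) and the ROI intensity `values`.
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  .check_aligned(volume, mask)
  if (bin_width <= 0) stop("bin width must be positive", call. = FALSE)
  inroi <- mask$voxels == 1L
  vals <- volume$voxels[inroi]
  lv <- array(0L, dim = dim(volume$voxels))
  lv[inroi] <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
  list(levels = lv, ng = max(lv), values = vals)
}

# per-axis index range of voxels whose `off`-neighbour is still in-grid;
# integer(0) when the offset exceeds the axis
.axis_range <- function(d_ax, off_ax) {
  lo <- max(1L, 1L - off_ax)
  hi <- min(d_ax, d_ax - off_ax)
  if (lo > hi) integer(0) else lo:hi
}

# (level_here, level_there) pairs for one integer offset; NULL if the offset
# does not fit in the grid
.offset_pairs <- function(gl, off) {
  d <- dim(gl)
  rng <- lapply(1:3, function(ax) .axis_range(d[ax], off[ax]))
  if (any(lengths(rng) == 0L)) return(NULL)
  a <- gl[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  b <- gl[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3], drop = FALSE]
  cbind(as.vector(a), as.vector(b))
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Symmetric co-occurrence counts of gray levels at the given voxel offset.
#'
#' @param gl integer gray-level array (0 = outside ROI).
#' @param ng number of gray levels.
#' @param offset integer length-3 direction, in voxels.
#' @param distance voxel distance multiplying the direction (default 1).
#' @return An `ng` x `ng` symmetric count matrix.
#' @export
glcm_matrix <- function(gl, ng, offset, distance = 1L) {
  p <- .offset_pairs(gl, offset * distance)
  m <- matrix(0, ng, ng)
  if (is.null(p)) return(m)
  p <- p[p[, 1] > 0L & p[, 2] > 0L, , drop = FALSE]
  if (nrow(p) == 0L) return(m)
  tab <- tabulate((p[, 1] - 1L) * ng + p[, 2], nbins = ng * ng)
  m <- matrix(tab, ng, ng, byrow = TRUE)
  m + t(m)
}

#' Gray-level run-length matrix for one direction
#'
#' Counts maximal runs of equal gray level along lines in the given
#' direction; out-of-mask voxels terminate runs.
#'
#' @inheritParams glcm_matrix
#' @return An `ng` x `max run length` count matrix.
#' @export
glrlm_matrix <- function(gl, ng, offset) {
  d <- dim(gl)
  idx <- arrayInd(seq_along(gl), d)
  # canonical base point of the line through each voxel: step back along the
  # first moving axis until its coordinate is zero
  ax1 <- which(offset != 0)[1]
  m <- idx[, ax1]
  base <- idx - m %o% offset
  span <- max(d) * 2L + 2L
  key <- (base[, 1] + max(d)) + (base[, 2] + max(d)) * span + (base[, 3] + max(d)) * span^2
  o <- order(key, m)
  v <- gl[o]
  k <- key[o]
  n <- length(v)
  newrun <- c(TRUE, v[-1] != v[-n] | k[-1] != k[-n])
  runlevel <- v[newrun]
  runlen <- tabulate(cumsum(newrun))
  keep <- runlevel > 0L
  runlevel <- runlevel[keep]
  runlen <- runlen[keep]
  nr <- max(runlen, 1L)
  mat <- matrix(0, ng, nr)
  tab <- tabulate((runlevel - 1L) * nr + runlen, nbins = ng * nr)
  matrix(tab, ng, nr, byrow = TRUE)
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level inside the ROI.
#'
#' @inheritParams glcm_matrix
#' @return An `ng` x `max zone size` count matrix.
#' @export
glszm_matrix <- function(gl, ng) {
  vox <- which(gl > 0L)
  id <- integer(length(gl))
  id[vox] <- seq_along(vox)
  edges <- NULL
  for (r in seq_len(nrow(.DIRECTIONS_13))) {
    off <- .DIRECTIONS_13[r, ]
    d <- dim(gl)
    rng <- lapply(1:3, function(ax) .axis_range(d[ax], off[ax]))
    if (any(lengths(rng) == 0L)) next
    lin <- as.vector(.linear_index(rng, d))
    lin2 <- as.vector(.linear_index(lapply(1:3, function(ax) rng[[ax]] + off[ax]), d))
    ok <- gl[lin] > 0L & gl[lin] == gl[lin2]
    if (any(ok)) edges <- rbind(edges, cbind(id[lin[ok]], id[lin2[ok]]))
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  # one representative voxel per component gives the zone's gray level
  zone_level <- gl[vox][match(seq_len(comp$no), comp$membership)]
  zone_size <- comp$csize
  ns <- max(zone_size, 1L)
  tab <- tabulate((as.integer(zone_level) - 1L) * ns + zone_size, nbins = ng * ns)
  matrix(tab, ng, ns, byrow = TRUE)
}

# linear indices of the sub-grid given by per-axis index ranges
.linear_index <- function(rng, d) {
  outer(
    outer(rng[[1]], (rng[[2]] - 1L) * d[1], "+"),
    (rng[[3]] - 1L) * d[1] * d[2], "+"
  )
}

# per-voxel 26-neighbourhood tallies inside the ROI:
# count of in-mask neighbours, count of equal-level neighbours, sum of
# neighbour levels. Returned for ROI voxels (level > 0) in array order.
.neighbor_tallies <- function(gl) {
  d <- dim(gl)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- gl
  nsum <- array(0, dim = d)
  ncount <- array(0L, dim = d)
  neq <- array(0L, dim = d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- pad[
      (2:(d[1] + 1)) + dx,
      (2:(d[2] + 1)) + dy,
      (2:(d[3] + 1)) + dz,
      drop = FALSE
    ]
    inm <- nb > 0L
    nsum <- nsum + nb * inm
    ncount <- ncount + inm
    neq <- neq + (inm & nb == gl)
  }
  sel <- gl > 0L
  list(
    level = gl[sel], nsum = nsum[sel],
    ncount = ncount[sel], neq = neq[sel]
  )
}

#' Gray-level dependence matrix
#'
#' The dependence of a voxel is the number of its 26-neighbours (inside the
#' ROI) whose gray level equals its own (tolerance alpha = 0); the matrix
#' counts voxels by (level, dependence).
#'
#' @inheritParams glcm_matrix
#' @return An `ng` x `max dependence + 1` count matrix; column `j` holds
#'   dependence `j - 1`.
#' @export
gldm_matrix <- function(gl, ng) {
  t <- .neighbor_tallies(gl)
  nd <- max(t$neq) + 1L
  tab <- tabulate((t$level - 1L) * nd + t$neq + 1L, nbins = ng * nd)
  matrix(tab, ng, nd, byrow = TRUE)
}

#' Neighbouring gray-tone difference table
#'
#' For each gray level `i` present in the ROI: `n_i` (voxel count), `p_i`
#' (probability) and `s_i`, the summed absolute difference between `i` and
#' the mean level of each voxel's in-ROI 26-neighbourhood. Voxels without
#' any in-ROI neighbour are excluded.
#'
#' @inheritParams glcm_matrix
#' @return A data.frame with columns `level`, `n`, `p`, `s`.
#' @export
ngtdm_table <- function(gl, ng) {
  t <- .neighbor_tallies(gl)
  has <- t$ncount > 0L
  lev <- t$level[has]
  abar <- t$nsum[has] / t$ncount[has]
  n_i <- tabulate(lev, nbins = ng)
  s_i <- vapply(seq_len(ng), function(i) {
    sum(abs(i - abar[lev == i]))
  }, numeric(1))
  data.frame(level = seq_len(ng), n = n_i, p = n_i / sum(n_i), s = s_i)
}
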