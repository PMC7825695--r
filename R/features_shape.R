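# 3D shape features on the ROI mask.
#
# Surface area and mesh volume come from a closed triangle mesh of the mask
# boundary built by marching tetrahedra (each boundary grid cell is split
# into 6 tetrahedra; crossings at edge midpoints of the binary indicator,
# iso-level 0.5), with triangles oriented outward so the divergence theorem
# gives the enclosed volume.

# cube corner offsets, corner ids 1..8
.CUBE_CORNERS <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1)
)
# 6-tetrahedra decomposition around the main diagonal 1-8
.CUBE_TETS <- rbind(
  c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
  c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8)
)

# triangle mesh (list of three n x 3 vertex matrices, outward oriented) of
# the ROI boundary; coords in mm.
#
# The mesh is the 0.5 level set of the mask indicator, lightly smoothed
# (Gaussian, ~0.8 voxel) so the staircase of the voxel grid does not
# inflate the surface area; crossings are linearly interpolated along
# tetrahedron edges. If the smoothed field of a very small mask never
# crosses 0.5, the raw binary indicator is meshed instead (crossings then
# sit at edge midpoints).
.mask_mesh <- function(mask, smooth = TRUE) {
  d <- dim(mask$voxels)
  sp <- mask$spacing
  npad <- if (smooth) 4L else 1L
  pad <- array(0, dim = d + 2L * npad)
  pad[
    npad + (1:d[1]), npad + (1:d[2]), npad + (1:d[3])
  ] <- mask$voxels
  if (smooth) {
    pad <- .smooth_gaussian(pad, 0.8 * max(sp), sp)
    if (max(pad) <= 0.5) return(.mask_mesh(mask, smooth = FALSE))
  }
  dp <- dim(pad)
  nc <- dp - 1L
  # corner values per cell, cells indexed by their low corner
  cellval <- matrix(0, prod(nc), 8)
  for (ci in 1:8) {
    o <- .CUBE_CORNERS[ci, ]
    cellval[, ci] <- as.vector(pad[
      (1:nc[1]) + o[1], (1:nc[2]) + o[2], (1:nc[3]) + o[3],
      drop = FALSE
    ])
  }
  inside_all <- cellval > 0.5
  nin <- rowSums(inside_all)
  mixed <- which(nin %in% 1:7)
  if (length(mixed) == 0L) {
    return(list(
      p1 = matrix(0, 0, 3), p2 = matrix(0, 0, 3), p3 = matrix(0, 0, 3)
    ))
  }
  cellval <- cellval[mixed, , drop = FALSE]
  ijk <- arrayInd(mixed, nc)
  # physical coordinate of each cell's low corner: padded voxel
  # (npad + 1, ...) is original voxel (1,1,1) at the origin (taken as 0)
  base <- sweep(ijk - (npad + 1L), 2, sp, "*")

  p1 <- p2 <- p3 <- NULL
  corner_xyz <- function(rows, ci) {
    sweep(base[rows, , drop = FALSE], 2, .CUBE_CORNERS[ci, ] * sp, "+")
  }
  mid <- function(rows, ca, cb) {
    # linear interpolation of the 0.5 crossing along the cell edge
    va <- cellval[rows, ca]
    vb <- cellval[rows, cb]
    t <- (0.5 - va) / (vb - va)
    corner_xyz(rows, ca) * (1 - t) + corner_xyz(rows, cb) * t
  }
  emit <- function(a, b, c, ref) {
    # orient so the normal points along ref (inside -> outside)
    n <- .cross3(b - a, c - a)
    flip <- rowSums(n * ref) < 0
    tmp <- b[flip, , drop = FALSE]
    b[flip, ] <- c[flip, , drop = FALSE]
    c[flip, ] <- tmp
    p1 <<- rbind(p1, a)
    p2 <<- rbind(p2, b)
    p3 <<- rbind(p3, c)
  }

  for (t in 1:6) {
    tc <- .CUBE_TETS[t, ]
    tv <- cellval[, tc, drop = FALSE] > 0.5
    k <- rowSums(tv)
    patt <- tv %*% c(1L, 2L, 4L, 8L) # bitmask of inside corners
    for (pt in 1:14) {
      rows <- which(patt == pt & k %in% 1:3)
      if (length(rows) == 0L) next
      inside <- which(bitwAnd(pt, c(1L, 2L, 4L, 8L)) > 0L)
      outside <- setdiff(1:4, inside)
      cin <- tc[inside]
      cout <- tc[outside]
      ref <- Reduce(`+`, lapply(cout, function(ci) corner_xyz(rows, ci))) / length(cout) -
        Reduce(`+`, lapply(cin, function(ci) corner_xyz(rows, ci))) / length(cin)
      if (length(cin) == 1L) {
        emit(
          mid(rows, cin, cout[1]), mid(rows, cin, cout[2]),
          mid(rows, cin, cout[3]), ref
        )
      } else if (length(cin) == 3L) {
        emit(
          mid(rows, cout, cin[1]), mid(rows, cout, cin[2]),
          mid(rows, cout, cin[3]), ref
        )
      } else {
        # two in, two out: a quad split into two triangles
        m1 <- mid(rows, cin[1], cout[1])
        m2 <- mid(rows, cin[1], cout[2])
        m3 <- mid(rows, cin[2], cout[2])
        m4 <- mid(rows, cin[2], cout[1])
        emit(m1, m2, m3, ref)
        emit(m1, m3, m4, ref)
      }
    }
  }
  list(p1 = p1, p2 = p2, p3 = p3)
}

.cross3 <- function(u, v) {
  cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
}

# largest pairwise distance among points (rows of a matrix), 0 if < 2 points
.max_pairwise <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  max(stats::dist(pts))
}

#' 3D shape features of an ROI mask
#'
#' The 14 IBSI-style shape descriptors: mesh and voxel volume, surface area,
#' surface-to-volume ratio, sphericity, maximum 3D diameter, three maximum
#' in-plane 2D diameters, the three principal axis lengths and the derived
#' elongation and flatness. Axis lengths are `4 * sqrt(lambda)` from the PCA
#' of voxel-centre coordinates; degenerate axes give length 0 and a
#' single-voxel mask gives elongation = flatness = 1 by convention.
#' Diameters are measured between centres of boundary voxels.
#'
#' @param mask an [roi_mask()].
#' @return A named numeric vector of length 14.
#' @export
compute_shape <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sp <- mask$spacing
  nvox <- sum(mask$voxels)
  mesh <- .mask_mesh(mask)
  cr <- .cross3(mesh$p2 - mesh$p1, mesh$p3 - mesh$p1)
  area <- sum(sqrt(rowSums(cr^2))) / 2
  vol <- sum(mesh$p1[, 1] * cr[, 1] + mesh$p1[, 2] * cr[, 2] + mesh$p1[, 3] * cr[, 3]) / 6

  # boundary voxels: at least one out-of-mask 6-neighbour
  m <- mask$voxels
  d <- dim(m)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  interior <- array(TRUE, dim = d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    o <- c(0L, 0L, 0L)
    o[ax] <- s
    nb <- pad[
      (2:(d[1] + 1)) + o[1], (2:(d[2] + 1)) + o[2], (2:(d[3] + 1)) + o[3],
      drop = FALSE
    ]
    interior <- interior & (nb == 1L)
  }
  bnd <- m == 1L & !interior
  bidx <- which(bnd, arr.ind = TRUE)
  bxyz <- sweep(bidx - 1, 2, sp, "*")

  max3d <- .max_pairwise(bxyz)
  max2d <- vapply(1:3, function(ax) {
    keep <- setdiff(1:3, ax)
    max(vapply(
      unique(bidx[, ax]),
      function(s) .max_pairwise(bxyz[bidx[, ax] == s, keep, drop = FALSE]),
      numeric(1)
    ))
  }, numeric(1))

  xyz <- .mask_coords(mask)
  if (nvox > 1L) {
    ev <- sort(eigen(stats::cov(xyz) * (nvox - 1) / nvox, symmetric = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  c(
    MeshVolume = vol,
    VoxelVolume = nvox * prod(sp),
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / area,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = max2d[3],
    Maximum2DDiameterColumn = max2d[2],
    Maximum2DDiameterRow = max2d[1],
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = elong,
    Flatness = flat
  )
}
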