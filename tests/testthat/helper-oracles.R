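# Independent brute-force oracles for the texture matrices and ranking
# metrics. These deliberately use naive elementwise loops so they share no
# code path with the package implementation.

oracle_directions <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# symmetric co-occurrence counts by explicit pair enumeration
oracle_glcm <- function(gl, ng, off) {
  d <- dim(gl)
  m <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- gl[x, y, z]
    if (a == 0) next
    q <- c(x, y, z) + off
    if (!in_grid(q, d)) next
    b <- gl[q[1], q[2], q[3]]
    if (b == 0) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m
}

# run-length counts by walking every line voxel by voxel
oracle_glrlm <- function(gl, ng, off) {
  d <- dim(gl)
  runs <- list()
  visited <- array(FALSE, dim = d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    p <- c(x, y, z)
    prev <- p - off
    # only start walking at the first voxel of each line
    if (in_grid(prev, d)) next
    lev <- -1L
    len <- 0L
    while (in_grid(p, d)) {
      v <- gl[p[1], p[2], p[3]]
      if (v == lev) {
        len <- len + 1L
      } else {
        if (lev > 0L) runs[[length(runs) + 1L]] <- c(lev, len)
        lev <- v
        len <- 1L
      }
      p <- p + off
    }
    if (lev > 0L) runs[[length(runs) + 1L]] <- c(lev, len)
  }
  if (length(runs) == 0L) return(matrix(0, ng, 1))
  rl <- do.call(rbind, runs)
  m <- matrix(0, ng, max(rl[, 2]))
  for (i in seq_len(nrow(rl))) m[rl[i, 1], rl[i, 2]] <- m[rl[i, 1], rl[i, 2]] + 1
  m
}

# zone counts by recursive flood fill over the 26-neighbourhood
oracle_glszm <- function(gl, ng) {
  d <- dim(gl)
  seen <- array(FALSE, dim = d)
  zones <- list()
  nb26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb26 <- nb26[rowSums(abs(nb26)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || gl[x, y, z] == 0L) next
    lev <- gl[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(nb26))) {
        q <- p + nb26[r, ]
        if (in_grid(q, d) && !seen[q[1], q[2], q[3]] && gl[q[1], q[2], q[3]] == lev) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(lev, size)
  }
  zs <- do.call(rbind, zones)
  m <- matrix(0, ng, max(zs[, 2]))
  for (i in seq_len(nrow(zs))) m[zs[i, 1], zs[i, 2]] <- m[zs[i, 1], zs[i, 2]] + 1
  m
}

# dependence counts by explicit neighbour loops
oracle_gldm <- function(gl, ng) {
  d <- dim(gl)
  nb26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb26 <- nb26[rowSums(abs(nb26)) > 0, ]
  recs <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- gl[x, y, z]
    if (a == 0L) next
    dep <- 0L
    for (r in seq_len(nrow(nb26))) {
      q <- c(x, y, z) + nb26[r, ]
      if (in_grid(q, d) && gl[q[1], q[2], q[3]] == a) dep <- dep + 1L
    }
    recs[[length(recs) + 1L]] <- c(a, dep)
  }
  rc <- do.call(rbind, recs)
  m <- matrix(0, ng, max(rc[, 2]) + 1L)
  for (i in seq_len(nrow(rc))) {
    m[rc[i, 1], rc[i, 2] + 1L] <- m[rc[i, 1], rc[i, 2] + 1L] + 1
  }
  m
}

# (n_i, s_i) by explicit neighbourhood averaging
oracle_ngtdm <- function(gl, ng) {
  d <- dim(gl)
  nb26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb26 <- nb26[rowSums(abs(nb26)) > 0, ]
  n_i <- numeric(ng)
  s_i <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- gl[x, y, z]
    if (a == 0L) next
    vals <- c()
    for (r in seq_len(nrow(nb26))) {
      q <- c(x, y, z) + nb26[r, ]
      if (in_grid(q, d) && gl[q[1], q[2], q[3]] > 0L) {
        vals <- c(vals, gl[q[1], q[2], q[3]])
      }
    }
    if (length(vals) == 0L) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(vals))
  }
  data.frame(level = 1:ng, n = n_i, s = s_i)
}

# AUC by exhaustive concordant/discordant pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# random small discretized volume with 0 = outside mask
random_gl_volume <- function(dims, ng, p_mask = 0.8) {
  gl <- array(
    ifelse(
      stats::runif(prod(dims)) < p_mask,
      sample.int(ng, prod(dims), replace = TRUE), 0L
    ),
    dim = dims
  )
  if (sum(gl > 0) < 2) gl[c(1, 2)] <- c(1L, ng)
  gl
}

# adjusted Rand index between two partitions (contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
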