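# Independent brute-force oracles (pure R, no calls into the package's
# optimized code paths) and small fixture builders shared across tests.

# 26- or 6-connected components by breadth-first flood fill
brute_components <- function(grid, connectivity = 26) {
  d <- dim(grid)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$di) + abs(offs$dj) + abs(offs$dk) == 1, ]
  idx <- which(grid)
  for (start in idx) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      t <- queue[1]; queue <- queue[-1]
      i <- (t - 1) %% d[1] + 1; j <- ((t - 1) %/% d[1]) %% d[2] + 1
      k <- (t - 1) %/% (d[1] * d[2]) + 1
      for (r in seq_len(nrow(offs))) {
        ii <- i + offs$di[r]; jj <- j + offs$dj[r]; kk <- k + offs$dk[r]
        if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3]) next
        u <- ii + d[1] * (jj - 1) + d[1] * d[2] * (kk - 1)
        if (grid[u] && lab[u] == 0L) { lab[u] <- nxt; queue <- c(queue, u) }
      }
    }
  }
  list(labels = lab, n = nxt)
}

# Euler characteristic by explicit cell enumeration over padded shifts
brute_chi <- function(grid) {
  d <- dim(grid)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- grid
  sh <- function(a, di, dj, dk) {
    p[(2:(d[1] + 2)) + di - 1, (2:(d[2] + 2)) + dj - 1, (2:(d[3] + 2)) + dk - 1, drop = FALSE]
  }
  # vertex (a,b,c) occupied if any of the 8 incident voxels is set
  vert <- sh(p, 0, 0, 0) | sh(p, 1, 0, 0) | sh(p, 0, 1, 0) | sh(p, 0, 0, 1) |
    sh(p, 1, 1, 0) | sh(p, 1, 0, 1) | sh(p, 0, 1, 1) | sh(p, 1, 1, 1)
  ex <- (sh(p, 1, 0, 0) | sh(p, 1, 1, 0) | sh(p, 1, 0, 1) | sh(p, 1, 1, 1))[1:d[1], , , drop = FALSE]
  ey <- (sh(p, 0, 1, 0) | sh(p, 1, 1, 0) | sh(p, 0, 1, 1) | sh(p, 1, 1, 1))[, 1:d[2], , drop = FALSE]
  ez <- (sh(p, 0, 0, 1) | sh(p, 1, 0, 1) | sh(p, 0, 1, 1) | sh(p, 1, 1, 1))[, , 1:d[3], drop = FALSE]
  fx <- (sh(p, 0, 1, 1) | sh(p, 1, 1, 1))[, 1:d[2], 1:d[3], drop = FALSE]
  fy <- (sh(p, 1, 0, 1) | sh(p, 1, 1, 1))[1:d[1], , 1:d[3], drop = FALSE]
  fz <- (sh(p, 1, 1, 0) | sh(p, 1, 1, 1))[1:d[1], 1:d[2], , drop = FALSE]
  sum(vert) - (sum(ex) + sum(ey) + sum(ez)) + (sum(fx) + sum(fy) + sum(fz)) - sum(grid)
}

# boundary voxels by direct 26-neighbour scan
brute_boundary <- function(grid) {
  d <- dim(grid)
  out <- array(FALSE, d)
  for (t in which(grid)) {
    i <- (t - 1) %% d[1] + 1; j <- ((t - 1) %/% d[1]) %% d[2] + 1
    k <- (t - 1) %/% (d[1] * d[2]) + 1
    onb <- FALSE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3] ||
          !grid[ii, jj, kk]) onb <- TRUE
    }
    if (onb) out[t] <- TRUE
  }
  out
}

# Euclidean distance of every pore voxel to the nearest background voxel
# centre (array border counts as background), by exhaustive scan
brute_distance <- function(grid) {
  d <- dim(grid)
  p <- array(TRUE, d + 2L)   # padded background
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- !grid
  bg <- which(p, arr.ind = TRUE)
  out <- array(NA_real_, d)
  for (t in which(grid)) {
    i <- (t - 1) %% d[1] + 2; j <- ((t - 1) %/% d[1]) %% d[2] + 2
    k <- (t - 1) %/% (d[1] * d[2]) + 2
    out[t] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2 + (bg[, 3] - k)^2))
  }
  out
}

# nearest-branch assignment by all-pairs distance scan (ties: smallest id)
brute_nearest_branch <- function(grid, branch_labels) {
  d <- dim(grid)
  out <- array(0L, d)
  sites <- which(branch_labels > 0L, arr.ind = TRUE)
  sl <- branch_labels[branch_labels > 0L]
  o <- order(sl)
  sites <- sites[o, , drop = FALSE]; sl <- sl[o]
  for (t in which(grid)) {
    i <- (t - 1) %% d[1] + 1; j <- ((t - 1) %/% d[1]) %% d[2] + 1
    k <- (t - 1) %/% (d[1] * d[2]) + 1
    d2 <- (sites[, 1] - i)^2 + (sites[, 2] - j)^2 + (sites[, 3] - k)^2
    out[t] <- sl[which.min(d2)]   # which.min takes the first = smallest id
  }
  out
}

# face-adjacency arc counts by double loop over all 6-adjacent voxel pairs
brute_arc_faces <- function(labels) {
  d <- dim(labels)
  acc <- list()
  for (t in which(labels > 0L)) {
    i <- (t - 1) %% d[1] + 1; j <- ((t - 1) %/% d[1]) %% d[2] + 1
    k <- (t - 1) %/% (d[1] * d[2]) + 1
    for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii > d[1] || jj > d[2] || kk > d[3]) next
      a <- labels[t]; b <- labels[ii, jj, kk]
      if (b == 0L || a == b) next
      key <- paste(min(a, b), max(a, b))
      acc[[key]] <- (acc[[key]] %||% 0L) + 1L
    }
  }
  acc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- fixture builders -------------------------------------------------------

line_volume <- function(n, dims = c(n + 2, 3, 3)) {
  g <- array(FALSE, dims)
  g[2:(n + 1), 2, 2] <- TRUE
  g
}

# star skeleton: `arms` arms of `len` voxels from a centre, along cube-corner
# diagonals so voxels of different arms are never 26-adjacent to each other
star_volume <- function(arms, len = 5) {
  w <- 2 * len + 3
  g <- array(FALSE, c(w, w, w))
  c0 <- len + 2
  g[c0, c0, c0] <- TRUE
  dirs <- list(c(1, 1, 1), c(-1, -1, -1), c(1, -1, -1), c(-1, 1, 1),
               c(1, 1, -1), c(-1, -1, 1), c(1, -1, 1), c(-1, 1, -1))
  for (a in seq_len(arms)) {
    u <- dirs[[a]]
    for (s in seq_len(len)) g[c0 + s * u[1], c0 + s * u[2], c0 + s * u[3]] <- TRUE
  }
  g
}

# planar 8-voxel closed octagonal ring: every voxel has exactly two neighbours
ring_volume <- function() {
  g <- array(FALSE, c(5, 5, 3))
  pts <- rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4), c(4, 3), c(4, 2), c(3, 1), c(2, 1))
  for (r in seq_len(nrow(pts))) g[pts[r, 1], pts[r, 2], 2] <- TRUE
  g
}

voxel_coords_of <- function(g) poreskel:::voxel_coords(g)

neighbour_labels_of <- function(lab, idx) {
  d <- dim(lab)
  i <- (idx - 1) %% d[1] + 1; j <- ((idx - 1) %/% d[1]) %% d[2] + 1
  k <- (idx - 1) %/% (d[1] * d[2]) + 1
  out <- integer(0)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    ii <- i + di; jj <- j + dj; kk <- k + dk
    if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3]) next
    out <- c(out, lab[ii, jj, kk])
  }
  out
}

# random connected-ish porous test volume (thin wrapper, fixed params)
small_random_volume <- function(seed, dims = c(12, 12, 12), porosity = 0.35) {
  make_random_porous(dims, porosity, correlation_length = 1.2, seed = seed)
}

# random geometric fixture graph: connected, deterministic per seed
make_fixture_graph <- function(n, seed = 1, extra_arcs = n) {
  poreskel:::with_seed(seed, {
    v <- runif(n, 0.5, 2)
    cx <- runif(n, 0, 20); cy <- runif(n, 0, 20); cz <- runif(n, 0, 20)
    r <- integer(0); s <- integer(0)
    for (t in 2:n) { r <- c(r, sample.int(t - 1L, 1L)); s <- c(s, t) }  # random tree
    tries <- 0L
    while (tries < extra_arcs) {
      a <- sample.int(n, 2L)
      lo <- min(a); hi <- max(a)
      if (!any(r == lo & s == hi)) { r <- c(r, lo); s <- c(s, hi) }
      tries <- tries + 1L
    }
    faces <- sample(1:6, length(r), replace = TRUE)
    dist <- runif(length(r), 1, 3)
    pore_graph(data.frame(id = seq_len(n), volume = v, cx = cx, cy = cy, cz = cz),
               data.frame(r = r, s = s, faces = faces, area_um2 = faces,
                          distance = dist))
  })
}

skeleton_from_mask <- function(mask) {
  structure(list(mask = mask, voxels = poreskel:::voxel_coords(mask),
                 parent_dims = dim(mask), resolution = 1), class = "skeleton")
}
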