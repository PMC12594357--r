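# Seeded generators of 3D fixtures with known topology and geometry.

#' Solid circular tube
#'
#' A solid cylinder (radius in voxels) along one axis, padded by background.
#' Euler characteristic 1, one 26-connected component.
#'
#' @param radius tube radius, voxels (>= 1).
#' @param length tube length, voxels (>= 3).
#' @param axis 1, 2 or 3 (the `k`/depth axis is 3).
#' @param pad background padding on each side, voxels.
#' @param axis_pad padding along the tube axis (0 makes the tube open at the
#'   volume faces, as the plane-injection benchmark requires).
#' @param resolution voxel edge length, micrometres.
#' @return a [voxel_volume()].
#' @export
make_tube <- function(radius, length, axis = 3, pad = 2, axis_pad = pad,
                      resolution = 1) {
  if (radius < 1) stop_config("radius must be >= 1")
  if (length < 3) stop_config("length must be >= 3")
  w <- 2L * (as.integer(radius) + as.integer(pad)) + 1L
  cs <- radius + pad + 1                     # axis centre (1-based)
  a <- seq_len(w) - cs
  disk <- outer(a^2, a^2, `+`) <= radius^2
  d <- c(w, w, as.integer(length) + 2L * as.integer(axis_pad))
  g <- array(FALSE, d)
  for (k in (axis_pad + 1):(axis_pad + length)) g[, , k] <- disk
  g <- aperm(g, order(replace(1:3, c(3, axis), c(axis, 3))))
  voxel_volume(g, resolution)
}

#' Solid torus
#'
#' Voxelized solid torus in the `i`-`j` plane: Euler characteristic 0 (one
#' tunnel), one component.
#'
#' @param major_r major radius (axis circle), voxels.
#' @param minor_r minor (tube) radius, voxels (>= 1, < `major_r`).
#' @param pad background padding.
#' @param resolution voxel edge length, micrometres.
#' @return a [voxel_volume()].
#' @export
make_torus <- function(major_r, minor_r, pad = 2, resolution = 1) {
  if (minor_r < 1 || major_r <= minor_r)
    stop_config("need major_r > minor_r >= 1")
  wxy <- 2L * ceiling(major_r + minor_r + pad) + 1L
  wz <- 2L * ceiling(minor_r + pad) + 1L
  cxy <- (wxy + 1) / 2
  cz <- (wz + 1) / 2
  ii <- slice.index(array(0, c(wxy, wxy, wz)), 1) - cxy
  jj <- slice.index(array(0, c(wxy, wxy, wz)), 2) - cxy
  kk <- slice.index(array(0, c(wxy, wxy, wz)), 3) - cz
  g <- (sqrt(ii^2 + jj^2) - major_r)^2 + kk^2 <= minor_r^2
  voxel_volume(array(g, c(wxy, wxy, wz)), resolution)
}

# union of capsules (segments with radius) — generic rasterizer
rasterize_capsules <- function(dims, segments, radius) {
  ii <- slice.index(array(0, dims), 1)
  jj <- slice.index(array(0, dims), 2)
  kk <- slice.index(array(0, dims), 3)
  g <- array(FALSE, dims)
  for (seg in segments) {
    p <- seg$from; q <- seg$to
    vx <- q - p
    L2 <- sum(vx^2)
    t <- ((ii - p[1]) * vx[1] + (jj - p[2]) * vx[2] + (kk - p[3]) * vx[3]) / L2
    t <- pmin(1, pmax(0, t))
    d2 <- (ii - (p[1] + t * vx[1]))^2 + (jj - (p[2] + t * vx[2]))^2 +
      (kk - (p[3] + t * vx[3]))^2
    g <- g | d2 <= radius^2
  }
  g
}

#' Y-shaped junction of three tubes
#'
#' Three capsule arms of equal radius and length meeting at a common centre
#' (one in-plane up, two down at +/- 120 degrees): Euler characteristic 1,
#' one component, a skeleton with three ending voxels and one junction.
#'
#' @param arm_radius arm radius, voxels.
#' @param arm_length arm length, voxels.
#' @param pad background padding.
#' @param resolution voxel edge length, micrometres.
#' @return a [voxel_volume()].
#' @export
make_y_junction <- function(arm_radius = 2, arm_length = 12, pad = 2,
                            resolution = 1) {
  ext <- arm_length + arm_radius + pad
  w <- 2L * ceiling(ext) + 1L
  ctr <- c((w + 1) / 2, (w + 1) / 2, (w + 1) / 2)
  dirs <- list(c(0, 0, 1),
               c(0, sin(2 * pi / 3), cos(2 * pi / 3)),
               c(0, -sin(2 * pi / 3), cos(2 * pi / 3)))
  segs <- lapply(dirs, function(u) list(from = ctr, to = ctr + arm_length * u))
  g <- rasterize_capsules(c(w, w, w), segs, arm_radius)
  voxel_volume(g, resolution)
}

#' Cube with a concentric cubic cavity
#'
#' A solid cube enclosing a hollow concentric cube — one component plus one
#' cavity, Euler characteristic 2. Defaults give the 10-voxel cube with the
#' 4-voxel cavity spanning (0-based) voxels 3..6 on every axis.
#'
#' @param outer outer cube edge, voxels.
#' @param inner inner (cavity) cube edge, voxels; centred.
#' @param pad background padding.
#' @param resolution voxel edge length, micrometres.
#' @return a [voxel_volume()].
#' @export
make_cavity_cube <- function(outer = 10, inner = 4, pad = 1, resolution = 1) {
  if (inner >= outer - 2) stop_config("cavity must be strictly interior")
  w <- outer + 2L * pad
  g <- array(FALSE, c(w, w, w))
  o <- (pad + 1):(pad + outer)
  g[o, o, o] <- TRUE
  lo <- pad + 1 + (outer - inner) %/% 2
  s <- lo:(lo + inner - 1)
  g[s, s, s] <- FALSE
  voxel_volume(g, resolution)
}

#' Correlated random porous medium
#'
#' Seeded Gaussian white noise smoothed with an isotropic Gaussian kernel of
#' the given correlation length and thresholded at the empirical quantile
#' matching the target porosity. Deterministic per seed; achieved porosity is
#' within +/-1% (absolute) of the target.
#'
#' @param dims integer vector of length 3.
#' @param target_porosity pore fraction in (0, 1).
#' @param correlation_length Gaussian smoothing sigma, voxels.
#' @param seed RNG seed.
#' @param resolution voxel edge length, micrometres.
#' @return a [voxel_volume()].
#' @export
make_random_porous <- function(dims, target_porosity, correlation_length = 2,
                               seed = 1, resolution = 1) {
  if (target_porosity <= 0 || target_porosity >= 1)
    stop_config("target_porosity must lie strictly between 0 and 1")
  dims <- as.integer(dims)
  noise <- with_seed(seed, rnorm(prod(dims)))
  field <- gauss3d_cpp(noise, dims, correlation_length)
  thr <- quantile(field, 1 - target_porosity, names = FALSE)
  voxel_volume(array(field > thr, dims), resolution)
}

#' Generate a fixture from a declarative spec
#'
#' @param spec list with `kind` (one of `tube`, `torus`, `y_junction`,
#'   `cavity_cube`, `random_porous`) and that generator's parameters.
#' @return a [voxel_volume()].
#' @export
make_fixture <- function(spec) {
  kind <- spec$kind
  args <- spec[setdiff(names(spec), "kind")]
  fun <- switch(kind,
                tube = make_tube,
                torus = make_torus,
                y_junction = make_y_junction,
                cavity_cube = make_cavity_cube,
                random_porous = make_random_porous,
                stop_config("unknown fixture kind: ", kind))
  do.call(fun, args)
}
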