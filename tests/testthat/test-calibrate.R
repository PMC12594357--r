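sliced_tube <- function(radius = 4, length = 60, slab = 4) {
  v <- make_tube(radius, length, pad = 2, axis_pad = 0)
  kk <- slice.index(array(0, v$dims), 3)
  lab <- array(0L, v$dims)
  lab[v$grid] <- ((kk[v$grid] - 1L) %/% slab) + 1L
  pt <- partition_from_labels(lab)
  list(volume = v, partition = pt, graph = build_graph(pt))
}

test_that("voxel-level reference: two-voxel exchange, equilibria and conservation", {
  g <- array(FALSE, c(2, 1, 1)); g[1:2, 1, 1] <- TRUE
  v <- voxel_volume(g)
  m0 <- array(0, dim(g)); m0[1, 1, 1] <- 1
  # one step with Dc*dt = 0.1 (voxel^2): c = (0.9, 0.1)
  prof <- voxel_diffusion_reference(v, m0, dc = 0.1 * 86400 / 30, dt = 30,
                                    duration_days = 30 / 86400)
  expect_equal(as.numeric(attr(prof, "mass"))[1:2], c(0.9, 0.1))

  # uniform concentration is stationary
  tube <- make_tube(3, 12, axis_pad = 0)
  u0 <- array(0, tube$dims); u0[tube$grid] <- 2
  p2 <- voxel_diffusion_reference(tube, u0, dc = 500, dt = 30, duration_days = 0.01)
  expect_equal(attr(p2, "mass"), u0, tolerance = 1e-12)

  # conservation under vigorous diffusion (internal sub-stepping engaged)
  r <- voxel_diffusion_reference(tube, 100, dc = 5e4, dt = 30, duration_days = 0.02)
  expect_equal(sum(r), 100, tolerance = 1e-9)
})

test_that("plane profiles spread region mass by plane membership and conserve it", {
  lab <- array(0L, c(3, 3, 5))
  lab[1:2, 1:2, 3] <- 1L                    # region 1 entirely in plane 3
  lab[3, 1:2, 4:5] <- 2L                    # region 2 split over planes 4 and 5
  pt <- partition_from_labels(lab)
  g <- suppressMessages(build_graph(pt))
  st <- bio_state(g, dom = c(5, 4))
  prof <- plane_profile(pt, st)
  expect_equal(as.numeric(prof), c(0, 0, 5, 2, 2))
  expect_equal(sum(prof), sum(st$b[, 2]))
})

test_that("injection benchmark: zero duration and zero conductance freeze the injection", {
  s <- sliced_tube()
  p0 <- run_injection_benchmark(s$volume, s$partition, s$graph, dc = 4000,
                                alpha = 0.5, total_mass = 100,
                                duration_days = 0, dt = 30)
  pa0 <- run_injection_benchmark(s$volume, s$partition, s$graph, dc = 4000,
                                 alpha = 0, total_mass = 100,
                                 duration_days = 0.05, dt = 30)
  expect_equal(as.numeric(p0), as.numeric(pa0))
  expect_equal(sum(p0), 100)
  # everything in the first slab, spread over its 4 planes
  expect_equal(sum(as.numeric(p0)[1:4]), 100)

  bad <- make_tube(3, 10, pad = 2)          # axial padding: empty entry planes
  sk <- curve_skeletonize(bad)
  pt <- assign_regions(bad, segment_branches(sk))
  gg <- build_graph(pt)
  expect_error(run_injection_benchmark(bad, pt, gg, 4000, 0.5, 100, 0.01, 30),
               "first two planes")
})

test_that("long-duration benchmark relaxes to the per-plane pore-count equilibrium", {
  s <- sliced_tube(radius = 3, length = 24)
  prof <- run_injection_benchmark(s$volume, s$partition, s$graph, dc = 4000,
                                  alpha = 1, total_mass = 100,
                                  duration_days = 10, dt = 3600)
  pore_per_plane <- apply(s$volume$grid, 3, sum)
  expect_equal(as.numeric(prof), 100 * pore_per_plane / sum(pore_per_plane),
               tolerance = 1e-4)
})

test_that("calibration recovers a conductance planted via the graph model itself", {
  v <- make_random_porous(c(20, 20, 20), 0.4, 2, seed = 12)
  sk <- curve_skeletonize(v)
  pt <- suppressMessages(assign_regions(v, segment_branches(sk)))
  g <- suppressMessages(build_graph(pt))
  planted <- run_injection_benchmark(v, pt, g, dc = 2000, alpha = 0.5,
                                     total_mass = 100, duration_days = 0.05,
                                     dt = 30)
  cal <- calibrate_alpha(v, pt, g, dc = 2000, total_mass = 100,
                         duration_days = 0.05, dt = 30,
                         alpha_grid = seq(0.1, 1, by = 0.1),
                         reference = planted)
  expect_equal(cal$alpha, 0.5)
  expect_equal(cal$score, 1, tolerance = 1e-9)

  one <- calibrate_alpha(v, pt, g, dc = 2000, total_mass = 100,
                         duration_days = 0.05, dt = 30,
                         alpha_grid = 0.35, reference = planted)
  expect_equal(one$alpha, 0.35)              # single-point grid returns it
})

test_that("on a straight tube the calibrated graph model matches the voxel reference", {
  s <- sliced_tube(radius = 4, length = 60, slab = 4)
  dc <- 4000
  ref <- voxel_diffusion_reference(s$volume, 100, dc, 30, 0.0743)
  cal <- calibrate_alpha(s$volume, s$partition, s$graph, dc, 100, 0.0743, 30,
                         alpha_grid = seq(0.05, 1, by = 0.05), reference = ref)
  expect_gt(cal$score, 0.99)
  # the arg-max beats every other grid point (exhaustive check)
  expect_true(all(cal$table$score <= cal$score + 1e-12))
  # slab chains are the geometry where the region model is exact: the
  # physically exact conductance for slabs of thickness h at distance h is 1
  expect_gte(cal$alpha, 0.9)
  prof <- run_injection_benchmark(s$volume, s$partition, s$graph, dc,
                                  cal$alpha, 100, 0.0743, 30)
  rel_l1 <- sum(abs(as.numeric(prof) - as.numeric(ref))) / sum(ref)
  expect_lt(rel_l1, 0.05)
})

test_that("degenerate constant profiles are rejected", {
  s <- sliced_tube(radius = 3, length = 16)
  flat <- structure(rep(1, s$volume$dims[3]), class = "plane_profile")
  expect_error(calibrate_alpha(s$volume, s$partition, s$graph, 4000, 100,
                               0.01, 30, alpha_grid = 0.5, reference = flat),
               "constant")
})
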