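test_that("distance transform gives exact Euclidean distances to the background", {
  g <- array(FALSE, c(3, 3, 3)); g[2, 2, 2] <- TRUE
  expect_equal(distance_transform(voxel_volume(g))$values[2, 2, 2], 1)

  g <- array(FALSE, c(9, 9, 9)); g[3:7, 3:7, 3:7] <- TRUE
  dm <- distance_transform(voxel_volume(g))
  expect_equal(dm$values[5, 5, 5], 3)          # centre of the 5^3 block
  expect_equal(dm$values[3, 5, 5], 1)          # face-adjacent to background

  for (seed in 1:3) {
    v <- small_random_volume(seed, dims = c(9, 9, 9))
    if (!any(v$grid)) next
    expect_equal(distance_transform(v)$values, brute_distance(v$grid))
  }

  expect_error(distance_transform(voxel_volume(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("Euler characteristic is correct on balls, tori, cavities and random sets", {
  g <- array(FALSE, c(7, 7, 7)); g[2:6, 2:6, 2:6] <- TRUE
  expect_equal(euler_characteristic(voxel_volume(g)), 1)          # solid cube

  expect_equal(euler_characteristic(make_torus(8, 2)), 0)         # genus 1

  # 10-cube minus concentric 4-cube: one component + one cavity
  expect_equal(euler_characteristic(make_cavity_cube()), 2)

  g <- array(FALSE, c(9, 9, 3)); g[2:3, 2:3, 2] <- TRUE; g[6:7, 6:7, 2] <- TRUE
  expect_equal(euler_characteristic(voxel_volume(g)), 2)          # two components

  for (seed in 1:5) {
    v <- small_random_volume(seed, dims = c(8, 8, 8))
    expect_equal(euler_characteristic(v), brute_chi(v$grid))
  }
})

test_that("deletability examples: line middles, isolated voxels, block corners", {
  g <- line_volume(3)
  expect_false(is_deletable(voxel_volume(g), c(3, 2, 2)))  # middle: would split

  g1 <- array(FALSE, c(3, 3, 3)); g1[2, 2, 2] <- TRUE
  expect_false(is_deletable(voxel_volume(g1), c(2, 2, 2))) # isolated: protected

  g2 <- array(FALSE, c(4, 4, 4)); g2[2:3, 2:3, 2:3] <- TRUE
  expect_true(is_deletable(voxel_volume(g2), c(2, 2, 2)))  # 2x2x2 corner

  expect_error(is_deletable(voxel_volume(g2), c(1, 1, 1)), "not in the pore set")
})

test_that("local simple-point test agrees with global Euler/component recomputation", {
  for (seed in 1:6) {
    v <- small_random_volume(seed, dims = c(8, 8, 8), porosity = 0.4)
    g <- v$grid
    chi0 <- brute_chi(g)
    ncomp0 <- brute_components(g)$n
    pores <- which(g, arr.ind = TRUE)
    bm <- brute_boundary(g)
    for (r in seq_len(nrow(pores))) {
      vox <- pores[r, ]
      nnb <- sum(g[max(1, vox[1] - 1):min(8, vox[1] + 1),
                   max(1, vox[2] - 1):min(8, vox[2] + 1),
                   max(1, vox[3] - 1):min(8, vox[3] + 1)]) - 1
      if (nnb < 2 || !bm[vox[1], vox[2], vox[3]]) {
        expect_false(is_deletable(v, vox))     # protected regardless of topology
        next
      }
      g2 <- g; g2[vox[1], vox[2], vox[3]] <- FALSE
      global_ok <- (brute_chi(g2) == chi0) && (brute_components(g2)$n == ncomp0)
      expect_identical(is_deletable(v, vox), global_ok)
    }
  }
})

test_that("thinning leaves one-voxel-wide curves unchanged", {
  g <- line_volume(10)
  sk <- curve_skeletonize(voxel_volume(g))
  expect_identical(sk$mask, g)
})

test_that("tube skeletons are simple paths and torus skeletons closed curves", {
  tube <- make_tube(3, 30)
  sk <- curve_skeletonize(tube)
  cl <- classify_voxels(sk)
  expect_equal(unname(cl$table["ending"]), 2)
  expect_equal(unname(cl$table["interior"]), 0)
  expect_equal(unname(cl$table["simple"]), nrow(sk$voxels) - 2)
  expect_equal(euler_characteristic(voxel_volume(sk$mask)), 1)

  tor <- make_torus(8, 2)
  skt <- curve_skeletonize(tor)
  clt <- classify_voxels(skt)
  expect_equal(unname(clt$table["simple"]), nrow(skt$voxels))  # every voxel has 2 neighbours
  expect_equal(euler_characteristic(voxel_volume(skt$mask)), 0)
})

test_that("skeletonization preserves topology, is idempotent and minimal", {
  fixtures <- list(tube = make_tube(3, 20),
                   torus = make_torus(7, 2),
                   y = make_y_junction(2, 10),
                   cavity = make_cavity_cube())
  for (seed in 1:3)
    fixtures[[paste0("rand", seed)]] <- small_random_volume(seed)

  for (nm in names(fixtures)) {
    v <- fixtures[[nm]]
    sk <- curve_skeletonize(v)
    expect_true(all(v$grid[sk$mask]), info = nm)   # skeleton within pore set
    expect_equal(euler_characteristic(voxel_volume(sk$mask)),
                 euler_characteristic(v), info = nm)
    expect_equal(brute_components(sk$mask)$n, brute_components(v$grid)$n, info = nm)
    # idempotence
    expect_identical(curve_skeletonize(voxel_volume(sk$mask))$mask, sk$mask,
                     info = nm)
    # minimality: no remaining voxel is deletable
    svox <- voxel_coords_of(sk$mask)
    skvol <- voxel_volume(sk$mask)
    del <- vapply(seq_len(nrow(svox)), function(r) is_deletable(skvol, svox[r, ]),
                  logical(1))
    expect_false(any(del), info = nm)
  }
})
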