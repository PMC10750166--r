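test_that("clean_borders removes instances on any of the six faces, exactly", {
  d <- c(8L, 20L, 20L)
  interior <- list(z = 2:7, y = 5:8, x = 5:8)
  # one face at a time: place a small box whose only violation is that face
  cases <- list(
    list(z = c(1, 2),  y = c(5, 8),   x = c(5, 8)),    # first z slice
    list(z = c(7, 8),  y = c(5, 8),   x = c(5, 8)),    # last z slice
    list(z = c(3, 5),  y = c(1, 3),   x = c(5, 8)),    # low y edge
    list(z = c(3, 5),  y = c(18, 20), x = c(5, 8)),    # high y edge
    list(z = c(3, 5),  y = c(5, 8),   x = c(1, 3)),    # low x edge
    list(z = c(3, 5),  y = c(5, 8),   x = c(18, 20)))  # high x edge
  for (cs in cases) {
    lv <- label_volume(make_box(d, cs$z, cs$y, cs$x))
    expect_identical(n_instances(clean_borders(lv)), 0L)
  }
  # fully interior instance is kept with identical voxels
  lv <- label_volume(make_box(d, c(2, 6), c(3, 9), c(3, 9), id = 4L))
  out <- clean_borders(lv)
  expect_identical(out$labels, lv$labels)
})

test_that("the 2-pixel lateral rule is a strict index threshold", {
  d <- c(8L, 20L, 20L)
  # 0-based min index 1 (row 2): within 2 px -> removed
  lv1 <- label_volume(make_box(d, c(3, 5), c(5, 8), c(2, 4)))
  expect_identical(n_instances(clean_borders(lv1)), 0L)
  # 0-based min index 2 (row 3): kept
  lv2 <- label_volume(make_box(d, c(3, 5), c(5, 8), c(3, 5)))
  expect_identical(n_instances(clean_borders(lv2)), 1L)
  # z is a touch rule only: instance on the second z slice is kept
  lv3 <- label_volume(make_box(d, c(2, 3), c(5, 8), c(5, 8)))
  expect_identical(n_instances(clean_borders(lv3)), 1L)
})

test_that("clean_borders is idempotent and only deletes", {
  set.seed(8)
  lv <- random_label_volume(c(10, 24, 24), 6, seed = 8)
  once <- clean_borders(lv)
  twice <- clean_borders(once)
  expect_identical(once$labels, twice$labels)
  kept <- instance_ids(once)
  for (id in kept)
    expect_identical(which(once$labels == id), which(lv$labels == id))
})

test_that("empty criteria are the identity; each criterion measures what it says", {
  d <- c(16L, 40L, 40L)
  ball <- label_volume(make_ball(d, c(8, 20, 20), 7))
  expect_identical(filter_masks(ball, filter_criteria())$labels, ball$labels)

  m <- measure_instances(ball)
  expect_identical(m$size_vox, sum(ball$labels > 0))
  expect_identical(m$z_thickness, 15L)     # slices 1..15 around centre 8
  expect_gt(m$solidity, 0.9)               # a ball is nearly convex
  expect_lt(m$elongation, 1.2)             # and nearly isotropic

  # half-ball: cut everything above the equatorial plane
  half <- ball$labels
  half[, 1:20, ] <- 0L
  mh <- measure_instances(label_volume(half))
  expect_gt(mh$solidity, 0.8)              # a half-ball is still convex
  cup <- ball$labels                       # hollow the core: non-convex
  cz <- slice.index(cup, 1); cy <- slice.index(cup, 2); cx <- slice.index(cup, 3)
  cup[(cz - 8)^2 + (cy - 20)^2 + (cx - 20)^2 <= 5.5^2] <- 0L
  mc <- measure_instances(label_volume(cup))
  expect_lt(mc$solidity, 0.9)

  expect_identical(n_instances(filter_masks(ball, filter_criteria(min_solidity = 0.9))), 1L)
  expect_identical(n_instances(filter_masks(label_volume(cup),
                                            filter_criteria(min_solidity = 0.9))), 0L)
})

test_that("solidity agrees with an independent convex-hull oracle", {
  d <- c(12L, 24L, 24L)
  shapes <- list(
    make_ball(d, c(6, 12, 12), 4.5),
    make_box(d, c(3, 8), c(4, 15), c(6, 12)),
    {
      a <- make_ball(d, c(6, 12, 12), 5)
      a[, , 12:24] <- 0L  # half ball
      a
    })
  for (arr in shapes) {
    cc <- which(arr > 0, arr.ind = TRUE)
    oracle <- scipy_hull_voxel_count(cc)
    skip_if(is.na(oracle), "python/scipy oracle unavailable")
    ours <- germseg:::convex_hull_voxel_count(cc)
    expect_identical(ours, as.integer(oracle))
  }
})

test_that("z-thickness and size filters count directly", {
  d <- c(10L, 20L, 20L)
  thin <- label_volume(make_box(d, c(4, 6), c(5, 10), c(5, 10)))  # 3 slices
  expect_identical(n_instances(filter_masks(thin, filter_criteria(min_z_thickness = 4))), 0L)
  expect_identical(n_instances(filter_masks(thin, filter_criteria(min_z_thickness = 3))), 1L)
  expect_identical(n_instances(filter_masks(thin, filter_criteria(min_size_vox = 109))), 0L)
  expect_identical(n_instances(filter_masks(thin, filter_criteria(min_size_vox = 108))), 1L)
})

test_that("elongation is measured in physical units, so anisotropy is not shape", {
  d <- c(12L, 30L, 30L)
  # sphere sampled on an anisotropy-2.5 grid: flat in voxel z, round in um
  ball <- make_ball(d, c(6, 15, 15), 10 / 2.5, z_scale = 2.5)
  arr <- array(0L, d); arr[ball > 0] <- 1L
  m_aniso <- measure_instances(label_volume(arr), pixel_size_xy_um = 1, z_step_um = 2.5)
  expect_lt(m_aniso$elongation, 1.3)
  # rod along x: strongly elongated whatever the units
  rod <- label_volume(make_box(d, c(5, 7), c(14, 16), c(3, 28)))
  m_rod <- measure_instances(rod, 1, 2.5)
  expect_gt(m_rod$elongation, 3)
  expect_identical(n_instances(filter_masks(rod, filter_criteria(max_elongation = 2), 1, 2.5)), 0L)
})

test_that("single-voxel instances use the stated conventions", {
  arr <- array(0L, c(5, 8, 8)); arr[3, 4, 4] <- 7L
  m <- measure_instances(label_volume(arr))
  expect_identical(m$size_vox, 1L)
  expect_identical(m$z_thickness, 1L)
  expect_identical(m$solidity, 1)
  expect_identical(m$elongation, 1)
})

test_that("tightening any single criterion never increases survivors", {
  lv <- generate_scene(synthetic_scene_spec(volume_shape_vox = c(24, 96, 96),
                                            n_nuclei = 6, seed = 3,
                                            diameter_mean_um = 2))$labels
  counts_for <- function(crit) n_instances(filter_masks(lv, crit, 0.117, 0.3))
  sweep_ok <- function(make_crit, values) {
    n <- sapply(values, function(v) counts_for(make_crit(v)))
    all(diff(n) <= 0L)
  }
  expect_true(sweep_ok(function(v) filter_criteria(min_size_vox = v),
                       c(1, 500, 2000, 1e5)))
  expect_true(sweep_ok(function(v) filter_criteria(min_solidity = v),
                       c(0, 0.5, 0.9, 0.99)))
  expect_true(sweep_ok(function(v) filter_criteria(min_z_thickness = v),
                       c(1, 5, 10, 30)))
  expect_true(sweep_ok(function(v) filter_criteria(max_elongation = v),
                       c(10, 2, 1.2, 1)))
})
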