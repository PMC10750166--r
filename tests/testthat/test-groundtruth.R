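make_view_fixture <- function(seed = 1, dims = c(10, 48, 48)) {
  generate_scene(synthetic_scene_spec(volume_shape_vox = dims,
                                      n_nuclei = 2, seed = seed,
                                      diameter_mean_um = 1.8,
                                      chromatin_blob_diameter_um = 0.5))
}

test_that("xy views pass through exactly; xz/yz views are made isotropic", {
  sc <- make_view_fixture()
  v <- extract_ortho_view(sc$grid, sc$labels, "xy", index = 4)
  expect_identical(v$image, sc$grid$data[4, , ])
  expect_identical(v$mask, sc$labels$labels[4, , ])

  a <- compute_anisotropy(sc$grid$z_step_um, sc$grid$pixel_size_xy_um)
  Z <- dim(sc$grid)[1]
  vxz <- extract_ortho_view(sc$grid, sc$labels, "xz", index = 24)
  expect_identical(ncol(vxz$image), dim(sc$grid)[3])
  expect_true(abs(nrow(vxz$image) - (round((Z - 1) * a) + 1)) <= 1)
  expect_identical(dim(vxz$mask), dim(vxz$image))
  # nearest-neighbour resampling cannot invent label ids
  expect_true(all(unique(as.vector(vxz$mask)) %in% c(0L, instance_ids(sc$labels))))

  vyz <- extract_ortho_view(sc$grid, sc$labels, "yz", index = 10)
  expect_identical(ncol(vyz$image), dim(sc$grid)[2])
  expect_error(extract_ortho_view(sc$grid, NULL, "xy", index = 99), "range")
})

test_that("anisotropy-2 stacks give xz views of height 2Z - 1", {
  g <- voxel_grid(array(runif(8 * 12 * 12), c(8, 12, 12)), 0.117, 0.234)
  v <- extract_ortho_view(g, NULL, "xz", index = 6)
  expect_identical(nrow(v$image), 15L)
})

test_that("split_train_test: 120 -> 108/12, partition, reproducible", {
  items <- sprintf("view_%03d", 1:120)
  sp <- split_train_test(items, test_fraction = 0.1, seed = 5)
  expect_identical(length(sp$train), 108L)
  expect_identical(length(sp$test), 12L)
  expect_identical(sort(c(sp$train, sp$test)), sort(items))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(split_train_test(items, 0.1, seed = 5), sp)
  expect_false(identical(split_train_test(items, 0.1, seed = 6), sp))
  expect_identical(lengths(split_train_test(1:10, 0.5, seed = 1)),
                   c(train = 5L, test = 5L))
  expect_error(split_train_test(1, 0.5), "at least 2")
  expect_error(split_train_test(1:10, 1.5), "test_fraction")
})

test_that("a degenerate augmentation spec is the identity", {
  sc <- make_view_fixture()
  v <- extract_ortho_view(sc$grid, sc$labels, "xy", index = 5)
  spec <- augmentation_spec(p_flip_h = 0, p_flip_v = 0,
                            rotation_range_deg = c(0, 0),
                            noise_sigma_range = c(0, 0),
                            intensity_rescale_range = c(1, 1),
                            blur_range = c(0, 0))
  out <- augment_pair(v, spec, seed = 3)
  expect_equal(out$image, v$image)
  expect_identical(out$mask, v$mask)
})

test_that("flips preserve mask voxel counts exactly", {
  sc <- make_view_fixture(seed = 2)
  v <- extract_ortho_view(sc$grid, sc$labels, "xy", index = 5)
  spec <- augmentation_spec(p_flip_h = 1, p_flip_v = 1,
                            rotation_range_deg = c(0, 0),
                            noise_sigma_range = c(0, 0),
                            intensity_rescale_range = c(1, 1),
                            blur_range = c(0, 0))
  out <- augment_pair(v, spec, seed = 3)
  expect_identical(table(out$mask[out$mask > 0]), table(v$mask[v$mask > 0]))
  expect_equal(sum(out$image), sum(v$image))
})

test_that("a pinned 90-degree rotation is a lattice bijection on square views", {
  img <- matrix(runif(48 * 48), 48, 48)
  msk <- matrix(0L, 48, 48)
  msk[10:20, 8:19] <- 1L; msk[30:41, 30:40] <- 2L
  v <- structure(list(image = img, mask = msk, orientation = "xy",
                      source_id = "fix", pixel_size_um = 0.117),
                 class = "ortho_view")
  spec <- augmentation_spec(p_flip_h = 0, p_flip_v = 0,
                            rotation_range_deg = c(90, 90),
                            noise_sigma_range = c(0, 0),
                            intensity_rescale_range = c(1, 1),
                            blur_range = c(0, 0))
  out <- augment_pair(v, spec, seed = 8)
  expect_identical(sort(unique(as.vector(out$mask))), c(0L, 1L, 2L))
  expect_identical(as.vector(table(out$mask[out$mask > 0])),
                   as.vector(table(msk[msk > 0])))
  expect_equal(sum(out$image), sum(img), tolerance = 1e-9)
})

test_that("geometric transforms never grow the label set; photometrics leave masks alone", {
  sc <- make_view_fixture(seed = 3)
  v <- extract_ortho_view(sc$grid, sc$labels, "xy", index = 5)
  spec <- augmentation_spec(seed = 1)
  for (seed in 1:10) {
    out <- augment_pair(v, spec, seed = seed)
    expect_true(all(unique(as.vector(out$mask)) %in% c(0L, unique(as.vector(v$mask)))))
    expect_identical(dim(out$image), dim(v$image))
    expect_identical(dim(out$mask), dim(v$mask))
  }
})

test_that("all sampled augmentation parameters fall inside the spec ranges", {
  sc <- make_view_fixture(seed = 4)
  v <- extract_ortho_view(sc$grid, sc$labels, "xy", index = 5)
  spec <- augmentation_spec(rotation_range_deg = c(10, 80),
                            noise_sigma_range = c(0.01, 0.05),
                            intensity_rescale_range = c(0.9, 1.1),
                            blur_range = c(0.5, 3))
  for (seed in 1:25) {
    p <- attr(augment_pair(v, spec, seed = seed), "params")
    expect_true(p$rotation_deg >= 10 && p$rotation_deg <= 80)
    expect_true(p$noise_sigma >= 0.01 && p$noise_sigma <= 0.05)
    expect_true(p$intensity_factor >= 0.9 && p$intensity_factor <= 1.1)
    expect_true(p$blurfactor >= 0.5 && p$blurfactor <= 3)
    expect_true(is.logical(p$flip_h) && is.logical(p$flip_v))
  }
})

test_that("build_training_set emits originals + variants with a reproducible manifest", {
  sc <- make_view_fixture(seed = 5)
  views <- c(
    lapply(c(3, 5, 7), function(i) extract_ortho_view(sc$grid, sc$labels, "xy", i,
                                                      source_id = paste0("xy", i))),
    lapply(c(20, 30), function(i) extract_ortho_view(sc$grid, sc$labels, "xz", i,
                                                     source_id = paste0("xz", i))),
    list(extract_ortho_view(sc$grid, sc$labels, "yz", 25, source_id = "yz25")))
  spec <- augmentation_spec(n_augment_per_image = 2L, seed = 7)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- build_training_set(views, spec, d1)
  m2 <- build_training_set(views, spec, d2)
  expect_identical(m1, m2)
  # 6 views x (1 original + 2 variants) image/mask pairs
  expect_length(list.files(d1, pattern = "_img[.]tif$"), 18L)
  expect_length(list.files(d1, pattern = "_masks[.]tif$"), 18L)
  expect_identical(nrow(m1), 18L)
  # orientation counts recoverable from the manifest (3/2/1 pattern here)
  expect_identical(as.vector(table(m1$orientation[m1$variant == 0])), c(3L, 2L, 1L))
  # byte-identical emitted files across runs with the same seed
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  cfg <- yaml::read_yaml(file.path(d1, "training_config.yml"))
  expect_identical(cfg$n_epochs, 500L)
  expect_identical(cfg$learning_rate, 0.05)
  expect_identical(cfg$min_train_masks, 2L)
})

test_that("the frozen training-config record carries the published hyperparameters", {
  cfg <- training_config_record()
  expect_identical(cfg, list(n_epochs = 500L, momentum = 0.9, weight_decay = 1e-05,
                             learning_rate = 0.05, min_train_masks = 2L,
                             normalize = TRUE, rescale = TRUE))
})
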