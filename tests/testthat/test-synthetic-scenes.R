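test_that("empty scene renders a constant background", {
  cfg <- scene_config(grid_shape = c(32, 32, 4), n_aggregates = 0,
                      n_planktonic = 0, noise_sd = 0, blur_sigma = 0,
                      depth_attenuation = 0, background_level = 10,
                      planktonic_intensity = 20, aggregate_intensity = 30)
  sc <- generate_scene(cfg)
  expect_true(all(sc$stack$data == 10))
  expect_equal(nrow(sc$truth$objects), 0)
  expect_true(all(sc$truth$label_volume == 0L))
})

test_that("a voxelized sphere matches the analytic volume", {
  # one sphere of radius 5 um on a (1, 1, 1) grid: 4/3*pi*125 ~ 523.6
  cfg <- scene_config(grid_shape = c(48, 48, 24), voxel_size = c(1, 1, 1),
                      n_aggregates = 1, n_planktonic = 0,
                      volume_range = c(523.6, 523.7),
                      volume_distribution = list(name = "lognormal",
                                                 meanlog = log(523.6),
                                                 sdlog = 1e-6),
                      aspect_ratio_range = c(1, 1), noise_sd = 0,
                      blur_sigma = 0, depth_attenuation = 0, rng_seed = 3)
  sc <- generate_scene(cfg)
  vc <- sc$truth$objects$voxel_count[1]
  expect_lt(abs(vc - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.15)
})

test_that("identical config and seed give bit-identical scenes", {
  cfg <- clean_scene_config(99, n_aggregates = 3, noise_sd = 5,
                            blur_sigma = 0.5)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$label_volume, b$truth$label_volume)
  expect_identical(a$truth$objects, b$truth$objects)
})

test_that("truth voxel volumes track the analytic ellipsoid volumes", {
  for (seed in 1:5) {
    sc <- generate_scene(clean_scene_config(seed, n_aggregates = 6))
    ob <- sc$truth$objects
    big <- ob[ob$voxel_count >= 100, ]
    expect_true(all(abs(big$volume_voxel_um3 - big$volume_analytic_um3) /
                      big$volume_analytic_um3 <= 0.15))
    # every nonzero label appears exactly once in the object table
    labs <- setdiff(unique(as.vector(sc$truth$label_volume)), 0L)
    expect_setequal(labs, ob$id)
  }
})

test_that("non-touching placements never overlap or abut", {
  sc <- generate_scene(clean_scene_config(5, n_aggregates = 6,
                                          n_planktonic = 15))
  lab <- sc$truth$label_volume
  # dilating any object by one voxel (6-connectivity) must meet no other
  d <- dim(lab)
  idx <- which(lab > 0L)
  for (off in c(1L, -1L, d[1], -d[1], d[1] * d[2], -d[1] * d[2])) {
    nb <- idx + off
    ok <- nb >= 1L & nb <= length(lab)
    pairs <- cbind(lab[idx[ok]], lab[nb[ok]])
    pairs <- pairs[pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
    expect_equal(nrow(pairs), 0)
  }
})

test_that("touching pairs share a face and zero interior voxels", {
  sc <- generate_scene(clean_scene_config(8, n_aggregates = 6, touching = 1,
                                          vr = c(300, 1200)))
  ob <- sc$truth$objects
  lab <- sc$truth$label_volume
  d <- dim(lab)
  pairs <- ob[!is.na(ob$touching_partner) & ob$id < ob$touching_partner, ]
  expect_gte(nrow(pairs), 1)
  for (k in seq_len(nrow(pairs))) {
    a <- which(lab == pairs$id[k])
    b <- which(lab == pairs$touching_partner[k])
    expect_length(intersect(a, b), 0)
    adj <- FALSE
    for (off in c(1L, -1L, d[1], -d[1], d[1] * d[2], -d[1] * d[2]))
      if (any((a + off) %in% b)) adj <- TRUE
    expect_true(adj)
  }
})

test_that("increasing noise strictly decreases the SNR estimate", {
  snrs <- vapply(c(5, 10, 20, 40), function(s) {
    estimate_snr(generate_scene(clean_scene_config(21, noise_sd = s)))
  }, 0)
  expect_true(all(diff(snrs) < 0))
})

test_that("impossible placements fail with an actionable error", {
  cfg <- scene_config(grid_shape = c(24, 24, 6), voxel_size = c(1, 1, 2),
                      n_aggregates = 40, n_planktonic = 0,
                      volume_range = c(500, 1000), noise_sd = 0,
                      blur_sigma = 0)
  expect_error(generate_scene(cfg), "n_aggregates|grid_shape")
})

test_that("scene_config rejects inconsistent parameters", {
  expect_error(scene_config(aggregate_intensity = 50,
                            planktonic_intensity = 60), "intensity")
  expect_error(scene_config(touching_pair_fraction = 1.5), "touching")
  expect_error(scene_config(grid_shape = c(0, 10, 10)), "grid_shape")
  expect_error(scene_config(voxel_size = c(1, -1, 2)), "voxel_size")
})

test_that("mosaic tiles partition the full image exactly", {
  cfg <- scene_config(grid_shape = c(96, 96, 1), voxel_size = c(1, 1, 1),
                      n_aggregates = 5, n_planktonic = 8,
                      volume_range = c(100, 400), noise_sd = 3,
                      blur_sigma = 0, rng_seed = 2)
  mo1 <- generate_mosaic(cfg, tiles = c(1, 1))
  expect_identical(mo1$tiles[[1]], mo1$full)
  mo <- generate_mosaic(cfg, tiles = c(2, 2))
  re <- assemble_tiles(mo$tiles, c(2, 2), pixel_size = 1)
  expect_identical(re$data, mo$full)
  expect_error(generate_mosaic(cfg, tiles = c(5, 2)), "divide")
})

test_that("mosaic truth lists every placed object with its disk area", {
  cfg <- scene_config(grid_shape = c(128, 128, 1), voxel_size = c(1, 1, 1),
                      n_aggregates = 7, n_planktonic = 0,
                      volume_range = c(150, 500), noise_sd = 0,
                      blur_sigma = 0, rng_seed = 4)
  mo <- generate_mosaic(cfg, tiles = c(2, 2))
  ob <- mo$truth$objects
  expect_equal(sum(ob$class == "aggregate"), 7)
  big <- ob[ob$pixel_count >= 100, ]
  expect_true(all(abs(big$area_pixel_um2 - big$area_analytic_um2) /
                    big$area_analytic_um2 <= 0.15))
})
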