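# build a plane-label list from a list of per-plane coordinate sets
planes_from_coords <- function(coord_sets, ny, nx) {
  lapply(coord_sets, function(objs) {
    lab <- matrix(0L, ny, nx)
    for (i in seq_along(objs)) lab[objs[[i]]] <- i
    lab
  })
}

test_that("a perfectly stacked column links into one aggregate", {
  sq <- as.matrix(expand.grid(y = 5:9, x = 5:9))
  planes <- planes_from_coords(rep(list(list(sq)), 10), 16, 16)
  vol <- link_planes(planes)
  expect_equal(max(vol), 1)
  rec <- filter_by_size(vol, c(1, 1, 1), 0)$records
  expect_equal(rec$z_extent, 10)
  expect_equal(rec$voxel_count, 250)
})

test_that("laterally disjoint columns stay separate aggregates", {
  a <- as.matrix(expand.grid(y = 2:4, x = 2:4))
  b <- as.matrix(expand.grid(y = 10:12, x = 10:12))
  planes <- planes_from_coords(rep(list(list(a, b)), 4), 16, 16)
  expect_equal(max(link_planes(planes)), 2)
})

test_that("a Y-shaped overlap merges transitively into one aggregate", {
  a <- as.matrix(expand.grid(y = 2:4, x = 2:4))
  b <- as.matrix(expand.grid(y = 2:4, x = 8:10))
  bridge <- as.matrix(expand.grid(y = 2:4, x = 2:10))
  planes <- planes_from_coords(list(list(a, b), list(bridge)), 16, 16)
  expect_equal(max(link_planes(planes)), 1)
})

test_that("linking agrees with an igraph closure oracle on random stacks", {
  # oracle: nodes = (z, label) objects, edges = footprint overlaps >= k,
  # components via igraph — an independent transitive-closure route
  withr::with_seed(13, {
    for (rep in 1:5) {
      planes <- lapply(1:6, function(z) {
        m <- matrix(runif(20 * 20) < 0.25, 20, 20)
        label_plane(m, 8)
      })
      vol <- link_planes(planes, overlap_min_voxels = 1)
      nodes <- character(0)
      edges <- character(0)
      for (z in 1:6) {
        k <- max(planes[[z]])
        if (k > 0) nodes <- c(nodes, paste(z, seq_len(k)))
        if (z < 6) {
          a <- planes[[z]]; b <- planes[[z + 1]]
          sel <- a > 0 & b > 0
          if (any(sel)) {
            ov <- unique(cbind(a[sel], b[sel]))
            edges <- c(edges, rbind(paste(z, ov[, 1]),
                                    paste(z + 1, ov[, 2])))
          }
        }
      }
      g <- igraph::make_empty_graph(directed = FALSE)
      g <- igraph::add_vertices(g, length(nodes), name = nodes)
      if (length(edges)) g <- igraph::add_edges(g, match(edges, nodes))
      expect_equal(max(vol), igraph::components(g)$no)
    }
  })
})

test_that("overlap_min_voxels gates weak links", {
  a <- as.matrix(expand.grid(y = 2:5, x = 2:5))       # 16 px
  b <- as.matrix(expand.grid(y = 5:8, x = 5:8))       # overlaps a in 1 px
  planes <- planes_from_coords(list(list(a), list(b)), 12, 12)
  expect_equal(max(link_planes(planes, overlap_min_voxels = 1)), 1)
  expect_equal(max(link_planes(planes, overlap_min_voxels = 2)), 2)
})

test_that("size filtering keeps exactly the in-range volumes", {
  # blobs of 10, 100 and 1000 voxels at (1, 1, 1) um -> 10/100/1000 um^3
  vol <- array(0L, c(20, 20, 10))
  vol[1:2, 1:5, 1] <- 1L                 # 10 voxels
  vol[11:20, 1:10, 2] <- 2L              # 100
  vol[1:10, 11:20, 1:10] <- 3L           # 1000
  set1 <- filter_by_size(vol, c(1, 1, 1), min_object_volume = 50)
  expect_setequal(set1$records$volume_um3, c(100, 1000))
  expect_equal(set1$removed$volume_um3, 10)
  expect_equal(set1$removed$reason, "below_min_volume")
  set2 <- filter_by_size(vol, c(1, 1, 1), min_object_volume = 50,
                         max_cluster_volume = 500)
  expect_equal(set2$records$volume_um3, 100)
  expect_setequal(set2$removed$reason,
                  c("below_min_volume", "above_max_volume"))
  # zero cutoff is the identity
  set0 <- filter_by_size(vol, c(1, 1, 1), min_object_volume = 0)
  expect_equal(nrow(set0$records), 3)
  expect_equal(nrow(set0$removed), 0)
  expect_error(filter_by_size(vol, c(1, 1, 1), 600, 500), "exceeds")
})

test_that("no voxel vanishes silently through filtering", {
  sc <- generate_scene(clean_scene_config(4, n_aggregates = 4,
                                          n_planktonic = 20))
  cfg <- run_config(intensity_threshold = 40, min_object_volume = 100)
  pl <- segment_planes(sc$stack, cfg)
  vol <- link_planes(pl, cfg$overlap_min_voxels)
  set <- filter_by_size(vol, sc$stack$voxel_size, cfg$min_object_volume)
  n_before <- sum(vol > 0L)
  n_kept <- sum(set$label_volume > 0L)
  n_logged <- sum(set$removed$voxel_count)
  expect_equal(n_kept + n_logged, n_before)
})

test_that("segment_stack recovers clean scenes exactly and deterministically", {
  sc <- generate_scene(clean_scene_config(6, n_aggregates = 5,
                                          n_planktonic = 12))
  cfg <- run_config(min_object_volume = 50)
  set1 <- segment_stack(sc$stack, cfg)
  set2 <- segment_stack(sc$stack, cfg)
  expect_identical(set1$records, set2$records)
  expect_identical(set1$label_volume, set2$label_volume)
  ob <- sc$truth$objects
  agg <- ob[ob$class == "aggregate", ]
  expect_equal(nrow(set1$records), nrow(agg))
  expect_setequal(set1$records$voxel_count, agg$voxel_count)
  # volumes within 15% of the analytic ellipsoid volumes
  v <- sort(set1$records$volume_um3)
  va <- sort(agg$volume_analytic_um3)
  expect_true(all(abs(v - va) / va <= 0.15))
})

test_that("a scene of only planktonic cells yields no aggregates", {
  sc <- generate_scene(clean_scene_config(9, n_aggregates = 0,
                                          n_planktonic = 30))
  set <- segment_stack(sc$stack, run_config(intensity_threshold = 40,
                                            min_object_volume = 50))
  expect_equal(nrow(set$records), 0)
  expect_gt(nrow(set$removed), 0)  # cells were seen, logged, filtered
})

test_that("volumes are stable under a finer z sampling of the same scene", {
  # same physical scene rendered at dz = 2 (nz = 16) and dz = 1 (nz = 32):
  # placement happens in physical units, so the object set is identical
  mk <- function(nz, dz) {
    generate_scene(scene_config(grid_shape = c(96L, 96L, nz),
                                voxel_size = c(1, 1, dz), n_aggregates = 4,
                                n_planktonic = 0, volume_range = c(300, 1200),
                                noise_sd = 0, blur_sigma = 0,
                                depth_attenuation = 0, rng_seed = 15))
  }
  coarse <- mk(16L, 2)
  fine <- mk(32L, 1)
  expect_equal(coarse$truth$objects$center_x_um, fine$truth$objects$center_x_um)
  s1 <- segment_stack(coarse$stack, run_config(min_object_volume = 50))
  s2 <- segment_stack(fine$stack, run_config(min_object_volume = 50))
  expect_equal(nrow(s1$records), nrow(s2$records))
  m1 <- s1$records[order(s1$records$centroid_x_um), ]
  m2 <- s2$records[order(s2$records$centroid_x_um), ]
  expect_true(all(abs(m1$volume_um3 - m2$volume_um3) / m2$volume_um3 < 0.10))
})
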