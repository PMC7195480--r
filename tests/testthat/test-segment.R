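test_that("3D labeling distinguishes 6- and 26-connectivity", {
  m <- array(FALSE, c(3, 4, 4))
  m[2, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE  # diagonal neighbor in-plane
  expect_equal(max(label_components_3d(m, 26)), 1)
  expect_equal(max(label_components_3d(m, 6)), 2)
})

test_that("labeling agrees with an independent per-voxel flood fill", {
  set.seed(3)
  m <- array(runif(10 * 12 * 12) < 0.2, c(10, 12, 12))
  for (conn in c(6, 26)) {
    ours <- label_components_3d(m, conn)
    oracle <- oracle_flood_fill(m, conn)
    expect_equal(max(ours), max(oracle))
    # identical partitions (label ids may differ)
    key <- paste(ours[m], oracle[m])
    expect_equal(length(unique(key)), max(ours))
  }
})

test_that("an all-zero stack yields no objects", {
  st <- toy_stack()
  lv <- segment_mitochondria(st)
  expect_equal(lv$object_count, 0)
})

test_that("even or tiny block sizes are configuration errors", {
  st <- toy_stack()
  expect_error(segment_mitochondria(st, block_size = 50),
               class = "mitofret_config_error")
  expect_error(segment_mitochondria(st, block_size = 1),
               class = "mitofret_config_error")
})

test_that("size constraint removes objects outside the physical window", {
  st <- toy_stack(nz = 5, ny = 40, nx = 40)  # 1 um voxels
  st$channels$CFP[3, 5:10, 5:10] <- 100      # 36 um^3 blob
  st$channels$YFP[3, 5:10, 5:10] <- 100
  st$channels$CFP[3, 30, 30] <- 100          # 1 um^3 blob
  st$channels$YFP[3, 30, 30] <- 100
  lv <- segment_mitochondria(st, block_size = 21, min_size = 2,
                             erode_px = 0)
  expect_equal(lv$object_count, 1)
  expect_true(all(which(lv$labels == 1) %in%
                    which(array(st$channels$CFP > 0, dim(st$channels$CFP)))))
  # with a permissive window both survive
  lv2 <- segment_mitochondria(st, block_size = 21, min_size = 0.5,
                              erode_px = 0)
  expect_equal(lv2$object_count, 2)
})

test_that("segmentation recovers synthetic objects with sub-um centroids", {
  sim <- generate_stack(n_objects = 25, dims = c(12, 160, 160), seed = 21)
  res <- process_stack(sim$stack)
  ev <- evaluate_segmentation(res$labels, sim$truth$labels)
  expect_gte(mean(ev$detected), 0.9)
  expect_gte(mean(ev$iou[ev$detected]), 0.7)
  expect_lt(max(ev$centroid_error_um, na.rm = TRUE), 1)
})

test_that("noise-free segmentation reproduces every object voxel-exactly", {
  sim <- generate_stack(n_objects = 20, dims = c(10, 160, 160),
                        poisson = FALSE, read_sd = 0, seed = 5)
  res <- process_stack(sim$stack)
  ev <- evaluate_segmentation(res$labels, sim$truth$labels)
  expect_true(all(ev$detected))
  expect_true(all(ev$iou >= 0.7))
})

test_that("segmentation is invariant to a common intensity scaling", {
  sim <- generate_stack(n_objects = 12, dims = c(8, 128, 128), seed = 9)
  res1 <- process_stack(sim$stack)
  scaled <- sim$stack
  scaled$channels$CFP <- scaled$channels$CFP * 5.3
  scaled$channels$YFP <- scaled$channels$YFP * 5.3
  res2 <- process_stack(scaled)
  expect_identical(res1$labels$labels, res2$labels$labels)
})

test_that("every labeled object is 3D-connected (flood-fill oracle)", {
  sim <- generate_stack(n_objects = 10, dims = c(8, 96, 96), seed = 13)
  res <- process_stack(sim$stack)
  for (k in seq_len(res$labels$object_count)) {
    mk <- res$labels$labels == k
    expect_equal(max(oracle_flood_fill(mk, 26)), 1)
  }
})

test_that("threshold-mode plaque extraction recovers a synthetic sphere", {
  plq <- tibble::tibble(center_z_um = 20, center_y_um = 20, center_x_um = 20,
                        radius_um = 15)
  sim <- generate_stack(n_objects = 5, dims = c(40, 40, 40),
                        voxel_size = c(1, 1, 1), plaques = plq,
                        min_separation_um = 5, poisson = FALSE, read_sd = 0,
                        seed = 2)
  ps <- extract_plaques(sim$stack, mode = "threshold")
  expect_equal(ps$n_plaques, 1)
  vol <- plaque_table(ps)$volume_um3
  expect_lt(abs(vol / (4 / 3 * pi * 15^3) - 1), 0.1)
})

test_that("an empty plaque channel gives an empty plaque set", {
  st <- toy_stack()
  st$channels$RED <- array(0, dim(st$channels$CFP))
  ps <- extract_plaques(st, mode = "threshold")
  expect_equal(ps$n_plaques, 0)
  expect_equal(nrow(ps$edges), 0)
})

test_that("mask-mode plaque extraction reproduces the supplied mask", {
  st <- toy_stack(nz = 6, ny = 20, nx = 20)
  mask <- array(FALSE, c(6, 20, 20))
  mask[2:4, 5:8, 5:8] <- TRUE
  ps <- extract_plaques(st, mode = "mask", mask = mask)
  expect_equal(ps$n_plaques, 1)
  expect_identical(ps$labels > 0, mask)
  expect_error(extract_plaques(st, mode = "mask"))
})
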