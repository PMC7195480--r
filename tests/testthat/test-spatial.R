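# A small stack with one or two spherical plaques, built through the
# generator's plaque renderer and extracted in threshold mode.
make_plaques <- function(centers, radii, dims = c(40, 40, 40),
                         voxel = c(1, 1, 1)) {
  plq <- tibble::tibble(center_z_um = centers[, 1],
                        center_y_um = centers[, 2],
                        center_x_um = centers[, 3],
                        radius_um = radii)
  sim <- generate_stack(n_objects = 2, dims = dims, voxel_size = voxel,
                        plaques = plq, poisson = FALSE, read_sd = 0,
                        min_separation_um = 3, seed = 1)
  extract_plaques(sim$stack, mode = "threshold")
}

obj_at <- function(z, y, x, ratio = 0.7) {
  tibble::tibble(centroid_z_um = z, centroid_y_um = y, centroid_x_um = x,
                 ratio = ratio)
}

test_that("distance to a synthetic sphere matches analytic geometry", {
  ps <- make_plaques(matrix(c(20, 20, 20), 1), 10)
  # centroid 15 um from the sphere center -> 5 um from the surface
  d <- distance_to_plaques(obj_at(20, 20, 35), ps)$distance_um
  expect_lt(abs(d - 5), sqrt(3))  # within one (diagonal) voxel
  # centroid inside the plaque -> 0
  expect_equal(distance_to_plaques(obj_at(20, 20, 22), ps)$distance_um, 0)
})

test_that("the nearest of several plaques wins", {
  ps <- make_plaques(matrix(c(20, 10, 10, 20, 32, 32), 2, byrow = TRUE),
                     c(4, 4))
  o <- distance_to_plaques(obj_at(20, 16, 16), ps)
  expect_equal(o$nearest_plaque_id, 1)
  d1 <- sqrt(2 * 6^2) - 4
  expect_lt(abs(o$distance_um - d1), sqrt(3))
})

test_that("distances scale linearly with voxel size", {
  ps1 <- make_plaques(matrix(c(20, 20, 20), 1), 8)
  ps2 <- make_plaques(matrix(c(40, 40, 40), 1), 16, voxel = c(2, 2, 2))
  d1 <- distance_to_plaques(obj_at(20, 20, 36), ps1)$distance_um
  d2 <- distance_to_plaques(obj_at(40, 40, 72), ps2)$distance_um
  expect_equal(d2, 2 * d1, tolerance = 0.15)
})

test_that("implementation agrees with a brute-force all-pairs oracle", {
  ps <- make_plaques(matrix(c(10, 12, 14), 1), 5, dims = c(20, 24, 28))
  objs <- obj_at(c(3, 10, 17), c(4, 20, 6), c(5, 25, 20))
  d <- distance_to_plaques(objs, ps)$distance_um
  # oracle: explicit loop over every edge voxel
  e <- ps$edges
  for (i in 1:3) {
    dd <- Inf
    for (j in seq_len(nrow(e)))
      dd <- min(dd, sqrt((e$z_um[j] - objs$centroid_z_um[i])^2 +
                         (e$y_um[j] - objs$centroid_y_um[i])^2 +
                         (e$x_um[j] - objs$centroid_x_um[i])^2))
    expect_equal(d[i], dd)
  }
})

test_that("empty plaque sets yield missing distances with a warning", {
  st <- toy_stack()
  st$channels$RED <- array(0, dim(st$channels$CFP))
  ps <- extract_plaques(st, mode = "threshold")
  expect_warning(o <- distance_to_plaques(obj_at(1, 1, 1), ps), "empty")
  expect_true(is.na(o$distance_um))
})

test_that("binned overload is zero everywhere when nothing exceeds", {
  objs <- tibble::tibble(ratio = runif(200, 0.6, 0.8),
                         distance_um = runif(200, 0, 99),
                         nearest_plaque_id = 1L)
  tab <- overload_vs_distance(objs, 0.99)
  expect_true(all(tab$overload_pct[tab$n > 0] == 0))
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$n_overload <= tab$n))
  expect_error(overload_vs_distance(objs, 0.99, bin_width = 0),
               class = "mitofret_config_error")
})

test_that("distance-independent overload stays flat across bins", {
  set.seed(31)
  n <- 8000
  p <- 0.15
  objs <- tibble::tibble(
    ratio = ifelse(runif(n) < p, 1.2, 0.7),
    distance_um = runif(n, 0, 100),
    nearest_plaque_id = sample(1:31, n, replace = TRUE)
  )
  tab <- overload_vs_distance(objs, 0.99)
  # every bin within a 4-sigma binomial envelope of p
  se <- sqrt(p * (1 - p) / tab$n)
  expect_true(all(abs(tab$overload_pct / 100 - p) < 4 * se))
})

test_that("spatially confined overload shows up only in near bins", {
  set.seed(32)
  n <- 4000
  d <- runif(n, 0, 100)
  objs <- tibble::tibble(
    ratio = ifelse(d < 30 & runif(n) < 0.3, 1.2, 0.7),
    distance_um = d,
    nearest_plaque_id = sample(1:10, n, replace = TRUE)
  )
  tab <- overload_vs_distance(objs, 0.99)
  expect_true(all(tab$overload_pct[tab$bin_hi <= 30] > 0))
  expect_true(all(tab$overload_pct[tab$bin_lo >= 30] == 0))
})

test_that("Kruskal-Wallis H matches the explicit ranking oracle", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  res <- kruskal_rank_test(v, g)
  expect_equal(res$statistic, oracle_kruskal_h(v, g), tolerance = 1e-12)
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)  # 3.857
  expect_equal(res$df, 1)
  # with ties, oracle and implementation still agree
  set.seed(2)
  vt <- sample(1:5, 40, replace = TRUE)
  gt <- rep(1:4, each = 10)
  expect_equal(kruskal_rank_test(vt, gt)$statistic,
               oracle_kruskal_h(vt, gt), tolerance = 1e-12)
})

test_that("identical constant groups give H = 0 and p = 1", {
  res <- kruskal_rank_test(rep(2.5, 12), rep(1:3, each = 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  expect_error(kruskal_rank_test(1:5, rep("a", 5)),
               class = "mitofret_test_precondition")
})

test_that("overload_distance_test runs on per-plaque bins", {
  set.seed(33)
  n <- 3000
  objs <- tibble::tibble(
    ratio = ifelse(runif(n) < 0.1, 1.2, 0.7),
    distance_um = runif(n, 0, 100),
    nearest_plaque_id = sample(1:31, n, replace = TRUE)
  )
  res <- overload_distance_test(objs, 0.99)
  expect_true(res$p.value > 0 && res$p.value <= 1)
  expect_s3_class(attr(res, "bin_table"), "tbl_df")
})
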