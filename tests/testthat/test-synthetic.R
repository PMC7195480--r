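test_that("generators are pure functions of their seed", {
  s1 <- generate_stack(n_objects = 8, dims = c(6, 64, 64), seed = 77)
  s2 <- generate_stack(n_objects = 8, dims = c(6, 64, 64), seed = 77)
  expect_identical(s1$stack$channels, s2$stack$channels)
  expect_identical(s1$truth$objects, s2$truth$objects)
  expect_identical(generate_cohort(seed = 5), generate_cohort(seed = 5))
  expect_identical(generate_longitudinal(seed = 5),
                   generate_longitudinal(seed = 5))
  expect_identical(generate_timelapse(noise_sd = 0.1, seed = 5),
                   generate_timelapse(noise_sd = 0.1, seed = 5))
  t1 <- generate_titration(noise_cv = 0.01, seed = 5)
  expect_identical(t1, generate_titration(noise_cv = 0.01, seed = 5))
})

test_that("seeded generation leaves the global RNG stream untouched", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(generate_stack(n_objects = 5, dims = c(6, 64, 64), seed = 9))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("titration tables follow the forward model exactly at zero noise", {
  crv <- default_calibration()
  tt <- generate_titration(crv)
  expect_equal(nrow(tt), 13)
  expect_equal(tt$free_ca_um[1], 0)
  expect_equal(tt$ratio[1], crv$r_min)
  expect_equal(tt$ratio, ca_to_ratio(tt$free_ca_um * 1000, crv))
  expect_error(generate_titration(conc_um = c(5, 1, 10)))
})

test_that("stack truth respects its own invariants", {
  sim <- generate_stack(n_objects = 12, dims = c(8, 96, 96), seed = 15)
  crv <- default_calibration()
  tr <- sim$truth$objects
  expect_true(all(tr$true_ratio > crv$r_min & tr$true_ratio < crv$r_max))
  expect_equal(tr$voxel_count,
               as.integer(tabulate(sim$truth$labels$labels[
                 sim$truth$labels$labels > 0], nbins = 12)))
  expect_true(all(tr$voxel_count >= 5))
  # compartment sizes: somatic clusters are the large objects
  expect_true(all(tr$voxel_count[tr$compartment == "soma"] >
                    max(tr$voxel_count[tr$compartment == "neurite"])))
  # background table matches the requested offsets
  expect_equal(sim$truth$background$offset, rep(10, 8))
})

test_that("timelapse shapes behave as constructed", {
  flat <- generate_timelapse("step", amplitude = 0)
  expect_equal(stats::var(flat$value), 0)
  st <- generate_timelapse("step", amplitude = 0.3, n_points = 120)
  expect_equal(normalize_trace(st$value)[1], 1)
  # the step's relative change equals the specified amplitude at plateau
  expect_equal(delta_r_over_r(st$value[1], st$value[120]), 30,
               tolerance = 1e-6)
  rise <- generate_timelapse("slow_rise", amplitude = 0.1)
  expect_true(all(diff(rise$value) >= 0))
})

test_that("longitudinal rule drives disappearance as specified", {
  none <- generate_longitudinal(n = 20, cut = Inf, seed = 8)
  expect_equal(nrow(none$followup), 20)
  expect_false(any(none$truth$map$disappeared))
  det <- generate_longitudinal(n = 30, cut = 1.4, seed = 8)
  expect_equal(det$truth$map$disappeared,
               det$baseline$ratio > 1.4)
})

test_that("cohort generator produces the declared hierarchy", {
  ch <- generate_cohort(seed = 3)
  expect_setequal(unique(ch$group), c("Wt", "Tg"))
  expect_equal(length(unique(ch$mouse_id[ch$group == "Wt"])), 11)
  expect_equal(length(unique(ch$mouse_id[ch$group == "Tg"])), 7)
  counts <- dplyr::count(ch, volume_id)
  expect_true(all(counts$n == 150))
  # every volume belongs to exactly one mouse, every mouse to one group
  vm <- dplyr::distinct(ch, volume_id, mouse_id)
  expect_equal(nrow(vm), length(unique(ch$volume_id)))
  mg <- dplyr::distinct(ch, mouse_id, group)
  expect_equal(nrow(mg), length(unique(ch$mouse_id)))
})

test_that("default cohort recovers its generator anchors", {
  ch <- generate_cohort(seed = 11)
  vs <- volume_summary(ch)
  grand <- dplyr::left_join(vs,
                            dplyr::distinct(ch, volume_id, group),
                            by = "volume_id") |>
    dplyr::group_by(group) |>
    dplyr::summarise(m = mean(mean_ratio))
  expect_equal(grand$m[grand$group == "Wt"], 0.67, tolerance = 0.02)
  expect_equal(grand$m[grand$group == "Tg"], 0.73, tolerance = 0.02)
})

test_that("simulate -> segment -> quantify recovers the truth end to end", {
  # noise-free: exact per-object ratio recovery through the full pipeline
  sim <- generate_stack(n_objects = 20, dims = c(10, 160, 160),
                        poisson = FALSE, read_sd = 0, seed = 31)
  res <- process_stack(sim$stack)
  ev <- evaluate_segmentation(res$labels, sim$truth$labels)
  expect_true(all(ev$detected))
  got <- res$objects$ratio[match(ev$matched_label, res$objects$object_id)]
  expect_lt(max(abs(got / sim$truth$objects$true_ratio - 1)), 1e-6)

  # noisy, fixed seeds: per-object ratios recovered within a few percent
  errs <- purrr::map_dbl(1:3, function(s) {
    sim <- generate_stack(n_objects = 25, dims = c(12, 160, 160), seed = s)
    res <- process_stack(sim$stack)
    ev <- evaluate_segmentation(res$labels, sim$truth$labels)
    got <- res$objects$ratio[match(ev$matched_label, res$objects$object_id)]
    mean(abs(got / sim$truth$objects$true_ratio - 1), na.rm = TRUE)
  })
  # shot noise alone puts ~3% relative sd on a 5-voxel object's ratio and
  # the residual background after bottom-5% subtraction adds a ~2% pull
  # toward 1, so a 7.5% mean absolute error bound is the clean-recovery bar
  expect_lt(max(errs), 0.075)
})
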