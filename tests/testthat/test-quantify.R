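test_that("object ratio is the ratio of channel sums", {
  st <- toy_stack(nz = 2, ny = 8, nx = 8)
  lab <- array(0L, c(2, 8, 8))
  lab[1, 2:3, 2:3] <- 1L
  st$channels$CFP[1, 2:3, 2:3] <- 25   # sums to 100
  st$channels$YFP[1, 2:3, 2:3] <- 50   # sums to 200
  obj <- measure_objects(label_volume(lab, c(1, 1, 1)), st)
  expect_equal(obj$sum_cfp, 100)
  expect_equal(obj$sum_yfp, 200)
  expect_equal(obj$ratio, 2)
})

test_that("a zero CFP sum flags the object instead of erroring", {
  st <- toy_stack(nz = 1, ny = 8, nx = 8)
  lab <- array(0L, c(1, 8, 8))
  lab[1, 2, 2] <- 1L
  st$channels$YFP[1, 2, 2] <- 10
  obj <- measure_objects(label_volume(lab, c(1, 1, 1)), st)
  expect_true(is.na(obj$ratio))
  expect_equal(obj$qc_flag, "zero_cfp_sum")
})

test_that("measured ratios are invariant to common channel scaling", {
  sim <- generate_stack(n_objects = 10, dims = c(8, 96, 96), seed = 8)
  lab <- sim$truth$labels
  o1 <- measure_objects(lab, sim$stack)
  scaled <- sim$stack
  scaled$channels$CFP <- scaled$channels$CFP * 3.7
  scaled$channels$YFP <- scaled$channels$YFP * 3.7
  o2 <- measure_objects(lab, scaled)
  expect_equal(o1$ratio, o2$ratio, tolerance = 1e-12)
})

test_that("noise-free forward model returns the true ratio exactly", {
  sim <- generate_stack(n_objects = 15, dims = c(10, 128, 128),
                        poisson = FALSE, read_sd = 0, background = 0,
                        seed = 4)
  obj <- measure_objects(sim$truth$labels, sim$stack,
                         curve = default_calibration())
  expect_lt(max(abs(obj$ratio / sim$truth$objects$true_ratio - 1)), 1e-6)
  expect_equal(obj$ca_nm, sim$truth$objects$true_ca_nm, tolerance = 1e-5)
})

test_that("Poisson-noise cohort mean ratio is unbiased within 2%", {
  objs <- purrr::map_dfr(1:4, function(s) {
    sim <- generate_stack(n_objects = 50, ratios = rep(0.8, 50), seed = s)
    sub <- subtract_background(sim$stack)
    measure_objects(sim$truth$labels, sub)
  })
  expect_gte(nrow(objs), 200)
  expect_lt(abs(mean(objs$ratio) / 0.8 - 1), 0.02)
})

test_that("volume summaries average objects unweighted by default", {
  objs <- tibble::tibble(volume_id = c("v1", "v2", "v2"),
                         ratio = c(0.7, 0.6, 0.8),
                         voxel_count = c(10L, 1L, 99L))
  vs <- volume_summary(objs)
  expect_equal(vs$mean_ratio[vs$volume_id == "v1"], 0.7)
  expect_equal(vs$mean_ratio[vs$volume_id == "v2"], 0.7)
  vw <- volume_summary(objs, weights = "voxel")
  expect_equal(vw$mean_ratio[vw$volume_id == "v2"],
               (0.6 * 1 + 0.8 * 99) / 100)
  expect_warning(
    empty <- volume_summary(tibble::tibble(volume_id = character(),
                                           ratio = numeric())),
    "empty"
  )
  expect_equal(nrow(empty), 0)
})

test_that("overload threshold is mean + 2 x sample SD of the control pool", {
  thr <- overload_threshold(c(0.6, 0.7, 0.8))
  expect_equal(thr$control_mean, 0.7)
  expect_equal(thr$control_sd, 0.1)
  expect_equal(thr$threshold, 0.9)
  expect_warning(flat <- overload_threshold(c(0.7, 0.7, 0.7)), "zero spread")
  expect_equal(flat$threshold, 0.7)
  expect_error(overload_threshold(0.7),
               class = "mitofret_threshold_precondition")
})

test_that("overload fraction uses strict exceedance and stays in [0, 100]", {
  objs <- tibble::tibble(ratio = c(rep(0.7, 38), 1.0, 1.1))
  of <- overload_fraction(objs, 0.99)
  expect_equal(of$overload_pct, 5)           # 2 of 40
  expect_equal(overload_fraction(objs, 2)$overload_pct, 0)
  # boundary: equality does not count
  expect_equal(overload_fraction(tibble::tibble(ratio = 0.99), 0.99)$n_overload,
               0)
  # monotone non-increasing in the threshold
  fr <- vapply(seq(0.5, 1.2, 0.05),
               function(t) overload_fraction(objs, t)$overload_pct,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("overload fraction of a mixture matches the closed-form exceedance", {
  set.seed(77)
  n <- 1e4
  hi <- runif(n) < 0.05
  r <- ifelse(hi, rnorm(n, 1.2, 0.1), rnorm(n, 0.67, 0.16))
  p <- 0.95 * pnorm(0.99, 0.67, 0.16, lower.tail = FALSE) +
       0.05 * pnorm(0.99, 1.2, 0.1, lower.tail = FALSE)
  frac <- overload_fraction(tibble::tibble(ratio = r), 0.99)$overload_pct
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(frac / 100 - p), 4 * se)
})

test_that("ratio histograms conserve mass and locate the data", {
  one <- ratio_histogram(tibble::tibble(ratio = 0.8), bin_width = 0.05)
  expect_equal(sum(one$frequency), 1)
  expect_equal(sum(one$count > 0), 1)
  set.seed(5)
  u <- runif(500, 0.70, 0.75)  # inside a single bin
  h <- ratio_histogram(u, bin_width = 0.05, range = c(0.5, 1))
  expect_equal(h$frequency[which.min(abs(h$bin_lo - 0.70))], 1)
  expect_equal(sum(h$frequency), 1)
  # histogram mean tracks a generator mean shift
  r1 <- rnorm(4000, 0.67, 0.1)
  r2 <- rnorm(4000, 0.73, 0.1)
  hm <- function(h) sum(h$bin_mid * h$frequency)
  shift <- hm(ratio_histogram(r2, 0.02, range = c(0, 1.5))) -
           hm(ratio_histogram(r1, 0.02, range = c(0, 1.5)))
  expect_lt(abs(shift - 0.06), 0.01)
  expect_error(ratio_histogram(u, bin_width = 0),
               class = "mitofret_config_error")
})

test_that("relative ratio change and the 5% responder rule", {
  expect_equal(delta_r_over_r(0.70, 0.756), 8, tolerance = 1e-10)
  expect_true(flag_responders(delta_r_over_r(0.70, 0.756)))
  expect_equal(delta_r_over_r(0.7, 0.7), 0)
  expect_false(flag_responders(0))
  # boundary: >= 5 is a response, 4.29% is not
  expect_equal(delta_r_over_r(0.70, 0.73), 100 * 0.03 / 0.7)
  expect_false(flag_responders(delta_r_over_r(0.70, 0.73)))
  expect_true(flag_responders(5))
  expect_error(delta_r_over_r(0, 0.7), class = "mitofret_baseline_error")
})

test_that("treatment response joins before/after volumes", {
  before <- tibble::tibble(volume_id = c("v1", "v2"),
                           mean_ratio = c(0.70, 0.70))
  after <- tibble::tibble(volume_id = c("v1", "v2"),
                          mean_ratio = c(0.756, 0.71))
  tr <- treatment_response(before, after)
  expect_equal(tr$delta_pct, c(8, 100 / 70), tolerance = 1e-10)
  expect_equal(tr$responder, c(TRUE, FALSE))
})

test_that("pseudocolor anchors hue at r_min and blanks zero intensity", {
  crv <- default_calibration()
  ratio <- matrix(c(crv$r_min, crv$r_max - 1e-9, 0.9, 0.9), 2, 2)
  yfp <- matrix(c(10, 10, 10, 20), 2, 2)
  cfp <- matrix(c(10, 10, 10, 20), 2, 2)
  rgb <- pseudocolor(ratio, yfp, cfp, crv)
  # r_min -> blue end of the ramp (hue 240 deg); colors are 8-bit quantized
  expect_equal(rgb[1, 1, ], c(0, 0, 0.5), tolerance = 0.01)
  # r_max -> red end
  expect_equal(rgb[2, 1, ][1] > 0 && rgb[2, 1, ][3] == 0, TRUE)
  # equal ratio, doubled intensity: same hue, double value
  expect_equal(rgb[2, 2, ], 2 * rgb[1, 2, ], tolerance = 0.01)
  # zero intensity is black whatever the ratio
  rgb0 <- pseudocolor(matrix(1.2), matrix(0), matrix(0), crv)
  expect_equal(as.vector(rgb0), c(0, 0, 0))
})

test_that("trace normalization divides by the baseline sample", {
  expect_equal(normalize_trace(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(normalize_trace(c(10, 5)), c(1, 0.5))
  expect_error(normalize_trace(c(0, 5)), class = "mitofret_baseline_error")
  # exponential decay normalizes to exp(-k t)
  tr <- generate_timelapse("decay", n_points = 30, baseline = 3, rate = 0.1)
  norm <- normalize_trace(tr$value)
  expect_equal(norm, exp(-0.1 * tr$time), tolerance = 1e-12)
})
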