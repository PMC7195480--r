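#' Measure per-mitochondrion ratios and calcium concentrations
#'
#' For each labeled object, sums the (background-subtracted) channel
#' intensities over the object's voxels and forms the YFP/CFP ratio from the
#' summed intensities: `ratio = sum(YFP) / sum(CFP)`. Concentrations come
#' from [ratio_to_ca()] when a calibration curve is supplied. Objects with a
#' non-positive CFP sum get a missing ratio and are flagged in the `qc_flag`
#' column. Compartments are tagged by a declared, overridable heuristic:
#' objects larger than `soma_cut` um^3, or whose centroid falls inside
#' `soma_mask`, are `"soma"`; the rest are `"neurite"`.
#'
#' By default ratios should be measured on background-subtracted but
#' unsmoothed intensities (smoothing assists segmentation, not quantification)
#' -- pass the appropriate stack; [process_stack()] wires this up.
#'
#' @param labels A [label_volume()] aligned with `stack`.
#' @param stack An [image_stack()] with CFP and YFP channels.
#' @param curve Optional [calibration_curve()] for concentration conversion.
#' @param volume_id,mouse_id Identifiers stamped on every row.
#' @param soma_cut Volume cut (um^3) above which an object is tagged as
#'   somatic (default 20).
#' @param soma_mask Optional 3D logical array overriding the volume heuristic.
#' @return Tibble with one row per object: ids, centroid (um), voxel count
#'   and volume, channel sums, `ratio`, `ca_nm`, `compartment`, `qc_flag`.
#' @export
measure_objects <- function(labels, stack, curve = NULL,
                            volume_id = NA_character_,
                            mouse_id = NA_character_,
                            soma_cut = 20, soma_mask = NULL) {
  stopifnot(inherits(labels, "label_volume"), inherits(stack, "image_stack"))
  if (!all(dim(labels$labels) == stack_dim(stack)))
    abort("`labels` and `stack` dimensions differ.")
  n <- labels$object_count
  vs <- stack$voxel_size
  empty <- tibble(
    object_id = integer(), volume_id = character(), mouse_id = character(),
    centroid_z_um = numeric(), centroid_y_um = numeric(),
    centroid_x_um = numeric(), voxel_count = integer(),
    volume_um3 = numeric(), sum_cfp = numeric(), sum_yfp = numeric(),
    ratio = numeric(), ca_nm = numeric(), compartment = character(),
    qc_flag = character()
  )
  if (n == 0) return(empty)

  idx <- which(labels$labels > 0L)
  lab <- labels$labels[idx]
  cfp <- get_channel(stack, "CFP")[idx]
  yfp <- get_channel(stack, "YFP")[idx]
  coords <- arrayInd(idx, dim(labels$labels))

  f <- factor(lab, levels = seq_len(n))
  sum_cfp <- as.numeric(tapply(cfp, f, sum, default = 0))
  sum_yfp <- as.numeric(tapply(yfp, f, sum, default = 0))
  count <- as.integer(tabulate(lab, nbins = n))
  cz <- as.numeric(tapply((coords[, 1] - 0.5) * vs[1], f, mean))
  cy <- as.numeric(tapply((coords[, 2] - 0.5) * vs[2], f, mean))
  cx <- as.numeric(tapply((coords[, 3] - 0.5) * vs[3], f, mean))

  ratio <- ifelse(sum_cfp > 0, sum_yfp / sum_cfp, NA_real_)
  ca_nm <- if (!is.null(curve)) ratio_to_ca(ratio, curve) else NA_real_

  compartment <- ifelse(count * prod(vs) > soma_cut, "soma", "neurite")
  if (!is.null(soma_mask)) {
    zi <- pmin(pmax(ceiling(cz / vs[1]), 1L), dim(soma_mask)[1])
    yi <- pmin(pmax(ceiling(cy / vs[2]), 1L), dim(soma_mask)[2])
    xi <- pmin(pmax(ceiling(cx / vs[3]), 1L), dim(soma_mask)[3])
    in_soma <- soma_mask[cbind(zi, yi, xi)]
    compartment <- ifelse(in_soma, "soma", compartment)
  }

  qc <- rep(NA_character_, n)
  qc[sum_cfp <= 0] <- "zero_cfp_sum"

  tibble(
    object_id = seq_len(n),
    volume_id = as.character(volume_id), mouse_id = as.character(mouse_id),
    centroid_z_um = cz, centroid_y_um = cy, centroid_x_um = cx,
    voxel_count = count, volume_um3 = count * prod(vs),
    sum_cfp = sum_cfp, sum_yfp = sum_yfp,
    ratio = ratio, ca_nm = ca_nm,
    compartment = compartment, qc_flag = qc
  )
}

#' Per-volume (z-stack) summary of object ratios
#'
#' Each mitochondrion counts once regardless of size (unweighted mean, the
#' default); voxel-weighted means are available. If an overload threshold is
#' supplied the overloaded percentage per volume is added.
#'
#' @param objects Object table from [measure_objects()] (or any tibble with
#'   `volume_id` and `ratio`).
#' @param threshold Optional [overload_threshold()] object or numeric cutoff.
#' @param weights `"none"` (default) or `"voxel"` (weight by `voxel_count`).
#' @return Tibble with one row per volume: object counts, mean ratio, mean
#'   concentration when present, and `overload_pct` when a threshold is given.
#' @export
volume_summary <- function(objects, threshold = NULL,
                           weights = c("none", "voxel")) {
  weights <- match.arg(weights)
  check_columns(objects, c("volume_id", "ratio"), "object table")
  if (nrow(objects) == 0 || all(is.na(objects$ratio))) {
    warn("No objects with a defined ratio; returning an empty summary.")
    return(tibble(volume_id = character(), n_objects = integer(),
                  n_defined = integer(), n_missing = integer(),
                  mean_ratio = numeric()))
  }
  thr <- if (inherits(threshold, "overload_threshold"))
    threshold$threshold else threshold
  out <- objects |>
    dplyr::group_by(.data$volume_id) |>
    dplyr::summarise(
      n_objects = dplyr::n(),
      n_defined = sum(!is.na(.data$ratio)),
      n_missing = sum(is.na(.data$ratio)),
      mean_ratio = if (weights == "voxel")
        stats::weighted.mean(.data$ratio, .data$voxel_count, na.rm = TRUE)
      else mean(.data$ratio, na.rm = TRUE),
      mean_ca_nm = if ("ca_nm" %in% names(objects))
        mean(.data$ca_nm, na.rm = TRUE) else NA_real_,
      overload_pct = if (!is.null(thr))
        100 * sum(.data$ratio > thr, na.rm = TRUE) /
          sum(!is.na(.data$ratio)) else NA_real_,
      .groups = "drop"
    )
  if (is.null(thr)) out$overload_pct <- NULL
  out
}

#' Calcium-overload threshold from a control cohort
#'
#' Overload is defined as a YFP/CFP ratio greater than two standard
#' deviations above the mean ratio of all pooled control mitochondria.
#' The sample (n-1) standard deviation is used.
#'
#' @param control Object table (tibble with a `ratio` column) or a numeric
#'   vector of control ratios. At least 2 defined ratios required.
#' @return An `overload_threshold` object with `control_mean`, `control_sd`,
#'   `threshold = mean + 2*sd` and `n_control`.
#' @export
overload_threshold <- function(control) {
  r <- if (is.data.frame(control)) {
    check_columns(control, "ratio", "control table")
    control$ratio
  } else as.numeric(control)
  r <- r[!is.na(r)]
  if (length(r) < 2)
    abort("Need at least 2 control objects with defined ratios.",
          class = "mitofret_threshold_precondition")
  m <- mean(r)
  s <- sd(r)
  if (s == 0)
    warn("Control ratios have zero spread; threshold is degenerate.")
  structure(
    list(control_mean = m, control_sd = s, threshold = m + 2 * s,
         n_control = length(r)),
    class = "overload_threshold"
  )
}

#' @export
print.overload_threshold <- function(x, ...) {
  cat(sprintf(
    "<overload_threshold> mean %.4g + 2 x SD %.4g = %.4g (n = %d)\n",
    x$control_mean, x$control_sd, x$threshold, x$n_control))
  invisible(x)
}

#' Percentage of calcium-overloaded mitochondria
#'
#' Strict exceedance: an object is overloaded when its ratio is strictly
#' greater than the threshold. Computed per volume when a `volume_id` column
#' is present, otherwise over the pool.
#'
#' @param objects Object table with a `ratio` column.
#' @param threshold An [overload_threshold()] or numeric cutoff.
#' @return Tibble with `n_defined`, `n_overload`, `overload_pct`
#'   (per `volume_id` when available).
#' @export
overload_fraction <- function(objects, threshold) {
  thr <- if (inherits(threshold, "overload_threshold"))
    threshold$threshold else threshold
  stopifnot_scalar_number(thr, "threshold")
  check_columns(objects, "ratio", "object table")
  grouped <- if ("volume_id" %in% names(objects))
    dplyr::group_by(objects, .data$volume_id) else objects
  dplyr::summarise(
    grouped,
    n_defined = sum(!is.na(.data$ratio)),
    n_overload = sum(.data$ratio > thr, na.rm = TRUE),
    overload_pct = ifelse(.data$n_defined > 0,
                          100 * .data$n_overload / .data$n_defined, NA_real_),
    .groups = "drop"
  )
}

#' Frequency distribution of YFP/CFP ratios
#'
#' @param objects Object table with a `ratio` column, or a numeric vector.
#' @param bin_width Bin width on the ratio scale (> 0).
#' @param range Optional `c(lo, hi)`; defaults to the data range snapped to
#'   bin boundaries.
#' @param normalize If `TRUE` (default) report relative frequencies summing
#'   to 1, else counts.
#' @param threshold Optional overload threshold annotated on the result (and
#'   drawn by [autoplot()]).
#' @return A tibble of class `ratio_histogram`: `bin_lo`, `bin_hi`,
#'   `bin_mid`, `count`, `frequency`.
#' @export
ratio_histogram <- function(objects, bin_width = 0.05, range = NULL,
                            normalize = TRUE, threshold = NULL) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    abort("`bin_width` must be > 0.", class = "mitofret_config_error")
  r <- if (is.data.frame(objects)) objects$ratio else as.numeric(objects)
  r <- r[!is.na(r)]
  if (length(r) == 0) abort("No defined ratios to bin.")
  if (is.null(range)) {
    lo <- floor(min(r) / bin_width) * bin_width
    hi <- ceiling(max(r) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
  } else {
    lo <- range[1]; hi <- range[2]
  }
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  # right-open bins, last bin closed
  bin <- findInterval(r, breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), length(breaks) - 1L)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  thr <- if (inherits(threshold, "overload_threshold"))
    threshold$threshold else threshold
  out <- tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    count = counts,
    frequency = if (normalize) counts / sum(counts) else as.numeric(counts)
  )
  attr(out, "threshold") <- thr
  class(out) <- c("ratio_histogram", class(out))
  out
}

#' Relative ratio change versus baseline
#'
#' `delta_r_over_r()` computes the percent change `100 * (after - before) /
#' before` of volume-mean ratios; `flag_responders()` applies the responder
#' criterion (change of at least `cut` percent, default 5, inclusive).
#'
#' @param before,after Numeric volume-mean ratios; `before` must be > 0.
#' @return Percent change (numeric vector).
#' @export
delta_r_over_r <- function(before, after) {
  if (any(!is.finite(before)) || any(before <= 0))
    abort("Baseline ratios must be finite and > 0.",
          class = "mitofret_baseline_error")
  100 * (after - before) / before
}

#' @rdname delta_r_over_r
#' @param delta_pct Percent changes from `delta_r_over_r()`.
#' @param cut Responder cut in percent (default 5; `>=` is a response).
#' @return Logical responder flags.
#' @export
flag_responders <- function(delta_pct, cut = 5) {
  delta_pct >= cut
}

#' Per-volume treatment response table
#'
#' Joins before/after volume summaries by `volume_id` and computes the
#' relative ratio change and responder flag per volume.
#'
#' @param before,after Volume summaries (from [volume_summary()]) with
#'   `volume_id` and `mean_ratio`.
#' @inheritParams flag_responders
#' @return Tibble: `volume_id`, `ratio_before`, `ratio_after`, `delta_pct`,
#'   `responder`.
#' @export
treatment_response <- function(before, after, cut = 5) {
  check_columns(before, c("volume_id", "mean_ratio"), "`before`")
  check_columns(after, c("volume_id", "mean_ratio"), "`after`")
  joined <- dplyr::inner_join(
    dplyr::select(before, "volume_id", ratio_before = "mean_ratio"),
    dplyr::select(after, "volume_id", ratio_after = "mean_ratio"),
    by = "volume_id"
  )
  joined |>
    dplyr::mutate(
      delta_pct = delta_r_over_r(.data$ratio_before, .data$ratio_after),
      responder = flag_responders(.data$delta_pct, cut)
    )
}

#' Pseudocolor rendering of a ratio image
#'
#' Maps the ratio (equivalently, calcium concentration) of each pixel to a
#' hue ramp anchored at the calibration curve's `r_min` and `r_max`
#' (blue = `r_min`, red = `r_max`; hue 240 -> 0 degrees at full saturation),
#' then sets the HSV value channel to the mean of the YFP and CFP intensity
#' images normalized to its maximum. Pixels with zero intensity are black
#' regardless of ratio.
#'
#' @param ratio 2D matrix of YFP/CFP ratios (NA allowed).
#' @param yfp,cfp 2D intensity matrices aligned with `ratio`.
#' @param curve A [calibration_curve()] anchoring the color range.
#' @return Numeric array `[y, x, 3]` of RGB values in `[0, 1]`.
#' @export
pseudocolor <- function(ratio, yfp, cfp, curve = default_calibration()) {
  stopifnot(all(dim(ratio) == dim(yfp)), all(dim(yfp) == dim(cfp)))
  t <- (ratio - curve$r_min) / (curve$r_max - curve$r_min)
  t[is.na(t)] <- 0
  t <- pmin(pmax(t, 0), 1)
  value <- (yfp + cfp) / 2
  vmax <- max(value)
  v <- if (vmax > 0) value / vmax else value
  hue <- (1 - t) * (240 / 360)
  cols <- col2rgb(hsv(h = as.vector(hue), s = 1, v = as.vector(v))) / 255
  out <- array(0, dim = c(dim(ratio), 3L))
  out[, , 1] <- cols[1, ]
  out[, , 2] <- cols[2, ]
  out[, , 3] <- cols[3, ]
  out
}

#' Normalize a fluorescence trace to its pre-treatment baseline
#'
#' Divides every sample by the value at the baseline index (t = 0, before
#' any solution was added), so the output equals 1 there.
#'
#' @param values Numeric trace.
#' @param t0_index Index of the baseline sample (default 1).
#' @return Normalized trace.
#' @export
normalize_trace <- function(values, t0_index = 1) {
  if (t0_index < 1 || t0_index > length(values))
    abort("`t0_index` is out of range.")
  v0 <- values[t0_index]
  if (!is.finite(v0) || v0 <= 0)
    abort("Baseline value must be > 0.", class = "mitofret_baseline_error")
  values / v0
}
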