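#' Distance from each mitochondrion to the nearest plaque edge
#'
#' Anisotropy-aware Euclidean distance (um) from the object centroid to the
#' nearest plaque edge voxel center; 0 when the centroid lies inside a
#' plaque. An empty plaque set yields missing distances with a warning.
#'
#' @param objects Object table from [measure_objects()] (needs the centroid
#'   columns in um).
#' @param plaques A `plaque_set` from [extract_plaques()].
#' @return `objects` with `distance_um` and `nearest_plaque_id` columns.
#' @export
distance_to_plaques <- function(objects, plaques) {
  stopifnot(inherits(plaques, "plaque_set"))
  check_columns(objects,
                c("centroid_z_um", "centroid_y_um", "centroid_x_um"),
                "object table")
  if (plaques$n_plaques == 0) {
    warn("Plaque set is empty; distances are missing.")
    objects$distance_um <- NA_real_
    objects$nearest_plaque_id <- NA_integer_
    return(objects)
  }
  e <- plaques$edges
  vs <- plaques$voxel_size
  dims <- dim(plaques$labels)
  n <- nrow(objects)
  dist <- numeric(n)
  nearest <- integer(n)
  for (i in seq_len(n)) {
    cz <- objects$centroid_z_um[i]
    cy <- objects$centroid_y_um[i]
    cx <- objects$centroid_x_um[i]
    # containment: label at the centroid's voxel
    zi <- pmin(pmax(ceiling(cz / vs[1]), 1L), dims[1])
    yi <- pmin(pmax(ceiling(cy / vs[2]), 1L), dims[2])
    xi <- pmin(pmax(ceiling(cx / vs[3]), 1L), dims[3])
    inside <- plaques$labels[zi, yi, xi]
    if (inside > 0) {
      dist[i] <- 0
      nearest[i] <- inside
    } else {
      d2 <- (e$z_um - cz)^2 + (e$y_um - cy)^2 + (e$x_um - cx)^2
      j <- which.min(d2)
      dist[i] <- sqrt(d2[j])
      nearest[i] <- e$plaque_id[j]
    }
  }
  objects$distance_um <- dist
  objects$nearest_plaque_id <- nearest
  objects
}

#' Overload probability binned by distance to the nearest plaque
#'
#' Bins objects by distance to the nearest plaque edge (contiguous,
#' right-open bins of width `bin_width` from 0 to `max_dist`) and reports the
#' overloaded percentage per bin. Objects beyond `max_dist` are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param objects Object table with `ratio` and `distance_um` columns (see
#'   [distance_to_plaques()]).
#' @param threshold An [overload_threshold()] or numeric cutoff.
#' @param bin_width Bin width in um (default 10, > 0).
#' @param max_dist Maximum distance analyzed in um (default 100).
#' @param by_plaque If `TRUE`, also group by `nearest_plaque_id` (the
#'   per-plaque analysis unit used for the rank test).
#' @return Tibble: `bin_lo`, `bin_hi`, (`nearest_plaque_id`,) `n`,
#'   `n_overload`, `overload_pct`.
#' @export
overload_vs_distance <- function(objects, threshold, bin_width = 10,
                                 max_dist = 100, by_plaque = FALSE) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    abort("`bin_width` must be > 0.", class = "mitofret_config_error")
  thr <- if (inherits(threshold, "overload_threshold"))
    threshold$threshold else threshold
  check_columns(objects, c("ratio", "distance_um"), "object table")
  dat <- objects |>
    dplyr::filter(!is.na(.data$ratio), !is.na(.data$distance_um))
  n_excluded <- sum(dat$distance_um >= max_dist)
  dat <- dat |> dplyr::filter(.data$distance_um < max_dist)
  breaks <- seq(0, max_dist, by = bin_width)
  dat$bin <- findInterval(dat$distance_um, breaks)
  grid <- tibble(bin = seq_len(length(breaks) - 1L))
  groups <- if (by_plaque) c("bin", "nearest_plaque_id") else "bin"
  out <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_overload = sum(.data$ratio > thr),
      overload_pct = 100 * .data$n_overload / .data$n,
      .groups = "drop"
    )
  if (!by_plaque)
    out <- dplyr::left_join(grid, out, by = "bin") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                    n_overload = dplyr::coalesce(.data$n_overload, 0L),
                    overload_pct = ifelse(.data$n > 0,
                                          dplyr::coalesce(.data$overload_pct,
                                                          0), NA_real_))
  out <- out |>
    dplyr::mutate(bin_lo = breaks[.data$bin],
                  bin_hi = breaks[.data$bin + 1L], .before = 1) |>
    dplyr::select(-"bin")
  attr(out, "n_excluded") <- n_excluded
  attr(out, "threshold") <- thr
  class(out) <- c("distance_bin_table", class(out))
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Tidy wrapper around [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-square reference with k-1 df).
#'
#' @param values Numeric observations.
#' @param groups Group membership (factor or coercible).
#' @return One-row tibble: `statistic` (H), `df`, `p.value`, `n_groups`,
#'   `method`.
#' @export
kruskal_rank_test <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2)
    abort("Need at least 2 groups.", class = "mitofret_test_precondition")
  if (diff(range(values, na.rm = TRUE)) == 0) {
    # all observations tied: no evidence against the null (H = 0 by
    # continuity; kruskal.test returns 0/0 here)
    return(tibble(statistic = 0, df = nlevels(g) - 1, p.value = 1,
                  n_groups = nlevels(g),
                  method = "Kruskal-Wallis rank sum test"))
  }
  ht <- suppressWarnings(kruskal.test(values, g))
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value,
    n_groups = nlevels(g),
    method = "Kruskal-Wallis rank sum test"
  )
}

#' Test whether overload probability depends on plaque distance
#'
#' Builds the per-plaque, per-bin overloaded percentages (the analysis unit
#' is one plaque's overload percentage within one distance bin) and runs a
#' Kruskal-Wallis test across distance bins.
#'
#' @inheritParams overload_vs_distance
#' @return One-row tibble from [kruskal_rank_test()] with the per-plaque bin
#'   table attached as attribute `"bin_table"`.
#' @export
overload_distance_test <- function(objects, threshold, bin_width = 10,
                                   max_dist = 100) {
  check_columns(objects, "nearest_plaque_id", "object table")
  tab <- overload_vs_distance(objects, threshold, bin_width, max_dist,
                              by_plaque = TRUE)
  res <- kruskal_rank_test(tab$overload_pct,
                           interaction(tab$bin_lo, tab$bin_hi))
  attr(res, "bin_table") <- tab
  res
}
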