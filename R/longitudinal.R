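#' Match cells/objects across two imaging sessions
#'
#' Greedy nearest-centroid matching: candidate pairs within `radius` um are
#' assigned in ascending order of displacement (ties broken by baseline then
#' follow-up index), each follow-up object used at most once. Baseline
#' records left unmatched are marked disappeared.
#'
#' @param baseline,followup Tibbles with `object_id`, `centroid_z_um`,
#'   `centroid_y_um`, `centroid_x_um` and (baseline) `ratio` columns, in a
#'   common coordinate frame.
#' @param radius Matching radius in um (default 10, soma scale; >= 0).
#' @param method `"greedy"` (default) or `"optimal"` (exhaustive assignment
#'   minimizing total displacement; only for small sessions).
#' @return Tibble: `baseline_id`, `followup_id` (`NA` when disappeared),
#'   `displacement_um`, `baseline_ratio`, `status`
#'   (`"remained"`/`"disappeared"`).
#' @export
match_sessions <- function(baseline, followup, radius = 10,
                           method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (!is.numeric(radius) || radius < 0)
    abort("`radius` must be >= 0.", class = "mitofret_config_error")
  cols <- c("object_id", "centroid_z_um", "centroid_y_um", "centroid_x_um")
  check_columns(baseline, c(cols, "ratio"), "`baseline`")
  check_columns(followup, cols, "`followup`")
  nb <- nrow(baseline)
  nf <- nrow(followup)
  d <- outer(seq_len(nb), seq_len(nf), function(i, j) {
    sqrt((baseline$centroid_z_um[i] - followup$centroid_z_um[j])^2 +
         (baseline$centroid_y_um[i] - followup$centroid_y_um[j])^2 +
         (baseline$centroid_x_um[i] - followup$centroid_x_um[j])^2)
  })
  match_f <- rep(NA_integer_, nb)
  disp <- rep(NA_real_, nb)
  if (nb > 0 && nf > 0) {
    if (method == "greedy") {
      cand <- which(d <= radius, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(d[cand], cand[, 1], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        used_f <- rep(FALSE, nf)
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (is.na(match_f[i]) && !used_f[j]) {
            match_f[i] <- j
            disp[i] <- d[i, j]
            used_f[j] <- TRUE
          }
        }
      }
    } else {
      if (nb > 8 || nf > 8)
        abort("`optimal` matching is exhaustive; use sessions of <= 8 objects.")
      # enumerate injective assignments of baseline -> followup or NA
      best <- NULL
      best_cost <- Inf
      assign_rec <- function(i, taken, cur, cost) {
        if (cost >= best_cost) return()
        if (i > nb) {
          n_matched <- sum(!is.na(cur))
          # prefer more matches, then lower cost
          total <- -n_matched * 1e6 + cost
          if (total < best_cost) {
            best_cost <<- total
            best <<- cur
          }
          return()
        }
        for (j in seq_len(nf)) {
          if (!taken[j] && d[i, j] <= radius) {
            taken[j] <- TRUE
            cur[i] <- j
            assign_rec(i + 1, taken, cur, cost + d[i, j])
            taken[j] <- FALSE
            cur[i] <- NA_integer_
          }
        }
        assign_rec(i + 1, taken, cur, cost)
      }
      assign_rec(1L, rep(FALSE, nf), rep(NA_integer_, nb), 0)
      match_f <- best
      disp <- ifelse(is.na(match_f), NA_real_, d[cbind(seq_len(nb), match_f)])
    }
  }
  tibble(
    baseline_id = baseline$object_id,
    followup_id = ifelse(is.na(match_f), NA,
                         followup$object_id[match_f]),
    displacement_um = disp,
    baseline_ratio = baseline$ratio,
    status = ifelse(is.na(match_f), "disappeared", "remained")
  )
}

#' Relate baseline mitochondrial calcium to cell disappearance
#'
#' Builds the 2x2 contingency of baseline ratio above/below a cut versus
#' remained/disappeared at follow-up, and compares baseline ratios between
#' the two outcome groups with a Student t-test (equal variances).
#'
#' @param matches Match table from [match_sessions()].
#' @param cut Baseline ratio cut (default 1.4; `> cut` counts as above).
#' @return A `survival_analysis` object; [tidy()] returns the contingency
#'   table, [glance()] the group comparison (difference in means, t statistic,
#'   p-value).
#' @export
survival_by_baseline_ratio <- function(matches, cut = 1.4) {
  if (nrow(matches) == 0)
    abort("Empty match table.", class = "mitofret_test_precondition")
  check_columns(matches, c("baseline_ratio", "status"), "`matches`")
  dat <- matches |>
    dplyr::mutate(ratio_group = ifelse(.data$baseline_ratio > cut,
                                       "above_cut", "below_cut"))
  tab <- tidyr::expand_grid(ratio_group = c("below_cut", "above_cut"),
                            status = c("remained", "disappeared")) |>
    dplyr::left_join(dplyr::count(dat, .data$ratio_group, .data$status),
                     by = c("ratio_group", "status")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  rem <- dat$baseline_ratio[dat$status == "remained"]
  dis <- dat$baseline_ratio[dat$status == "disappeared"]
  test <- if (length(rem) >= 2 && length(dis) >= 2) {
    if (sd(c(rem - mean(rem), dis - mean(dis))) == 0) {
      # degenerate: zero within-group variance
      tibble(estimate = mean(dis) - mean(rem),
             statistic = if (mean(dis) == mean(rem)) 0 else Inf,
             p.value = if (mean(dis) == mean(rem)) 1 else 0,
             method = "Two Sample t-test")
    } else {
      ht <- t.test(dis, rem, var.equal = TRUE)
      tibble(estimate = unname(diff(rev(ht$estimate))),
             statistic = unname(ht$statistic),
             p.value = ht$p.value,
             method = "Two Sample t-test")
    }
  } else {
    tibble(estimate = NA_real_, statistic = NA_real_, p.value = NA_real_,
           method = "Two Sample t-test (insufficient group sizes)")
  }
  structure(list(table = tab, test = test, cut = cut,
                 n = nrow(dat)),
            class = "survival_analysis")
}

#' @export
print.survival_analysis <- function(x, ...) {
  cat(sprintf("<survival_analysis> baseline ratio cut %.3g, n = %d\n",
              x$cut, x$n))
  print(x$table)
  print(x$test)
  invisible(x)
}

#' @describeIn survival_by_baseline_ratio Contingency counts.
#' @param x A `survival_analysis`.
#' @param ... Unused.
#' @method tidy survival_analysis
#' @export
tidy.survival_analysis <- function(x, ...) x$table

#' @describeIn survival_by_baseline_ratio Group-comparison summary.
#' @method glance survival_analysis
#' @export
glance.survival_analysis <- function(x, ...) x$test
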