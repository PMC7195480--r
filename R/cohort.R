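#' Mixed-effects group comparison with mouse as random effect
#'
#' Fits `response ~ group + (1 | mouse)` by REML ([lme4::lmer()] via
#' lmerTest), mirroring the hierarchical design in which volumes (z-stacks)
#' are nested in mice and mice in treatment groups. Reports least-squares
#' means with standard errors per group (via emmeans) and pairwise group
#' contrasts with Satterthwaite degrees of freedom.
#'
#' @param data Tibble with one row per volume-level observation.
#' @param response Bare column name of the response (e.g. a volume mean
#'   ratio, overloaded percentage or relative ratio change).
#' @param group,mouse Bare column names of the group and mouse identifiers
#'   (defaults `group` and `mouse_id`).
#' @return A `cohort_lmm`: fitted model plus tidy LS-mean and contrast
#'   tables. Methods: [tidy()] (`effects = "means"` or `"contrasts"`),
#'   [glance()], [autoplot()].
#' @export
fit_group_lmm <- function(data, response, group = group, mouse = mouse_id) {
  resp <- as_name(enquo(response))
  grp <- as_name(enquo(group))
  mse <- as_name(enquo(mouse))
  check_columns(data, c(resp, grp, mse), "cohort table")
  df <- data.frame(
    value = data[[resp]],
    group = factor(data[[grp]]),
    mouse = factor(data[[mse]])
  )
  df <- df[stats::complete.cases(df), ]
  if (nlevels(droplevels(df$group)) < 2)
    abort("Need at least 2 groups.", class = "mitofret_lmm_precondition")
  mice_per_group <- tapply(df$mouse, df$group,
                           function(m) length(unique(m)))
  if (any(mice_per_group < 2))
    abort(paste0(
      "Every group needs >= 2 mice for a mouse-level random effect; ",
      "use a paired or naive per-volume analysis instead."
    ), class = "mitofret_lmm_precondition")

  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(value ~ group + (1 | mouse), data = df, REML = TRUE,
                   # one observation per mouse is a legitimate design here
                   # (volume-level response collapses to mouse means)
                   control = lme4::lmerControl(
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore"))
  ))
  emm <- emmeans::emmeans(fit, "group", lmer.df = "satterthwaite")
  means <- as_tibble(as.data.frame(emm))
  contrasts <- as_tibble(as.data.frame(
    emmeans::contrast(emm, method = "pairwise", adjust = "none")
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      model = fit,
      means = means,
      contrasts = contrasts,
      sd_mouse = vc$sdcor[vc$grp == "mouse"],
      sigma = vc$sdcor[vc$grp == "Residual"],
      response = resp,
      n_obs = nrow(df),
      n_mice = length(unique(df$mouse))
    ),
    class = "cohort_lmm"
  )
}

#' @export
print.cohort_lmm <- function(x, ...) {
  cat(sprintf("<cohort_lmm> %s ~ group + (1 | mouse), %d obs, %d mice\n",
              x$response, x$n_obs, x$n_mice))
  cat("Least-squares means:\n")
  print(x$means)
  cat("Contrasts (Satterthwaite df):\n")
  print(x$contrasts)
  invisible(x)
}

#' @describeIn fit_group_lmm LS means (`effects = "means"`, default) or
#'   pairwise contrasts (`effects = "contrasts"`).
#' @param x A `cohort_lmm`.
#' @param effects Which table to return.
#' @param ... Unused.
#' @method tidy cohort_lmm
#' @export
tidy.cohort_lmm <- function(x, effects = c("means", "contrasts"), ...) {
  effects <- match.arg(effects)
  if (effects == "means") x$means else x$contrasts
}

#' @describeIn fit_group_lmm One-row model summary (variance components,
#'   sizes, p-value of the first group contrast).
#' @method glance cohort_lmm
#' @export
glance.cohort_lmm <- function(x, ...) {
  tibble(
    sd_mouse = x$sd_mouse,
    sigma = x$sigma,
    n_obs = x$n_obs,
    n_mice = x$n_mice,
    estimate = x$contrasts$estimate[1],
    p.value = x$contrasts$p.value[1]
  )
}

#' Cluster (mouse-level) bootstrap for the group difference
#'
#' Nonparametric cross-check of [fit_group_lmm()]: mice are resampled with
#' replacement within each group, the statistic is the difference between
#' group means of per-mouse means (second factor level minus first), and a
#' percentile confidence interval is reported.
#'
#' @inheritParams fit_group_lmm
#' @param n_boot Number of bootstrap replicates (default 1000; a warning is
#'   issued below 100).
#' @param seed Optional integer seed.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `contrast`, `estimate`, `conf.low`, `conf.high`,
#'   `n_boot`.
#' @export
cluster_bootstrap <- function(data, response, group = group,
                              mouse = mouse_id, n_boot = 1000, seed = NULL,
                              conf = 0.95) {
  resp <- as_name(enquo(response))
  grp <- as_name(enquo(group))
  mse <- as_name(enquo(mouse))
  check_columns(data, c(resp, grp, mse), "cohort table")
  if (n_boot < 100) warn("`n_boot` < 100 gives unstable intervals.")
  df <- data.frame(value = data[[resp]], group = factor(data[[grp]]),
                   mouse = data[[mse]])
  lev <- levels(df$group)
  if (length(lev) != 2)
    abort("cluster_bootstrap() compares exactly 2 groups.",
          class = "mitofret_lmm_precondition")
  # per-mouse means within group
  mm <- df |>
    dplyr::group_by(.data$group, .data$mouse) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  m1 <- mm$m[mm$group == lev[1]]
  m2 <- mm$m[mm$group == lev[2]]
  est <- mean(m2) - mean(m1)
  boots <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      mean(sample(m2, replace = TRUE)) - mean(sample(m1, replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  tibble(
    contrast = paste(lev[2], "-", lev[1]),
    estimate = est,
    conf.low = ci[1],
    conf.high = ci[2],
    n_boot = as.integer(n_boot)
  )
}
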