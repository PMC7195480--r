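#' Calibration curve for a ratiometric FRET calcium indicator
#'
#' Bundles the four constants of the Hill-sigmoid titration curve of a
#' FRET-based cameleon sensor: the ratio at zero calcium (`r_min`), the ratio
#' at saturating calcium (`r_max`), the apparent dissociation constant
#' (`kd_um`, in micromolar) and the Hill coefficient (`hill_n`). The forward
#' model is
#' \deqn{R(C) = R_{min} + (R_{max}-R_{min}) \frac{C^n}{K_d'^n + C^n}}
#' and its algebraic inverse converts measured YFP/CFP ratios to free calcium
#' concentrations (see [ratio_to_ca()]).
#'
#' @param r_min,r_max Sensor ratio at zero and saturating calcium.
#'   Must satisfy `0 < r_min < r_max`.
#' @param kd_um Apparent dissociation constant, in uM (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @return An object of class `calibration_curve`.
#' @seealso [default_calibration()], [fit_calibration()], [ratio_to_ca()],
#'   [ca_to_ratio()]
#' @export
calibration_curve <- function(r_min, r_max, kd_um, hill_n) {
  stopifnot_scalar_number(r_min, "r_min", positive = TRUE)
  stopifnot_scalar_number(r_max, "r_max", positive = TRUE)
  stopifnot_scalar_number(kd_um, "kd_um", positive = TRUE)
  stopifnot_scalar_number(hill_n, "hill_n", positive = TRUE)
  if (r_min >= r_max)
    abort("`r_min` must be strictly smaller than `r_max`.",
          class = "mitofret_invalid_curve")
  structure(
    list(r_min = r_min, r_max = r_max, kd_um = kd_um, hill_n = hill_n),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>\n")
  cat(sprintf("  r_min = %.4g, r_max = %.4g\n", x$r_min, x$r_max))
  cat(sprintf("  Kd' = %.4g uM, Hill n = %.4g\n", x$kd_um, x$hill_n))
  invisible(x)
}

#' Packaged in-situ calibration profile
#'
#' The default calibration of the mitochondrially targeted cameleon YC3.6
#' sensor obtained by in-situ titration in permeabilized N2a cells:
#' `r_min = 0.606`, `r_max = 2.6921`, `kd_um = 4.21`, `hill_n = 1.57`.
#'
#' @return A [calibration_curve()].
#' @export
default_calibration <- function() {
  calibration_curve(r_min = 0.606, r_max = 2.6921, kd_um = 4.21, hill_n = 1.57)
}

#' Convert YFP/CFP ratios to free calcium concentration (nM)
#'
#' Inverts the Hill sigmoid of the calibration curve:
#' \deqn{[Ca^{2+}] = K_d' \left(\frac{R - R_{min}}{R_{max} - R}\right)^{1/n}}
#' Concentrations are returned in nM (the curve stores \eqn{K_d'} in uM; the
#' conversion factor is fixed at 1000).
#'
#' Ratios below `r_min` or at/above `r_max` cannot be inverted (they arise
#' under measurement noise) and map to `NA` rather than being clipped, so
#' that downstream code can count them; `R = r_min` maps to exactly 0 nM.
#' Use [conversion_qc()] to tabulate out-of-range ratios.
#'
#' @param ratio Numeric vector of YFP/CFP ratios.
#' @param curve A [calibration_curve()]. Defaults to the packaged profile.
#' @return Numeric vector of free calcium concentrations in nM; `NA` where
#'   the ratio is out of range.
#' @examples
#' ratio_to_ca(0.99)  # ~1631 nM with the packaged constants
#' @export
ratio_to_ca <- function(ratio, curve = default_calibration()) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- rep(NA_real_, length(ratio))
  ok <- !is.na(ratio) & ratio >= curve$r_min & ratio < curve$r_max
  r <- ratio[ok]
  out[ok] <- 1000 * curve$kd_um *
    ((r - curve$r_min) / (curve$r_max - r))^(1 / curve$hill_n)
  out
}

#' Convert free calcium concentration (nM) to a YFP/CFP ratio
#'
#' Forward Hill model of the calibration curve; exact algebraic inverse of
#' [ratio_to_ca()]. `ca_nm = 0` gives `r_min`; `ca_nm` equal to the apparent
#' Kd (in nM) gives the ratio midpoint `(r_min + r_max)/2`.
#'
#' @param ca_nm Numeric vector of free calcium concentrations in nM (>= 0).
#' @inheritParams ratio_to_ca
#' @return Numeric vector of ratios in `[r_min, r_max)`.
#' @export
ca_to_ratio <- function(ca_nm, curve = default_calibration()) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(ca_nm < 0, na.rm = TRUE))
    abort("Concentrations must be >= 0.", class = "mitofret_negative_conc")
  c_um <- ca_nm / 1000
  frac <- c_um^curve$hill_n / (curve$kd_um^curve$hill_n + c_um^curve$hill_n)
  curve$r_min + (curve$r_max - curve$r_min) * frac
}

#' Tabulate out-of-range ratios for a calibration curve
#'
#' @inheritParams ratio_to_ca
#' @return One-row tibble with counts of convertible, below-range and
#'   at-or-above-range ratios (and `NA` inputs).
#' @export
conversion_qc <- function(ratio, curve = default_calibration()) {
  stopifnot(inherits(curve, "calibration_curve"))
  tibble(
    n = length(ratio),
    n_missing = sum(is.na(ratio)),
    n_below_rmin = sum(ratio < curve$r_min, na.rm = TRUE),
    n_at_or_above_rmax = sum(ratio >= curve$r_max, na.rm = TRUE),
    n_converted = sum(ratio >= curve$r_min & ratio < curve$r_max, na.rm = TRUE)
  )
}

#' Fit the Hill-sigmoid titration curve of a ratiometric indicator
#'
#' Least-squares fit of the four-parameter Hill sigmoid
#' \eqn{R(C) = R_{min} + (R_{max}-R_{min}) C^n / (K_d'^n + C^n)} to a
#' titration table of measured YFP/CFP ratios at known free calcium
#' concentrations. \eqn{K_d'} and \eqn{n} are fitted on the log scale to
#' enforce positivity; `r_min`/`r_max` start at the observed ratio extremes,
#' \eqn{K_d'} at the concentration whose ratio is nearest the midpoint, and
#' \eqn{n} at 1. Optimization uses Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]).
#'
#' @param titration Data frame with columns `free_ca_um` (free calcium, uM,
#'   non-negative and strictly increasing) and `ratio` (> 0); at least 5 rows.
#'   Optional columns `n_cells` and `ratio_sd` are carried through.
#' @param weights Optional per-row weights for the least-squares objective.
#' @return A `calibration_fit` object: the fitted [calibration_curve()] in
#'   `$curve` plus diagnostics (`$fit`: residuals, RMS residual, parameter
#'   covariance, convergence info). Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @export
fit_calibration <- function(titration, weights = NULL) {
  check_columns(titration, c("free_ca_um", "ratio"), "titration table")
  ca <- titration$free_ca_um
  r  <- titration$ratio
  if (length(ca) < 5)
    abort("Titration table must have at least 5 rows.",
          class = "mitofret_fit_precondition")
  if (any(!is.finite(ca)) || any(ca < 0))
    abort("free_ca_um must be finite and >= 0.",
          class = "mitofret_fit_precondition")
  if (any(diff(ca) <= 0))
    abort("free_ca_um must be strictly increasing.",
          class = "mitofret_fit_precondition")
  if (any(!is.finite(r)) || any(r <= 0))
    abort("Ratios must be finite and > 0.",
          class = "mitofret_fit_precondition")
  if (diff(range(r)) == 0)
    abort("Ratios are all equal; the sigmoid is unidentifiable.",
          class = "mitofret_fit_precondition")

  # Initialization: observed extremes, concentration nearest the midpoint.
  mid <- (min(r) + max(r)) / 2
  pos <- ca > 0
  kd0 <- if (any(pos)) ca[pos][which.min(abs(r[pos] - mid))] else 1
  start <- list(rmin = min(r), rmax = max(r), lkd = log(kd0), ln = 0)

  dat <- data.frame(ca = ca, r = r)
  args <- list(
    r ~ rmin + (rmax - rmin) * ca^exp(ln) /
      (exp(lkd)^exp(ln) + ca^exp(ln)),
    data = dat, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) abort(
      paste0("Calibration fit did not converge: ", conditionMessage(e)),
      class = "mitofret_fit_failure"
    )
  )

  est <- coef(fit)
  curve <- calibration_curve(
    r_min = unname(est["rmin"]), r_max = unname(est["rmax"]),
    kd_um = exp(unname(est["lkd"])), hill_n = exp(unname(est["ln"]))
  )
  res <- resid(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 4, 4))
  structure(
    list(
      curve = curve,
      fit = list(
        residuals = as.numeric(res),
        rms = sqrt(mean(res^2)),
        sigma = summary(fit)$sigma,
        cov = vc,
        converged = fit$convInfo$isConv,
        iterations = fit$convInfo$finIter,
        nobs = length(r)
      ),
      data = as_tibble(titration),
      model = fit
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> Hill sigmoid, Levenberg-Marquardt\n")
  print(x$curve)
  cat(sprintf("  RMS residual = %.3g on %d points\n", x$fit$rms, x$fit$nobs))
  invisible(x)
}

#' @describeIn fit_calibration Parameter estimates and standard errors
#'   (delta method for the log-fitted Kd' and Hill n).
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) {
  est <- c(x$curve$r_min, x$curve$r_max, x$curve$kd_um, x$curve$hill_n)
  se_raw <- sqrt(diag(x$fit$cov))
  se <- c(se_raw[1], se_raw[2], x$curve$kd_um * se_raw[3],
          x$curve$hill_n * se_raw[4])
  tibble(
    term = c("r_min", "r_max", "kd_um", "hill_n"),
    estimate = est,
    std.error = unname(se)
  )
}

#' @describeIn fit_calibration One-row fit summary.
#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(
    rms = x$fit$rms, sigma = x$fit$sigma, nobs = x$fit$nobs,
    iterations = x$fit$iterations, converged = x$fit$converged
  )
}

#' Write / read a calibration curve as JSON
#'
#' The JSON document has fields `r_min`, `r_max`, `kd_um`, `hill_n` and,
#' when written from a `calibration_fit`, a `fit` block with diagnostics.
#'
#' @param x A [calibration_curve()] or `calibration_fit`.
#' @param path File path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a [calibration_curve()].
#' @export
write_calibration <- function(x, path) {
  if (inherits(x, "calibration_fit")) {
    doc <- c(unclass(x$curve),
             list(fit = list(rms = x$fit$rms, sigma = x$fit$sigma,
                             nobs = x$fit$nobs, converged = x$fit$converged)))
  } else {
    stopifnot(inherits(x, "calibration_curve"))
    doc <- unclass(x)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_curve(doc$r_min, doc$r_max, doc$kd_um, doc$hill_n)
}
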