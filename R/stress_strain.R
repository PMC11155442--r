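#' Fit the cervical stress-strain slope
#'
#' The core model: ordinary least squares of applied pressure `p` (kPa) on
#' echo depth `d` (mm) over the valid frames of a depth track,
#' `p = c0 + c1 d`. The cervical elasticity is the absolute slope `|c1|` in
#' kPa/mm — the applied stress divided by the resulting absolute shortening
#' (the "strain" here is a displacement in mm, not a dimensionless ratio) —
#' and the cervical length is the depth at which the fitted line crosses
#' zero pressure, `-c0 / c1`.
#'
#' A fit is flagged valid only when it uses at least `min_frames` frames,
#' spans at least `min_span_kpa` of pressure, reaches `min_r2` in R^2, and
#' has a negative slope of usable magnitude; otherwise `valid` is `FALSE`
#' with a `reason` code (`"too_few_frames"`, `"small_span"`, `"poor_fit"`,
#' `"no_compression"`, `"positive_slope"`). Quality thresholds guard against
#' the low-amplitude failure mode of very soft cervixes. The default span
#' gate of 1 kPa sits about 33 standard deviations above the tactile
#' sensor's 30 Pa noise floor: exams with less compression than that cannot
#' distinguish a slope from pressure noise, while softer-but-measurable
#' cervixes (small spans with clean linear tracks) are retained, matching a
#' study flow in which every examined subject yields an elasticity.
#'
#' @param track A `depth_track` from [track_exam()], or any data frame with
#'   columns `pressure_kpa`, `depth_mm` and (optionally) `valid`.
#' @param quality List of gates: `min_frames` (default 20), `min_span_kpa`
#'   (default 1), `min_r2` (default 0.8).
#' @param method `"ols"` (default) or `"lad"` for a robust
#'   least-absolute-deviations variant (iteratively reweighted least squares
#'   started at the OLS solution).
#' @param sector Optional sector label carried into the fit.
#' @return An object of class `stress_strain_fit` with components
#'   `coefficients` (intercept, slope), `elasticity` (kPa/mm),
#'   `zero_pressure_length` (mm), `r_squared`, `n_frames_used`,
#'   `pressure_span`, `valid`, `reason`, and the `(depth, pressure)` data
#'   used. Supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot` and `simulate`.
#' @examples
#' d <- data.frame(pressure_kpa = c(0, 21), depth_mm = c(43, 25))
#' fit <- fit_stress_strain(d, quality = list(min_frames = 2, min_span_kpa = 5,
#'                                            min_r2 = 0.8))
#' coef(fit)            # elasticity 21/18 = 1.1667 kPa/mm, length 43 mm
#' @export
fit_stress_strain <- function(track, quality = list(), method = c("ols", "lad"),
                              sector = NULL) {
  method <- match.arg(method)
  q <- utils::modifyList(list(min_frames = 20, min_span_kpa = 1, min_r2 = 0.8),
                         quality)
  stopifnot(is.data.frame(track),
            all(c("pressure_kpa", "depth_mm") %in% names(track)))
  use <- if ("valid" %in% names(track)) track$valid else rep(TRUE, nrow(track))
  use <- use & is.finite(track$pressure_kpa) & is.finite(track$depth_mm)
  d <- track$depth_mm[use]
  p <- track$pressure_kpa[use]
  n <- length(d)
  if (n < 2) stop("need at least 2 valid frames to fit the stress-strain slope")

  var_d <- stats::var(d)
  if (var_d < .Machine$double.eps) {
    fit <- .ss_fit_obj(c(NA_real_, NA_real_), NA_real_, NA_real_, NA_real_,
                       n, diff(range(p)), FALSE, "no_compression",
                       d, p, method, sector)
    return(fit)
  }
  c1 <- stats::cov(d, p) / var_d
  c0 <- mean(p) - c1 * mean(d)
  if (method == "lad") {
    co <- .lad_line(d, p, c(c0, c1))
    c0 <- co[1]; c1 <- co[2]
  }
  res <- p - (c0 + c1 * d)
  ss_tot <- sum((p - mean(p))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  span <- diff(range(p))

  reason <- NULL
  if (abs(c1) < 1e-6) reason <- "no_compression"
  else if (c1 > 0) reason <- "positive_slope"
  else if (n < q$min_frames) reason <- "too_few_frames"
  else if (span < q$min_span_kpa) reason <- "small_span"
  else if (r2 < q$min_r2) reason <- "poor_fit"
  valid <- is.null(reason)

  .ss_fit_obj(c(c0, c1), abs(c1), -c0 / c1, r2, n, span, valid,
              if (valid) NA_character_ else reason, d, p, method, sector)
}

.ss_fit_obj <- function(coefs, elasticity, length0, r2, n, span, valid,
                        reason, d, p, method, sector) {
  structure(list(
    coefficients = stats::setNames(coefs, c("intercept_kpa", "slope_kpa_mm")),
    elasticity = elasticity,
    zero_pressure_length = length0,
    r_squared = r2,
    n_frames_used = n,
    pressure_span = span,
    valid = valid,
    reason = reason,
    sector = sector,
    method = method,
    data = data.frame(depth_mm = d, pressure_kpa = p)
  ), class = "stress_strain_fit")
}

# Least-absolute-deviations line via IRLS, started at the OLS solution.
.lad_line <- function(d, p, start, iter = 50, tol = 1e-10) {
  co <- start
  X <- cbind(1, d)
  for (k in seq_len(iter)) {
    r <- as.numeric(p - X %*% co)
    w <- 1 / pmax(abs(r), 1e-8)
    fit <- stats::lm.wfit(X, p, w)
    new <- unname(fit$coefficients)
    if (max(abs(new - co)) < tol) break
    co <- new
  }
  co
}

#' @export
print.stress_strain_fit <- function(x, ...) {
  cat("Cervical stress-strain fit",
      if (!is.null(x$sector)) sprintf("(%s sector)", x$sector), "\n")
  if (x$valid) {
    cat(sprintf("  elasticity %.3f kPa/mm, cervical length %.1f mm\n",
                x$elasticity, x$zero_pressure_length))
  } else {
    cat(sprintf("  INVALID (%s)\n", x$reason))
  }
  cat(sprintf("  R^2 = %.4f over %d frames, pressure span %.1f kPa\n",
              x$r_squared, x$n_frames_used, x$pressure_span))
  invisible(x)
}

#' @export
coef.stress_strain_fit <- function(object, ...) {
  c(elasticity_kpa_mm = object$elasticity,
    length_mm = object$zero_pressure_length)
}

#' @export
fitted.stress_strain_fit <- function(object, ...) {
  co <- object$coefficients
  co[1] + co[2] * object$data$depth_mm
}

#' @export
residuals.stress_strain_fit <- function(object, ...) {
  object$data$pressure_kpa - fitted(object)
}

#' Predict applied pressure at given echo depths
#'
#' @param object A [fit_stress_strain()] model.
#' @param newdata Optional data frame with `depth_mm` (defaults to the fit
#'   data).
#' @param ... Unused.
#' @return Predicted pressure, kPa.
#' @export
predict.stress_strain_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$depth_mm else newdata$depth_mm
  co <- object$coefficients
  unname(co[1] + co[2] * d)
}

#' @export
summary.stress_strain_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object,
                 sigma = stats::sd(r),
                 resid_quantiles = stats::quantile(r)),
            class = "summary.stress_strain_fit")
}

#' @export
print.summary.stress_strain_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sd %.3f kPa\n", x$sigma))
  cat("  residual quantiles (kPa):\n")
  print(round(x$resid_quantiles, 3))
  invisible(x)
}

#' Plot a stress-strain fit
#'
#' Scatter of applied pressure against echo depth with the fitted line,
#' extended to its zero-pressure intercept (the cervical length).
#'
#' @param x A [fit_stress_strain()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stress_strain_fit <- function(x, ...) {
  d <- x$data$depth_mm; p <- x$data$pressure_kpa
  xlim <- range(c(d, x$zero_pressure_length), na.rm = TRUE)
  graphics::plot(d, p, xlab = "Echo depth (mm)",
                 ylab = "Applied pressure (kPa)", xlim = xlim, ...)
  if (all(is.finite(x$coefficients))) {
    graphics::abline(x$coefficients[1], x$coefficients[2], lty = 2, col = 4)
    graphics::abline(h = 0, col = "grey")
    if (is.finite(x$zero_pressure_length)) {
      graphics::points(x$zero_pressure_length, 0, pch = 4, col = 2)
    }
  }
  invisible(x)
}

#' Simulate new exams from a fitted stress-strain model
#'
#' Turns the fitted elasticity and zero-pressure length back into a
#' [tissue_model()] and simulates fresh exam recordings from it.
#'
#' @param object A valid [fit_stress_strain()] model.
#' @param nsim Number of exams.
#' @param seed Optional seed.
#' @param probe,protocol Acquisition settings for the simulated exams.
#' @param ... Passed to [simulate_exam()] (e.g. `snr_db`).
#' @return A list of `exam_recording` objects.
#' @export
simulate.stress_strain_fit <- function(object, nsim = 1, seed = NULL,
                                       probe = probe_spec(),
                                       protocol = compression_protocol(), ...) {
  if (!object$valid) stop("cannot simulate from an invalid fit")
  if (!is.null(seed)) set.seed(seed)
  tis <- tissue_model(true_elasticity = object$elasticity,
                      rest_length = object$zero_pressure_length)
  lapply(seq_len(nsim), function(i) {
    simulate_exam(tis, probe, protocol, seed = NULL, ...)
  })
}

#' Per-subject average of the two sector fits
#'
#' Averages the anterior (12 o'clock) and posterior (6 o'clock) elasticity
#' and length over the sectors whose fits are valid; falls back to the single
#' valid sector with a flag when one failed.
#'
#' @param anterior,posterior [fit_stress_strain()] models (either may be
#'   invalid, but not both).
#' @return List with `avg_elasticity` (kPa/mm), `avg_length` (mm),
#'   `n_sectors` and `single_sector` flag.
#' @export
subject_summary <- function(anterior, posterior) {
  fits <- list(anterior = anterior, posterior = posterior)
  ok <- vapply(fits, function(f) inherits(f, "stress_strain_fit") && f$valid,
               logical(1))
  if (!any(ok)) stop("both sector fits invalid: subject unusable")
  e <- vapply(fits[ok], function(f) f$elasticity, numeric(1))
  l <- vapply(fits[ok], function(f) f$zero_pressure_length, numeric(1))
  list(avg_elasticity = mean(e), avg_length = mean(l),
       n_sectors = sum(ok), single_sector = sum(ok) == 1L)
}
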