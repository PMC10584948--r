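#' FRAP time-intensity trace
#'
#' A fluorescence-recovery-after-photobleaching series: time in seconds
#' (t = 0 at the first post-bleach sample, strictly increasing) and
#' intensity in arbitrary units.
#'
#' @param t Sampling times, s.
#' @param intensity Intensities, same length (>= 4 samples).
#' @return A data.frame of class `frap_trace`.
#' @export
frap_trace <- function(t, intensity) {
  stopifnot(length(t) == length(intensity), length(t) >= 4L)
  if (any(diff(t) <= 0)) stop("FRAP times must be strictly increasing")
  if (any(!is.finite(t)) || any(!is.finite(intensity))) {
    stop("FRAP trace values must be finite")
  }
  structure(data.frame(t = as.numeric(t), intensity = as.numeric(intensity)),
            class = c("frap_trace", "data.frame"))
}

#' Normalize a FRAP trace to pre-bleach intensity
#'
#' Divides intensities by the mean pre-bleach intensity and re-zeroes
#' time to the first post-bleach sample.
#'
#' @param raw A [frap_trace()].
#' @param prebleach Mean pre-bleach intensity (> 0).
#' @return A normalized [frap_trace()].
#' @export
normalize_trace <- function(raw, prebleach) {
  stopifnot(inherits(raw, "frap_trace"))
  if (!is.finite(prebleach) || prebleach <= 0) {
    stop("prebleach intensity must be positive")
  }
  frap_trace(t = raw$t - raw$t[1L], intensity = raw$intensity / prebleach)
}

#' Fit an exponential association recovery
#'
#' Least-squares fit of `I(t) = f0 + (plateau - f0) * (1 - exp(-k t))`
#' to a FRAP trace (Levenberg-Marquardt). Start values: `f0` = first
#' sample, `plateau` = last sample, `k` = 1 / (time at which the trace
#' first crosses half its span). The recovery half-time is `ln(2)/k`.
#'
#' @param trace A [frap_trace()].
#' @return Object of class `frap_fit`: `f0`, `plateau`, `k` (1/s),
#'   `half_time` (s), `covariance` (3x3, order f0/plateau/k),
#'   `converged`, `message`. A flat or non-recovering trace yields
#'   `converged = FALSE` with a diagnostic message rather than numbers.
#' @export
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  y <- trace$intensity
  tt <- trace$t
  span <- y[length(y)] - y[1L]
  fail <- function(msg) {
    structure(list(f0 = NA_real_, plateau = NA_real_, k = NA_real_,
                   half_time = NA_real_, covariance = NULL,
                   converged = FALSE, message = msg),
              class = "frap_fit")
  }
  scale <- max(abs(y), 1e-12)
  if (abs(span) < 1e-10 * scale && stats::sd(y) < 1e-10 * scale) {
    return(fail("flat trace: recovery rate k is unidentifiable"))
  }
  half_level <- y[1L] + span / 2
  cross <- which(if (span >= 0) y >= half_level else y <= half_level)
  t_half0 <- if (length(cross) && tt[cross[1L]] > 0) tt[cross[1L]]
  else max(tt[2L], 1e-6)
  start <- list(f0 = y[1L], plateau = y[length(y)], k = 1 / t_half0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      intensity ~ f0 + (plateau - f0) * (1 - exp(-k * t)),
      data = data.frame(t = tt, intensity = y),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500L,
                                           ftol = 1e-10, ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(fail(paste("fit failure:", conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  if (!is.finite(cf[["k"]]) || cf[["k"]] <= 0) {
    return(fail(sprintf("fit failure: non-positive rate k = %g", cf[["k"]])))
  }
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(list(f0 = unname(cf[["f0"]]), plateau = unname(cf[["plateau"]]),
                 k = unname(cf[["k"]]),
                 half_time = log(2) / unname(cf[["k"]]),
                 covariance = vc, converged = TRUE, message = "ok"),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<frap_fit> k = %.4g /s, half-time = %.1f s, f0 = %.3g, plateau = %.3g\n",
      x$k, x$half_time, x$f0, x$plateau))
  } else {
    cat("<frap_fit> not converged:", x$message, "\n")
  }
  invisible(x)
}

#' Bleach-region geometry for diffusion estimates
#'
#' Describes the photobleached region. A square region of side L is
#' mapped to the equal-area circle (effective radius `L / sqrt(pi)`)
#' because the diffusion formula assumes a circular beam.
#'
#' @param shape `"circle"` or `"square"`.
#' @param size Radius (circle) or side length (square), um.
#' @param gamma Dimensionless beam factor; 0.88 for a uniform circular
#'   beam.
#' @return A list of class `bleach_geometry` with `effective_radius`
#'   (um).
#' @export
bleach_geometry <- function(shape = c("square", "circle"), size = 5,
                            gamma = 0.88) {
  shape <- match.arg(shape)
  stopifnot(size > 0, gamma > 0)
  w <- switch(shape, circle = size, square = size / sqrt(pi))
  structure(list(shape = shape, size = size, effective_radius = w,
                 gamma = gamma),
            class = "bleach_geometry")
}

#' Diffusion coefficient from a FRAP fit
#'
#' Classic spot-photobleaching estimate: `D = gamma * w^2 / (4 * t_half)`
#' with `w` the effective bleach radius (um) and `t_half` the recovery
#' half-time (s).
#'
#' @param fit A converged [fit_recovery()] result.
#' @param geom A [bleach_geometry()].
#' @return Diffusion coefficient, um^2/s.
#' @export
diffusion_coefficient <- function(fit, geom) {
  stopifnot(inherits(fit, "frap_fit"), inherits(geom, "bleach_geometry"))
  if (!fit$converged) stop("cannot compute D from a non-converged fit")
  if (!is.finite(fit$half_time) || fit$half_time <= 0) {
    stop("half_time must be positive, got ", fit$half_time)
  }
  geom$gamma * geom$effective_radius^2 / (4 * fit$half_time)
}

#' Fit a batch of FRAP traces
#'
#' @param traces List of [frap_trace()] objects.
#' @param geom Optional [bleach_geometry()]; when given, a diffusion
#'   coefficient column is added.
#' @param ids Optional trace identifiers.
#' @return Data.frame: trace_id, f0, plateau, k, half_time_s, D_um2_s,
#'   converged.
#' @export
fit_frap_batch <- function(traces, geom = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("trace%03d", seq_along(traces))
  rows <- lapply(seq_along(traces), function(i) {
    f <- fit_recovery(traces[[i]])
    data.frame(trace_id = ids[i], f0 = f$f0, plateau = f$plateau,
               k = f$k, half_time_s = f$half_time,
               D_um2_s = if (!is.null(geom) && f$converged)
                 diffusion_coefficient(f, geom) else NA_real_,
               converged = f$converged)
  })
  do.call(rbind, rows)
}
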