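#' Bolus time-intensity model
#'
#' The per-pixel contrast time-intensity curve is modelled as
#' \deqn{I(t) = a_0 + a_1 \frac{e^{-a_2 t}}{1 + e^{-a_3 (t - t_0)}}}
#' where `a0` is the baseline intensity before contrast arrival, `a1` the
#' intensity increment of the bolus, `a2` (1/s) the washout rate at which
#' the peak intensity is halved, `a3` (1/s) the rising slope of the wash-in,
#' and `t0` (s) the transition point of the perfusion process. The decay
#' exponential multiplies only the increment, so `I(t) -> a0` as
#' `t -> Inf` whenever `a2 > 0`.
#'
#' @param t time(s) in seconds (vectorized).
#' @param a0,a1,a2,a3,t0 model parameters; alternatively pass a `tic_fit`
#'   object via `fit` and leave these unset.
#' @param fit optional `tic_fit` object supplying the parameters.
#' @return Model intensity at `t`.
#' @examples
#' bolus_model(seq(0, 10, 0.5), a0 = 0, a1 = 80, a2 = 0.1, a3 = 3, t0 = 1.5)
#' @export
bolus_model <- function(t, a0, a1, a2, a3, t0, fit = NULL) {
  if (!is.null(fit)) {
    p <- coef(fit)
    a0 <- p[["a0"]]; a1 <- p[["a1"]]; a2 <- p[["a2"]]
    a3 <- p[["a3"]]; t0 <- p[["t0"]]
  }
  a0 + a1 * exp(-a2 * t) / (1 + exp(-a3 * (t - t0)))
}

# analytic time derivative of the bolus model
bolus_model_deriv <- function(t, a1, a2, a3, t0) {
  lgs <- 1 / (1 + exp(-a3 * (t - t0)))
  a1 * exp(-a2 * t) * lgs * (a3 * (1 - lgs) - a2)
}

#' Estimate transition time and baseline from frame differences
#'
#' The transition point `t0` is the acquisition time of the frame with the
#' largest positive frame-to-frame intensity difference (earliest frame on
#' ties). The baseline `a0` is the mean intensity of the frames acquired
#' strictly before the *onset* of the rise: starting from the
#' maximum-difference frame, the onset is found by walking backwards while
#' successive differences still exceed `onset_frac` of the peak difference,
#' so that the shoulder of the wash-in does not contaminate the baseline.
#' If no frame precedes the onset, the first frame's value is used.
#'
#' A transition is only `detected` when the peak difference exceeds
#' `k_mad` times the median absolute deviation of all frame-to-frame
#' differences of the pixel — a robust noise floor suited to the short
#' series that 6 fps runs produce. Constant series return
#' `detected = FALSE` with `t0 = NA` and `a0` equal to the constant.
#'
#' @param series numeric vector of per-pixel intensities over frames
#'   (length >= 2).
#' @param fps frames per second.
#' @param k_mad noise-floor multiplier (default 3). The MAD of the
#'   differences over-estimates pure noise when the bolus occupies a
#'   sizeable share of a short series, so the multiplier is deliberately
#'   conservative.
#' @param onset_frac fraction of the peak frame difference below which the
#'   rise is considered not yet underway (default 0.05).
#' @return List with `t0` (s, `NA` when undetected), `a0`, `detected`.
#' @export
estimate_t0_a0 <- function(series, fps, k_mad = 3, onset_frac = 0.05) {
  if (length(series) < 2L)
    stop("`series` needs at least 2 frames", call. = FALSE)
  d <- diff(series)
  k <- which.max(d)
  dmax <- d[k]
  if (!is.finite(dmax) || dmax <= 0)
    return(list(t0 = NA_real_, a0 = mean(series), detected = FALSE))
  floor_ <- k_mad * stats::mad(d)
  detected <- dmax > floor_
  # walk back from the peak-slope frame to the rise onset
  j <- k
  while (j > 1L && d[j - 1L] > onset_frac * dmax) j <- j - 1L
  a0 <- if (j == 1L) series[1L] else mean(series[seq_len(j)])
  t0 <- k / fps  # difference k sits between frames k-1 and k (0-based frame k)
  if (!detected) t0 <- NA_real_
  list(t0 = t0, a0 = a0, detected = detected)
}

#' Fit the bolus model to a pixel's time-intensity curve
#'
#' Two-stage procedure: `t0` and `a0` are fixed at their frame-difference
#' estimates (see [estimate_t0_a0()]) and only `(a1, a2, a3)` are fitted by
#' bounded nonlinear least squares (Levenberg-Marquardt,
#' `minpack.lm::nls.lm`). Bounds: `a1` in `[0, 10 * range(series)]`,
#' `a2` and `a3` in `[0, 50]` 1/s. Start values: `a1 = range(series)`,
#' `a2 = 0.1`, `a3 = 2`; at most 200 iterations, objective tolerance 1e-8.
#' Optimizer failure is reported via `converged = FALSE`, not an error.
#'
#' @param series numeric vector of intensities over frames (length >= 6).
#' @param fps frames per second.
#' @param init list with `t0`, `a0`, `detected` from [estimate_t0_a0()];
#'   computed automatically when omitted.
#' @return An object of class `tic_fit` with methods [coef()], [predict()],
#'   [fitted()], [residuals()], [print()] and [summary()].
#' @examples
#' t <- (0:59) / 6
#' y <- bolus_model(t, a0 = 10, a1 = 60, a2 = 0.15, a3 = 15, t0 = 2)
#' fit <- fit_tic(y, fps = 6)
#' coef(fit)
#' @export
fit_tic <- function(series, fps, init = NULL) {
  if (length(series) < 6L)
    stop("`series` needs at least 6 frames to fit 3 free parameters",
         call. = FALSE)
  if (is.null(init)) init <- estimate_t0_a0(series, fps)
  if (!isTRUE(init$detected))
    stop("no contrast transition detected; nothing to fit", call. = FALSE)
  t <- (seq_along(series) - 1) / fps
  a0 <- init$a0; t0 <- init$t0
  rng <- diff(range(series))
  if (rng == 0) rng <- 1
  obj <- function(p) bolus_model(t, a0, p[1L], p[2L], p[3L], t0) - series
  res <- tryCatch(
    minpack.lm::nls.lm(par = c(a1 = rng, a2 = 0.1, a3 = 2),
                       lower = c(0, 0, 0), upper = c(10 * rng, 50, 50),
                       fn = obj,
                       control = minpack.lm::nls.lm.control(maxiter = 200,
                                                            ftol = 1e-8)),
    error = function(e) NULL)
  if (is.null(res)) {
    pars <- c(a1 = rng, a2 = 0.1, a3 = 2)
    converged <- FALSE
  } else {
    pars <- res$par
    converged <- res$info %in% 1:4
  }
  resid <- obj(pars)
  structure(
    list(coefficients = c(a0 = unname(a0), a1 = unname(pars[["a1"]]),
                          a2 = unname(pars[["a2"]]), a3 = unname(pars[["a3"]]),
                          t0 = unname(t0)),
         rss = sum(resid^2), converged = converged,
         series = series, fps = fps, times = t),
    class = "tic_fit")
}

#' @export
coef.tic_fit <- function(object, ...) object$coefficients

#' @export
predict.tic_fit <- function(object, t = object$times, ...) {
  bolus_model(t, fit = object)
}

#' @export
fitted.tic_fit <- function(object, ...) predict(object)

#' @export
residuals.tic_fit <- function(object, ...) object$series - fitted(object)

#' @export
print.tic_fit <- function(x, ...) {
  p <- x$coefficients
  cat(sprintf(paste0("<tic_fit> a0=%.4g  a1=%.4g  a2=%.4g/s  a3=%.4g/s  ",
                     "t0=%.4g s\n  rss=%.4g over %d frames at %g fps%s\n"),
              p["a0"], p["a1"], p["a2"], p["a3"], p["t0"],
              x$rss, length(x$series), x$fps,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' @export
summary.tic_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  peak model enhancement %.4g at t=%.3g s\n",
              max(fitted(object)) - object$coefficients["a0"],
              object$times[which.max(fitted(object))]))
  invisible(object)
}

#' Plot a fitted time-intensity curve
#'
#' @param x a `tic_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tic_fit <- function(x, ...) {
  graphics::plot(x$times, x$series, xlab = "time (s)", ylab = "intensity",
                 pch = 16, cex = 0.6, ...)
  tt <- seq(min(x$times), max(x$times), length.out = 400)
  graphics::lines(tt, predict(x, tt), col = "red3", lwd = 2)
  graphics::abline(v = x$coefficients["t0"], lty = 3)
  invisible(x)
}
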