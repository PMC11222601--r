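#' Parameter-map computation settings
#'
#' @param threshold_fraction rise/fall trigger as a fraction of the
#'   per-pixel enhancement range (peak minus baseline); default 0.15, i.e.
#'   a "greater than 15%" increase marks arrival. Interpreted relative to
#'   the enhancement range rather than the raw baseline because subtracted
#'   angiograms have near-zero backgrounds.
#' @param window analysis time window `c(t_start, t_end)` in seconds, the
#'   "selected time region"; `NULL` (default) means the full sequence. A
#'   single global window, not per-pixel.
#' @return A list of class `param_config`.
#' @export
param_config <- function(threshold_fraction = 0.15, window = NULL) {
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("`threshold_fraction` must be in (0, 1)", call. = FALSE)
  if (!is.null(window)) {
    if (length(window) != 2L || !all(is.finite(window)) ||
        window[1] < 0 || window[1] >= window[2])
      stop("`window` must be c(t_start, t_end) with 0 <= t_start < t_end",
           call. = FALSE)
  }
  structure(list(threshold_fraction = threshold_fraction, window = window),
            class = "param_config")
}

# indices of frame times inside the window
window_frames <- function(times, cfg) {
  if (is.null(cfg$window)) return(seq_along(times))
  idx <- which(times >= cfg$window[1] & times <= cfg$window[2])
  if (length(idx) < 2L)
    stop("analysis window contains fewer than 2 frames", call. = FALSE)
  idx
}

#' Time of arrival of contrast at a pixel
#'
#' The time of the first frame (inside the analysis window) whose intensity
#' exceeds `baseline + threshold_fraction * (peak - baseline)`, with the
#' baseline taken from [estimate_t0_a0()] and the peak being the windowed
#' series maximum. Times are absolute (seconds since acquisition start).
#'
#' @param series per-pixel intensities over frames.
#' @param fps frames per second.
#' @param cfg a [param_config()].
#' @return List with `toa` (s) and `valid`.
#' @export
compute_toa <- function(series, fps, cfg = param_config()) {
  times <- (seq_along(series) - 1) / fps
  idx <- window_frames(times, cfg)
  y <- series[idx]
  est <- estimate_t0_a0(y, fps)
  pk <- max(y)
  if (!est$detected || pk <= est$a0)
    return(list(toa = NA_real_, valid = FALSE))
  thr <- est$a0 + cfg$threshold_fraction * (pk - est$a0)
  hit <- which(y > thr)[1]
  if (is.na(hit)) return(list(toa = NA_real_, valid = FALSE))
  list(toa = times[idx[hit]], valid = TRUE)
}

#' Transit time of contrast through a pixel
#'
#' Time between the first significant rise (as in [compute_toa()]) and the
#' first frame *after* the peak whose intensity drops below
#' `peak - threshold_fraction * (peak - baseline)`. Invalid when either
#' trigger is absent (e.g. a monotone series with no washout).
#'
#' @inheritParams compute_toa
#' @return List with `transit` (s, >= 0) and `valid`.
#' @export
compute_transit <- function(series, fps, cfg = param_config()) {
  times <- (seq_along(series) - 1) / fps
  idx <- window_frames(times, cfg)
  y <- series[idx]
  rise <- compute_toa(series, fps, cfg)
  if (!rise$valid) return(list(transit = NA_real_, valid = FALSE))
  est <- estimate_t0_a0(y, fps)
  pk <- max(y)
  kpk <- which.max(y)
  thr <- pk - cfg$threshold_fraction * (pk - est$a0)
  after <- which(seq_along(y) > kpk & y < thr)[1]
  if (is.na(after)) return(list(transit = NA_real_, valid = FALSE))
  list(transit = times[idx[after]] - rise$toa, valid = TRUE)
}

#' Time to peak of a pixel's time-intensity curve
#'
#' Time of the first frame attaining the windowed maximum (earliest frame
#' wins ties). Constant series are invalid.
#'
#' @inheritParams compute_toa
#' @return List with `ttp` (s) and `valid`.
#' @export
compute_ttp <- function(series, fps, cfg = param_config()) {
  times <- (seq_along(series) - 1) / fps
  idx <- window_frames(times, cfg)
  y <- series[idx]
  if (diff(range(y)) == 0) return(list(ttp = NA_real_, valid = FALSE))
  list(ttp = times[idx[which.max(y)]], valid = TRUE)
}

#' Area under the fitted enhancement curve
#'
#' Trapezoidal integral, over the analysis window sampled at the frame
#' times, of `max(bolus_model(t) - a0, 0)` — the fitted enhancement above
#' baseline. Requires a converged fit.
#'
#' @param fit a [fit_tic()] result.
#' @param cfg a [param_config()].
#' @param fps frames per second (defaults to the fit's).
#' @return List with `auc` (intensity * s, >= 0) and `valid`.
#' @export
compute_auc <- function(fit, cfg = param_config(), fps = fit$fps) {
  if (!isTRUE(fit$converged)) return(list(auc = NA_real_, valid = FALSE))
  times <- fit$times
  idx <- window_frames(times, cfg)
  tt <- times[idx]
  enh <- pmax(predict(fit, tt) - coef(fit)[["a0"]], 0)
  auc <- sum(diff(tt) * (utils::head(enh, -1) + utils::tail(enh, -1)) / 2)
  list(auc = auc, valid = TRUE)
}

#' Contrast inflow rate at a pixel
#'
#' The maximum of the analytic time derivative of the fitted bolus curve
#' over the analysis window, evaluated on a grid with 10x the frame-rate
#' resolution — a wash-in rate proxy for the speed of contrast flow.
#'
#' @inheritParams compute_auc
#' @return List with `flow` (intensity / s) and `valid`.
#' @export
compute_flow <- function(fit, cfg = param_config(), fps = fit$fps) {
  if (!isTRUE(fit$converged)) return(list(flow = NA_real_, valid = FALSE))
  times <- fit$times
  idx <- window_frames(times, cfg)
  tt <- seq(times[idx[1]], times[idx[length(idx)]], by = 1 / (10 * fps))
  p <- coef(fit)
  dv <- bolus_model_deriv(tt, p[["a1"]], p[["a2"]], p[["a3"]], p[["t0"]])
  list(flow = max(dv), valid = TRUE)
}

param_units <- c(AUC = "intensity*s", TTP = "s", TOA = "s",
                 TRANSIT = "s", FLOW = "intensity/s")

#' Build a per-pixel parameter map
#'
#' Applies the kind-specific parameter computation to every pixel inside
#' the vessel mask. `TOA`, `TTP` and `TRANSIT` are read directly off the
#' (smoothed) series; `AUC` and `FLOW` are computed from the fitted bolus
#' curve, so pixels where no transition is detected or the fit does not
#' converge come out invalid. Pixels outside the mask are always invalid.
#'
#' @param seq a preprocessed (smoothed, polarity-normalized)
#'   [dsa_sequence()].
#' @param mask a [segment_vessels()] result (or logical matrix).
#' @param kind one of `"AUC"`, `"TTP"`, `"TOA"`, `"TRANSIT"`, `"FLOW"`.
#' @param cfg a [param_config()].
#' @return An object of class `param_map`: `kind`, `values` (matrix),
#'   `valid` (logical matrix), `units`, `fps`.
#' @export
build_param_map <- function(seq, mask, kind = c("TOA", "TTP", "TRANSIT",
                                                "AUC", "FLOW"),
                            cfg = param_config()) {
  stopifnot(inherits(seq, "dsa_sequence"))
  kind <- match.arg(toupper(kind), c("TOA", "TTP", "TRANSIT", "AUC", "FLOW"))
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  d <- dim(seq$frames)
  if (!is.logical(m) || nrow(m) != d[2] || ncol(m) != d[3])
    stop("mask size does not match the sequence frames", call. = FALSE)
  values <- matrix(NA_real_, d[2], d[3])
  valid <- matrix(FALSE, d[2], d[3])
  fps <- seq$fps
  px <- which(m, arr.ind = TRUE)
  for (i in seq_len(nrow(px))) {
    r <- px[i, 1]; cc <- px[i, 2]
    y <- seq$frames[, r, cc]
    res <- switch(kind,
      TOA = { z <- compute_toa(y, fps, cfg); list(v = z$toa, ok = z$valid) },
      TTP = { z <- compute_ttp(y, fps, cfg); list(v = z$ttp, ok = z$valid) },
      TRANSIT = { z <- compute_transit(y, fps, cfg)
                  list(v = z$transit, ok = z$valid) },
      AUC = ,
      FLOW = {
        est <- estimate_t0_a0(y, fps)
        if (!est$detected) list(v = NA_real_, ok = FALSE)
        else {
          fit <- fit_tic(y, fps, init = est)
          if (kind == "AUC") { z <- compute_auc(fit, cfg, fps)
                               list(v = z$auc, ok = z$valid) }
          else { z <- compute_flow(fit, cfg, fps)
                 list(v = z$flow, ok = z$valid) }
        }
      })
    if (isTRUE(res$ok) && is.finite(res$v)) {
      values[r, cc] <- res$v
      valid[r, cc] <- TRUE
    }
  }
  if (!any(valid))
    stop("empty parameter map: no pixel produced a valid ", kind, " value",
         call. = FALSE)
  structure(list(kind = kind, values = values, valid = valid,
                 units = unname(param_units[kind]), fps = fps),
            class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<param_map> %s (%s), %d x %d px, %d valid pixels\n",
              x$kind, x$units, nrow(x$values), ncol(x$values), length(v)))
  cat(sprintf("  value range [%.4g, %.4g], median %.4g\n",
              min(v), max(v), stats::median(v)))
  invisible(x)
}

#' Render a parameter map with a color lookup table
#'
#' @param x a `param_map`.
#' @param lut a [color_lut()] (default the red-yellow-blue arrival scale).
#' @param lo_pct,hi_pct normalization percentiles (see [normalize_map()]).
#' @param ... unused.
#' @export
plot.param_map <- function(x, lut = lut_preset("toa-ryb"),
                           lo_pct = 1, hi_pct = 99, ...) {
  nm <- normalize_map(x, lo_pct, hi_pct)
  rgb <- apply_lut(nm$norm, nm$valid, lut)
  img <- grDevices::as.raster(rgb / 255)
  graphics::plot(c(0, ncol(x$values)), c(0, nrow(x$values)), type = "n",
                 asp = 1, xlab = "", ylab = "", axes = FALSE,
                 main = paste0(x$kind, " (", x$units, ")"))
  graphics::rasterImage(img, 0, 0, ncol(x$values), nrow(x$values))
  invisible(x)
}
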