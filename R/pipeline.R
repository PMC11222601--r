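#' Run configuration for the processing pipeline
#'
#' Every field has a default; the fully-default configuration processes a
#' phantom end to end. A JSON config file with any subset of these fields
#' can seed the configuration; explicit arguments override it.
#'
#' @param input path to the input sequence (TIFF stack, frame directory or
#'   DICOM file).
#' @param out output directory (created if missing).
#' @param fps frame-rate override (frames/s); `NULL` uses source metadata
#'   or the 6 fps default.
#' @param sigma_px Gaussian presmoothing std in pixels.
#' @param threshold_fraction rise/fall trigger fraction (see
#'   [param_config()]).
#' @param window `NULL` or `c(t_start, t_end)` seconds.
#' @param params character vector of parameter kinds, or `"all"`.
#' @param lut LUT preset name or a [color_lut()].
#' @param pct normalization percentiles `c(lo, hi)`.
#' @param min_component_px segmentation component-size floor.
#' @param overlay_alpha `NULL`, or an opacity in (0, 1] to also write
#'   overlay PNGs on the peak-enhancement frame.
#' @param seed integer seed echoed into the run record.
#' @param verbose print stage log lines to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, out = "dsacolor-out", fps = NULL,
                       sigma_px = 1, threshold_fraction = 0.15,
                       window = NULL, params = "all", lut = "toa-ryb",
                       pct = c(1, 99), min_component_px = 16,
                       overlay_alpha = NULL, seed = 1L, verbose = TRUE) {
  kinds <- c("AUC", "TTP", "TOA", "TRANSIT", "FLOW")
  params <- toupper(params)
  if (identical(params, "ALL")) params <- kinds
  bad <- setdiff(params, kinds)
  if (length(bad))
    stop("unknown parameter kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(input = input, out = out, fps = fps, sigma_px = sigma_px,
                 threshold_fraction = threshold_fraction, window = window,
                 params = params, lut = lut, pct = pct,
                 min_component_px = min_component_px,
                 overlay_alpha = overlay_alpha, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Merge a JSON config file with explicit overrides
#'
#' @param path JSON file with any subset of [run_config()] fields.
#' @param ... overrides applied on top of the file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  dots <- list(...)
  spec[names(dots)] <- dots
  do.call(run_config, spec)
}

log_stage <- function(verbose, ...) {
  if (verbose) message("[dsacolor] ", sprintf(...))
}

#' Process a DSA sequence into parameter maps and color renderings
#'
#' The full pipeline: load, polarity-normalize, Gaussian smoothing, vessel
#' segmentation, per-pixel parameter computation and pseudo-color export.
#' Per requested parameter kind it writes `<kind>_map.tif` (16-bit
#' grayscale + JSON scale sidecar), `<kind>_color.png` (8-bit RGB) and,
#' when `overlay_alpha` is set, `<kind>_overlay.png`; plus
#' `vessel_mask.png` and `run_config.json` (a config echo sufficient to
#' reproduce the run, seed included).
#'
#' @param config a [run_config()] with a non-`NULL` `input`.
#' @return Invisibly, a named list of written file paths.
#' @export
run_process <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input))
    stop("`config$input` is required", call. = FALSE)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  v <- config$verbose
  log_stage(v, "load: %s", config$input)
  seq <- load_sequence(config$input, fps_override = config$fps)
  log_stage(v, "smooth: Gaussian sigma = %g px", config$sigma_px)
  sm <- gaussian_lowpass(seq, config$sigma_px)
  log_stage(v, "segment: Otsu on peak enhancement")
  mask <- segment_vessels(sm, segment_config(sigma_px = 0,
                          min_component_px = config$min_component_px))
  log_stage(v, "segment: %d vessel pixels (%.2f%%)", sum(mask$mask),
            100 * mask$coverage_fraction)
  cfg <- param_config(threshold_fraction = config$threshold_fraction,
                      window = config$window)
  lut <- if (inherits(config$lut, "color_lut")) config$lut
         else lut_preset(config$lut)
  written <- list(mask = file.path(config$out, "vessel_mask.png"))
  write_mask_png(mask$mask, written$mask)
  peak_frame <- apply(sm$frames, c(2, 3), max)
  for (kind in config$params) {
    log_stage(v, "map: %s", kind)
    map <- build_param_map(sm, mask, kind, cfg)
    nm <- normalize_map(map, config$pct[1], config$pct[2])
    rgb <- apply_lut(nm$norm, nm$valid, lut)
    base <- file.path(config$out, tolower(kind))
    write_param_tiff(map, paste0(base, "_map.tif"))
    write_color_png(rgb, paste0(base, "_color.png"))
    written[[paste0(kind, "_map")]] <- paste0(base, "_map.tif")
    written[[paste0(kind, "_color")]] <- paste0(base, "_color.png")
    if (!is.null(config$overlay_alpha)) {
      ov <- render_overlay(rgb, peak_frame, config$overlay_alpha)
      write_color_png(ov, paste0(base, "_overlay.png"))
      written[[paste0(kind, "_overlay")]] <- paste0(base, "_overlay.png")
    }
  }
  echo <- config
  echo$lut <- if (inherits(config$lut, "color_lut")) "custom" else config$lut
  cfg_path <- file.path(config$out, "run_config.json")
  jsonlite::write_json(unclass(echo), cfg_path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  written$config <- cfg_path
  log_stage(v, "done: %d artifacts in %s", length(written), config$out)
  invisible(written)
}

#' Generate a phantom and write it to disk
#'
#' Writes the sequence (`sequence.tif` + sidecar), the ground-truth masks
#' (`vessel_mask.png`, `leak_mask.png` when present), the true arrival-time
#' map (`toa_true.tif`, 16-bit with JSON scale sidecar) and the phantom
#' spec echo (`phantom_spec.json`).
#'
#' @param spec a [phantom_spec()].
#' @param out output directory.
#' @param verbose print stage log lines.
#' @return Invisibly, the generated `phantom_truth`.
#' @export
run_phantom <- function(spec = phantom_spec(), out = "phantom-out",
                        verbose = TRUE) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_stage(verbose, "phantom: %dx%d, %d frames, seed %d", spec$height,
            spec$width, spec$n_frames, spec$seed)
  ph <- generate_phantom(spec)
  save_sequence(ph$sequence, file.path(out, "sequence.tif"))
  write_mask_png(ph$vessel_mask, file.path(out, "vessel_mask.png"))
  if (any(ph$leak_mask))
    write_mask_png(ph$leak_mask, file.path(out, "leak_mask.png"))
  toa <- ph$toa_true
  fin <- is.finite(toa)
  map <- structure(list(kind = "TOA", values = toa, valid = fin,
                        units = "s", fps = spec$fps), class = "param_map")
  write_param_tiff(map, file.path(out, "toa_true.tif"))
  sp <- spec
  sp$tube_path <- apply(sp$tube_path, 1, paste, collapse = ",")
  jsonlite::write_json(unclass(sp), file.path(out, "phantom_spec.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  log_stage(verbose, "phantom: written to %s", out)
  invisible(ph)
}

#' Evaluate a paired reader-score table
#'
#' Computes reinforcement counts and the paired Wilcoxon signed-rank test
#' in both directions and returns (optionally writes) a JSON-ready report.
#'
#' @param path CSV path in the [load_scores()] schema.
#' @param out_json optional path for the JSON report.
#' @return The report as a named list, invisibly when `out_json` is given.
#' @export
run_evaluate <- function(path, out_json = NULL) {
  tab <- load_scores(path)
  wsr <- wilcoxon_signed_rank(tab$score_dsa, tab$score_combined)
  report <- list(
    n_cases = nrow(tab),
    toward_bleeding = count_reinforced(tab, "toward_bleeding"),
    toward_no_bleeding = count_reinforced(tab, "toward_no_bleeding"),
    wilcoxon = list(statistic = wsr$statistic, p_value = wsr$p_value,
                    n_effective = wsr$n_effective, method = wsr$method))
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}

#' Re-render an exported parameter map with a new LUT
#'
#' Reads a `<kind>_map.tif` written by [run_process()] (and its JSON scale
#' sidecar), renormalizes and applies a LUT without refitting anything.
#'
#' @param map_tiff path to the 16-bit map TIFF.
#' @param out_png output PNG path.
#' @param lut LUT preset name or [color_lut()].
#' @param pct normalization percentiles.
#' @return `out_png`, invisibly.
#' @export
run_colorize <- function(map_tiff, out_png, lut = "toa-ryb", pct = c(1, 99)) {
  meta <- jsonlite::read_json(sidecar_path(map_tiff), simplifyVector = TRUE)
  u <- tiff::readTIFF(map_tiff)
  valid <- u > 0
  if (!any(valid)) stop("map has no valid pixels", call. = FALSE)
  values <- matrix(NA_real_, nrow(u), ncol(u))
  values[valid] <- as.numeric(meta$offset) +
    (u[valid] * 65535 - 1) / 65534 * as.numeric(meta$scale)
  map <- structure(list(kind = meta$kind, values = values, valid = valid,
                        units = meta$units, fps = NA_real_),
                   class = "param_map")
  lut <- if (inherits(lut, "color_lut")) lut else lut_preset(lut)
  nm <- normalize_map(map, pct[1], pct[2])
  write_color_png(apply_lut(nm$norm, nm$valid, lut), out_png)
  invisible(out_png)
}
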