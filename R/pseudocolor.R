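#' Color lookup table
#'
#' A LUT is an ordered list of stops: positions in `[0, 1]` (first at 0,
#' last at 1, strictly increasing) with RGB triples 0-255. A table of
#' `n_entries` colors is precomputed by channel-wise linear interpolation
#' in RGB space, so rendering is deterministic and monotone along the stop
#' sequence.
#'
#' @param positions numeric vector of stop positions.
#' @param colors matrix with one row per stop and columns R, G, B (0-255).
#' @param n_entries table length (default 256).
#' @return An object of class `color_lut`.
#' @seealso [lut_preset()], [apply_lut()]
#' @export
color_lut <- function(positions, colors, n_entries = 256L) {
  colors <- as.matrix(colors)
  if (length(positions) < 2L || nrow(colors) != length(positions) ||
      ncol(colors) != 3L)
    stop("need >= 2 stops, one RGB triple per stop", call. = FALSE)
  if (positions[1] != 0 || positions[length(positions)] != 1 ||
      any(diff(positions) <= 0))
    stop("stop positions must go from 0 to 1, strictly increasing",
         call. = FALSE)
  if (any(colors < 0 | colors > 255))
    stop("RGB values must be 0-255", call. = FALSE)
  grid <- seq(0, 1, length.out = n_entries)
  table <- vapply(1:3, function(ch)
    stats::approx(positions, colors[, ch], xout = grid)$y,
    numeric(n_entries))
  structure(list(positions = positions, colors = colors,
                 n_entries = as.integer(n_entries), table = table),
            class = "color_lut")
}

#' Built-in lookup tables
#'
#' `"toa-ryb"` is the clinical arrival-time scale: red (255,0,0) for the
#' earliest-arriving contrast, through yellow (255,255,0) at mid-scale, to
#' blue (0,0,255) for the latest arrivals. It is also the default for the
#' other four parameter kinds, and can be overridden with any
#' [color_lut()].
#'
#' @param name LUT name; currently `"toa-ryb"` or `"gray"`.
#' @return A [color_lut()].
#' @export
lut_preset <- function(name = "toa-ryb") {
  switch(name,
    "toa-ryb" = color_lut(c(0, 0.5, 1),
                          rbind(c(255, 0, 0), c(255, 255, 0), c(0, 0, 255))),
    "gray" = color_lut(c(0, 1), rbind(c(0, 0, 0), c(255, 255, 255))),
    stop("unknown LUT preset '", name, "'", call. = FALSE))
}

#' @export
print.color_lut <- function(x, ...) {
  cat(sprintf("<color_lut> %d stops, %d entries\n", length(x$positions),
              x$n_entries))
  for (i in seq_along(x$positions))
    cat(sprintf("  %.3f -> rgb(%d, %d, %d)\n", x$positions[i],
                x$colors[i, 1], x$colors[i, 2], x$colors[i, 3]))
  invisible(x)
}

#' Normalize a parameter map onto [0, 1]
#'
#' Valid values are affinely mapped so the `lo_pct` percentile goes to 0
#' and the `hi_pct` percentile to 1, then clipped — percentile rather than
#' min-max normalization keeps single-pixel outliers from unstable fits
#' from compressing the scale. When all valid values are identical they all
#' map to 0.5 (documented convention).
#'
#' @param map a [build_param_map()] result.
#' @param lo_pct,hi_pct percentiles, `0 <= lo_pct < hi_pct <= 100`
#'   (defaults 1 and 99).
#' @return List with `norm` (matrix in `[0, 1]`, `NA` outside validity) and
#'   `valid`.
#' @export
normalize_map <- function(map, lo_pct = 1, hi_pct = 99) {
  stopifnot(inherits(map, "param_map"))
  if (!is.numeric(lo_pct) || !is.numeric(hi_pct) || lo_pct < 0 ||
      hi_pct > 100 || lo_pct >= hi_pct)
    stop("need 0 <= lo_pct < hi_pct <= 100", call. = FALSE)
  v <- map$values[map$valid]
  if (!length(v)) stop("map has no valid pixels", call. = FALSE)
  q <- stats::quantile(v, c(lo_pct, hi_pct) / 100, names = FALSE)
  norm <- matrix(NA_real_, nrow(map$values), ncol(map$values))
  if (q[2] > q[1]) {
    norm[map$valid] <- pmin(1, pmax(0, (map$values[map$valid] - q[1]) /
                                         (q[2] - q[1])))
  } else {
    norm[map$valid] <- 0.5
  }
  list(norm = norm, valid = map$valid)
}

#' Apply a color LUT to a normalized map
#'
#' Valid pixels are colored by channel-wise linear interpolation between
#' the LUT stops at their normalized value; invalid pixels get the
#' background color (default black, matching the dark background of
#' subtracted angiograms). Deterministic: the output depends only on the
#' normalized values, the validity mask and the LUT.
#'
#' @param norm matrix of values in `[0, 1]` (where valid).
#' @param valid logical matrix.
#' @param lut a [color_lut()].
#' @param background RGB triple 0-255 for invalid pixels.
#' @return Integer array `height x width x 3`, values 0-255.
#' @export
apply_lut <- function(norm, valid, lut = lut_preset("toa-ryb"),
                      background = c(0, 0, 0)) {
  stopifnot(inherits(lut, "color_lut"), is.logical(valid),
            all(dim(norm) == dim(valid)))
  out <- array(0L, c(nrow(norm), ncol(norm), 3L))
  v <- norm[valid]
  for (ch in 1:3) {
    plane <- matrix(background[ch], nrow(norm), ncol(norm))
    plane[valid] <- stats::approx(lut$positions, lut$colors[, ch],
                                  xout = v)$y
    out[, , ch] <- round(plane)
  }
  storage.mode(out) <- "integer"
  out
}

#' Alpha-blend a color rendering over a grayscale reference frame
#'
#' The reference frame is rescaled to its min-max range, replicated to RGB
#' and blended as `alpha * color + (1 - alpha) * reference`. `alpha = 1`
#' returns the color image, `alpha = 0` the reference rendered as RGB.
#'
#' @param color integer RGB array 0-255, `height x width x 3`.
#' @param reference_frame numeric matrix of the same height/width.
#' @param alpha opacity of the color layer in `[0, 1]` (default 0.5).
#' @return Integer RGB array 0-255.
#' @export
render_overlay <- function(color, reference_frame, alpha = 0.5) {
  if (length(dim(color)) != 3L || !all(dim(color)[1:2] == dim(reference_frame)))
    stop("color image and reference frame shapes do not match", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("`alpha` must be in [0, 1]", call. = FALSE)
  rng <- range(reference_frame)
  g <- if (rng[2] > rng[1]) (reference_frame - rng[1]) / (rng[2] - rng[1]) * 255
       else matrix(0, nrow(reference_frame), ncol(reference_frame))
  out <- array(0L, dim(color))
  for (ch in 1:3) out[, , ch] <- round(alpha * color[, , ch] + (1 - alpha) * g)
  storage.mode(out) <- "integer"
  out
}
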