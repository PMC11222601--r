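#' Construct a DSA image sequence
#'
#' A `dsa_sequence` is the raw input of every pipeline stage: a time-ordered
#' stack of equally sized grayscale frames with a frame rate. Frame `k`
#' (counted from 0) is acquired at time `k / fps` seconds after acquisition
#' start, which the pipeline equates with contrast injection.
#'
#' Intensities are stored as doubles with the convention that contrast
#' arrival *increases* intensity. Use [normalize_polarity()] (applied
#' automatically by [load_sequence()]) for raw material where iodine is dark.
#'
#' @param frames 3D numeric array, `time x height x width`. All values must
#'   be finite and at least 2 frames are required.
#' @param fps frames per second (> 0). Clinical hemorrhage runs are
#'   typically acquired at 6 fps, the package default elsewhere.
#' @param polarity_inverted logical flag recording whether the loader
#'   inverted intensities to make contrast bright.
#' @param source provenance string (file path or generator description).
#' @return An object of class `dsa_sequence`.
#' @seealso [load_sequence()], [save_sequence()], [frame_times()]
#' @export
dsa_sequence <- function(frames, fps, polarity_inverted = FALSE,
                         source = "<memory>") {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3D array (time x height x width)", call. = FALSE)
  if (dim(frames)[1] < 2L)
    stop("a DSA sequence needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(frames)))
    stop("frame intensities must all be finite", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  structure(
    list(frames = frames, fps = as.numeric(fps),
         polarity_inverted = isTRUE(polarity_inverted),
         source = as.character(source)),
    class = "dsa_sequence")
}

#' Acquisition times of each frame
#'
#' @param seq a [dsa_sequence()].
#' @return Numeric vector `c(0, 1/fps, ..., (T-1)/fps)` in seconds.
#' @export
frame_times <- function(seq) {
  stopifnot(inherits(seq, "dsa_sequence"))
  (seq_len(dim(seq$frames)[1]) - 1) / seq$fps
}

#' @export
print.dsa_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dsa_sequence> %d frames of %d x %d px at %g fps (%.2f s)\n",
              d[1], d[2], d[3], x$fps, (d[1] - 1) / x$fps))
  cat(sprintf("  intensity range [%.4g, %.4g]%s\n  source: %s\n",
              min(x$frames), max(x$frames),
              if (x$polarity_inverted) ", polarity inverted on load" else "",
              x$source))
  invisible(x)
}

#' @export
dim.dsa_sequence <- function(x) dim(x$frames)

#' Normalize contrast polarity of a sequence
#'
#' Raw DSA material often encodes iodine as *dark* (subtraction leaves
#' vessels below the background level). All downstream definitions assume
#' that contrast arrival raises intensity, so on load the polarity is
#' checked: over the 1% of pixels with the largest absolute late-minus-first
#' intensity change, if the mean change is negative the whole stack is
#' inverted (`I <- max(I) - I`) and the flag recorded.
#'
#' The "late" intensity is the per-pixel mean over the final 20% of frames,
#' which is robust to single-frame noise at the low frame counts typical of
#' 6 fps runs.
#'
#' @param seq a [dsa_sequence()].
#' @return The sequence, inverted if needed, with `polarity_inverted` set.
#' @export
normalize_polarity <- function(seq) {
  stopifnot(inherits(seq, "dsa_sequence"))
  f <- seq$frames
  nt <- dim(f)[1]
  late_from <- max(2L, nt - max(1L, ceiling(0.2 * nt)) + 1L)
  late <- apply(f[late_from:nt, , , drop = FALSE], c(2, 3), mean)
  change <- late - f[1, , ]
  n_top <- max(1L, ceiling(0.01 * length(change)))
  top <- order(abs(change), decreasing = TRUE)[seq_len(n_top)]
  if (mean(change[top]) < 0) {
    seq$frames <- max(f) - f
    seq$polarity_inverted <- !seq$polarity_inverted
  }
  seq
}

#' Snap intensities to the on-disk storage grid
#'
#' [save_sequence()] stores intensities as 16-bit integers under an affine
#' min/max scale (relative step 1/65535 of the intensity range).
#' `snap_to_storage()` projects an array onto that grid, so that a
#' subsequent save/load round trip reproduces values bit for bit. The
#' phantom generator applies this to its output. The scale is
#' canonicalized to the fixpoint of `(lo + s) - lo` so that the saver,
#' which recomputes it from the snapped data's min/max, lands on the same
#' floating-point number.
#'
#' @param x numeric array.
#' @return `x` with every value moved to the nearest storable value.
#' @export
snap_to_storage <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(x)
  m <- 65535
  s <- hi - lo
  repeat {
    s2 <- (lo + s) - lo
    if (identical(s2, s)) break
    s <- s2
  }
  u <- round((x - lo) / s * m)
  array(lo + u / m * s, dim(x))
}
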