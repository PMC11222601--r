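#' Load a DSA sequence from disk
#'
#' Reads a multi-frame TIFF stack, a directory of equally sized PNG/TIFF
#' frames (strict lexicographic filename order = time order), or an
#' uncompressed grayscale multi-frame DICOM file. The returned sequence is
#' polarity-normalized so that contrast arrival increases intensity (see
#' [normalize_polarity()]).
#'
#' The frame rate is taken, in order of precedence, from a JSON sidecar
#' written by [save_sequence()], from the DICOM CineRate / FrameTime
#' elements, from `fps_override`, and finally from the default of 6 fps.
#'
#' @param path file or directory path.
#' @param fps_override optional frames per second, used when the source
#'   carries no frame-rate metadata.
#' @return A [dsa_sequence()].
#' @export
load_sequence <- function(path, fps_override = NULL) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file or directory", call. = FALSE)
  if (dir.exists(path)) {
    out <- read_frame_dir(path)
  } else if (is_dicom_file(path)) {
    out <- read_dicom_sequence(path)
  } else {
    out <- read_tiff_stack(path)
  }
  fps <- out$fps
  if (is.null(fps)) fps <- fps_override
  if (is.null(fps)) fps <- 6
  seq <- dsa_sequence(out$frames, fps = fps, source = path)
  if (isTRUE(out$polarity_inverted)) {
    # sidecar says the stored data were already normalized on a previous save
    seq$polarity_inverted <- TRUE
    seq
  } else {
    normalize_polarity(seq)
  }
}

sidecar_path <- function(path) paste0(path, ".json")

read_tiff_stack <- function(path) {
  imgs <- tryCatch(tiff::readTIFF(path, all = TRUE),
                   error = function(e) stop("cannot read '", path,
                                            "' as TIFF: ", conditionMessage(e),
                                            call. = FALSE))
  if (!is.list(imgs)) imgs <- list(imgs)
  if (length(imgs) < 2L)
    stop("'", path, "' holds a single frame; a sequence needs at least 2",
         call. = FALSE)
  imgs <- lapply(imgs, drop_channels)
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames in '", path, "' have mismatched sizes", call. = FALSE)
  frames <- array(0, c(length(imgs), dims[1, 1], dims[2, 1]))
  for (k in seq_along(imgs)) frames[k, , ] <- imgs[[k]]
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    offset <- as.numeric(meta$offset); scale <- as.numeric(meta$scale)
    frames <- offset + frames * scale
    list(frames = frames, fps = as.numeric(meta$fps),
         polarity_inverted = isTRUE(meta$polarity_inverted))
  } else {
    list(frames = frames, fps = NULL, polarity_inverted = FALSE)
  }
}

read_frame_dir <- function(path) {
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- files[order(basename(files), method = "radix")]
  if (length(files) < 2L)
    stop("directory '", path, "' holds fewer than 2 image frames",
         call. = FALSE)
  read1 <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
    drop_channels(img)
  }
  imgs <- lapply(files, read1)
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames in '", path, "' have mismatched sizes", call. = FALSE)
  frames <- array(0, c(length(imgs), dims[1, 1], dims[2, 1]))
  for (k in seq_along(imgs)) frames[k, , ] <- imgs[[k]]
  list(frames = frames, fps = NULL, polarity_inverted = FALSE)
}

# collapse an RGB(A) plane to grayscale by averaging color channels
drop_channels <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- min(dim(img)[3], 3L)
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  img
}

#' Save a DSA sequence as a TIFF stack
#'
#' Writes a multi-frame TIFF plus a JSON sidecar (`<path>.json`) carrying
#' the frame rate, the affine intensity scale and the polarity flag.
#' Samples are stored as 16-bit integers under a min/max affine map; the
#' sidecar records `offset` and `scale` at full double precision so that
#' [load_sequence()] reproduces intensities exactly for any sequence on the
#' storage grid (see [snap_to_storage()]); other sequences are quantized to
#' 1/65535 of their intensity range on the first save and exactly
#' thereafter.
#'
#' @param seq a [dsa_sequence()].
#' @param path output file path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
save_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "dsa_sequence"))
  if (!dir.exists(dirname(path)))
    stop("parent directory '", dirname(path), "' does not exist",
         call. = FALSE)
  f <- seq$frames
  lo <- min(f); hi <- max(f)
  scale <- hi - lo
  # quantize to the 16-bit grid ourselves (round to nearest); exact grid
  # values pass through the TIFF encoder unchanged
  u <- if (scale > 0) round((f - lo) / scale * 65535) / 65535
       else array(0, dim(f))
  planes <- lapply(seq_len(dim(f)[1]), function(k) u[k, , ])
  n_written <- tiff::writeTIFF(planes, path, bits.per.sample = 16L,
                               compression = "none", reduce = FALSE)
  if (!identical(as.integer(n_written), length(planes)))
    stop("failed to write TIFF stack to '", path, "'", call. = FALSE)
  meta <- list(format = "dsacolor-sequence", version = 1L,
               fps = seq$fps,
               offset = sprintf("%.17g", lo),
               scale = sprintf("%.17g", if (scale > 0) scale else 0),
               polarity_inverted = seq$polarity_inverted)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Load a paired reader-score table
#'
#' Reads a CSV with columns `case_id`, `score_dsa`, `score_combined` (and an
#' optional `truth` column) holding one consensus 1-5 Likert confidence
#' score per case for the DSA-only and the DSA-plus-color reading:
#' 1 definitely no bleeding, 2 probably none, 3 uncertain, 4 probable
#' bleeding, 5 definite bleeding.
#'
#' @param path CSV file path (UTF-8, header row required).
#' @return A `paired_scores` data frame.
#' @seealso [count_reinforced()], [wilcoxon_signed_rank()],
#'   [clinical_fixtures()]
#' @export
load_scores <- function(path) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  paired_scores(df)
}

#' Construct a paired score table
#'
#' @param df data frame with columns `case_id`, `score_dsa`,
#'   `score_combined` and optionally `truth` (one of `"bleeding"`,
#'   `"no_bleeding"`, `"unknown"`).
#' @return A data frame of class `paired_scores`.
#' @export
paired_scores <- function(df) {
  need <- c("case_id", "score_dsa", "score_combined")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("score table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("score table has no rows", call. = FALSE)
  for (col in c("score_dsa", "score_combined")) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v != round(v) | v < 1 | v > 5)
    if (length(bad))
      stop(sprintf("column '%s' has a score outside 1-5 in row %d (case '%s')",
                   col, bad[1], df$case_id[bad[1]]), call. = FALSE)
    df[[col]] <- as.integer(v)
  }
  dup <- df$case_id[duplicated(df$case_id)]
  if (length(dup))
    stop("duplicate case_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (is.null(df$truth)) df$truth <- "unknown"
  bad_truth <- setdiff(unique(df$truth), c("bleeding", "no_bleeding", "unknown"))
  if (length(bad_truth))
    stop("column 'truth' has unknown label(s): ",
         paste(bad_truth, collapse = ", "), call. = FALSE)
  class(df) <- c("paired_scores", "data.frame")
  df
}

#' @export
print.paired_scores <- function(x, ...) {
  cat(sprintf("<paired_scores> %d cases (DSA-only vs DSA+color, 1-5 Likert)\n",
              nrow(x)))
  print(as.data.frame(utils::head(x, 6)))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask logical matrix; `TRUE` pixels are written as 255.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Export a parameter map as a 16-bit grayscale TIFF
#'
#' Valid values are affinely scaled to the 16-bit range; the scale (offset,
#' step) and units go to a JSON sidecar so the map can be reconstructed.
#' Invalid pixels are written as 0 and flagged by the sidecar's
#' `invalid_value` convention.
#'
#' @param map a [build_param_map()] result.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_param_tiff <- function(map, path) {
  stopifnot(inherits(map, "param_map"))
  v <- map$values[map$valid]
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  # valid pixels occupy gray levels 1..65535; level 0 is reserved for invalid
  u <- matrix(0, nrow(map$values), ncol(map$values))
  u[map$valid] <- pmin(1, pmax(0, (1 + 65534 * (map$values[map$valid] - lo) /
                                     scale) / 65535))
  tiff::writeTIFF(u, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(format = "dsacolor-parammap", version = 1L,
               kind = map$kind, units = map$units,
               offset = sprintf("%.17g", lo), scale = sprintf("%.17g", scale),
               n_valid = sum(map$valid), invalid_value = 0)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Write an RGB image to PNG
#'
#' @param rgb integer array `height x width x 3` with values 0-255.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_color_png <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  png::writePNG(rgb / 255, path)
  invisible(path)
}
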