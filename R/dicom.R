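# Minimal reader for uncompressed little-endian grayscale multi-frame DICOM
# (XA / secondary capture). Supported transfer syntaxes: implicit VR LE
# (1.2.840.10008.1.2) and explicit VR LE (1.2.840.10008.1.2.1). Compressed
# syntaxes, big-endian and color photometric interpretations are rejected.

is_dicom_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", n = 132L)
  length(hdr) == 132L && rawToChar(hdr[129:132]) == "DICM"
}

u16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
u32 <- function(r, i) {
  as.numeric(r[i]) + 256 * as.numeric(r[i + 1L]) +
    65536 * as.numeric(r[i + 2L]) + 16777216 * as.numeric(r[i + 3L])
}

# VRs whose explicit-VR header carries a 2-byte reserved field + 4-byte length
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one data element starting at offset i (1-based) of raw vector r.
# Returns list(group, element, vr, len, value_offset, next_offset).
parse_element <- function(r, i, explicit) {
  group <- u16(r, i); element <- u16(r, i + 2L)
  if (explicit && !(group == 0xFFFEL)) {
    vr <- rawToChar(r[(i + 4L):(i + 5L)])
    if (vr %in% LONG_VRS) {
      len <- u32(r, i + 8L); vo <- i + 12L
    } else {
      len <- u16(r, i + 6L); vo <- i + 8L
    }
  } else {
    vr <- "UN"; len <- u32(r, i + 4L); vo <- i + 8L
  }
  list(group = group, element = element, vr = vr, len = len,
       value_offset = vo, next_offset = if (len == 0xFFFFFFFF) vo else vo + len)
}

# Skip an undefined-length sequence by scanning for its delimitation item.
skip_undefined <- function(r, i) {
  while (i + 7L <= length(r)) {
    g <- u16(r, i); e <- u16(r, i + 2L); len <- u32(r, i + 4L)
    if (g == 0xFFFEL && e == 0xE0DDL) return(i + 8L)          # SQ delimiter
    if (g == 0xFFFEL && e == 0xE0DEL) { i <- i + 8L; next }   # item delimiter
    if (g == 0xFFFEL && e == 0xE000L) {                       # item
      i <- if (len == 0xFFFFFFFF) i + 8L else i + 8L + len
      next
    }
    stop("unsupported undefined-length element in DICOM stream", call. = FALSE)
  }
  stop("unterminated undefined-length sequence in DICOM file", call. = FALSE)
}

dicom_string <- function(r, el) {
  if (el$len == 0) return("")
  trimws(rawToChar(r[el$value_offset:(el$value_offset + el$len - 1L)]))
}

read_dicom_sequence <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 140L || rawToChar(r[129:132]) != "DICM")
    stop("'", path, "' is not a DICOM file", call. = FALSE)
  i <- 133L
  ts <- "1.2.840.10008.1.2.1"
  # file meta group (0002,xxxx) is always explicit VR little endian
  while (i + 7L <= length(r)) {
    el <- parse_element(r, i, explicit = TRUE)
    if (el$group != 2L) break
    if (el$element == 0x0010L) ts <- dicom_string(r, el)
    i <- el$next_offset
  }
  explicit <- switch(ts,
    "1.2.840.10008.1.2" = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stop("unsupported DICOM transfer syntax '", ts,
         "' (only uncompressed little endian is supported)", call. = FALSE))

  rows <- cols <- n_frames <- bits <- NULL
  pixel_rep <- 0L; photometric <- "MONOCHROME2"
  fps <- NULL; pixel <- NULL
  while (i + 7L <= length(r)) {
    el <- parse_element(r, i, explicit)
    tag <- sprintf("%04X,%04X", el$group, el$element)
    if (el$len == 0xFFFFFFFF) {
      if (tag == "7FE0,0010")
        stop("encapsulated (compressed) DICOM pixel data is not supported",
             call. = FALSE)
      i <- skip_undefined(r, el$value_offset)
      next
    }
    val <- function() r[el$value_offset:(el$value_offset + el$len - 1L)]
    switch(tag,
      "0018,0040" = { fps <- as.numeric(dicom_string(r, el)) },           # CineRate
      "0018,1063" = { ft <- as.numeric(dicom_string(r, el))              # FrameTime ms
                      if (is.null(fps) && is.finite(ft) && ft > 0) fps <- 1000 / ft },
      "0028,0002" = { if (u16(r, el$value_offset) != 1L)
                        stop("color DICOM (SamplesPerPixel > 1) is not supported",
                             call. = FALSE) },
      "0028,0004" = { photometric <- dicom_string(r, el) },
      "0028,0008" = { n_frames <- as.integer(dicom_string(r, el)) },
      "0028,0010" = { rows <- u16(r, el$value_offset) },
      "0028,0011" = { cols <- u16(r, el$value_offset) },
      "0028,0100" = { bits <- u16(r, el$value_offset) },
      "0028,0103" = { pixel_rep <- u16(r, el$value_offset) },
      "7FE0,0010" = { pixel <- val() },
      NULL)
    i <- el$next_offset
  }
  if (!photometric %in% c("MONOCHROME1", "MONOCHROME2"))
    stop("unsupported photometric interpretation '", photometric,
         "' (grayscale DICOM only)", call. = FALSE)
  if (is.null(rows) || is.null(cols) || is.null(bits) || is.null(pixel))
    stop("DICOM file is missing image geometry or pixel data", call. = FALSE)
  if (is.null(n_frames)) n_frames <- 1L
  if (n_frames < 2L)
    stop("'", path, "' holds a single frame; a sequence needs at least 2",
         call. = FALSE)
  if (!bits %in% c(8L, 16L))
    stop("unsupported BitsAllocated = ", bits, call. = FALSE)
  npx <- rows * cols * n_frames
  if (length(pixel) < npx * (bits / 8L))
    stop("DICOM pixel data is shorter than Rows*Columns*NumberOfFrames",
         call. = FALSE)
  vals <- readBin(pixel, what = "integer", n = npx, size = bits / 8L,
                  signed = (pixel_rep == 1L && bits == 16L),
                  endian = "little")
  if (pixel_rep == 1L && bits == 8L) vals <- ifelse(vals > 127L, vals - 256L, vals)
  if (pixel_rep == 0L && bits == 16L) vals <- ifelse(vals < 0L, vals + 65536, vals)
  # pixel order within a frame is row-major (row by row)
  frames <- array(0, c(n_frames, rows, cols))
  per <- rows * cols
  for (k in seq_len(n_frames)) {
    fr <- matrix(vals[((k - 1) * per + 1):(k * per)], nrow = rows,
                 ncol = cols, byrow = TRUE)
    frames[k, , ] <- fr
  }
  if (photometric == "MONOCHROME1") frames <- max(frames) - frames
  list(frames = frames, fps = fps, polarity_inverted = FALSE)
}
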