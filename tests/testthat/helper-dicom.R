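# Construct a minimal uncompressed explicit-VR little-endian multi-frame
# grayscale DICOM file in code, for exercising the DICOM reading path.

le16 <- function(x) as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
le32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

dcm_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L)
    value_raw <- c(value_raw, as.raw(if (vr == "UI") 0L else 32L))
  hdr <- c(le16(group), le16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0L, 0L)), le32(length(value_raw)), value_raw)
  } else {
    c(hdr, le16(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, element, vr, s) dcm_element(group, element, vr,
                                                       charToRaw(s))
dcm_us <- function(group, element, x) dcm_element(group, element, "US",
                                                  le16(as.integer(x)))

# frames: list of integer matrices (rows x cols), values 0..65535
write_test_dicom <- function(path, frames, frame_time_ms = NULL,
                             cine_rate = NULL,
                             photometric = "MONOCHROME2") {
  rows <- nrow(frames[[1]]); cols <- ncol(frames[[1]])
  pix <- unlist(lapply(frames, function(f) as.integer(t(f))))  # row-major
  pix_raw <- writeBin(pix, raw(), size = 2L, endian = "little")
  meta <- c(
    dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    dcm_str(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1"))
  meta <- c(dcm_element(0x0002L, 0x0000L, "UL", le32(length(meta))), meta)
  body <- raw(0)
  if (!is.null(cine_rate))
    body <- c(body, dcm_str(0x0018L, 0x0040L, "IS", as.character(cine_rate)))
  if (!is.null(frame_time_ms))
    body <- c(body, dcm_str(0x0018L, 0x1063L, "DS",
                            as.character(frame_time_ms)))
  body <- c(body,
    dcm_us(0x0028L, 0x0002L, 1L),
    dcm_str(0x0028L, 0x0004L, "CS", photometric),
    dcm_str(0x0028L, 0x0008L, "IS", as.character(length(frames))),
    dcm_us(0x0028L, 0x0010L, rows),
    dcm_us(0x0028L, 0x0011L, cols),
    dcm_us(0x0028L, 0x0100L, 16L),
    dcm_us(0x0028L, 0x0103L, 0L),
    dcm_element(0x7FE0L, 0x0010L, "OW", pix_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
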