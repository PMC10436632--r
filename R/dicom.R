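# Minimal multi-frame DICOM codec: uncompressed little-endian transfer
# syntaxes only (explicit VR 1.2.840.10008.1.2.1, implicit VR
# 1.2.840.10008.1.2), 8- or 16-bit grayscale or 8-bit interleaved RGB.
# Vendor private tags are skipped; compressed syntaxes are rejected.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"

.u16 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "little",
          signed = FALSE)
}
.u32 <- function(raw, off) {
  v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
               endian = "little")
  if (v < 0) v <- v + 2^32
  v
}
.ascii <- function(raw, off, len) {
  if (len == 0) return("")
  bytes <- raw[(off + 1):(off + len)]
  while (length(bytes) &&
         (bytes[length(bytes)] == as.raw(0) ||
          bytes[length(bytes)] == as.raw(32))) {
    bytes <- bytes[-length(bytes)]
  }
  rawToChar(bytes)
}

# VRs that use the 12-byte explicit header (2 reserved + 4-byte length)
.LONG_VRS <- c("OB", "OW", "OF", "OL", "OD", "SQ", "UC", "UR", "UT", "UN")

# Advance past an undefined-length value by scanning for the sequence
# delimitation item (FFFE,E0DD). Returns the offset just past it.
.skip_undefined <- function(raw, off) {
  n <- length(raw)
  while (off + 8 <= n) {
    if (.u16(raw, off) == 0xFFFE && .u16(raw, off + 2) == 0xE0DD) {
      return(off + 8)
    }
    off <- off + 2
  }
  stop("unterminated undefined-length DICOM element", call. = FALSE)
}

# Parse one data element starting at byte offset `off` (0-based).
# Returns list(group, elem, vr, value_off, value_len, next_off).
.parse_element <- function(raw, off, explicit) {
  group <- .u16(raw, off)
  elem <- .u16(raw, off + 2)
  if (explicit) {
    vr <- rawToChar(raw[(off + 5):(off + 6)])
    if (vr %in% .LONG_VRS) {
      len <- .u32(raw, off + 8)
      value_off <- off + 12
    } else {
      len <- .u16(raw, off + 6)
      value_off <- off + 8
    }
  } else {
    vr <- NA_character_
    len <- .u32(raw, off + 4)
    value_off <- off + 8
  }
  if (len == 4294967295) {  # 0xFFFFFFFF: undefined length
    next_off <- .skip_undefined(raw, value_off)
    len <- 0
  } else {
    next_off <- value_off + len
  }
  list(group = group, elem = elem, vr = vr,
       value_off = value_off, value_len = len, next_off = next_off)
}

#' Read a multi-frame DICOM cine loop
#'
#' Reads an uncompressed little-endian multi-frame DICOM file into a
#' [frame_sequence]. Color frames (RGB) are converted to grayscale with
#' the standard luma weights (0.299, 0.587, 0.114); 16-bit grayscale is
#' rescaled linearly onto `[0, 255]`. The frame interval is taken from
#' the Frame Time attribute (0018,1063), falling back to
#' `default_interval` when absent. Pixel Spacing (0028,0030) populates
#' `pixel_spacing` when present.
#'
#' @param path path to a multi-frame DICOM file.
#' @param default_interval seconds per frame to use when the file carries
#'   no Frame Time attribute; `NULL` (the default) makes a missing
#'   attribute an error.
#' @return a [frame_sequence].
#' @export
read_dicom_sequence <- function(path, default_interval = NULL) {
  if (!file.exists(path)) {
    stop("cannot read DICOM file: ", path, call. = FALSE)
  }
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140) stop("not a DICOM file: ", path, call. = FALSE)

  if (rawToChar(raw[129:132]) == "DICM") {
    off <- 132
  } else if (rawToChar(raw[1:4]) == "DICM") {
    off <- 4
  } else {
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  }

  # File meta group (0002) is always explicit VR little endian.
  transfer_syntax <- UID_EXPLICIT_LE
  n <- length(raw)
  while (off + 8 <= n && .u16(raw, off) == 0x0002) {
    el <- .parse_element(raw, off, explicit = TRUE)
    if (el$elem == 0x0010) {
      transfer_syntax <- .ascii(raw, el$value_off, el$value_len)
    }
    off <- el$next_off
  }
  if (!transfer_syntax %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE)) {
    stop("unsupported (compressed?) transfer syntax: ", transfer_syntax,
         call. = FALSE)
  }
  explicit <- transfer_syntax == UID_EXPLICIT_LE

  tags <- list()
  pixel_data <- NULL
  while (off + 8 <= n) {
    el <- .parse_element(raw, off, explicit)
    key <- sprintf("%04X%04X", el$group, el$elem)
    if (el$group == 0x7FE0 && el$elem == 0x0010) {
      pixel_data <- raw[(el$value_off + 1):(el$value_off + el$value_len)]
      break
    }
    if (el$group == 0x0008 || el$group == 0x0018 || el$group == 0x0028) {
      vr <- el$vr
      if (is.na(vr)) {
        vr <- switch(key,
                     "00280002" = , "00280006" = , "00280010" = ,
                     "00280011" = , "00280100" = , "00280101" = ,
                     "00280102" = , "00280103" = "US",
                     "TXT")
      }
      tags[[key]] <- if (vr == "US") {
        .u16(raw, el$value_off)
      } else {
        .ascii(raw, el$value_off, el$value_len)
      }
    }
    off <- el$next_off
  }
  if (is.null(pixel_data)) {
    stop("DICOM file has no pixel data: ", path, call. = FALSE)
  }

  rows <- tags[["00280010"]]
  cols <- tags[["00280011"]]
  if (is.null(rows) || is.null(cols)) {
    stop("DICOM file lacks Rows/Columns attributes", call. = FALSE)
  }
  nframes <- if (!is.null(tags[["00280008"]])) {
    as.integer(tags[["00280008"]])
  } else 1L
  if (nframes < 2L) {
    stop("not a cine loop: DICOM file has ", nframes, " frame(s)",
         call. = FALSE)
  }
  samples <- if (!is.null(tags[["00280002"]])) tags[["00280002"]] else 1L
  bits <- if (!is.null(tags[["00280100"]])) tags[["00280100"]] else 8L
  if (!bits %in% c(8L, 16L)) {
    stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  }
  if (bits == 16L && samples != 1L) {
    stop("16-bit color DICOM is not supported", call. = FALSE)
  }

  frame_time_ms <- tags[["00181063"]]
  if (!is.null(frame_time_ms) && nzchar(frame_time_ms)) {
    frame_interval <- as.numeric(frame_time_ms) / 1000
  } else if (!is.null(default_interval)) {
    frame_interval <- default_interval
  } else {
    stop("DICOM file has no Frame Time (0018,1063) and no ",
         "default_interval was supplied", call. = FALSE)
  }

  pixel_spacing <- NULL
  ps <- tags[["00280030"]]
  if (!is.null(ps) && nzchar(ps)) {
    pixel_spacing <- as.numeric(strsplit(ps, "\\\\")[[1]])[1:2]
  }

  npx <- as.numeric(rows) * cols * nframes * samples
  if (bits == 8L) {
    vals <- as.numeric(pixel_data[seq_len(npx)])
  } else {
    vals <- readBin(pixel_data, "integer", n = npx, size = 2,
                    endian = "little", signed = FALSE)
    vmax <- max(vals)
    vals <- if (vmax > 255) vals * (255 / vmax) else as.numeric(vals)
  }

  frames <- vector("list", nframes)
  per_frame <- rows * cols * samples
  for (k in seq_len(nframes)) {
    fv <- vals[((k - 1) * per_frame + 1):(k * per_frame)]
    if (samples == 3L) {
      # interleaved RGB (PlanarConfiguration 0) -> luma
      r <- fv[seq(1, per_frame, by = 3)]
      g <- fv[seq(2, per_frame, by = 3)]
      b <- fv[seq(3, per_frame, by = 3)]
      fv <- 0.299 * r + 0.587 * g + 0.114 * b
    }
    frames[[k]] <- matrix(fv, nrow = rows, ncol = cols, byrow = TRUE)
  }

  frame_sequence(frames, frame_interval, pixel_spacing = pixel_spacing,
                 source_id = path)
}

# UI values are padded with NUL, text values with space, to even length
.raw_str <- function(s, nul = FALSE) {
  out <- charToRaw(s)
  if (length(out) %% 2 == 1) out <- c(out, if (nul) as.raw(0) else charToRaw(" "))
  out
}

.w_short <- function(con, group, elem, vr, value_raw) {
  writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
  writeChar(vr, con, nchars = 2, eos = NULL)
  writeBin(as.integer(length(value_raw)), con, size = 2, endian = "little")
  if (length(value_raw)) writeBin(value_raw, con)
}

.w_long <- function(con, group, elem, vr, value_raw) {
  writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
  writeChar(vr, con, nchars = 2, eos = NULL)
  writeBin(as.integer(c(0)), con, size = 2, endian = "little")
  writeBin(as.integer(length(value_raw)), con, size = 4, endian = "little")
  writeBin(value_raw, con)
}

.raw_us <- function(x) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.integer(x), con, size = 2, endian = "little")
  rawConnectionValue(con)
}

#' Write a frame sequence as a multi-frame DICOM file
#'
#' Writes an explicit-VR little-endian, uncompressed multi-frame DICOM
#' file (Secondary Capture SOP class). Intended for building test
#' fixtures and for exporting phantom loops in a clinical container;
#' round-trips exactly through [read_dicom_sequence()].
#'
#' @param seq a [frame_sequence]; intensities are rounded to 8-bit.
#' @param path output file path.
#' @param rgb if `TRUE`, store each frame as RGB with R=G=B (for testing
#'   the color pathway).
#' @param omit_frame_time if `TRUE`, do not write the Frame Time
#'   attribute (for testing the fallback contract).
#' @return `path`, invisibly.
#' @export
write_dicom_sequence <- function(seq, path, rgb = FALSE,
                                 omit_frame_time = FALSE) {
  stopifnot(inherits(seq, "frame_sequence"))
  d <- dim(seq$frames[[1]])
  con <- file(path, "wb")
  on.exit(close(con))

  # file meta group, always explicit VR LE
  meta <- rawConnection(raw(0), "wb")
  mw <- function(group, elem, vr, value_raw) {
    writeBin(as.integer(c(group, elem)), meta, size = 2, endian = "little")
    writeChar(vr, meta, nchars = 2, eos = NULL)
    writeBin(as.integer(length(value_raw)), meta, size = 2,
             endian = "little")
    writeBin(value_raw, meta)
  }
  mw(0x0002, 0x0002, "UI", .raw_str("1.2.840.10008.5.1.4.1.1.7", nul = TRUE))
  mw(0x0002, 0x0003, "UI", .raw_str("1.2.826.0.1.3680043.9999.1", nul = TRUE))
  mw(0x0002, 0x0010, "UI", .raw_str(UID_EXPLICIT_LE, nul = TRUE))
  meta_raw <- rawConnectionValue(meta)
  close(meta)

  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  # (0002,0000) File Meta Information Group Length
  writeBin(as.integer(c(0x0002, 0x0000)), con, size = 2, endian = "little")
  writeChar("UL", con, nchars = 2, eos = NULL)
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(length(meta_raw), con, size = 4, endian = "little")
  writeBin(meta_raw, con)

  .w_short(con, 0x0008, 0x0016, "UI",
           .raw_str("1.2.840.10008.5.1.4.1.1.7", nul = TRUE))
  if (!omit_frame_time) {
    .w_short(con, 0x0018, 0x1063, "DS",
             .raw_str(sprintf("%g", seq$frame_interval * 1000)))
  }
  samples <- if (rgb) 3L else 1L
  .w_short(con, 0x0028, 0x0002, "US", .raw_us(samples))
  .w_short(con, 0x0028, 0x0004, "CS",
           .raw_str(if (rgb) "RGB" else "MONOCHROME2"))
  if (rgb) .w_short(con, 0x0028, 0x0006, "US", .raw_us(0L))
  .w_short(con, 0x0028, 0x0008, "IS",
           .raw_str(sprintf("%d", length(seq$frames))))
  .w_short(con, 0x0028, 0x0010, "US", .raw_us(d[1]))
  .w_short(con, 0x0028, 0x0011, "US", .raw_us(d[2]))
  if (!is.null(seq$pixel_spacing)) {
    .w_short(con, 0x0028, 0x0030, "DS",
             .raw_str(sprintf("%g\\%g", seq$pixel_spacing[1],
                              seq$pixel_spacing[2])))
  }
  .w_short(con, 0x0028, 0x0100, "US", .raw_us(8L))
  .w_short(con, 0x0028, 0x0101, "US", .raw_us(8L))
  .w_short(con, 0x0028, 0x0102, "US", .raw_us(7L))
  .w_short(con, 0x0028, 0x0103, "US", .raw_us(0L))

  px <- unlist(lapply(seq$frames, function(f) {
    v <- as.integer(round(t(f)))  # row-major order
    if (rgb) v <- rep(v, each = 3L)
    v
  }), use.names = FALSE)
  if (length(px) %% 2 == 1) px <- c(px, 0L)
  .w_long(con, 0x7FE0, 0x0010, "OB", as.raw(px))
  invisible(path)
}
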