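# Minimal single-frame monochrome DICOM codec (explicit VR little endian).
#
# Scope: uncompressed unsigned-integer grayscale frames, 12 or 16 bits
# stored in 16-bit words, MONOCHROME2, as produced by this package and by
# mainstream archives for CT/MR slices. Anything else (color, multi-frame,
# compressed transfer syntaxes, implicit VR) is rejected explicitly.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_SOP_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
DICOM_IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.10.1462.1"

# deterministic pseudo-UID; DICOM only requires syntactic validity here
dicom_make_uid <- function(pixels) {
  h <- sum(as.numeric(pixels) * (seq_along(pixels) %% 97 + 1)) %% 1e9
  paste0(DICOM_IMPLEMENTATION_UID, ".", format(h, scientific = FALSE), ".",
         nrow(pixels), ".", ncol(pixels))
}

uint16_to_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(as.vector(rbind(v %% 256, (v %/% 256) %% 256)))
}

uint32_to_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

dicom_pad_even <- function(r, pad = as.raw(0L)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

# one explicit-VR data element
dicom_element <- function(group, element, vr, value_raw) {
  value_raw <- dicom_pad_even(value_raw,
                              pad = if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" "))
  head <- c(uint16_to_raw(group), uint16_to_raw(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(head, as.raw(c(0, 0)), uint32_to_raw(length(value_raw)), value_raw)
  } else {
    c(head, uint16_to_raw(length(value_raw)), value_raw)
  }
}

dicom_write_minimal <- function(pixels, path, bit_depth = 16L, modality = "OTHER") {
  stopifnot(is.matrix(pixels))
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1)) {
    stop("pixel value exceeds bit depth range")
  }
  rows <- nrow(pixels); cols <- ncol(pixels)
  sop_uid <- dicom_make_uid(pixels)
  mod <- if (modality %in% c("CT", "MR")) modality else "OT"

  meta <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dicom_element(0x0002, 0x0002, "UI", charToRaw(DICOM_SOP_SECONDARY_CAPTURE)),
    dicom_element(0x0002, 0x0003, "UI", charToRaw(sop_uid)),
    dicom_element(0x0002, 0x0010, "UI", charToRaw(DICOM_TS_EXPLICIT_LE)),
    dicom_element(0x0002, 0x0012, "UI", charToRaw(DICOM_IMPLEMENTATION_UID))
  )
  # pixel data in row-major order as DICOM expects
  pix_raw <- uint16_to_raw(as.vector(t(pixels)))
  body <- c(
    dicom_element(0x0008, 0x0016, "UI", charToRaw(DICOM_SOP_SECONDARY_CAPTURE)),
    dicom_element(0x0008, 0x0018, "UI", charToRaw(sop_uid)),
    dicom_element(0x0008, 0x0060, "CS", charToRaw(mod)),
    dicom_element(0x0028, 0x0002, "US", uint16_to_raw(1L)),
    dicom_element(0x0028, 0x0004, "CS", charToRaw("MONOCHROME2")),
    dicom_element(0x0028, 0x0010, "US", uint16_to_raw(rows)),
    dicom_element(0x0028, 0x0011, "US", uint16_to_raw(cols)),
    dicom_element(0x0028, 0x0100, "US", uint16_to_raw(16L)),
    dicom_element(0x0028, 0x0101, "US", uint16_to_raw(bit_depth)),
    dicom_element(0x0028, 0x0102, "US", uint16_to_raw(bit_depth - 1L)),
    dicom_element(0x0028, 0x0103, "US", uint16_to_raw(0L)),
    dicom_element(0x7FE0, 0x0010, "OW", pix_raw)
  )
  out <- c(rep(as.raw(0L), 128L), charToRaw("DICM"),
           dicom_element(0x0002, 0x0000, "UL", uint32_to_raw(length(meta))),
           meta, body)
  writeBin(out, path)
  invisible(path)
}

raw_to_uint <- function(r) sum(as.numeric(r) * 256^(seq_along(r) - 1))

dicom_read_minimal <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 140) stop("unreadable DICOM file: ", path)
  buf <- readBin(path, "raw", n = n)
  if (rawToChar(buf[129:132]) != "DICM") stop("unreadable DICOM file (no DICM marker): ", path)
  pos <- 133L
  fields <- list(modality = "OTHER")
  long_vrs <- c("OB", "OW", "SQ", "UN", "UT")
  repeat {
    if (pos + 7L > n) break
    group <- raw_to_uint(buf[pos:(pos + 1L)])
    element <- raw_to_uint(buf[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("unsupported format: implicit VR or corrupt element at offset ", pos)
    }
    if (vr %in% long_vrs) {
      len <- raw_to_uint(buf[(pos + 8L):(pos + 11L)])
      val_start <- pos + 12L
    } else {
      len <- raw_to_uint(buf[(pos + 6L):(pos + 7L)])
      val_start <- pos + 8L
    }
    if (len == 4294967295) stop("unsupported format: undefined-length element")
    val <- if (len > 0) buf[val_start:(val_start + len - 1L)] else raw(0)
    key <- sprintf("%04X%04X", group, element)
    if (key == "00020010") {
      ts <- sub("\\x00+$", "", rawToChar(val))
      if (ts != DICOM_TS_EXPLICIT_LE) {
        stop("unsupported format: transfer syntax ", ts)
      }
    } else if (key == "00080060") {
      fields$modality <- trimws(rawToChar(val))
    } else if (key == "00280002") {
      if (raw_to_uint(val[1:2]) != 1) stop("unsupported format: SamplesPerPixel != 1")
    } else if (key == "00280008") {
      if (suppressWarnings(as.integer(trimws(rawToChar(val)))) > 1L) {
        stop("unsupported format: multi-frame DICOM")
      }
    } else if (key == "00280010") {
      fields$rows <- raw_to_uint(val[1:2])
    } else if (key == "00280011") {
      fields$cols <- raw_to_uint(val[1:2])
    } else if (key == "00280100") {
      if (raw_to_uint(val[1:2]) != 16) stop("unsupported format: BitsAllocated != 16")
    } else if (key == "00280101") {
      fields$bit_depth <- raw_to_uint(val[1:2])
    } else if (key == "00280103") {
      if (raw_to_uint(val[1:2]) != 0) stop("unsupported format: signed pixel data")
    } else if (key == "7FE00010") {
      fields$pixel_raw <- val
      break
    }
    pos <- val_start + len
  }
  if (is.null(fields$rows) || is.null(fields$cols) || is.null(fields$pixel_raw)) {
    stop("unreadable DICOM file: missing Rows/Columns/PixelData")
  }
  if (is.null(fields$bit_depth)) fields$bit_depth <- 16L
  npx <- fields$rows * fields$cols
  if (length(fields$pixel_raw) < 2 * npx) stop("unreadable DICOM file: truncated pixel data")
  b <- as.numeric(fields$pixel_raw[seq_len(2 * npx)])
  v <- b[c(TRUE, FALSE)] + 256 * b[c(FALSE, TRUE)]
  pixels <- matrix(v, nrow = fields$rows, ncol = fields$cols, byrow = TRUE)
  list(pixels = pixels, bit_depth = as.integer(fields$bit_depth),
       modality = fields$modality)
}
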