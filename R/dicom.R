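#' Minimal uncompressed RGB multi-frame DICOM IO
#'
#' A small, self-contained codec for the one encoding the pipeline needs:
#' little-endian uncompressed 8-bit RGB multi-frame files (Explicit VR on
#' write; Explicit or Implicit VR accepted on read). It is not a general
#' DICOM implementation — compressed transfer syntaxes and nested sequences
#' are rejected with a clear error. No R DICOM package is declared because
#' the package only ever touches this single, fully specified layout.
#'
#' @name dicom_io
NULL

uint_le <- function(x, size) {
  x <- as.numeric(x)
  raws <- raw(size)
  for (i in seq_len(size)) {
    raws[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  raws
}

read_uint_le <- function(con, size) {
  b <- readBin(con, "raw", n = size)
  if (length(b) < size) stop("unexpected end of DICOM file")
  sum(as.numeric(b) * 256^(seq_len(size) - 1))
}

even_pad <- function(bytes, pad = as.raw(0L)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

# string value with trailing NUL/space padding stripped
raw_string <- function(bytes) {
  bytes <- bytes[bytes != as.raw(0L)]
  trimws(rawToChar(bytes))
}

dicom_element <- function(group, element, vr, value) {
  if (is.character(value)) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value <- even_pad(charToRaw(value), pad)
  }
  header <- c(uint_le(group, 2L), uint_le(element, 2L), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(header, raw(2L), uint_le(length(value), 4L), value)
  } else {
    c(header, uint_le(length(value), 2L), value)
  }
}

#' @rdname dicom_io
#' @param frames List of [frame_image()]s with identical dimensions.
#' @param path Output file path.
#' @return `write_dicom_rgb()`: `path`, invisibly. `read_dicom_rgb()`: list
#'   of [frame_image()]s in frame order.
#' @export
write_dicom_rgb <- function(frames, path) {
  if (length(frames) == 0L) stop("cannot write a DICOM file with 0 frames")
  d <- dim(frames[[1]]$pixels)
  for (f in frames) {
    if (!identical(dim(f$pixels), d)) stop("all frames must share dimensions")
  }
  H <- d[1]; W <- d[2]; n <- length(frames)

  # pixel order per frame: channel fastest, then column, then row
  pixel_data <- do.call(c, lapply(frames, function(f) {
    as.raw(as.vector(aperm(f$pixels, c(3L, 2L, 1L))))
  }))
  pixel_data <- even_pad(pixel_data)

  sop_class <- "1.2.840.10008.5.1.4.1.1.3.1"  # US multi-frame image storage
  sop_inst <- "1.2.826.0.1.3680043.9.9999.1.1"
  transfer <- "1.2.840.10008.1.2.1"           # explicit VR little endian

  meta <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dicom_element(0x0002, 0x0002, "UI", sop_class),
    dicom_element(0x0002, 0x0003, "UI", sop_inst),
    dicom_element(0x0002, 0x0010, "UI", transfer),
    dicom_element(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.9999.2")
  )
  meta <- c(dicom_element(0x0002, 0x0000, "UL", uint_le(length(meta), 4L)),
            meta)

  body <- c(
    dicom_element(0x0008, 0x0016, "UI", sop_class),
    dicom_element(0x0008, 0x0018, "UI", sop_inst),
    dicom_element(0x0008, 0x0060, "CS", "US"),
    dicom_element(0x0028, 0x0002, "US", uint_le(3L, 2L)),
    dicom_element(0x0028, 0x0004, "CS", "RGB"),
    dicom_element(0x0028, 0x0006, "US", uint_le(0L, 2L)),
    dicom_element(0x0028, 0x0008, "IS", as.character(n)),
    dicom_element(0x0028, 0x0010, "US", uint_le(H, 2L)),
    dicom_element(0x0028, 0x0011, "US", uint_le(W, 2L)),
    dicom_element(0x0028, 0x0100, "US", uint_le(8L, 2L)),
    dicom_element(0x0028, 0x0101, "US", uint_le(8L, 2L)),
    dicom_element(0x0028, 0x0102, "US", uint_le(7L, 2L)),
    dicom_element(0x0028, 0x0103, "US", uint_le(0L, 2L)),
    dicom_element(0x7FE0, 0x0010, "OB", pixel_data)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# parse one data element; returns list(group, element, value (raw)) or NULL
# at end of file. `explicit` switches the VR encoding.
read_dicom_element <- function(con, explicit) {
  gb <- readBin(con, "raw", n = 2L)
  if (length(gb) < 2L) return(NULL)
  group <- sum(as.numeric(gb) * c(1, 256))
  element <- read_uint_le(con, 2L)
  if (explicit || group == 0x0002) {
    vr <- rawToChar(readBin(con, "raw", n = 2L))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      readBin(con, "raw", n = 2L)  # reserved
      len <- read_uint_le(con, 4L)
    } else {
      len <- read_uint_le(con, 2L)
    }
  } else {
    vr <- NA_character_
    len <- read_uint_le(con, 4L)
  }
  if (len == 4294967295) {
    stop("undefined-length DICOM elements (sequences/encapsulation) are not supported")
  }
  value <- readBin(con, "raw", n = len)
  if (length(value) < len) stop("truncated DICOM element")
  list(group = group, element = element, vr = vr, value = value)
}

#' @rdname dicom_io
#' @export
read_dicom_rgb <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", n = 132L)
  if (length(preamble) < 132L ||
      !identical(rawToChar(preamble[129:132]), "DICM")) {
    stop(sprintf("'%s' is not a DICOM file (missing DICM magic)", path))
  }
  tags <- list()
  explicit <- TRUE
  repeat {
    el <- read_dicom_element(con, explicit)
    if (is.null(el)) break
    key <- sprintf("%04x,%04x", el$group, el$element)
    tags[[key]] <- el
    if (key == "0002,0010") {
      ts <- raw_string(el$value)
      if (ts == "1.2.840.10008.1.2") {
        explicit <- FALSE
      } else if (ts != "1.2.840.10008.1.2.1") {
        stop(sprintf("unsupported DICOM transfer syntax '%s' in '%s'", ts, path))
      }
    }
    if (key == "7fe0,0010") break
  }
  get_u16 <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) stop(sprintf("DICOM tag (%s) missing in '%s'", key, path))
    sum(as.numeric(v$value[1:2]) * c(1, 256))
  }
  get_str <- function(key, default = NULL) {
    v <- tags[[key]]
    if (is.null(v)) return(default)
    raw_string(v$value)
  }
  H <- get_u16("0028,0010")
  W <- get_u16("0028,0011")
  spp <- get_u16("0028,0002")
  bits <- get_u16("0028,0100")
  planar <- if (is.null(tags[["0028,0006"]])) 0 else get_u16("0028,0006")
  n <- as.integer(get_str("0028,0008", "1"))
  photo <- get_str("0028,0004", "")
  if (spp != 3L || bits != 8L || photo != "RGB" || planar != 0) {
    stop(sprintf(
      "'%s': only uncompressed 8-bit interleaved RGB is supported (got %s, %d bits, %d samples)",
      path, photo, bits, spp))
  }
  px <- tags[["7fe0,0010"]]
  if (is.null(px)) stop(sprintf("'%s' has no pixel data", path))
  need <- H * W * 3 * n
  if (length(px$value) < need) stop(sprintf("'%s': truncated pixel data", path))
  lapply(seq_len(n), function(i) {
    chunk <- as.integer(px$value[((i - 1) * H * W * 3 + 1):(i * H * W * 3)])
    arr <- aperm(array(chunk, dim = c(3L, W, H)), c(3L, 2L, 1L))
    frame_image(arr, index = i - 1L)
  })
}
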