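## Minimal EXIF support for PNG images.
##
## Photogrammetry software reads the camera identity and optics from image
## metadata. PNG carries EXIF in the registered eXIf chunk, whose payload is
## a little-endian TIFF IFD structure. This file implements just enough of
## that structure for the pipeline's required fields: Make (0x010F), Model
## (0x0110) and an Exif sub-IFD holding FocalLength (0x920A, rational),
## FocalLengthIn35mmFilm (0xA405, short), BodySerialNumber (0xA431, ASCII)
## and the sensor width in mm. EXIF has no standard sensor-width tag (it is
## a maker/composite field in external tools), so it is stored under the
## private tag 0xEA31 as a rational; read_exif() understands it.

## ---- CRC32 (PNG chunk checksums) ----

## logical (unsigned) right shift on a 32-bit signed integer
shr32 <- function(x, n) {
  if (x >= 0L) return(bitwShiftR(x, n))
  bitwOr(bitwShiftR(bitwAnd(x, 2147483647L), n),
         bitwShiftL(1L, 31L - n))
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L) != 0L)
          bitwXor(-306674912L, shr32(c, 1L))  # 0xEDB88320 as signed int
        else shr32(c, 1L)
      t[n + 1L] <- c
    }
    tab <<- t
    tab
  }
})

## CRC-32 (ISO 3309, as used by PNG); returns an unsigned numeric
crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(shr32(crc, 8L), tab[idx + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 4294967296 else as.numeric(crc)
}

uint32_be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

uint_le <- function(x, width) {
  x <- as.numeric(x) %% (256^width)
  as.raw((x %/% 256^(0:(width - 1))) %% 256)
}

le_to_num <- function(bytes) sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))

## ---- PNG chunk plumbing ----
## Original chunk bytes are kept verbatim (their stored CRCs remain valid);
## only newly inserted chunks need a CRC computation.

png_sig <- function() as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

png_chunks <- function(raw) {
  if (length(raw) < 8L || !identical(raw[1:8], png_sig()))
    stop("not a PNG file")
  chunks <- list()
  pos <- 9L
  while (pos + 7L <= length(raw)) {
    len <- sum(as.numeric(raw[pos:(pos + 3L)]) * 256^(3:0))
    type <- rawToChar(raw[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) raw[(pos + 8L):(pos + 7L + len)] else raw(0)
    chunks[[length(chunks) + 1L]] <-
      list(type = type, data = data, bytes = raw[pos:(pos + 11L + len)])
    pos <- pos + 12L + len
  }
  chunks
}

png_make_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  list(type = type, data = data,
       bytes = c(uint32_be(length(data)), td, uint32_be(crc32(td))))
}

png_assemble <- function(chunks) {
  c(png_sig(), unlist(lapply(chunks, `[[`, "bytes")))
}

## ---- TIFF-IFD EXIF payload ----

TAG_MAKE <- 0x010FL; TAG_MODEL <- 0x0110L; TAG_EXIF_IFD <- 0x8769L
TAG_FOCAL <- 0x920AL; TAG_FOCAL35 <- 0xA405L; TAG_SERIAL <- 0xA431L
TAG_SENSOR_WIDTH <- 0xEA31L  # private tag, see header comment

exif_build <- function(fields) {
  ## entry: list(tag, type, count, value_bytes)
  ascii <- function(tag, s) {
    v <- c(charToRaw(s), as.raw(0L))
    list(tag = tag, type = 2L, count = length(v), value = v)
  }
  rational <- function(tag, x) {
    num <- round(x * 10000); den <- 10000
    list(tag = tag, type = 5L, count = 1L,
         value = c(uint_le(num, 4L), uint_le(den, 4L)))
  }
  short <- function(tag, x)
    list(tag = tag, type = 3L, count = 1L, value = uint_le(round(x), 2L))
  long_ <- function(tag, x)
    list(tag = tag, type = 4L, count = 1L, value = uint_le(x, 4L))

  build_ifd <- function(entries, ifd_offset, next_ifd = 0) {
    entries <- entries[order(vapply(entries, `[[`, integer(1L), "tag"))]
    n <- length(entries)
    type_size <- c(1, 1, 2, 4, 8)
    data_start <- ifd_offset + 2 + 12 * n + 4
    data <- raw(0)
    rows <- lapply(entries, function(e) {
      sz <- length(e$value)
      inline <- sz <= 4
      val_field <- if (inline) c(e$value, raw(4 - sz)) else {
        off <- data_start + length(data)
        data <<- c(data, e$value)
        uint_le(off, 4L)
      }
      c(uint_le(e$tag, 2L), uint_le(e$type, 2L), uint_le(e$count, 4L), val_field)
    })
    list(bytes = c(uint_le(n, 2L), unlist(rows), uint_le(next_ifd, 4L), data),
         end = data_start + length(data))
  }

  exif_entries <- list(
    rational(TAG_FOCAL, fields$FocalLength),
    short(TAG_FOCAL35, fields$FocalLengthIn35mmFormat),
    ascii(TAG_SERIAL, fields$CameraSerialNumber),
    rational(TAG_SENSOR_WIDTH, fields$SensorWidth)
  )
  ## two-pass: IFD0 size depends only on entry count, so compute offsets
  ifd0_offset <- 8
  ifd0_n <- 3L
  ## placeholder Exif pointer to size IFD0's data area
  mk <- function(exif_ptr) list(
    ascii(TAG_MAKE, fields$Make),
    ascii(TAG_MODEL, fields$Model),
    long_(TAG_EXIF_IFD, exif_ptr)
  )
  tmp <- build_ifd(mk(0), ifd0_offset)
  exif_offset <- tmp$end
  ifd0 <- build_ifd(mk(exif_offset), ifd0_offset)
  stopifnot(ifd0$end == exif_offset)
  exif_ifd <- build_ifd(exif_entries, exif_offset)
  header <- c(charToRaw("II"), uint_le(42L, 2L), uint_le(ifd0_offset, 4L))
  c(header, ifd0$bytes, exif_ifd$bytes)
}

exif_parse <- function(payload) {
  if (length(payload) < 8L) stop("EXIF payload too short")
  if (!identical(rawToChar(payload[1:2]), "II"))
    stop("only little-endian EXIF payloads are supported")
  u <- function(off, width) le_to_num(payload[(off + 1):(off + width)])
  out <- list()
  read_ifd <- function(off) {
    n <- u(off, 2L)
    for (k in seq_len(n)) {
      e <- off + 2L + 12L * (k - 1L)
      tag <- u(e, 2L); type <- u(e + 2L, 2L); count <- u(e + 4L, 4L)
      size <- c(1, 1, 2, 4, 8)[type] * count
      voff <- if (size <= 4) e + 8L else u(e + 8L, 4L)
      val <- switch(as.character(type),
        "2" = {
          b <- payload[(voff + 1):(voff + count)]
          rawToChar(b[b != as.raw(0L)])
        },
        "3" = u(voff, 2L),
        "4" = u(voff, 4L),
        "5" = u(voff, 4L) / u(voff + 4L, 4L),
        stop("unsupported EXIF type ", type))
      key <- switch(sprintf("0x%04X", tag),
        "0x010F" = "Make", "0x0110" = "Model",
        "0x920A" = "FocalLength", "0xA405" = "FocalLengthIn35mmFormat",
        "0xA431" = "CameraSerialNumber", "0xEA31" = "SensorWidth",
        "0x8769" = "ExifIFD", NA_character_)
      if (identical(key, "ExifIFD")) read_ifd(val)
      else if (!is.na(key)) out[[key]] <<- val
    }
  }
  read_ifd(u(4L, 4L))
  out
}

#' Embed camera metadata in a PNG image
#'
#' Writes the metadata photogrammetry software requires into the image's
#' EXIF (PNG `eXIf` chunk): `Make` and `Model` (camera-database lookup),
#' `CameraSerialNumber` (all EDOF images of a scan must share it so one set
#' of solved intrinsics applies to every view), `FocalLength` (mm, as
#' printed on the lens; magnification/undistortion), `FocalLengthIn35mmFormat`
#' (mm) and `SensorWidth` (mm). Pixel data are untouched — only a metadata
#' chunk is inserted (replacing any previous one).
#'
#' @param image_path path to an existing PNG file.
#' @param intrinsics a [camera_intrinsics()], or a named list with the six
#'   fields `Make`, `Model`, `CameraSerialNumber`, `FocalLength`,
#'   `FocalLengthIn35mmFormat`, `SensorWidth`.
#' @return `image_path`, invisibly.
#' @export
write_exif <- function(image_path, intrinsics) {
  if (!file.exists(image_path)) stop("write_exif: no such file: ", image_path)
  fields <- if (inherits(intrinsics, "camera_intrinsics")) {
    list(Make = intrinsics$make, Model = intrinsics$model,
         CameraSerialNumber = intrinsics$serial,
         FocalLength = intrinsics$focal_length_mm,
         FocalLengthIn35mmFormat = intrinsics$focal_length_35mm,
         SensorWidth = intrinsics$sensor_width_mm)
  } else intrinsics
  required <- c("Make", "Model", "CameraSerialNumber", "FocalLength",
                "FocalLengthIn35mmFormat", "SensorWidth")
  for (f in required) {
    v <- fields[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v) ||
        (is.character(v) && !nzchar(v)))
      stop("write_exif: required metadata field missing: ", f)
  }
  raw <- readBin(image_path, "raw", file.size(image_path))
  chunks <- png_chunks(raw)
  chunks <- Filter(function(ch) ch$type != "eXIf", chunks)
  exif <- png_make_chunk("eXIf", exif_build(fields))
  first_idat <- which(vapply(chunks, `[[`, character(1L), "type") == "IDAT")[1L]
  chunks <- append(chunks, list(exif), after = first_idat - 1L)
  writeBin(png_assemble(chunks), image_path)
  invisible(image_path)
}

#' Read camera metadata from a PNG written by [write_exif()]
#'
#' @param image_path PNG path.
#' @return named list of metadata fields, or `NULL` if the image carries no
#'   EXIF chunk.
#' @export
read_exif <- function(image_path) {
  raw <- readBin(image_path, "raw", file.size(image_path))
  chunks <- png_chunks(raw)
  ex <- Filter(function(ch) ch$type == "eXIf", chunks)
  if (length(ex) == 0L) return(NULL)
  exif_parse(ex[[1L]]$data)
}
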