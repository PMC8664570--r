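#' Minimal baseline TIFF reader and writer
#'
#' The pipeline stores image scenes as plain multi-page grayscale TIFF:
#' uncompressed, one sample per pixel, strip-organised. The writer emits
#' little-endian files with 8/16-bit unsigned or 32-bit IEEE float samples and
#' records the stack layout in the `ImageDescription` tag as a small JSON
#' blob (`{"axes":"ZCYX","shape":[z,c,h,w]}`), the same convention used by
#' common scientific TIFF tooling for "shaped" files. The reader understands
#' both byte orders, 8/16/32-bit unsigned and 32-bit float samples, and any
#' strip layout, which covers everything this package writes plus simple
#' exports from ImageJ-style tools.
#'
#' These are deliberately minimal: no compression, tiles, palettes or RGB.
#'
#' @param path file path.
#' @param data for [write_tiff()], either a numeric matrix (one page) or a
#'   list of matrices (pages, in `z`-major then channel order when `axes`
#'   metadata is supplied).
#' @param dtype sample type: `"float32"` (default), `"uint16"` or `"uint8"`.
#' @param axes optional named list with `axes` (string, e.g. `"ZCYX"`) and
#'   `shape` (integer vector) stored in ImageDescription.
#' @return [read_tiff()] returns a list with `pages` (list of numeric
#'   matrices) and `description` (string or `NULL`).
#' @keywords internal
#' @name tiff_io
NULL

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

#' @rdname tiff_io
#' @export
write_tiff <- function(path, data, dtype = c("float32", "uint16", "uint8"),
                       axes = NULL) {
  dtype <- match.arg(dtype)
  if (is.matrix(data)) data <- list(data)
  assert_that(length(data) >= 1L && all(vapply(data, is.matrix, logical(1))),
              "data must be a matrix or list of matrices")
  h <- nrow(data[[1L]]); w <- ncol(data[[1L]])
  assert_that(all(vapply(data, function(m) nrow(m) == h && ncol(m) == w,
                         logical(1))), "all pages must share dimensions")
  desc <- if (!is.null(axes)) {
    axes$shape <- as.integer(axes$shape)
    as.character(jsonlite::toJSON(axes, auto_unbox = TRUE))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- switch(dtype, float32 = 32L, uint16 = 16L, uint8 = 8L)
  fmt <- if (dtype == "float32") 3L else 1L
  bytes_px <- bits %/% 8L
  strip_len <- h * w * bytes_px

  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # first IFD offset written after we lay out the header
  desc_raw <- if (!is.null(desc)) c(charToRaw(as.character(desc)), as.raw(0L))
  pos <- 8L                                 # running file offset
  n_pages <- length(data)
  n_tags <- if (is.null(desc)) 10L else 11L
  ifd_size <- 2L + n_tags * 12L + 4L
  # layout: header(8) | per page: [desc (page 1 only)] strip data | IFDs at end
  desc_off <- if (!is.null(desc)) pos else NULL
  if (!is.null(desc)) pos <- pos + length(desc_raw) + (length(desc_raw) %% 2L)
  strip_offs <- integer(n_pages)
  for (i in seq_len(n_pages)) { strip_offs[i] <- pos; pos <- pos + strip_len }
  ifd_offs <- pos + (seq_len(n_pages) - 1L) * ifd_size
  writeBin(as.integer(ifd_offs[1L]), con, size = 4, endian = "little")
  if (!is.null(desc)) {
    writeBin(desc_raw, con)
    if (length(desc_raw) %% 2L) writeBin(as.raw(0L), con)
  }
  for (m in data) {
    v <- as.vector(t(m))                    # row-major pixel order
    if (dtype == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      v <- as.integer(round(v))
      if (dtype == "uint8") {
        writeBin(as.raw(pmin(pmax(v, 0L), 255L)), con)
      } else {
        v <- pmin(pmax(v, 0L), 65535L)
        v <- ifelse(v > 32767L, v - 65536L, v)   # reinterpret as signed int16
        writeBin(v, con, size = 2, endian = "little")
      }
    }
  }
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L && count == 1L) {        # SHORT packed left-justified
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_len(n_pages)) {
    writeBin(n_tags, con, size = 2, endian = "little")
    tag(256L, 3L, 1L, w)                    # ImageWidth
    tag(257L, 3L, 1L, h)                    # ImageLength
    tag(258L, 3L, 1L, bits)                 # BitsPerSample
    tag(259L, 3L, 1L, 1L)                   # Compression: none
    tag(262L, 3L, 1L, 1L)                   # Photometric: BlackIsZero
    if (!is.null(desc)) tag(270L, 2L, length(desc_raw), desc_off)
    tag(273L, 4L, 1L, strip_offs[i])        # StripOffsets
    tag(277L, 3L, 1L, 1L)                   # SamplesPerPixel
    tag(278L, 3L, 1L, h)                    # RowsPerStrip
    tag(279L, 4L, 1L, strip_len)            # StripByteCounts
    tag(339L, 3L, 1L, fmt)                  # SampleFormat
    nxt <- if (i < n_pages) ifd_offs[i + 1L] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  assert_that(length(raw) >= 8L, sprintf("not a TIFF file: %s", path))
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop(sprintf("not a TIFF file: %s", path), call. = FALSE))
  rint <- function(off, size, n = 1L) {
    # signed only applies to 1- and 2-byte reads; 4-byte offsets fit in R int
    readBin(raw[(off + 1L):(off + size * n)], what = "integer", n = n,
            size = size, endian = endian, signed = size >= 4L)
  }
  assert_that(rint(2L, 2L) == 42L, sprintf("not a TIFF file: %s", path))
  ifd_off <- rint(4L, 4L)
  pages <- list()
  description <- NULL
  while (ifd_off != 0L) {
    n_tags <- rint(ifd_off, 2L)
    tags <- list()
    for (k in seq_len(n_tags)) {
      toff <- ifd_off + 2L + (k - 1L) * 12L
      id <- rint(toff, 2L)
      type <- rint(toff + 2L, 2L)
      count <- rint(toff + 4L, 4L)
      tsize <- TIFF_TYPE_SIZES[type]
      nbytes <- tsize * count
      voff <- if (nbytes <= 4L) toff + 8L else rint(toff + 8L, 4L)
      value <- switch(as.character(type),
        `1` = as.integer(raw[(voff + 1L):(voff + count)]),
        `2` = rawToChar(raw[(voff + 1L):(voff + count - 1L)]),
        `3` = {
          v <- rint(voff, 2L, count)
          ifelse(v < 0L, v + 65536L, v)
        },
        `4` = rint(voff, 4L, count),
        NULL)
      tags[[as.character(id)]] <- value
    }
    need <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v) && is.null(default)) {
        stop(sprintf("TIFF missing required tag %d", id), call. = FALSE)
      }
      v %||% default
    }
    w <- need(256L); h <- need(257L)
    bits <- need(258L, 8L)[1L]
    comp <- need(259L, 1L)
    assert_that(comp == 1L, "compressed TIFF not supported")
    spp <- need(277L, 1L)
    assert_that(spp == 1L, "multi-sample (RGB) TIFF not supported")
    fmt <- need(339L, 1L)[1L]
    offs <- need(273L)
    counts <- need(279L, h * w * bits %/% 8L)
    if (is.null(description)) description <- tags[["270"]]
    buf <- raw(sum(counts))
    at <- 0L
    for (s in seq_along(offs)) {
      buf[(at + 1L):(at + counts[s])] <- raw[(offs[s] + 1L):(offs[s] + counts[s])]
      at <- at + counts[s]
    }
    px <- if (fmt == 3L) {
      assert_that(bits == 32L, "only 32-bit float TIFF supported")
      readBin(buf, "numeric", n = h * w, size = 4, endian = endian)
    } else if (bits == 8L) {
      as.numeric(readBin(buf, "integer", n = h * w, size = 1, signed = FALSE,
                         endian = endian))
    } else if (bits == 16L) {
      v <- readBin(buf, "integer", n = h * w, size = 2, signed = FALSE,
                   endian = endian)
      as.numeric(v)
    } else if (bits == 32L) {
      as.numeric(readBin(buf, "integer", n = h * w, size = 4, endian = endian))
    } else stop("unsupported BitsPerSample", call. = FALSE)
    pages[[length(pages) + 1L]] <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- rint(ifd_off + 2L + n_tags * 12L, 4L)
  }
  list(pages = pages, description = description)
}
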