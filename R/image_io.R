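#' Two-channel image scenes
#'
#' The unit of analysis: a set of co-registered 2D intensity channels (usually
#' the maximum projection of a z-stack) plus the pixel size. Channel matrices
#' are `h x w`, intensities finite and non-negative.
#'
#' @param channels named list of numeric matrices sharing dimensions.
#' @param pixel_size micrometres per pixel (> 0).
#' @param provenance free-form list (source path, projection flag, ...).
#' @return object of class `image_scene`.
#' @export
image_scene <- function(channels, pixel_size, provenance = list()) {
  assert_that(is.list(channels) && length(channels) >= 1L &&
                !is.null(names(channels)) && all(nzchar(names(channels))),
              "channels must be a named list of matrices")
  d <- dim(channels[[1L]])
  for (ch in channels) {
    assert_that(is.matrix(ch) && identical(dim(ch), d),
                "all channels must share shape")
    assert_that(all(is.finite(ch)) && all(ch >= 0),
                "intensities must be finite and >= 0")
  }
  assert_that(is_scalar_num(pixel_size) && pixel_size > 0,
              "pixel_size must be > 0")
  structure(list(channels = channels, pixel_size = pixel_size,
                 provenance = provenance), class = "image_scene")
}

#' @export
print.image_scene <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<image_scene> %d x %d px, %.3g um/px, channels: %s\n",
              d[1L], d[2L], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Read an image stack from TIFF, normalising axes to (z, channel, y, x)
#'
#' Accepts 2D (one page), 3D (pages = z or channel) and 4D (z and channel)
#' grayscale TIFFs. Axis order is taken from the shaped `ImageDescription`
#' metadata when present (`axes` of `"YX"`, `"ZYX"`, `"CYX"`, `"ZCYX"` or
#' `"CZYX"`); without metadata, pages are assumed to be z-slices of a single
#' channel. Singleton axes are inserted so the result is always 4D.
#'
#' @param path TIFF file path.
#' @return numeric 4D array `[z, channel, y, x]`, with a `channel_names`
#'   attribute when the file carries one.
#' @export
read_stack <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  tf <- tryCatch(read_tiff(path), error = function(e) {
    stop(sprintf("cannot read '%s' as TIFF: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  pages <- tf$pages
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  meta <- NULL
  if (!is.null(tf$description)) {
    meta <- tryCatch(jsonlite::fromJSON(tf$description),
                     error = function(e) NULL)
  }
  nz <- length(pages); nc <- 1L; order_cz <- FALSE
  ch_names <- NULL
  if (!is.null(meta) && !is.null(meta$axes)) {
    ax <- toupper(meta$axes)
    shp <- as.integer(meta$shape)
    dims <- stats::setNames(shp, strsplit(ax, "")[[1L]])
    assert_that(isTRUE(dims[["Y"]] == h) && isTRUE(dims[["X"]] == w),
                "ImageDescription shape disagrees with page size")
    nz <- if ("Z" %in% names(dims)) dims[["Z"]] else 1L
    nc <- if ("C" %in% names(dims)) dims[["C"]] else 1L
    assert_that(nz * nc == length(pages),
                "ImageDescription shape disagrees with page count")
    pre <- sub("YX$", "", ax)
    if (!pre %in% c("", "Z", "C", "ZC", "CZ")) {
      stop(sprintf(paste0("ambiguous axis order '%s': tag axes as one of ",
                          "YX, ZYX, CYX, ZCYX, CZYX"), ax), call. = FALSE)
    }
    order_cz <- identical(pre, "CZ")      # pages iterate z fastest
    if (!is.null(meta$channel_names)) ch_names <- unlist(meta$channel_names)
  }
  out <- array(0, dim = c(nz, nc, h, w))
  for (p in seq_along(pages)) {
    if (order_cz) {                        # page index = (c-1)*nz + z
      z <- (p - 1L) %% nz + 1L; cc <- (p - 1L) %/% nz + 1L
    } else {                               # page index = (z-1)*nc + c
      cc <- (p - 1L) %% nc + 1L; z <- (p - 1L) %/% nc + 1L
    }
    out[z, cc, , ] <- pages[[p]]
  }
  if (!is.null(ch_names)) attr(out, "channel_names") <- ch_names
  out
}

#' Write a (z, channel, y, x) stack or scene to shaped TIFF
#'
#' @param x an `image_scene` (written as a 1-slice ZCYX stack) or a 4D array.
#' @param path output path.
#' @param channel_names optional channel names stored in the metadata.
#' @param dtype sample type passed to [write_tiff()].
#' @export
write_stack <- function(x, path, channel_names = NULL, dtype = "float32") {
  if (inherits(x, "image_scene")) {
    channel_names <- channel_names %||% names(x$channels)
    d <- dim(x$channels[[1L]])
    arr <- array(0, dim = c(1L, length(x$channels), d[1L], d[2L]))
    for (i in seq_along(x$channels)) arr[1L, i, , ] <- x$channels[[i]]
    x <- arr
  }
  assert_that(is.array(x) && length(dim(x)) == 4L,
              "x must be an image_scene or a 4D (z, c, y, x) array")
  dz <- dim(x)
  pages <- vector("list", dz[1L] * dz[2L])
  for (z in seq_len(dz[1L])) for (cc in seq_len(dz[2L])) {
    pages[[(z - 1L) * dz[2L] + cc]] <- matrix(x[z, cc, , ], dz[3L], dz[4L])
  }
  desc <- list(axes = "ZCYX", shape = dz)
  if (!is.null(channel_names)) desc$channel_names <- as.list(channel_names)
  write_tiff(path, pages, dtype = dtype, axes = desc)
  invisible(path)
}

#' Maximum z-projection of a stack
#'
#' Collapses `[z, channel, y, x]` to one 2D image per channel by the pixelwise
#' maximum over z — the projection performed before every quantification step.
#' Projecting an already-projected scene is the identity.
#'
#' @param stack 4D array as returned by [read_stack()], or an `image_scene`
#'   (returned unchanged).
#' @param pixel_size micrometres per pixel for the resulting scene.
#' @param channel_names names for the channels; defaults to the stack's
#'   `channel_names` attribute or `ch1, ch2, ...`.
#' @param provenance optional provenance list.
#' @return an [image_scene()].
#' @export
max_project <- function(stack, pixel_size = 1, channel_names = NULL,
                        provenance = list()) {
  if (inherits(stack, "image_scene")) return(stack)
  assert_that(is.array(stack) && length(dim(stack)) == 4L,
              "stack must be a 4D (z, c, y, x) array")
  d <- dim(stack)
  channel_names <- channel_names %||% attr(stack, "channel_names") %||%
    paste0("ch", seq_len(d[2L]))
  chans <- stats::setNames(vector("list", d[2L]), channel_names)
  for (cc in seq_len(d[2L])) {
    m <- matrix(stack[1L, cc, , ], d[3L], d[4L])
    if (d[1L] > 1L) {
      for (z in 2L:d[1L]) m <- pmax(m, matrix(stack[z, cc, , ], d[3L], d[4L]))
    }
    chans[[cc]] <- m
  }
  provenance$projection <- "max"
  image_scene(chans, pixel_size, provenance)
}
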