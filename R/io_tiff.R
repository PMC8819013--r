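# Minimal baseline TIFF 6.0 codec for diffraction movies and float maps.
# No TIFF package exists in the deployment environment, so the subset this
# pipeline needs is implemented directly: multi-page, single-sample
# grayscale, uncompressed, strip-organised. Writing emits little-endian
# uint16 (counts; values above 65535 saturate with a warning) or float32
# (maps, NaN = absent). Reading accepts either byte order, 8/16/32-bit
# unsigned integer and 32/64-bit float samples, and multiple strips.

.TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples_per_pixel = 277L,
  rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L
)

#' Write a movie (or map stack) as a multi-page TIFF
#'
#' @param movie A [diffraction_movie()] or a 3-D array.
#' @param path Output file path.
#' @param dtype `"uint16"` for photon counts (saturating at 65535) or
#'   `"float32"` for maps; `"auto"` picks uint16 for non-negative
#'   integer-valued data and float32 otherwise.
#' @param sidecar Write a JSON sidecar `<path>.json` holding the exposure
#'   (only when `movie` is a [diffraction_movie()]). Default TRUE.
#' @return `path`, invisibly. Attribute `saturated` on the return value
#'   reports how many pixels were clipped (uint16 only).
#' @export
write_movie <- function(movie, path, dtype = c("auto", "uint16", "float32"),
                        sidecar = TRUE) {
  dtype <- match.arg(dtype)
  counts <- if (inherits(movie, "diffraction_movie")) movie$counts else movie
  if (!is.array(counts) || length(dim(counts)) != 3L) {
    stop("`movie` must be a diffraction_movie or a 3-D array", call. = FALSE)
  }
  if (dtype == "auto") {
    intish <- all(is.finite(counts)) && all(counts >= 0) &&
      max(abs(counts - round(counts))) == 0
    dtype <- if (intish) "uint16" else "float32"
  }
  d <- dim(counts)
  nr <- d[1]; nc <- d[2]; nf <- d[3]
  bps <- if (dtype == "uint16") 2L else 4L
  fmt <- if (dtype == "uint16") 1L else 3L
  saturated <- 0L
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  w16(42L)
  header_len <- 8L
  strip_len <- nr * nc * bps
  ifd_len <- 2L + 10L * 12L + 4L
  # page p data at header + (p-1)*(strip+ifd), its IFD right after the data
  data_off <- function(p) header_len + (p - 1L) * (strip_len + ifd_len)
  ifd_off <- function(p) data_off(p) + strip_len
  w32(ifd_off(1L))
  entry <- function(tag, type, value) {  # single inline value
    w16(tag); w16(type); w32(1L)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (p in seq_len(nf)) {
    fr <- t(counts[, , p])  # row-major pixel order
    if (dtype == "uint16") {
      v <- round(as.vector(fr))
      over <- v > 65535
      if (any(over)) {
        saturated <- saturated + sum(over)
        v[over] <- 65535
      }
      v[v < 0] <- 0
      writeBin(as.integer(v), con, size = 2, endian = "little")
    } else {
      writeBin(as.double(as.vector(fr)), con, size = 4, endian = "little")
    }
    w16(10L)  # entry count
    entry(.TIFF_TAGS[["width"]], 4L, nc)
    entry(.TIFF_TAGS[["length"]], 4L, nr)
    entry(.TIFF_TAGS[["bits"]], 3L, 8L * bps)
    entry(.TIFF_TAGS[["compression"]], 3L, 1L)
    entry(.TIFF_TAGS[["photometric"]], 3L, 1L)
    entry(.TIFF_TAGS[["strip_offsets"]], 4L, data_off(p))
    entry(.TIFF_TAGS[["samples_per_pixel"]], 3L, 1L)
    entry(.TIFF_TAGS[["rows_per_strip"]], 4L, nr)
    entry(.TIFF_TAGS[["strip_bytes"]], 4L, strip_len)
    entry(.TIFF_TAGS[["sample_format"]], 3L, fmt)
    w32(if (p < nf) ifd_off(p + 1L) else 0L)
  }
  if (saturated > 0L) {
    warning(sprintf("%d pixel value(s) saturated at 65535 in uint16 output", saturated))
  }
  if (sidecar && inherits(movie, "diffraction_movie")) {
    jsonlite::write_json(
      list(exposure_s = movie$exposure, n_frames = nf, shape = c(nr, nc), dtype = dtype),
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  out <- path
  attr(out, "saturated") <- saturated
  invisible(out)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file path.
#' @param exposure Exposure time per frame, s. Default: read from the JSON
#'   sidecar `<path>.json` if present, else 1.
#' @return A [diffraction_movie()].
#' @export
read_movie <- function(path, exposure = NULL) {
  pages <- read_tiff_pages(path)
  shapes <- vapply(pages, dim, integer(2))
  if (length(pages) > 1L && any(shapes[1, ] != shapes[1, 1] | shapes[2, ] != shapes[2, 1])) {
    bad <- which(shapes[1, ] != shapes[1, 1] | shapes[2, ] != shapes[2, 1])[1]
    stop(sprintf(
      "ragged TIFF: page %d is %d x %d but page 1 is %d x %d",
      bad, shapes[1, bad], shapes[2, bad], shapes[1, 1], shapes[2, 1]
    ), call. = FALSE)
  }
  counts <- array(unlist(pages, use.names = FALSE),
                  dim = c(shapes[1, 1], shapes[2, 1], length(pages)))
  if (is.null(exposure)) {
    sc <- paste0(path, ".json")
    exposure <- if (file.exists(sc)) jsonlite::read_json(sc)$exposure_s else 1
  }
  diffraction_movie(counts, exposure = exposure)
}

# parse all pages of a baseline TIFF into a list of matrices
read_tiff_pages <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) < 8L) stop("not a TIFF file (truncated header)", call. = FALSE)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark)", call. = FALSE)
  rint <- function(off, size, n = 1L, signed = size == 4L) {
    # readBin only honours signed = FALSE for 1- and 2-byte integers
    readBin(raw_all[(off + 1L):(off + size * n)], "integer",
            n = n, size = size, signed = signed || size == 4L, endian = endian)
  }
  rdbl <- function(off, size, n = 1L) {
    readBin(raw_all[(off + 1L):(off + size * n)], "double",
            n = n, size = size, endian = endian)
  }
  if (rint(2L, 2L) != 42L) stop("not a TIFF file (magic != 42)", call. = FALSE)
  ifd <- rint(4L, 4L)
  pages <- list()
  page_no <- 0L
  while (ifd != 0L) {
    page_no <- page_no + 1L
    n_entries <- rint(ifd, 2L)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- ifd + 2L + (i - 1L) * 12L
      tag <- rint(e, 2L)
      type <- rint(e + 2L, 2L)
      count <- rint(e + 4L, 4L)
      type_size <- c(1L, 1L, 2L, 4L, 8L)[type]
      if (is.na(type_size)) next
      inline <- type_size * count <= 4L
      voff <- if (inline) e + 8L else rint(e + 8L, 4L)
      vals <- if (type %in% c(1L, 2L)) rint(voff, 1L, count)
        else if (type == 3L) rint(voff, 2L, count)
        else if (type == 4L) rint(voff, 4L, count)
        else NULL
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    comp <- g(.TIFF_TAGS[["compression"]], 1L)[1]
    if (comp != 1L) {
      stop(sprintf("page %d: unsupported TIFF compression %d", page_no, comp), call. = FALSE)
    }
    spp <- g(.TIFF_TAGS[["samples_per_pixel"]], 1L)[1]
    if (spp != 1L) {
      stop(sprintf("page %d: only single-sample grayscale supported", page_no), call. = FALSE)
    }
    nc <- g(.TIFF_TAGS[["width"]])[1]
    nr <- g(.TIFF_TAGS[["length"]])[1]
    bits <- g(.TIFF_TAGS[["bits"]], 1L)[1]
    fmt <- g(.TIFF_TAGS[["sample_format"]], 1L)[1]
    if (is.null(nc) || is.null(nr)) {
      stop(sprintf("page %d: missing image dimensions", page_no), call. = FALSE)
    }
    offs <- g(.TIFF_TAGS[["strip_offsets"]])
    lens <- g(.TIFF_TAGS[["strip_bytes"]])
    if (is.null(offs) || is.null(lens)) {
      stop(sprintf("page %d: missing strip layout", page_no), call. = FALSE)
    }
    bsize <- bits %/% 8L
    npx_strip <- lens %/% bsize
    vals <- unlist(lapply(seq_along(offs), function(s) {
      if (fmt == 3L) rdbl(offs[s], bsize, npx_strip[s])
      else rint(offs[s], bsize, npx_strip[s],
                signed = fmt == 2L || bsize == 4L)
    }), use.names = FALSE)
    if (length(vals) != nr * nc) {
      stop(sprintf("page %d: strip data does not match %d x %d image",
                   page_no, nr, nc), call. = FALSE)
    }
    pages[[page_no]] <- t(matrix(vals, nc, nr))  # data is row-major
    ifd <- rint(ifd + 2L + n_entries * 12L, 4L)
  }
  if (!length(pages)) stop("TIFF contains no pages", call. = FALSE)
  pages
}

#' Write a float map (e.g. a decay-constant image) as single-page TIFF
#'
#' `NaN` marks absent values.
#' @param map Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  stopifnot(is.matrix(map))
  write_movie(array(map, dim = c(dim(map), 1L)), path, dtype = "float32",
              sidecar = FALSE)
}

#' Read a single-page float map TIFF
#' @param path TIFF path.
#' @return Numeric matrix.
#' @export
read_map_tiff <- function(path) {
  read_tiff_pages(path)[[1]]
}
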