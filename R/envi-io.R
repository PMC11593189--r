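## ENVI flat-binary cube I/O. The format is a plain binary block plus a
## text .hdr; all three interleaves (bsq, bil, bip) and both byte orders
## are supported. The `wavelength` header field is mandatory on read
## because every downstream stage needs the band axis.

ENVI_DTYPES <- list(
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `4`  = list(what = "numeric", size = 4L, signed = TRUE),
  `5`  = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

#' Write a hypercube as an ENVI file pair
#'
#' Writes `<path>.dat` (binary, 64-bit IEEE doubles by default so the
#' write/read round trip is exact) and `<path>.hdr` with the wavelength
#' list.
#'
#' @param cube a `hypercube`.
#' @param path output path without extension.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param byte_order 0 (little-endian) or 1 (big-endian).
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       byte_order = 0L, data_type = 5L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  dt <- ENVI_DTYPES[[as.character(data_type)]]
  if (is.null(dt) || dt$what != "numeric")
    stopf("unsupported write data type %s (use 4 or 5)", data_type)
  d <- dim(cube$data)   # rows (lines) x cols (samples) x bands
  ## file order: innermost varies fastest
  vec <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),  # sample, line, band
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),  # sample, band, line
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))  # band, sample, line
  endian <- if (byte_order == 0L) "little" else "big"
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(vec, con, size = dt$size, endian = endian)
  hdr <- c(
    "ENVI",
    "description = { bolushsi export }",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    sprintf("byte order = %d", byte_order),
    "wavelength units = nm",
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, digits = 15, trim = TRUE),
                  collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key,
                                        "\\s*=\\s*([^\\n{]+)"), txt, perl = TRUE))[[1]]
    if (length(m) < 2) NULL else trimws(m[2])
  }
  get_block <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key, "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NULL else m[2]
  }
  need <- function(key) {
    v <- get_scalar(key)
    if (is.null(v)) stopf("ENVI header missing `%s` field", key)
    v
  }
  wl_block <- get_block("wavelength")
  if (is.null(wl_block)) stopf("ENVI header missing `wavelength` list")
  wl <- as.numeric(strsplit(gsub("[\\n\\r]", " ", wl_block), ",")[[1]])
  list(samples = as.integer(need("samples")),
       lines = as.integer(need("lines")),
       bands = as.integer(need("bands")),
       data_type = as.integer(need("data type")),
       interleave = tolower(need("interleave")),
       byte_order = as.integer(need("byte order")),
       offset = as.integer(get_scalar("header offset") %||% "0"),
       wavelengths = wl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an ENVI file pair into a hypercube
#'
#' @param path path without extension, or the `.hdr`/`.dat` path itself.
#' @param kind cube kind tag for the result (`"raw"` default).
#' @return A `hypercube`.
#' @export
read_envi <- function(path, kind = "raw") {
  base <- sub("\\.(hdr|dat|raw|img)$", "", path)
  hdr_path <- paste0(base, ".hdr")
  dat_path <- Filter(file.exists, paste0(base, c(".dat", ".raw", ".img")))[1]
  if (!file.exists(hdr_path)) stopf("header not found: %s", hdr_path)
  if (is.na(dat_path)) stopf("data file not found for %s", base)
  h <- parse_envi_header(hdr_path)
  if (length(h$wavelengths) != h$bands)
    stopf("header lists %d wavelengths for %d bands",
          length(h$wavelengths), h$bands)
  dt <- ENVI_DTYPES[[as.character(h$data_type)]]
  if (is.null(dt)) stopf("unsupported ENVI data type %d", h$data_type)
  n <- h$samples * h$lines * h$bands
  avail <- file.size(dat_path) - h$offset
  if (avail != n * dt$size)
    stopf("data file has %d bytes, header implies %d",
          avail, n * dt$size)
  con <- file(dat_path, "rb")
  on.exit(close(con), add = TRUE)
  if (h$offset > 0) readBin(con, "raw", h$offset)
  endian <- if (h$byte_order == 0L) "little" else "big"
  vec <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                 signed = dt$signed)
  arr <- switch(h$interleave,
    bsq = aperm(array(vec, c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    bil = aperm(array(vec, c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bip = aperm(array(vec, c(h$bands, h$samples, h$lines)), c(3, 2, 1)),
    stopf("unknown interleave `%s`", h$interleave))
  hypercube(arr, h$wavelengths, kind = kind)
}
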