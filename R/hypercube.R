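#' Hyperspectral data cube
#'
#' A `hypercube` is a rows x cols x bands numeric array together with its
#' wavelength axis (nm, strictly increasing) and a `kind` tag distinguishing
#' raw detector intensity from calibrated reflectance. Reflectance cubes are
#' expected to lie in `[0, 1.05]`; the 5% headroom absorbs detector noise on
#' bright pixels.
#'
#' @param data numeric array with `dim = c(rows, cols, bands)`.
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, one per band.
#' @param kind `"raw"` or `"reflectance"`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3-D array (rows x cols x bands)")
  if (length(wavelengths) != dim(data)[3L])
    stopf("wavelength vector length (%d) != number of bands (%d)",
          length(wavelengths), dim(data)[3L])
  if (any(diff(wavelengths) <= 0))
    stopf("wavelengths must be strictly increasing")
  if (!all(is.finite(data)))
    stopf("cube contains non-finite values")
  if (kind == "reflectance" && (min(data) < -1e-9 || max(data) > 1.05 + 1e-9))
    stopf("reflectance cube outside [0, 1.05]: range [%g, %g]",
          min(data), max(data))
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube %s: %d x %d pixels, %d bands, %.1f-%.1f nm>\n",
              x$kind, d[1], d[2], d[3],
              x$wavelengths[1], x$wavelengths[length(x$wavelengths)]))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Dark/white reference frame
#'
#' Reference frames may be full-frame (rows x cols x bands), a push-broom
#' line reference (1 x cols x bands, broadcast over rows), or a per-band
#' vector (constant over pixels, the convention used by the synthetic
#' generator).
#'
#' @param data numeric array (3-D) or per-band numeric vector.
#' @param role `"black"` or `"white"`.
#' @return An object of class `reference_frame`.
#' @export
reference_frame <- function(data, role = c("black", "white")) {
  role <- match.arg(role)
  if (!(is.numeric(data) && (is.null(dim(data)) || length(dim(data)) == 3L)))
    stopf("reference data must be a numeric vector or 3-D array")
  structure(list(data = data, role = role), class = "reference_frame")
}

## Expand a reference (vector / line / full frame) to the cube's dimensions.
broadcast_reference <- function(ref, dims) {
  x <- if (inherits(ref, "reference_frame")) ref$data
       else if (inherits(ref, "hypercube")) ref$data
       else ref
  if (is.null(dim(x))) {
    if (length(x) == 1L) return(array(x, dims))
    if (length(x) != dims[3L])
      stopf("per-band reference has %d values, cube has %d bands",
            length(x), dims[3L])
    return(aperm(array(x, c(dims[3L], dims[1L], dims[2L])), c(2, 3, 1)))
  }
  d <- dim(x)
  if (d[1L] == 1L && all(d[2:3] == dims[2:3])) {
    out <- array(0, dims)
    for (b in seq_len(dims[3L]))
      out[, , b] <- matrix(x[1, , b], dims[1L], dims[2L], byrow = TRUE)
    return(out)
  }
  if (all(d == dims)) return(x)
  stopf("reference dims (%s) incompatible with cube dims (%s)",
        paste(d, collapse = "x"), paste(dims, collapse = "x"))
}

#' Black/white reflectance calibration
#'
#' Converts raw detector intensity to relative reflectance using the
#' standard two-point correction `R = (I - B) / (W - B)`, where `B` is the
#' dark-current frame and `W` the white-reference frame. Values are clipped
#' to `[0, clip_max]`; the number of clipped voxels is recorded in the
#' `"clipped"` attribute of the returned cube (never silently dropped).
#'
#' @param cube a `hypercube` of kind `"raw"`.
#' @param black,white dark and white references (`reference_frame`, 3-D
#'   array, or per-band vector).
#' @param clip_max upper clip ceiling for reflectance (default 1.05).
#' @return A `hypercube` of kind `"reflectance"` with attribute `"clipped"`.
#' @export
calibrate_reflectance <- function(cube, black, white, clip_max = 1.05) {
  stopifnot(inherits(cube, "hypercube"))
  dims <- dim(cube$data)
  B <- broadcast_reference(black, dims)
  W <- broadcast_reference(white, dims)
  denom <- W - B
  if (any(denom <= 0)) {
    bad <- which(apply(denom <= 0, 3, any))
    stopf("white - black <= 0 at band index(es): %s",
          paste(head(bad, 10), collapse = ", "))
  }
  R <- (cube$data - B) / denom
  n_clip <- sum(R < 0) + sum(R > clip_max)
  R[R < 0] <- 0
  R[R > clip_max] <- clip_max
  out <- hypercube(R, cube$wavelengths, kind = "reflectance")
  attr(out, "clipped") <- n_clip
  out
}

#' Region-of-interest selection
#'
#' Coordinates are 0-based and half-open: the ROI covers rows
#' `row_start .. row_start + height - 1`. Center placement uses
#' `floor((dim - size) / 2)` for the start.
#'
#' @param height,width ROI size in pixels (study convention: 100 x 100).
#' @param row_start,col_start 0-based inclusive starts; `NULL` for center
#'   placement.
#' @return An object of class `roi_selection`.
#' @export
roi_selection <- function(height = 100L, width = 100L,
                          row_start = NULL, col_start = NULL) {
  stopifnot(height >= 1, width >= 1)
  structure(list(height = as.integer(height), width = as.integer(width),
                 row_start = if (is.null(row_start)) NULL else as.integer(row_start),
                 col_start = if (is.null(col_start)) NULL else as.integer(col_start),
                 placement = if (is.null(row_start)) "center" else "explicit"),
            class = "roi_selection")
}

#' Extract a rectangular ROI from a cube
#'
#' @param cube a `hypercube`.
#' @param roi an `roi_selection`.
#' @return The sub-cube, exactly `height x width x bands`. An ROI that does
#'   not fit inside the cube is an error, never silently shrunk.
#' @export
extract_roi <- function(cube, roi) {
  stopifnot(inherits(cube, "hypercube"), inherits(roi, "roi_selection"))
  d <- dim(cube$data)
  r0 <- if (is.null(roi$row_start)) (d[1L] - roi$height) %/% 2L else roi$row_start
  c0 <- if (is.null(roi$col_start)) (d[2L] - roi$width) %/% 2L else roi$col_start
  if (r0 < 0 || c0 < 0 || r0 + roi$height > d[1L] || c0 + roi$width > d[2L])
    stopf("ROI %dx%d at (%d,%d) exceeds cube %dx%d",
          roi$height, roi$width, r0, c0, d[1L], d[2L])
  sub <- cube$data[(r0 + 1L):(r0 + roi$height),
                   (c0 + 1L):(c0 + roi$width), , drop = FALSE]
  hypercube(sub, cube$wavelengths, kind = cube$kind)
}

#' Mean spectrum over (masked) pixels
#'
#' @param cube a `hypercube`.
#' @param mask optional logical rows x cols matrix; `TRUE` pixels enter the
#'   average. Must select at least one pixel.
#' @return Numeric vector, one arithmetic mean per band.
#' @export
mean_spectrum <- function(cube, mask = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  m <- matrix(cube$data, d[1L] * d[2L], d[3L])
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == d[1:2]))
    if (!any(mask)) stopf("mask selects no pixels")
    m <- m[as.vector(mask), , drop = FALSE]
  }
  colMeans(m)
}

## Nearest band index for a wavelength in nm; ties resolve to the lower index.
nearest_band <- function(wavelengths, nm) {
  if (nm < min(wavelengths) || nm > max(wavelengths))
    stopf("wavelength %g nm outside cube range [%g, %g]",
          nm, min(wavelengths), max(wavelengths))
  which.min(abs(wavelengths - nm))
}

#' Threshold-based foreground mask
#'
#' Segments sample pixels from the (Petri-dish) background by thresholding
#' reflectance at the band nearest to `threshold_nm`. Optionally keeps only
#' the largest 4-connected component.
#'
#' @param cube a reflectance `hypercube`.
#' @param threshold_nm wavelength (nm) of the thresholding band.
#' @param threshold reflectance threshold.
#' @param keep `"below"` keeps pixels darker than the threshold (absorbing
#'   sample on a bright background), `"above"` the converse.
#' @param largest_component keep only the largest connected component.
#' @return Logical rows x cols matrix; an all-`FALSE` result is an error.
#' @export
foreground_mask <- function(cube, threshold_nm, threshold,
                            keep = c("below", "above"),
                            largest_component = FALSE) {
  stopifnot(inherits(cube, "hypercube"))
  keep <- match.arg(keep)
  b <- nearest_band(cube$wavelengths, threshold_nm)
  img <- cube$data[, , b]
  mask <- if (keep == "below") img < threshold else img > threshold
  if (!any(mask)) stopf("foreground mask is empty (threshold %g, keep %s)",
                        threshold, keep)
  if (largest_component) mask <- largest_cc(mask)
  mask
}

## Largest 4-connected component of a logical matrix (iterative flood fill).
largest_cc <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      r <- (p - 1L) %% nrow(mask) + 1L
      cc <- (p - 1L) %/% nrow(mask) + 1L
      nb <- c(if (r > 1L) p - 1L, if (r < nrow(mask)) p + 1L,
              if (cc > 1L) p - nrow(mask), if (cc < ncol(mask)) p + nrow(mask))
      stack <- c(stack, nb[mask[nb] & lab[nb] == 0L])
    }
  }
  if (cur == 0L) return(mask)
  best <- which.max(tabulate(lab[lab > 0L]))
  lab == best
}
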