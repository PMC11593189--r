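#' Spectral pretreatment specification
#'
#' The three pretreatments compared in the pipeline are Savitzky-Golay
#' smoothing (SG), Gaussian filtering (GF) and normalization (N); they are
#' alternatives, not a chain — each candidate model uses exactly one.
#' Defaults (SG window 11 / order 2, GF sigma 2 bands, unit-vector
#' normalization) are conventional NIR choices and fully configurable.
#'
#' @param method `"none"`, `"N"`, `"GF"` or `"SG"`.
#' @param sg_window odd window length in bands, `> sg_polyorder`.
#' @param sg_polyorder polynomial degree of the local fit.
#' @param gf_sigma Gaussian kernel standard deviation in bands, `> 0`.
#' @param norm_mode `"unit_vector"`, `"minmax"` or `"snv"`.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("none", "N", "GF", "SG"),
                            sg_window = 11L, sg_polyorder = 2L,
                            gf_sigma = 2.0,
                            norm_mode = c("unit_vector", "minmax", "snv")) {
  method <- match.arg(method)
  norm_mode <- match.arg(norm_mode)
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window %% 2L == 0L) stopf("sg_window must be odd, got %d", sg_window)
  if (sg_window <= sg_polyorder)
    stopf("sg_window (%d) must exceed sg_polyorder (%d)", sg_window, sg_polyorder)
  if (gf_sigma <= 0) stopf("gf_sigma must be > 0")
  structure(list(method = method, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, gf_sigma = gf_sigma,
                 norm_mode = norm_mode, boundary = "reflect"),
            class = "preprocess_spec")
}

## Mirror padding about the edge sample (edge not duplicated):
## x1 x2 x3 ... -> x_{k+1} ... x2 | x1 x2 ... | x_{n-1} ... x_{n-k}
pad_reflect <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  if (k >= n) stopf("reflect pad width %d >= spectrum length %d", k, n)
  c(x[(k + 1L):2L], x, x[(n - 1L):(n - k)])
}

## Savitzky-Golay convolution weights for the smoothed (0th-derivative)
## value at the window center: center row of the least-squares hat matrix.
sg_coefficients <- function(window, polyorder) {
  half <- (window - 1L) %/% 2L
  z <- (-half):half
  A <- outer(z, 0:polyorder, `^`)
  h <- A %*% solve(crossprod(A), t(A))
  h[half + 1L, ]
}

## Discrete Gaussian kernel truncated at 4*sigma (optionally capped at
## max_radius for small images), renormalized to sum 1.
gaussian_kernel <- function(sigma, max_radius = NULL) {
  if (sigma <= 0) stopf("sigma must be > 0")
  r <- max(1L, ceiling(4 * sigma))
  if (!is.null(max_radius)) r <- min(r, as.integer(max_radius))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

## Convolve each row of X (spectra) with kernel `k`, reflect boundaries.
## Implemented as a padded matrix product so whole cubes stay vectorized.
filter_rows <- function(X, k) {
  p <- ncol(X)
  half <- (length(k) - 1L) %/% 2L
  Xp <- t(apply(X, 1L, pad_reflect, k = half))
  if (nrow(X) == 1L) Xp <- matrix(Xp, 1L)
  K <- matrix(0, p + 2L * half, p)
  for (j in seq_len(p)) K[j:(j + 2L * half), j] <- rev(k)
  Xp %*% K
}

#' Savitzky-Golay smoothing
#'
#' Each point is replaced by the value at its position of the least-squares
#' polynomial of degree `polyorder` fitted over the centered window.
#' Boundaries are mirror-padded, so the output has the input's length.
#' Polynomials of degree `<= polyorder` are reproduced exactly in the
#' interior.
#'
#' @param x numeric spectrum.
#' @param window odd window length, `> polyorder` and `<=` spectrum length.
#' @param polyorder local polynomial degree.
#' @return Smoothed spectrum of the same length.
#' @export
savitzky_golay <- function(x, window = 11L, polyorder = 2L) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window <= polyorder)
    stopf("window must be odd and > polyorder (got %d, %d)", window, polyorder)
  if (length(x) < window)
    stopf("spectrum length %d < window %d", length(x), window)
  drop(filter_rows(matrix(x, 1L), sg_coefficients(window, polyorder)))
}

#' Gaussian filtering of a spectrum
#'
#' Convolution with a discrete Gaussian kernel truncated at 4 sigma and
#' renormalized to sum exactly 1, with mirror boundary handling.
#'
#' @param x numeric spectrum.
#' @param sigma kernel standard deviation in bands, `> 0`.
#' @return Filtered spectrum of the same length.
#' @export
gaussian_filter <- function(x, sigma = 2.0) {
  k <- gaussian_kernel(sigma)
  if ((length(k) - 1L) %/% 2L >= length(x))
    stopf("kernel radius exceeds spectrum length")
  drop(filter_rows(matrix(x, 1L), k))
}

#' Spectrum normalization
#'
#' `unit_vector` scales to unit Euclidean norm, `minmax` maps onto
#' `[0, 1]`, `snv` (standard normal variate) centers and scales to unit
#' standard deviation. Degenerate inputs (zero vector; constant vector for
#' minmax/snv) are errors.
#'
#' @param x numeric spectrum.
#' @param mode `"unit_vector"`, `"minmax"` or `"snv"`.
#' @return Normalized spectrum.
#' @export
normalize_spectrum <- function(x, mode = c("unit_vector", "minmax", "snv")) {
  mode <- match.arg(mode)
  switch(mode,
    unit_vector = {
      nrm <- sqrt(sum(x^2))
      if (nrm == 0) stopf("cannot unit-vector normalize a zero spectrum")
      x / nrm
    },
    minmax = {
      r <- range(x)
      if (r[1] == r[2]) stopf("cannot minmax normalize a constant spectrum")
      (x - r[1]) / (r[2] - r[1])
    },
    snv = {
      s <- sd(x)
      if (s == 0) stopf("cannot SNV normalize a constant spectrum")
      (x - mean(x)) / s
    })
}

#' Apply one pretreatment to a spectrum, a spectra matrix, or a cube
#'
#' The selected method is applied independently to every spectrum: each row
#' of a matrix, or each pixel of a `hypercube`.
#'
#' @param x numeric vector (one spectrum), matrix (rows = spectra), or
#'   `hypercube`.
#' @param spec a `preprocess_spec`.
#' @return Object of the same shape and type as `x`.
#' @export
apply_chain <- function(x, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  if (inherits(x, "hypercube")) {
    d <- dim(x$data)
    m <- apply_chain(matrix(x$data, d[1L] * d[2L], d[3L]), spec)
    return(hypercube(array(m, d), x$wavelengths, kind = x$kind))
  }
  if (is.null(dim(x))) return(drop(apply_chain(matrix(x, 1L), spec)))
  switch(spec$method,
    none = x,
    SG = filter_rows(x, sg_coefficients(spec$sg_window, spec$sg_polyorder)),
    GF = filter_rows(x, gaussian_kernel(spec$gf_sigma)),
    N = t(apply(x, 1L, normalize_spectrum, mode = spec$norm_mode)))
}

## Short provenance tag, e.g. "SG(11,2)", recorded in model metadata.
preprocess_label <- function(spec) {
  switch(spec$method,
    none = "none",
    SG = sprintf("SG(%d,%d)", spec$sg_window, spec$sg_polyorder),
    GF = sprintf("GF(%.3g)", spec$gf_sigma),
    N = sprintf("N(%s)", spec$norm_mode))
}
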