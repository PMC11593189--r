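#' Pixel-wise analyte prediction map
#'
#' Applies a trained model to every masked pixel of a calibrated
#' reflectance cube: each pixel's spectrum is preprocessed with the model's
#' stored `preprocess_spec` and predicted; background pixels are `NA`.
#'
#' @param cube a reflectance `hypercube` whose band count matches the
#'   model.
#' @param model a `spectral_model`.
#' @param mask optional logical rows x cols foreground mask (default: all
#'   pixels).
#' @param analyte label stored on the map.
#' @return An object of class `distribution_map` (fields `values`, `mask`,
#'   `analyte`, `display_range`). The default display range is the robust
#'   1st-99th percentile span of the masked values.
#' @export
predict_pixelwise <- function(cube, model, mask = NULL, analyte = "analyte") {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "spectral_model"))
  d <- dim(cube$data)
  if (d[3L] != length(model$coefficients))
    stopf("cube has %d bands, model expects %d", d[3L],
          length(model$coefficients))
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  stopifnot(is.logical(mask), all(dim(mask) == d[1:2]))
  if (!any(mask)) stopf("empty mask")
  m <- matrix(cube$data, d[1L] * d[2L], d[3L])[as.vector(mask), , drop = FALSE]
  pred <- predict(model, m, apply_preprocess = TRUE)
  values <- matrix(NA_real_, d[1L], d[2L])
  values[mask] <- pred
  distribution_map(values, mask, analyte)
}

#' Construct a distribution map
#'
#' @param values rows x cols numeric matrix, finite on the mask, `NA`
#'   elsewhere.
#' @param mask logical foreground matrix.
#' @param analyte label.
#' @param display_range optional `c(lo, hi)`, `lo < hi`; default is the
#'   robust percentile range of the masked values (a constant map is
#'   padded by one unit either side).
#' @return An object of class `distribution_map`.
#' @export
distribution_map <- function(values, mask, analyte = "analyte",
                             display_range = NULL) {
  stopifnot(is.matrix(values), is.logical(mask),
            all(dim(mask) == dim(values)))
  if (!all(is.finite(values[mask]))) stopf("non-finite values on the mask")
  map <- structure(list(values = values, mask = mask, analyte = analyte,
                        display_range = NULL),
                   class = "distribution_map")
  map$display_range <- if (is.null(display_range)) shared_scale(list(map))
                       else as.numeric(display_range)
  if (map$display_range[1] >= map$display_range[2])
    stopf("display_range lo must be < hi")
  map
}

#' @export
print.distribution_map <- function(x, ...) {
  cat(sprintf("<distribution_map %s: %d x %d, %d/%d foreground, range [%.4g, %.4g]>\n",
              x$analyte, nrow(x$values), ncol(x$values), sum(x$mask),
              length(x$mask), x$display_range[1], x$display_range[2]))
  invisible(x)
}

#' Common display range for a set of maps
#'
#' The 1st-99th percentile span of all masked values pooled across the
#' maps, so one color bar serves every chew time and bread of an analyte;
#' the percentile rule keeps single extreme pixels from stretching the
#' scale. A degenerate (constant) range is padded by one unit either side.
#'
#' @param maps list of `distribution_map`s (at least one).
#' @return Numeric `c(lo, hi)`.
#' @export
shared_scale <- function(maps) {
  stopifnot(length(maps) >= 1L)
  vals <- unlist(lapply(maps, function(m) m$values[m$mask]))
  r <- unname(quantile(vals, c(0.01, 0.99), names = FALSE))
  if (r[1] >= r[2]) r <- c(r[1] - 1, r[2] + 1)
  r
}

#' Blue-to-red pseudo-color lookup
#'
#' @param n number of colors.
#' @return Character vector of hex colors, cool (blue) to warm (red).
#' @export
jet_palette <- function(n = 256L) {
  colorRampPalette(c("#00007F", "blue", "cyan", "green", "yellow",
                     "orange", "red", "#7F0000"))(n)
}

#' Map values to pseudo-colors
#'
#' Linear value-to-color lookup over `range`, clamped at the endpoints, so
#' warmer colors always mean higher values.
#'
#' @param values numeric vector/matrix.
#' @param range `c(lo, hi)` display range.
#' @param palette color vector (low to high).
#' @return Character vector/matrix of hex colors (`NA` for `NA` input).
#' @export
value_to_color <- function(values, range, palette = jet_palette()) {
  idx <- (values - range[1]) / (range[2] - range[1])
  idx[idx < 0] <- 0; idx[idx > 1] <- 1
  out <- palette[1L + round(idx * (length(palette) - 1L))]
  out[is.na(values)] <- NA_character_
  if (is.matrix(values)) out <- matrix(out, nrow(values))
  out
}

#' Render a distribution map as a pseudo-color PNG
#'
#' Blue = low, red = high; background (masked-out) pixels are neutral
#' gray; a labeled color bar is drawn on the right. Output bytes are
#' deterministic for identical inputs (cairo device). A JSON sidecar
#' records the analyte and display range.
#'
#' @param map a `distribution_map`.
#' @param path output PNG path.
#' @param palette color vector (low to high).
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
render_pseudocolor <- function(map, path, palette = jet_palette(),
                               width = 480L, height = 400L) {
  stopifnot(inherits(map, "distribution_map"))
  if (!any(map$mask)) stopf("all pixels are masked out")
  rng <- map$display_range
  png(path, width = width, height = height, type = "cairo")
  on.exit(dev.off(), add = TRUE)
  graphics::layout(matrix(1:2, 1L), widths = c(4, 1))
  par(mar = c(1, 1, 2, 1))
  z <- map$values
  z[z < rng[1]] <- rng[1]; z[z > rng[2]] <- rng[2]
  z[!map$mask] <- NA
  ## image() draws x right, y up; transpose/flip so row 1 is at the top
  image(t(z[nrow(z):1, , drop = FALSE]), col = palette,
        zlim = rng, axes = FALSE, useRaster = TRUE, main = map$analyte)
  rect(par("usr")[1], par("usr")[3], par("usr")[2], par("usr")[4],
       border = "black")
  par(mar = c(1, 0.5, 2, 2.5))
  ticks <- pretty(rng, 5)
  ticks <- ticks[ticks >= rng[1] & ticks <= rng[2]]
  image(1, seq(rng[1], rng[2], length.out = 256L),
        matrix(seq(rng[1], rng[2], length.out = 256L), 1L),
        col = palette, zlim = rng, axes = FALSE, xlab = "", ylab = "")
  axis(4, at = ticks, las = 1, cex.axis = 0.8)
  sidecar <- sub("\\.png$", ".json", path)
  jsonlite::write_json(list(analyte = map$analyte,
                            display_range = rng,
                            n_foreground = sum(map$mask)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a map as a CSV grid
#'
#' @param map a `distribution_map`.
#' @param path output CSV path (plain grid, `NA` for background).
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}
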