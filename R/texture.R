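#' Moisture content from bolus weighings
#'
#' Oven-drying arithmetic: `m1` is the chewed-bolus mass, `m2` the dried
#' mass. The default follows the dry-basis form `(m1 - m2) / m2`; the
#' wet-basis alternative `(m1 - m2) / m1` ("weight loss relative to the
#' initial weight") is available by flag. The result carries its
#' convention in the `"basis"` attribute so the two are never confused.
#'
#' @param m1 chewed bolus mass (g).
#' @param m2 dried bolus mass (g), `> 0` and `<= m1`.
#' @param basis `"dry"` (default) or `"wet"`.
#' @return Moisture fraction with attribute `"basis"`.
#' @export
moisture_content <- function(m1, m2, basis = c("dry", "wet")) {
  basis <- match.arg(basis)
  if (any(m2 <= 0)) stopf("dried mass m2 must be > 0")
  if (any(m1 < m2)) stopf("chewed mass m1 must be >= dried mass m2")
  out <- if (basis == "dry") (m1 - m2) / m2 else (m1 - m2) / m1
  attr(out, "basis") <- basis
  out
}

#' Glucose standard curve (DNS assay)
#'
#' Ordinary least-squares line `A = slope * c + intercept` through the
#' standards' absorbance at 540 nm. A non-positive slope indicates an
#' invalid assay and is an error.
#'
#' @param concentrations glucose standard concentrations (`>= 3` distinct
#'   values).
#' @param absorbances measured absorbances at 540 nm.
#' @return An object of class `standard_curve` (fields `slope`,
#'   `intercept`, `r2`, `analyte`).
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  if (length(concentrations) < 3L || length(absorbances) != length(concentrations))
    stopf("need >= 3 paired standards")
  if (sd(concentrations) == 0) stopf("standard concentrations are constant")
  slope <- cov(concentrations, absorbances) / var(concentrations)
  intercept <- mean(absorbances) - slope * mean(concentrations)
  if (slope <= 0) stopf("fitted slope %.4g <= 0: invalid assay", slope)
  fitted <- intercept + slope * concentrations
  ss_tot <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum((absorbances - fitted)^2) / ss_tot
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 analyte = "glucose"), class = "standard_curve")
}

#' Reducing-sugar concentration from absorbance
#'
#' Inverts the standard curve, `c = (A - intercept) / slope`, scaled by the
#' sample dilution factor.
#'
#' @param curve a `standard_curve`.
#' @param absorbance measured A540 value(s).
#' @param dilution dilution factor applied to the extract.
#' @return Concentration in the standards' units (mg/g after dilution
#'   scaling).
#' @export
rs_from_absorbance <- function(curve, absorbance, dilution = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  (absorbance - curve$intercept) / curve$slope * dilution
}

#' Quantize a map to discrete gray levels
#'
#' Linear binning of the masked value range into `0 .. levels - 1`; the
#' maximum maps to `levels - 1`; background stays `NA`. A constant map
#' quantizes to level 0 everywhere with a warning.
#'
#' @param map a `distribution_map` or numeric matrix (then `mask` applies).
#' @param levels number of gray levels `L >= 2` (default 64).
#' @param mask optional logical matrix when `map` is a plain matrix.
#' @param range optional fixed `c(lo, hi)` binning range (values outside
#'   are clamped). Default: the masked min/max of this map. Use a shared
#'   range when contrasts are compared across maps — per-map ranges make
#'   the statistic blind to the map's absolute spread.
#' @return Integer matrix in `0 .. L-1` with `NA` background.
#' @export
quantize_map <- function(map, levels = 64L, mask = NULL, range = NULL) {
  if (inherits(map, "distribution_map")) {
    vals <- map$values; mask <- map$mask
  } else {
    vals <- map
    if (is.null(mask)) mask <- matrix(TRUE, nrow(vals), ncol(vals))
  }
  if (levels < 2L) stopf("levels must be >= 2")
  v <- vals[mask]
  if (!all(is.finite(v))) stopf("masked values must be finite")
  r <- if (is.null(range)) base::range(v) else as.numeric(range)
  out <- matrix(NA_integer_, nrow(vals), ncol(vals))
  if (r[1] == r[2]) {
    warnf("constant map: all pixels quantized to level 0")
    out[mask] <- 0L
    return(out)
  }
  v[v < r[1]] <- r[1]; v[v > r[2]] <- r[2]
  q <- floor((v - r[1]) / (r[2] - r[1]) * levels)
  q[q == levels] <- levels - 1L
  out[mask] <- as.integer(q)
  out
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs `(x, x + offset)` with both endpoints inside
#' the image and the mask, symmetrizes (each pair is counted in both
#' directions) and normalizes to total mass 1.
#'
#' @param img integer matrix with levels in `0 .. levels-1` (`NA` =
#'   background).
#' @param offset integer `c(di, dj)` displacement, not `c(0, 0)`.
#' @param levels number of gray levels `L`; default `max(img) + 1`.
#' @param mask optional logical matrix (`NA` pixels are always excluded).
#' @return An object of class `glcm`: `matrix` (L x L, sums to 1),
#'   `levels`, `offset`, `symmetric = TRUE`, `n_pairs`.
#' @export
glcm_compute <- function(img, offset, levels = NULL, mask = NULL) {
  stopifnot(is.matrix(img), length(offset) == 2L)
  if (all(offset == 0L)) stopf("offset must not be (0, 0)")
  if (is.null(mask)) mask <- !is.na(img)
  mask <- mask & !is.na(img)
  if (!any(mask)) stopf("no valid pixel pairs under the mask")
  if (is.null(levels)) levels <- max(img[mask]) + 1L
  L <- as.integer(levels)
  nr <- nrow(img); nc <- ncol(img)
  di <- offset[1]; dj <- offset[2]
  r1 <- seq_len(nr); r2 <- r1 + di
  c1 <- seq_len(nc); c2 <- c1 + dj
  ok_r <- r2 >= 1L & r2 <= nr
  ok_c <- c2 >= 1L & c2 <= nc
  if (!any(ok_r) || !any(ok_c)) stopf("no valid pixel pairs for offset")
  a <- img[r1[ok_r], c1[ok_c], drop = FALSE]
  b <- img[r2[ok_r], c2[ok_c], drop = FALSE]
  valid <- mask[r1[ok_r], c1[ok_c], drop = FALSE] &
           mask[r2[ok_r], c2[ok_c], drop = FALSE]
  if (!any(valid)) stopf("no valid pixel pairs under the mask")
  i <- a[valid]; j <- b[valid]
  counts <- matrix(tabulate(i * L + j + 1L, nbins = L * L), L, L,
                   byrow = TRUE)
  counts <- counts + t(counts)      # symmetrize: both directions
  structure(list(matrix = counts / sum(counts), levels = L,
                 offset = as.integer(offset), symmetric = TRUE,
                 n_pairs = sum(valid)),
            class = "glcm")
}

## The four standard direction offsets at a given pixel distance:
## 0, 45, 90 and 135 degrees.
glcm_offsets <- function(distance = 1L) {
  d <- as.integer(distance)
  list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
}

#' GLCM contrast
#'
#' The moment of inertia about the co-occurrence matrix diagonal,
#' `sum_i sum_j (i - j)^2 P(i, j)`: zero for a perfectly uniform image,
#' growing with local gray-level variation.
#'
#' @param x a `glcm`, or a quantized integer matrix (then the four-
#'   direction mean at `distance` is returned).
#' @param distance pixel distance for the matrix form.
#' @param mask optional mask for the matrix form.
#' @return Scalar contrast value.
#' @export
glcm_contrast <- function(x, distance = 1L, mask = NULL) {
  if (inherits(x, "glcm")) {
    idx <- seq_len(x$levels) - 1L
    return(sum(outer(idx, idx, `-`)^2 * x$matrix))
  }
  offs <- glcm_offsets(distance)
  mean(vapply(offs, function(o)
    glcm_contrast(glcm_compute(x, o, mask = mask)), numeric(1)))
}

#' Map-uniformity contrast
#'
#' Quantizes a distribution map to `levels` gray levels and returns the
#' mean GLCM contrast over the four directions at the given distance —
#' the pipeline's spatial-uniformity statistic (larger = less uniform).
#'
#' @param map a `distribution_map`.
#' @param levels gray levels (default 64).
#' @param distance pair distance in pixels (default 1).
#' @param range optional fixed quantization range (see [quantize_map()]);
#'   pass a per-analyte shared range when comparing uniformity across
#'   boluses or chew times.
#' @return Scalar contrast.
#' @export
map_contrast <- function(map, levels = 64L, distance = 1L, range = NULL) {
  q <- quantize_map(map, levels = levels, range = range)
  offs <- glcm_offsets(distance)
  mean(vapply(offs, function(o)
    glcm_contrast(glcm_compute(q, o, levels = levels)), numeric(1)))
}

#' Spearman rank correlation matrix with significance stars
#'
#' Mid-rank (average-rank) Spearman correlation for every variable pair,
#' pairwise-complete over missing values. Two-sided p-values use the
#' t-approximation `t = rho sqrt((n - 2) / (1 - rho^2))` with `n - 2`
#' degrees of freedom; for very small samples (`n <= exact_max`) an exact
#' permutation p-value is computed instead. Stars: `*` for p <= 0.05,
#' `**` for p <= 0.01. Constant variables give flagged `NA` cells, never
#' silent ones.
#'
#' @param data data frame of numeric variables.
#' @param exact_max largest pair size for exact permutation p-values
#'   (default 8; full enumeration of `n!` orderings).
#' @return An object of class `correlation_matrix`: `rho`, `p`, `stars`,
#'   `n` (pairwise counts), `flagged` (logical, degenerate cells).
#' @export
spearman_matrix <- function(data, exact_max = 8L) {
  stopifnot(is.data.frame(data))
  vars <- names(data)
  k <- length(vars)
  rho <- p <- n_mat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  flagged <- matrix(FALSE, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1; diag(p) <- 0
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (b <= a) next
    ok <- is.finite(data[[a]]) & is.finite(data[[b]])
    n <- sum(ok)
    n_mat[a, b] <- n_mat[b, a] <- n
    if (n < 5L) { flagged[a, b] <- flagged[b, a] <- TRUE; next }
    x <- rank(data[[a]][ok], ties.method = "average")
    y <- rank(data[[b]][ok], ties.method = "average")
    if (sd(x) == 0 || sd(y) == 0) {
      flagged[a, b] <- flagged[b, a] <- TRUE
      next
    }
    r <- cov(x, y) / (sd(x) * sd(y))
    rho[a, b] <- rho[b, a] <- r
    p[a, b] <- p[b, a] <- if (n <= exact_max) spearman_perm_p(x, y, r)
                          else spearman_t_p(r, n)
  }
  stars <- matrix("", k, k, dimnames = list(vars, vars))
  stars[!is.na(p) & p <= 0.05] <- "*"
  stars[!is.na(p) & p <= 0.01] <- "**"
  diag(stars) <- ""
  structure(list(rho = rho, p = p, stars = stars, n = n_mat,
                 flagged = flagged),
            class = "correlation_matrix")
}

spearman_t_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t_stat), df = n - 2)
}

## Exact two-sided permutation p-value: proportion of the n! orderings of
## y whose |rho| is at least the observed |rho| (feasible for small n).
spearman_perm_p <- function(rx, ry, r_obs) {
  perms <- all_permutations(length(ry))
  denom <- sd(rx) * sd(ry)
  r_all <- apply(perms, 1L, function(idx) cov(rx, ry[idx]) / denom)
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("Spearman rank correlations (stars: * p<=0.05, ** p<=0.01)\n")
  m <- matrix(sprintf(paste0("%.", digits, "f%s"), x$rho, x$stars),
              nrow(x$rho), dimnames = dimnames(x$rho))
  diag(m) <- "1"
  m[is.na(x$rho)] <- "--"
  print(m, quote = FALSE)
  invisible(x)
}

#' Write a correlation matrix as CSV layers
#'
#' @param cm a `correlation_matrix`.
#' @param path_prefix files `<prefix>_rho.csv`, `<prefix>_p.csv`,
#'   `<prefix>_stars.csv` are written.
#' @return The prefix, invisibly.
#' @export
write_correlation_csv <- function(cm, path_prefix) {
  write.csv(cm$rho, paste0(path_prefix, "_rho.csv"))
  write.csv(cm$p, paste0(path_prefix, "_p.csv"))
  write.csv(cm$stars, paste0(path_prefix, "_stars.csv"))
  invisible(path_prefix)
}
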