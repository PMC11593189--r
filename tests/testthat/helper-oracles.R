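## Shared fixtures and independent oracles for the suite.

## Small, fast generator config used by most tests.
tiny_config <- function(...) {
  args <- modifyList(
    list(n_rows = 32L, n_cols = 32L, n_bands = 64L,
         n_panelists = 2L, n_replicates = 1L,
         noise_sd = 0, label_cv = 0, field_smoothness = 4, seed = 42L),
    list(...))
  do.call(generator_config, args)
}

random_cube <- function(nr = 6L, nc = 5L, nb = 8L, seed = 1L) {
  set.seed(seed)
  hypercube(array(runif(nr * nc * nb), c(nr, nc, nb)),
            wavelengths = seq(900, 1700, length.out = nb))
}

## --- oracle: ordinary least squares via normal equations ---------------
ols_oracle <- function(X, y, X_new = X) {
  Xc <- cbind(1, X)
  beta <- solve(crossprod(Xc), crossprod(Xc, y))
  drop(cbind(1, X_new) %*% beta)
}

## --- oracle: Savitzky-Golay by explicit per-window polynomial fits -----
## Same mirror padding convention as the implementation.
sg_oracle <- function(x, window, polyorder) {
  half <- (window - 1L) %/% 2L
  n <- length(x)
  xp <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  vapply(seq_len(n), function(i) {
    seg <- xp[i:(i + 2L * half)]
    z <- (-half):half
    fit <- lm.fit(outer(z, 0:polyorder, `^`), seg)
    unname(fit$coefficients[1L])        # value at window center (z = 0)
  }, numeric(1))
}

## --- oracle: naive masked mean spectrum --------------------------------
mean_spectrum_oracle <- function(cube, mask) {
  nb <- dim(cube$data)[3L]
  out <- numeric(nb)
  cnt <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c]) next
    out <- out + cube$data[r, c, ]
    cnt <- cnt + 1L
  }
  out / cnt
}

## --- oracle: exhaustive-pair GLCM --------------------------------------
glcm_oracle <- function(img, offset, levels) {
  L <- levels
  counts <- matrix(0, L, L)
  nr <- nrow(img); nc <- ncol(img)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    if (is.na(img[r, c]) || is.na(img[r2, c2])) next
    i <- img[r, c] + 1L; j <- img[r2, c2] + 1L
    counts[i, j] <- counts[i, j] + 1
    counts[j, i] <- counts[j, i] + 1   # symmetric
  }
  counts / sum(counts)
}

## Rotate a matrix 90 degrees counter-clockwise.
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

expect_close <- function(actual, expected, tol = 1e-10) {
  expect_lt(max(abs(actual - expected)), tol)
}
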