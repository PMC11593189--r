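test_that("moisture arithmetic supports both denominator conventions", {
  expect_equal(as.numeric(moisture_content(2, 2)), 0)
  expect_equal(as.numeric(moisture_content(2, 1)), 1.0)
  expect_equal(as.numeric(moisture_content(3, 2)), 0.5)            # dry basis
  expect_equal(as.numeric(moisture_content(3, 2, basis = "wet")), 1 / 3)
  expect_equal(attr(moisture_content(3, 2, "wet"), "basis"), "wet")
  expect_error(moisture_content(3, 0), "m2")
  expect_error(moisture_content(1, 2), "m1")
})

test_that("glucose standard curve fits and inverts", {
  curve <- fit_standard_curve(c(0, 1, 2), c(0, 0.5, 1.0))
  expect_equal(curve$slope, 0.5)
  expect_equal(curve$intercept, 0)
  expect_equal(curve$r2, 1)
  expect_equal(rs_from_absorbance(curve, 0.75), 1.5)
  expect_equal(rs_from_absorbance(curve, curve$intercept), 0)
  expect_equal(rs_from_absorbance(curve, 0.75, dilution = 10), 15)
  ## noisy but positive-slope standards round trip at the fit line
  set.seed(41)
  conc <- 0:5
  ab <- 0.1 + 0.3 * conc + rnorm(6, sd = 0.01)
  c2 <- fit_standard_curve(conc, ab)
  expect_gt(c2$r2, 0.99)
  ## decreasing absorbance is an invalid assay
  expect_error(fit_standard_curve(0:3, c(1, 0.8, 0.5, 0.1)), "slope")
  expect_error(fit_standard_curve(0:1, 0:1), "standards")
})

test_that("quantization bins masked values linearly", {
  ramp <- matrix(seq(0, 1, length.out = 64), 8, 8)
  q <- quantize_map(ramp, levels = 4L)
  expect_equal(sort(unique(as.vector(q))), 0:3)
  expect_equal(as.vector(table(q)), rep(16L, 4))
  ## max maps to L-1, two-valued map hits the extremes
  two <- matrix(c(2, 7), 2, 2)
  q2 <- quantize_map(two, levels = 8L)
  expect_setequal(unique(as.vector(q2)), c(0L, 7L))
  expect_warning(qc <- quantize_map(matrix(1, 3, 3), 8L), "constant")
  expect_true(all(qc == 0L))
  ## fixed-range quantization clamps outside values
  qr <- quantize_map(matrix(c(-1, 0.5, 2), 1, 3), levels = 4L,
                     range = c(0, 1))
  expect_equal(as.vector(qr), c(0L, 2L, 3L))
})

test_that("GLCM equals the exhaustive pair-enumeration oracle", {
  set.seed(42)
  for (rep in 1:50) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    L <- sample(2:5, 1)
    img <- matrix(sample(0:(L - 1), nr * nc, replace = TRUE), nr, nc)
    off <- sample(list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
                       c(0L, 2L), c(-2L, 1L)), 1)[[1]]
    if (abs(off[1]) >= nr || abs(off[2]) >= nc) next
    g <- glcm_compute(img, off, levels = L)
    expect_identical(g$matrix, glcm_oracle(img, off, L))
    expect_equal(sum(g$matrix), 1, tolerance = 1e-12)
    expect_identical(g$matrix, t(g$matrix))
  }
})

test_that("GLCM handles the textbook miniatures", {
  ## constant image: all mass on the diagonal, contrast 0
  g <- glcm_compute(matrix(3L, 4, 4), c(0L, 1L), levels = 4L)
  expect_equal(g$matrix[4, 4], 1)
  expect_equal(glcm_contrast(g), 0)
  ## single horizontal pair [0, 1]
  g2 <- glcm_compute(matrix(c(0L, 1L), 1, 2), c(0L, 1L), levels = 2L)
  expect_equal(g2$matrix, matrix(c(0, 0.5, 0.5, 0), 2))
  ## masks exclude pairs touching background
  img <- matrix(0:3, 2, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  g3 <- glcm_compute(img, c(1L, 0L), levels = 4L, mask = mask)
  expect_equal(g3$n_pairs, 1L)       # only the left column pair survives
  expect_error(glcm_compute(img, c(0L, 0L)), "offset")
  expect_error(glcm_compute(img, c(1L, 0L), mask = matrix(FALSE, 2, 2)),
               "mask")
})

test_that("checkerboard contrast scales as the squared level gap", {
  cb <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  g <- glcm_compute(cb, c(0L, 1L), levels = 2L)
  expect_equal(glcm_contrast(g), 1)
  cb2 <- cb * 2L                      # levels {0, 2}
  g2 <- glcm_compute(cb2, c(0L, 1L), levels = 3L)
  expect_equal(glcm_contrast(g2), 4)
})

test_that("contrast is invariant under gray reversal and 4-dir rotation", {
  set.seed(43)
  L <- 6L
  img <- matrix(sample(0:(L - 1), 49, replace = TRUE), 7, 7)
  for (off in glcm_offsets(1L)) {
    c1 <- glcm_contrast(glcm_compute(img, off, levels = L))
    c2 <- glcm_contrast(glcm_compute(L - 1L - img, off, levels = L))
    expect_equal(c1, c2)
  }
  ## 90-degree rotation permutes directional contrasts; their mean is fixed
  per_dir <- function(im) vapply(glcm_offsets(1L), function(o)
    glcm_contrast(glcm_compute(im, o, levels = L)), numeric(1))
  a <- per_dir(img)
  b <- per_dir(rot90(img))
  expect_equal(sort(a), sort(b))
  expect_equal(mean(a), mean(b))
  expect_equal(glcm_contrast(img), mean(a))
})

test_that("Spearman matrix matches rank-formula and reference values", {
  df <- data.frame(x = c(1, 2, 3, 4, 5), y = c(1, 3, 2, 5, 4))
  cm <- spearman_matrix(df)
  expect_equal(cm$rho["x", "y"], 0.8)     # 1 - 6*4/(5*24)
  expect_equal(unname(diag(cm$rho)), c(1, 1))
  ## identical and reversed rankings
  df2 <- data.frame(a = 1:8, b = 1:8, c = 8:1)
  cm2 <- spearman_matrix(df2)
  expect_equal(cm2$rho["a", "b"], 1)
  expect_equal(cm2$rho["a", "c"], -1)
  ## agreement with the reference implementation (t-approximation regime)
  set.seed(44)
  df3 <- data.frame(u = rnorm(30), v = rnorm(30))
  cm3 <- spearman_matrix(df3)
  expect_equal(cm3$rho["u", "v"],
               unname(cor(df3$u, df3$v, method = "spearman")),
               tolerance = 1e-12)
})

test_that("Spearman rho survives strictly monotone transforms", {
  set.seed(45)
  x <- rnorm(20); y <- rnorm(20)
  base <- spearman_matrix(data.frame(x, y))$rho[1, 2]
  warped <- spearman_matrix(data.frame(x = exp(3 * x), y = y^3))$rho[1, 2]
  expect_equal(base, warped)
})

test_that("Spearman p-values, stars and degenerate flags behave", {
  set.seed(46)
  n <- 40
  x <- rnorm(n)
  df <- data.frame(x = x, y = x + rnorm(n, sd = 0.3), z = rnorm(n),
                   const = rep(1, n))
  cm <- spearman_matrix(df)
  expect_equal(cm$stars["x", "y"], "**")    # strong monotone association
  expect_true(cm$flagged["x", "const"])
  expect_true(is.na(cm$rho["x", "const"]))
  ## t-approximation formula check
  r <- cm$rho["x", "z"]
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(cm$p["x", "z"], 2 * pt(-abs(t_stat), n - 2))
  ## exact permutation p for small n: a perfect ranking of n = 5 has
  ## two-sided p = 2/5! (only the identity and the reversal reach |rho| = 1)
  cm5 <- spearman_matrix(data.frame(a = 1:5, b = c(2, 4, 6, 8, 10)))
  expect_equal(cm5$rho["a", "b"], 1)
  expect_equal(cm5$p["a", "b"], 2 / factorial(5))
})
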