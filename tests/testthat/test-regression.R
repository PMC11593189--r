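test_that("PLSR and PCR reduce to OLS at full rank", {
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 5), 20)
    y <- rnorm(20)
    ols <- ols_oracle(X, y)
    expect_close(fit_plsr(X, y, 5L)$fitted, ols, 1e-8)
    expect_close(fit_pcr(X, y, 5L)$fitted, ols, 1e-8)
  }
})

test_that("noiseless linear response is fit exactly", {
  set.seed(22)
  X <- matrix(rnorm(30 * 6), 30)
  beta <- rnorm(6)
  y <- drop(X %*% beta) + 2
  m <- fit_plsr(X, y, 6L)
  expect_close(m$fitted, y, 1e-8)
  expect_equal(compute_metrics(y, m$fitted)$r2, 1, tolerance = 1e-10)
})

test_that("NIPALS scores are mutually orthogonal", {
  set.seed(23)
  X <- matrix(rnorm(25 * 10), 25)
  y <- rnorm(25)
  m <- fit_plsr(X, y, 6L)
  G <- crossprod(m$scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
})

test_that("rank-1 X gives the univariate closed-form fit", {
  set.seed(24)
  u <- rnorm(15); v <- rnorm(8)
  X <- outer(u, v)
  y <- 3 * u + rnorm(15, sd = 0.1)
  m <- fit_plsr(X, y, 1L)
  ## closed form: simple regression of y on the single score t = Xc w
  Xc <- sweep(X, 2, colMeans(X))
  w <- crossprod(Xc, y - mean(y)); w <- w / sqrt(sum(w^2))
  t1 <- drop(Xc %*% w)
  pred <- mean(y) + t1 * sum(t1 * (y - mean(y))) / sum(t1^2)
  expect_close(m$fitted, pred, 1e-8)
})

test_that("PCR k = 1 equals regression on the leading principal score", {
  set.seed(25)
  X <- matrix(rnorm(30 * 6), 30) %*% diag(c(5, 1, 1, 0.5, 0.2, 0.1))
  y <- rnorm(30)
  m <- fit_pcr(X, y, 1L)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  t1 <- sv$u[, 1] * sv$d[1]
  pred <- mean(y) + t1 * sum(t1 * (y - mean(y))) / sum(t1^2)
  expect_close(m$fitted, pred, 1e-8)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
})

test_that("PLSR calibration residuals never exceed PCR's at equal k", {
  set.seed(26)
  for (rep in 1:20) {
    X <- matrix(rnorm(24 * 12), 24)
    y <- rnorm(24)
    k <- sample(1:6, 1)
    ssr <- function(m) sum((y - m$fitted)^2)
    expect_lte(ssr(fit_plsr(X, y, k)), ssr(fit_pcr(X, y, k)) + 1e-10)
  }
})

test_that("prediction honors centering and batch consistency", {
  set.seed(27)
  X <- matrix(rnorm(20 * 8), 20)
  y <- rnorm(20)
  m <- fit_plsr(X, y, 3L)
  expect_close(predict(m, X), m$fitted, 1e-12)
  expect_equal(predict(m, m$x_mean), m$y_mean)
  expect_equal(predict(m, X[7, ]), predict(m, X)[7])
  expect_error(predict(m, X[, 1:5]), "bands")
})

test_that("metrics match hand arithmetic and definitions", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$r2, 0.5)
  y <- c(2, 4, 6, 8)
  expect_equal(compute_metrics(y, y), list(r2 = 1, rmse = 0))
  expect_equal(compute_metrics(y, rep(mean(y), 4))$r2, 0)
  expect_error(compute_metrics(rep(1, 4), 1:4), "constant")
})

test_that("Kennard-Stone picks extremes first and splits deterministically", {
  X <- matrix(c(0, 1, 10, 5), 4)
  sp <- split_calibration_prediction(X, cal_fraction = 0.5)
  expect_true(all(c(1, 3) %in% sp$cal))      # the two most distant points
  expect_setequal(c(sp$cal, sp$pred), 1:4)
  set.seed(28)
  X2 <- matrix(rnorm(96 * 5), 96)
  sp2 <- split_calibration_prediction(X2, cal_fraction = 0.75)
  expect_length(sp2$cal, 72)
  expect_length(sp2$pred, 24)
  expect_identical(sp2, split_calibration_prediction(X2, cal_fraction = 0.75))
  spr <- split_calibration_prediction(X2, method = "random", seed = 5L)
  expect_identical(spr,
                   split_calibration_prediction(X2, method = "random",
                                                seed = 5L))
  expect_error(split_calibration_prediction(X[1:3, , drop = FALSE]), "4")
})

test_that("cross-validation matches a brute-force leave-one-out refit loop", {
  set.seed(29)
  X <- matrix(rnorm(5 * 3), 5)
  y <- rnorm(5)
  cv <- cross_validate(X, y, "PLSR", 2L, folds = 5L, seed = 1L)
  ## oracle: explicit 5 refits (leave-one-out; every fold is a singleton)
  pred <- vapply(1:5, function(i) {
    m <- fit_plsr(X[-i, ], y[-i], 2L)
    predict(m, X[i, ])
  }, numeric(1))
  expect_close(cv$predictions, pred, 1e-10)
  expect_equal(cv$rmsecv, sqrt(mean((y - pred)^2)), tolerance = 1e-10)
  ## noiseless linear response: RCV2 = 1
  Xl <- matrix(rnorm(30 * 4), 30)
  yl <- drop(Xl %*% c(1, -2, 0.5, 3))
  expect_equal(cross_validate(Xl, yl, "PLSR", 4L, folds = 10L)$rcv2, 1,
               tolerance = 1e-8)
})

test_that("component selection follows the parsimony rule", {
  ## three latent factors, 1% noise: k* lands on 3 or 4
  set.seed(30)
  n <- 60; p <- 50
  Tlat <- matrix(rnorm(n * 3), n)
  P <- matrix(rnorm(3 * p), 3)
  X <- Tlat %*% P + matrix(rnorm(n * p, sd = 0.01), n)
  y <- drop(Tlat %*% c(2, -1, 0.5)) + rnorm(n, sd = 0.01)
  sel <- select_n_components(X, y, "PLSR", max_k = 10L, seed = 1L)
  expect_true(sel$k %in% c(3L, 4L))
  ## single candidate
  sel1 <- select_n_components(X[1:3, ], y[1:3], "PLSR", max_k = 1L,
                              folds = 3L)
  expect_equal(sel1$k, 1L)
})

test_that("shuffled predictions are worse than honest ones", {
  set.seed(31)
  X <- matrix(rnorm(40 * 10), 40)
  y <- drop(X %*% rnorm(10)) + rnorm(40, sd = 0.05)
  m <- fit_plsr(X, y, 5L)
  honest <- compute_metrics(y, m$fitted)$rmse
  shuffled <- compute_metrics(y, sample(m$fitted))$rmse
  expect_gt(shuffled, honest)
})

test_that("comparison table has the full method-model-analyte cross", {
  set.seed(32)
  n <- 24
  X <- matrix(rnorm(n * 40), n)
  X <- t(apply(X, 1, cumsum))       # smooth-ish spectra
  Y <- data.frame(a1 = drop(X %*% rnorm(40, sd = 0.1)) + rnorm(n, sd = 0.01),
                  a2 = drop(X %*% rnorm(40, sd = 0.1)) + rnorm(n, sd = 0.01),
                  a3 = drop(X %*% rnorm(40, sd = 0.1)) + rnorm(n, sd = 0.01))
  tab <- model_comparison_table(X, Y, max_k = 5L, folds = 5L, seed = 1L)
  expect_equal(nrow(tab), 18L)               # 3 analytes x 3 methods x 2 models
  expect_equal(sum(tab$best), 3L)            # one winner per analyte
  expect_true(all(tab$rmsec >= 0) && all(tab$rc2 <= 1))
  for (a in unique(tab$analyte)) {
    sub <- tab[tab$analyte == a, ]
    expect_equal(max(sub$rp2), sub$rp2[sub$best])
  }
  tab2 <- model_comparison_table(X, Y, max_k = 5L, folds = 5L, seed = 1L)
  expect_identical(tab, tab2)
})
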