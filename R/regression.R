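#' Fit a univariate PLSR model by NIPALS
#'
#' Partial least squares regression with mean-centered `X` and `y` (no
#' variance scaling, the usual convention for spectra). For a univariate
#' response the NIPALS weight is available in closed form per component:
#' `w = X'y / ||X'y||`, `t = Xw`, loadings `p = X't/(t't)`,
#' `q = y't/(t't)`, then rank-one deflation `X <- X - t p'`. The per-band
#' regression vector is assembled as `b = W (P'W)^{-1} q`, so prediction is
#' a single dot product per spectrum.
#'
#' @param X n x p numeric matrix of (preprocessed) spectra.
#' @param y numeric response vector, length n.
#' @param n_components number of latent variables,
#'   `<= min(n - 1, p)`.
#' @param preprocess optional `preprocess_spec` recorded as provenance
#'   (prediction can re-apply it, see [predict.spectral_model()]).
#' @return A `spectral_model` with fields `kind`, `coefficients` (per-band
#'   `b`), `x_mean`, `y_mean`, `n_components`, `scores`, `fitted`.
#' @export
fit_plsr <- function(X, y, n_components, preprocess = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  check_fit_inputs(X, y, n_components)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  if (sd(y) == 0) stopf("response has zero variance")
  k_max <- as.integer(n_components)
  W <- P <- matrix(0, p, k_max)
  Tm <- matrix(0, n, k_max)
  q <- numeric(k_max)
  Xd <- Xc
  k_eff <- 0L
  for (k in seq_len(k_max)) {
    w <- crossprod(Xd, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) { warnf("PLSR stopped early at %d components", k - 1L); break }
    w <- w / wn
    t_k <- Xd %*% w
    tt <- sum(t_k^2)
    if (tt < 1e-12) { warnf("PLSR stopped early at %d components", k - 1L); break }
    p_k <- crossprod(Xd, t_k) / tt
    q[k] <- sum(yc * t_k) / tt
    Xd <- Xd - t_k %*% t(p_k)
    W[, k] <- w; P[, k] <- p_k; Tm[, k] <- t_k
    k_eff <- k
  }
  if (k_eff == 0L) stopf("no usable PLS component (X'y is numerically zero)")
  W <- W[, seq_len(k_eff), drop = FALSE]
  P <- P[, seq_len(k_eff), drop = FALSE]
  Tm <- Tm[, seq_len(k_eff), drop = FALSE]
  q <- q[seq_len(k_eff)]
  b <- W %*% solve(crossprod(P, W), q)
  fitted <- drop(y_mean + Xc %*% b)
  new_spectral_model("PLSR", b, x_mean, y_mean, k_eff, Tm, fitted,
                     n_cal = n, preprocess = preprocess)
}

#' Fit a principal component regression model
#'
#' PCA of the mean-centered `X` by singular value decomposition; `y` is
#' regressed on the first `n_components` score vectors and the coefficients
#' are back-transformed to a per-band vector.
#'
#' @inheritParams fit_plsr
#' @return A `spectral_model` (see [fit_plsr()]); also carries
#'   `explained_variance`, the non-increasing per-component variances.
#' @export
fit_pcr <- function(X, y, n_components, preprocess = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  check_fit_inputs(X, y, n_components)
  if (sd(y) == 0) stopf("response has zero variance")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-12
  k_eff <- min(as.integer(n_components), sum(pos))
  if (k_eff < n_components)
    warnf("rank %d < requested %d components; truncating", k_eff, n_components)
  Tm <- sv$u[, seq_len(k_eff), drop = FALSE] %*%
    diag(sv$d[seq_len(k_eff)], k_eff)
  V <- sv$v[, seq_len(k_eff), drop = FALSE]
  g <- crossprod(Tm, yc) / sv$d[seq_len(k_eff)]^2   # scores are orthogonal
  b <- V %*% g
  fitted <- drop(y_mean + Xc %*% b)
  m <- new_spectral_model("PCR", b, x_mean, y_mean, k_eff, Tm, fitted,
                          n_cal = n, preprocess = preprocess)
  m$explained_variance <- sv$d[seq_len(k_eff)]^2 / (n - 1)
  m
}

check_fit_inputs <- function(X, y, n_components) {
  if (anyNA(X) || anyNA(y)) stopf("NA values in X or y")
  if (nrow(X) < 2L) stopf("need at least 2 samples")
  if (length(y) != nrow(X)) stopf("length(y) != nrow(X)")
  if (n_components < 1L || n_components > min(nrow(X) - 1L, ncol(X)))
    stopf("n_components must be in 1..min(n-1, p) = %d",
          min(nrow(X) - 1L, ncol(X)))
}

new_spectral_model <- function(kind, b, x_mean, y_mean, k, scores, fitted,
                               n_cal, preprocess = NULL) {
  structure(list(kind = kind, coefficients = drop(b), x_mean = x_mean,
                 y_mean = y_mean, n_components = k, scores = scores,
                 fitted = fitted, n_cal = n_cal, preprocess = preprocess),
            class = "spectral_model")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf("<%s model: %d components, %d bands, n_cal = %d%s>\n",
              x$kind, x$n_components, length(x$coefficients), x$n_cal,
              if (!is.null(x$preprocess))
                paste0(", preprocess = ", preprocess_label(x$preprocess))
              else ""))
  invisible(x)
}

#' Predict analyte values from spectra
#'
#' @param object a `spectral_model`.
#' @param X spectra matrix (rows = samples) or a single spectrum vector,
#'   with the model's band count.
#' @param apply_preprocess if `TRUE`, the model's stored `preprocess_spec`
#'   is applied to `X` first (use for raw spectra).
#' @param ... unused.
#' @return Numeric vector of predictions, `y_mean + (X - x_mean) b`.
#' @export
predict.spectral_model <- function(object, X, apply_preprocess = FALSE, ...) {
  if (is.null(dim(X))) X <- matrix(X, 1L)
  if (ncol(X) != length(object$coefficients))
    stopf("spectra have %d bands, model expects %d",
          ncol(X), length(object$coefficients))
  if (apply_preprocess && !is.null(object$preprocess))
    X <- apply_chain(X, object$preprocess)
  drop(object$y_mean + sweep(X, 2L, object$x_mean) %*% object$coefficients)
}

#' Coefficient of determination and root-mean-square error
#'
#' `rmse = sqrt(mean((y - yhat)^2))`; `r2 = 1 - SS_res / SS_tot`. Both in
#' the analyte's units. R-squared is undefined for a constant `y_true`.
#'
#' @param y_true,y_pred numeric vectors of equal length `>= 2`.
#' @return List with elements `r2` and `rmse`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    stopf("y_true and y_pred must have equal length >= 2")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stopf("r2 undefined for constant y_true")
  ss_res <- sum((y_true - y_pred)^2)
  list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(mean((y_true - y_pred)^2)))
}

#' Calibration/prediction set split
#'
#' @param X spectra matrix used for Kennard-Stone distances (already
#'   preprocessed); ignored for the random method except for its row count.
#' @param method `"kennard_stone"` (default) selects calibration samples by
#'   the max-min Euclidean distance rule, seeded with the two most distant
#'   samples; `"random"` is a seeded uniform draw.
#' @param cal_fraction fraction assigned to calibration (floor rule).
#' @param seed RNG seed for the random method.
#' @return List with integer vectors `cal` and `pred` (disjoint,
#'   exhaustive, 1-based).
#' @export
split_calibration_prediction <- function(X, method = c("kennard_stone", "random"),
                                         cal_fraction = 0.75, seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stopf("need at least 4 samples to split")
  if (cal_fraction <= 0 || cal_fraction >= 1) stopf("cal_fraction must be in (0,1)")
  n_cal <- max(2L, floor(n * cal_fraction))
  cal <- if (method == "kennard_stone") kennard_stone(X, n_cal)
         else with_seed(seed, sort(sample.int(n, n_cal)))
  list(cal = cal, pred = setdiff(seq_len(n), cal))
}

## Kennard-Stone max-min selection; ties resolve to the lowest index.
kennard_stone <- function(X, m) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  first <- which(D == max(D), arr.ind = TRUE)
  first <- sort(first[order(first[, 1], first[, 2]), ][1, ])
  sel <- as.integer(first)
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < m) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  sort(sel)
}

#' K-fold cross-validation of a latent-variable model
#'
#' Fold assignment is a seeded random permutation (deterministic given
#' `seed`); each fold is predicted by a model fit on the remaining folds
#' with centering recomputed per fold. Pooled residuals give RMSECV and
#' pooled R-squared (RCV2).
#'
#' @param X,y calibration spectra and response.
#' @param kind `"PLSR"` or `"PCR"`.
#' @param n_components latent variables per fold model.
#' @param folds number of folds (`>= 2`), or `n` for leave-one-out.
#' @param seed fold-assignment seed.
#' @return List with `rcv2`, `rmsecv` and the pooled `predictions`.
#' @export
cross_validate <- function(X, y, kind = c("PLSR", "PCR"), n_components,
                           folds = 10L, seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- as.integer(min(folds, n))
  if (folds < 2L) stopf("folds must be >= 2")
  assign <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- numeric(n)
  fit_fun <- if (kind == "PLSR") fit_plsr else fit_pcr
  for (f in seq_len(folds)) {
    hold <- which(assign == f)
    keep <- which(assign != f)
    if (length(keep) < 2L) stopf("fold %d leaves < 2 calibration samples", f)
    k <- min(n_components, length(keep) - 1L, ncol(X))
    m <- fit_fun(X[keep, , drop = FALSE], y[keep], k)
    pred[hold] <- predict(m, X[hold, , drop = FALSE])
  }
  met <- compute_metrics(y, pred)
  list(rcv2 = met$r2, rmsecv = met$rmse, predictions = pred)
}

#' Choose the number of latent variables by parsimonious cross-validation
#'
#' RMSECV is computed for `k = 1..max_k` with a shared fold assignment;
#' the selected `k*` is the smallest `k` whose RMSECV lies within
#' `tolerance` (default 2%) of the global minimum.
#'
#' @inheritParams cross_validate
#' @param max_k largest candidate component count (capped at
#'   `min(n - 2, p)` so every fold model is feasible).
#' @param tolerance relative slack on the minimum RMSECV.
#' @return List with `k`, and the per-candidate `rmsecv` vector.
#' @export
select_n_components <- function(X, y, kind = c("PLSR", "PCR"), max_k = 15L,
                                folds = 10L, seed = 1L, tolerance = 0.02) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  max_k <- min(as.integer(max_k), nrow(X) - 2L, ncol(X))
  if (max_k < 1L) stopf("max_k must be >= 1")
  rmse <- vapply(seq_len(max_k), function(k)
    suppressWarnings(
      cross_validate(X, y, kind, k, folds = folds, seed = seed)$rmsecv),
    numeric(1))
  k_star <- which(rmse <= min(rmse) * (1 + tolerance))[1L]
  list(k = k_star, rmsecv = rmse)
}

#' Full pretreatment-by-model comparison table
#'
#' Crosses each pretreatment candidate with each model kind for each
#' analyte: Kennard-Stone (or random) calibration/prediction split on the
#' preprocessed spectra, component count chosen by cross-validated
#' parsimony, then calibration (RC2/RMSEC), cross-validation
#' (RCV2/RMSECV) and prediction-set (RP2/RMSEP) metrics. The best row per
#' analyte is flagged by maximum RP2.
#'
#' @param X raw (calibrated-reflectance) spectra matrix, rows = samples.
#' @param Y data frame of analyte columns (e.g. `mc`, `rs`, `chewiness`).
#' @param methods list of `preprocess_spec` candidates (default SG, GF, N).
#' @param models character vector from `c("PLSR", "PCR")`.
#' @param cal_fraction,split_method passed to
#'   [split_calibration_prediction()].
#' @param max_k,folds,seed model-selection controls.
#' @return `data.frame` with one row per analyte x method x model and
#'   columns `analyte, method, model, n_components, rc2, rmsec, rcv2,
#'   rmsecv, rp2, rmsep, best`.
#' @export
model_comparison_table <- function(X, Y,
                                   methods = list(preprocess_spec("SG"),
                                                  preprocess_spec("GF"),
                                                  preprocess_spec("N")),
                                   models = c("PLSR", "PCR"),
                                   cal_fraction = 0.75,
                                   split_method = "kennard_stone",
                                   max_k = 15L, folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(is.data.frame(Y), nrow(Y) == nrow(X))
  rows <- list()
  for (analyte in names(Y)) {
    y <- Y[[analyte]]
    for (spec in methods) {
      Xp <- apply_chain(X, spec)
      sp <- split_calibration_prediction(Xp, method = split_method,
                                         cal_fraction = cal_fraction,
                                         seed = seed)
      for (kind in models) {
        sel <- select_n_components(Xp[sp$cal, , drop = FALSE], y[sp$cal],
                                   kind, max_k = max_k, folds = folds,
                                   seed = seed)
        fit_fun <- if (kind == "PLSR") fit_plsr else fit_pcr
        m <- fit_fun(Xp[sp$cal, , drop = FALSE], y[sp$cal], sel$k,
                     preprocess = spec)
        cv <- cross_validate(Xp[sp$cal, , drop = FALSE], y[sp$cal], kind,
                             sel$k, folds = folds, seed = seed)
        mc_ <- compute_metrics(y[sp$cal], m$fitted)
        mp_ <- compute_metrics(y[sp$pred],
                               predict(m, Xp[sp$pred, , drop = FALSE]))
        rows[[length(rows) + 1L]] <- data.frame(
          analyte = analyte, method = spec$method, model = kind,
          n_components = sel$k,
          rc2 = mc_$r2, rmsec = mc_$rmse,
          rcv2 = cv$rcv2, rmsecv = cv$rmsecv,
          rp2 = mp_$r2, rmsep = mp_$rmse,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$best <- FALSE
  for (a in unique(tab$analyte)) {
    i <- which(tab$analyte == a)
    tab$best[i[which.max(tab$rp2[i])]] <- TRUE
  }
  tab
}
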