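#' Synthetic-scene generator configuration
#'
#' Describes the simulated oral-processing experiment: two bread
#' formulations (plain wheat `B0` and 50% whole-wheat `B50`, encoded by a
#' `fiber_factor` in `[0, 1]`), four chew times, a push-broom NIR camera
#' (899-1748 nm, 512 bands) and a panel of chewers with replicates. The
#' generator composes per-pixel absorbance from analyte concentration
#' fields and endmember spectra through a Beer-Lambert surrogate
#' `R = exp(-sum_k c_k eps_k)`, then re-encodes reflectance as raw detector
#' intensity `I = B + R (W - B) + noise` so the standard black/white
#' correction inverts it exactly when `noise_sd = 0`.
#'
#' @param n_rows,n_cols scene size in pixels. 64 x 64 by default, chosen
#'   for test speed; the ROI stays configurable.
#' @param n_bands number of spectral bands (`>= 8`).
#' @param wavelength_start,wavelength_end band-axis limits in nm.
#' @param bread_types named numeric vector of fiber factors per label.
#' @param chew_times chew durations in seconds.
#' @param n_panelists,n_replicates panel size and replicates per cell.
#' @param noise_sd additive Gaussian detector noise on raw intensities
#'   (reflectance-equivalent units).
#' @param label_cv coefficient of variation of the multiplicative lognormal
#'   inter-panelist label noise (0 disables it).
#' @param field_smoothness correlation length of the concentration fields,
#'   in pixels.
#' @param dark_level,white_level constant dark/white reference levels.
#' @param seed integer master seed; everything downstream derives from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_rows = 64L, n_cols = 64L, n_bands = 512L,
                             wavelength_start = 899, wavelength_end = 1748,
                             bread_types = c(B0 = 0.0, B50 = 0.5),
                             chew_times = c(0, 6, 12, 18),
                             n_panelists = 8L, n_replicates = 3L,
                             noise_sd = 0.005, label_cv = 0.05,
                             field_smoothness = 8, dark_level = 0.08,
                             white_level = 0.92, seed = 1L) {
  if (n_bands < 8L) stopf("n_bands must be >= 8")
  if (wavelength_start >= wavelength_end)
    stopf("wavelength_start must be < wavelength_end")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (any(c(n_rows, n_cols, n_panelists, n_replicates) < 1L))
    stopf("all counts must be >= 1")
  if (is.null(names(bread_types)) || any(bread_types < 0 | bread_types > 1))
    stopf("bread_types must be a named vector of fiber factors in [0,1]")
  if (white_level <= dark_level) stopf("white_level must exceed dark_level")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_bands = as.integer(n_bands),
                 wavelength_start = wavelength_start,
                 wavelength_end = wavelength_end,
                 bread_types = bread_types, chew_times = chew_times,
                 n_panelists = as.integer(n_panelists),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, label_cv = label_cv,
                 field_smoothness = field_smoothness,
                 dark_level = dark_level, white_level = white_level,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Evenly spaced wavelength grid
#'
#' @param config a `generator_config`.
#' @return Numeric vector of length `n_bands`, first element
#'   `wavelength_start`, last `wavelength_end`, uniform spacing.
#' @export
make_wavelength_grid <- function(config) {
  seq(config$wavelength_start, config$wavelength_end,
      length.out = config$n_bands)
}

## Default absorption-band table: (center nm, width nm, amplitude).
## Water: O-H second overtone near 960 nm and the stronger O-H first
## overtone near 1450 nm. Starch/sugar: C-H / O-H combination band near
## 980 nm. Fat: C-H second overtone at 1200 nm. Fiber: broad, weak,
## low-sloped absorption across the window.
default_band_table <- function() {
  list(
    water        = list(c(960, 30, 0.35), c(1450, 45, 1.00)),
    starch_sugar = list(c(980, 40, 0.55), c(1530, 80, 0.20)),
    fat          = list(c(1200, 25, 0.60)),
    fiber        = list(c(1350, 300, 0.25))
  )
}

#' Endmember absorptivity spectra
#'
#' Builds one nonnegative absorptivity vector per analyte as a sum of
#' Gaussian absorption bands on the wavelength grid.
#'
#' @param grid ascending wavelength vector (nm).
#' @param bands band table: named list (per endmember) of
#'   `c(center, width, amplitude)` triplets. Defaults place the water bands
#'   at 960/1450 nm (1450 stronger), fat at 1200 nm, starch/sugar near
#'   980 nm and a broad fiber band.
#' @return Named list of `endmember` objects (fields `name`,
#'   `absorptivity`). A band center outside the grid warns and contributes
#'   its tail only.
#' @export
make_endmembers <- function(grid, bands = default_band_table()) {
  if (any(diff(grid) <= 0)) stopf("grid must be sorted ascending")
  lapply(stats::setNames(names(bands), names(bands)), function(nm) {
    eps <- numeric(length(grid))
    for (b in bands[[nm]]) {
      if (b[1] < min(grid) || b[1] > max(grid))
        warnf("band center %g nm of `%s` outside grid; tail only", b[1], nm)
      eps <- eps + b[3] * exp(-(grid - b[1])^2 / (2 * b[2]^2))
    }
    structure(list(name = nm, absorptivity = eps), class = "endmember")
  })
}

#' Spatially correlated concentration field
#'
#' A Gaussian random field (white noise blurred by a separable Gaussian of
#' width `smoothness`, then standardized) scaled to the requested
#' coefficient of variation, shifted/clipped to nonnegative, and rescaled
#' so the mean equals `target_mean` exactly.
#'
#' @param shape `c(rows, cols)`.
#' @param target_mean positive field mean (concentration units).
#' @param heterogeneity requested coefficient of variation (`>= 0`).
#' @param smoothness Gaussian correlation length in pixels.
#' @param seed RNG seed (same seed, same field, bit for bit).
#' @return An object of class `concentration_field` (fields `values`,
#'   `target_mean`, `heterogeneity`). Heterogeneity so large that clipping
#'   removes more than 10% of the mass is an error.
#' @export
make_field <- function(shape, target_mean, heterogeneity = 0.15,
                       smoothness = 8, seed = 1L) {
  if (target_mean <= 0) stopf("target_mean must be > 0")
  if (heterogeneity < 0) stopf("heterogeneity must be >= 0")
  nr <- shape[1]; nc <- shape[2]
  if (heterogeneity == 0) {
    vals <- matrix(target_mean, nr, nc)
  } else {
    z <- with_seed(seed, matrix(rnorm(nr * nc), nr, nc))
    k <- gaussian_kernel(smoothness, max_radius = min(nr, nc) - 1L)
    z <- t(filter_rows(z, k))          # blur along rows of each column
    z <- t(filter_rows(z, k))          # then along columns
    z <- (z - mean(z)) / sd(z)
    vals <- target_mean * (1 + heterogeneity * z)
    clipped_mass <- -sum(vals[vals < 0])
    if (clipped_mass > 0.10 * target_mean * nr * nc)
      stopf("heterogeneity %g clips > 10%% of field mass", heterogeneity)
    vals[vals < 0] <- 0
    vals <- vals * (target_mean / mean(vals))
  }
  structure(list(values = vals, target_mean = target_mean,
                 heterogeneity = heterogeneity),
            class = "concentration_field")
}

## ---- label schedules -------------------------------------------------
## Saturating-exponential trajectories anchored exactly at the observed
## t = 0 and t = 18 s endpoints for each bread, linear in fiber_factor
## between the B0 (0.0) and B50 (0.5) anchors. mc is a mass fraction,
## rs is mg/g, chewiness is N.

anchor_interp <- function(fiber_factor, v_b0, v_b50) {
  v_b0 + (fiber_factor / 0.5) * (v_b50 - v_b0)
}

sat_exp <- function(t, v0, v_end, t_end, tau) {
  e <- exp(-t_end / tau)
  v_inf <- (v_end - v0 * e) / (1 - e)
  v_inf + (v0 - v_inf) * exp(-t / tau)
}

label_schedule <- function(fiber_factor, chew_time) {
  f <- fiber_factor
  list(
    mc = sat_exp(chew_time, anchor_interp(f, 0.4228, 0.3433),
                 anchor_interp(f, 0.5510, 0.4724), 18, 7),
    rs = sat_exp(chew_time, anchor_interp(f, 20, 15),
                 anchor_interp(f, 45, 32), 18, 8),
    chewiness = sat_exp(chew_time, anchor_interp(f, 29.16, 53.36),
                        anchor_interp(f, 2.00, 2.44), 18, 5)
  )
}

## Heterogeneity (CV) schedules over chew time: moisture and chewiness
## rise to a peak at ~6 s then relax (saliva first wets the bolus rim,
## later mixing homogenizes it); reducing sugars start patchy and
## homogenize monotonically.
heterogeneity_schedule <- function(chew_time) {
  t <- chew_time
  list(mc = 0.05 + 0.20 * (t / 6) * exp(1 - t / 6),
       chewiness = 0.06 + 0.22 * (t / 6) * exp(1 - t / 6),
       rs = 0.04 + 0.28 * exp(-t / 12),
       fat = 0.05)
}

## Linear label -> mean-concentration maps (invertible, so the stored
## label always equals the field mean through the map).
label_to_concentration <- function(labels) {
  c(water = labels$mc * 1.0,
    starch_sugar = labels$rs / 100,
    fiber = labels$chewiness / 100,
    fat = 0.05)
}

#' Generate the per-bolus sample table
#'
#' One record per bread type x chew time x panelist x replicate. Noise-free
#' labels follow saturating-exponential schedules anchored at the observed
#' endpoints (moisture and reducing sugars rise with chew time, chewiness
#' falls; the fiber-rich bread starts drier, lower in sugars and chewier);
#' `label_cv > 0` adds multiplicative lognormal panelist effects plus
#' half-sized replicate scatter. Each record carries its own derived scene
#' seed and heterogeneity values so scenes can be regenerated on demand.
#'
#' @param config a `generator_config`.
#' @return `data.frame` with columns `sample_id, bread_type, chew_time_s,
#'   panelist, replicate, mc, rs_mg_per_g, chewiness_N, het_mc, het_rs,
#'   het_chewiness, scene_seed`.
#' @export
make_sample_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  grid_df <- expand.grid(replicate = seq_len(config$n_replicates),
                         panelist = seq_len(config$n_panelists),
                         chew_time = config$chew_times,
                         bread_type = names(config$bread_types),
                         stringsAsFactors = FALSE)
  n <- nrow(grid_df)
  ## per-(panelist, analyte) lognormal factors, unit median
  sdlog <- sqrt(log(1 + config$label_cv^2))
  pan_fac <- with_seed(derive_seed(config$seed, "panelist"),
    matrix(exp(rnorm(config$n_panelists * 3, -sdlog^2 / 2, sdlog)),
           config$n_panelists, 3))
  rep_fac <- with_seed(derive_seed(config$seed, "replicate"),
    matrix(exp(rnorm(n * 3, -(sdlog / 2)^2 / 2, sdlog / 2)), n, 3))
  if (config$label_cv == 0) { pan_fac[] <- 1; rep_fac[] <- 1 }
  rows <- lapply(seq_len(n), function(i) {
    g <- grid_df[i, ]
    f <- config$bread_types[[g$bread_type]]
    lab <- label_schedule(f, g$chew_time)
    het <- heterogeneity_schedule(g$chew_time)
    fac <- pan_fac[g$panelist, ] * rep_fac[i, ]
    data.frame(
      sample_id = sprintf("%s_t%02d_p%02d_r%d", g$bread_type, g$chew_time,
                          g$panelist, g$replicate),
      bread_type = g$bread_type, chew_time_s = g$chew_time,
      panelist = g$panelist, replicate = g$replicate,
      mc = lab$mc * fac[1], rs_mg_per_g = lab$rs * fac[2],
      chewiness_N = lab$chewiness * fac[3],
      het_mc = het$mc, het_rs = het$rs, het_chewiness = het$chewiness,
      scene_seed = derive_seed(config$seed, "scene", i),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble one synthetic scene
#'
#' Per pixel, absorbance is `A(lambda) = sum_k c_k(x) eps_k(lambda)` over
#' the supplied concentration fields and endmembers; true reflectance is
#' `R = exp(-A)` (in `(0, 1]`); the raw cube is
#' `I = dark + R (white - dark) + N(0, noise_sd)` with constant reference
#' levels from the config. Ground truth (reflectance and fields) is kept
#' on the scene.
#'
#' @param config a `generator_config`.
#' @param record one-row data frame from [make_sample_table()] (or a list
#'   with `sample_id` and `scene_seed`).
#' @param fields named list of `concentration_field`s, one per endmember.
#' @param endmembers named list from [make_endmembers()].
#' @return An object of class `synthetic_scene` with `raw_cube`,
#'   `dark_frame`, `white_frame`, `true_reflectance`, `fields`, `record`.
#' @export
assemble_scene <- function(config, record, fields, endmembers) {
  stopifnot(inherits(config, "generator_config"))
  if (!all(names(endmembers) %in% names(fields)))
    stopf("fields must cover all endmembers: missing %s",
          paste(setdiff(names(endmembers), names(fields)), collapse = ", "))
  if (config$white_level <= config$dark_level)
    stopf("white reference must exceed dark reference everywhere")
  nr <- config$n_rows; nc <- config$n_cols; nb <- config$n_bands
  grid <- make_wavelength_grid(config)
  K <- length(endmembers)
  C <- matrix(0, nr * nc, K)
  E <- matrix(0, K, nb)
  for (k in seq_len(K)) {
    nm <- names(endmembers)[k]
    stopifnot(all(dim(fields[[nm]]$values) == c(nr, nc)))
    C[, k] <- as.vector(fields[[nm]]$values)
    E[k, ] <- endmembers[[nm]]$absorptivity
  }
  A <- C %*% E
  R <- exp(-A)                      # in (0, 1] since A >= 0
  dark <- rep(config$dark_level, nb)
  white <- rep(config$white_level, nb)
  raw <- sweep(R, 2L, white - dark, `*`)
  raw <- sweep(raw, 2L, dark, `+`)
  if (config$noise_sd > 0)
    raw <- raw + with_seed(record$scene_seed,
                           matrix(rnorm(length(raw), 0, config$noise_sd),
                                  nrow(raw)))
  structure(list(
    raw_cube = hypercube(array(raw, c(nr, nc, nb)), grid, kind = "raw"),
    dark_frame = reference_frame(dark, "black"),
    white_frame = reference_frame(white, "white"),
    true_reflectance = hypercube(array(R, c(nr, nc, nb)), grid,
                                 kind = "reflectance"),
    fields = fields, record = record),
    class = "synthetic_scene")
}

#' Generate the scene for one sample record
#'
#' Reconstructs the analyte concentration fields implied by the record's
#' labels and heterogeneity values (deterministically from its
#' `scene_seed`) and assembles the cube.
#'
#' @param config a `generator_config`.
#' @param record one row of [make_sample_table()] output.
#' @param endmembers optional endmember list (built from the config's grid
#'   if omitted).
#' @return A `synthetic_scene`.
#' @export
generate_scene <- function(config, record, endmembers = NULL) {
  if (is.null(endmembers))
    endmembers <- make_endmembers(make_wavelength_grid(config))
  labs <- list(mc = record$mc, rs = record$rs_mg_per_g,
               chewiness = record$chewiness_N)
  conc <- label_to_concentration(labs)
  het <- c(water = record$het_mc, starch_sugar = record$het_rs,
           fiber = record$het_chewiness, fat = 0.05)
  shape <- c(config$n_rows, config$n_cols)
  fields <- lapply(stats::setNames(names(conc), names(conc)), function(nm)
    make_field(shape, conc[[nm]], het[[nm]], config$field_smoothness,
               seed = derive_seed(record$scene_seed, nm)))
  assemble_scene(config, record, fields, endmembers)
}

#' Mean ROI spectra for every sample of a table
#'
#' For each record: generate the scene, apply the black/white correction,
#' cut the ROI, and average to one spectrum. This is the bridge from the
#' generator to the chemometric models.
#'
#' @param config a `generator_config`.
#' @param table output of [make_sample_table()].
#' @param roi an `roi_selection` (default: centered half-scene window).
#' @return Matrix `nrow(table) x n_bands` of mean ROI reflectance spectra,
#'   with the wavelength grid in attribute `"wavelengths"`.
#' @export
dataset_spectra <- function(config, table, roi = NULL) {
  if (is.null(roi))
    roi <- roi_selection(config$n_rows %/% 2L, config$n_cols %/% 2L)
  endm <- make_endmembers(make_wavelength_grid(config))
  X <- matrix(0, nrow(table), config$n_bands)
  for (i in seq_len(nrow(table))) {
    sc <- generate_scene(config, table[i, ], endm)
    R <- calibrate_reflectance(sc$raw_cube, sc$dark_frame, sc$white_frame)
    X[i, ] <- mean_spectrum(extract_roi(R, roi))
  }
  attr(X, "wavelengths") <- make_wavelength_grid(config)
  X
}

#' Write a scene to disk (ENVI cubes + CSV record)
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param interleave ENVI interleave for the cubes.
#' @return The directory, invisibly.
#' @export
write_scene <- function(scene, dir, interleave = "bsq") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_envi(scene$raw_cube, file.path(dir, "raw"), interleave = interleave)
  nb <- length(scene$raw_cube$wavelengths)
  d <- dim(scene$raw_cube$data)
  to_cube <- function(v) hypercube(
    aperm(array(v, c(nb, d[1], d[2])), c(2, 3, 1)),
    scene$raw_cube$wavelengths, kind = "raw")
  write_envi(to_cube(scene$dark_frame$data), file.path(dir, "dark"),
             interleave = interleave)
  write_envi(to_cube(scene$white_frame$data), file.path(dir, "white"),
             interleave = interleave)
  rec <- scene$record
  write.csv(rec[, c("sample_id", "bread_type", "chew_time_s", "panelist",
                    "replicate", "mc", "rs_mg_per_g", "chewiness_N")],
            file.path(dir, "record.csv"), row.names = FALSE)
  invisible(dir)
}
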