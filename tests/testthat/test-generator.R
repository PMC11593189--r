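test_that("wavelength grid is uniform with exact endpoints", {
  cfg <- generator_config(n_bands = 512L)
  g <- make_wavelength_grid(cfg)
  expect_length(g, 512L)
  expect_equal(g[1], 899)
  expect_equal(g[512], 1748)
  expect_close(diff(g), rep((1748 - 899) / 511, 511), 1e-10)
  g2 <- make_wavelength_grid(generator_config(n_bands = 8L,
                                              wavelength_start = 0,
                                              wavelength_end = 7))
  expect_equal(g2, 0:7)
})

test_that("endmember absorption bands sit at their NIR assignments", {
  grid <- make_wavelength_grid(generator_config(n_bands = 512L))
  em <- make_endmembers(grid)
  expect_setequal(names(em), c("water", "starch_sugar", "fat", "fiber"))
  for (e in em) expect_true(all(e$absorptivity >= 0))
  ## global water maximum within +-10 nm of the 1450 nm O-H first overtone
  expect_lt(abs(grid[which.max(em$water$absorptivity)] - 1450), 10)
  ## fat peaks at the 1200 nm C-H second overtone
  expect_lt(abs(grid[which.max(em$fat$absorptivity)] - 1200), 10)
  ## zero-amplitude band table gives a zero vector
  em0 <- make_endmembers(grid, bands = list(w = list(c(1000, 50, 0))))
  expect_equal(em0$w$absorptivity, numeric(length(grid)))
  ## out-of-grid center warns and contributes only a tail
  expect_warning(make_endmembers(grid, bands = list(x = list(c(100, 50, 1)))),
                 "outside grid")
})

test_that("concentration fields hit mean, CV and determinism contracts", {
  f <- make_field(c(128, 128), target_mean = 1, heterogeneity = 0.3,
                  smoothness = 4, seed = 7L)
  expect_lt(abs(mean(f$values) - 1), 1e-9)
  cv <- sd(f$values) / mean(f$values)
  expect_lt(abs(cv - 0.3), 0.045)     # within 15% of requested
  expect_true(all(f$values >= 0))
  f2 <- make_field(c(128, 128), 1, 0.3, smoothness = 4, seed = 7L)
  expect_identical(f$values, f2$values)
  f3 <- make_field(c(128, 128), 1, 0.3, smoothness = 4, seed = 8L)
  expect_false(identical(f$values, f3$values))
  ## zero heterogeneity is a constant field
  f0 <- make_field(c(16, 16), 2.5, 0, seed = 1L)
  expect_equal(f0$values, matrix(2.5, 16, 16))
  ## absurd heterogeneity clips too much mass
  expect_error(make_field(c(64, 64), 1, 50, smoothness = 4, seed = 1L),
               "clips")
})

test_that("assembled scenes invert exactly under black/white correction", {
  cfg <- tiny_config()
  tab <- make_sample_table(cfg)
  sc <- generate_scene(cfg, tab[1, ])
  R <- calibrate_reflectance(sc$raw_cube, sc$dark_frame, sc$white_frame)
  expect_close(R$data, sc$true_reflectance$data, 1e-12)
  ## zero concentrations -> R = 1 everywhere
  grid <- make_wavelength_grid(cfg)
  em <- make_endmembers(grid)
  zf <- lapply(em, function(e)
    structure(list(values = matrix(1e-12, 32, 32), target_mean = 1e-12,
                   heterogeneity = 0), class = "concentration_field"))
  sc0 <- assemble_scene(cfg, tab[1, ], zf, em)
  expect_close(sc0$true_reflectance$data, 1, 1e-9)
})

test_that("doubling the water field doubles its absorbance band", {
  cfg <- tiny_config()
  tab <- make_sample_table(cfg)
  sc <- generate_scene(cfg, tab[1, ])
  grid <- sc$raw_cube$wavelengths
  b1450 <- which.min(abs(grid - 1450))
  f2 <- sc$fields
  f2$water$values <- 2 * f2$water$values
  sc2 <- assemble_scene(cfg, tab[1, ], f2, make_endmembers(grid))
  A1 <- -log(sc$true_reflectance$data)
  A2 <- -log(sc2$true_reflectance$data)
  em <- make_endmembers(grid)
  water_part <- outer(as.vector(sc$fields$water$values),
                      em$water$absorptivity)
  delta <- matrix(A2[, , b1450] - A1[, , b1450], 32 * 32)
  expect_close(delta, matrix(water_part[, b1450], 32 * 32), 1e-10)
})

test_that("sample table follows the oral-processing trajectories", {
  cfg <- tiny_config(n_panelists = 3L, n_replicates = 2L)
  tab <- make_sample_table(cfg)
  expect_equal(nrow(tab), 2 * 4 * 3 * 2)
  ## fiber-rich bread is chewier at every matched time point (noise off)
  for (t in c(0, 6, 12, 18)) {
    b0 <- tab$chewiness_N[tab$bread_type == "B0" & tab$chew_time_s == t][1]
    b50 <- tab$chewiness_N[tab$bread_type == "B50" & tab$chew_time_s == t][1]
    expect_gt(b50, b0)
  }
  ## noise off: strictly monotone trajectories per panelist and bread
  for (b in c("B0", "B50")) for (p in 1:3) {
    sub <- tab[tab$bread_type == b & tab$panelist == p &
                 tab$replicate == 1L, ]
    sub <- sub[order(sub$chew_time_s), ]
    expect_true(all(diff(sub$mc) > 0))
    expect_true(all(diff(sub$rs_mg_per_g) > 0))
    expect_true(all(diff(sub$chewiness_N) < 0))
  }
  ## anchored endpoints (fractions / mg/g / N)
  expect_equal(tab$mc[tab$bread_type == "B0" & tab$chew_time_s == 0][1],
               0.4228, tolerance = 1e-12)
  expect_equal(tab$mc[tab$bread_type == "B0" & tab$chew_time_s == 18][1],
               0.5510, tolerance = 1e-12)
  expect_equal(tab$mc[tab$bread_type == "B50" & tab$chew_time_s == 18][1],
               0.4724, tolerance = 1e-12)
  ## determinism
  expect_identical(tab, make_sample_table(tiny_config(n_panelists = 3L,
                                                      n_replicates = 2L)))
})

test_that("per-cell Monte-Carlo mean of noisy labels matches the schedule", {
  ## 200 independent single-record draws of the same design cell
  set.seed(123)
  cell <- replicate(200, {
    cfg <- generator_config(n_rows = 8L, n_cols = 8L, n_bands = 8L,
                            n_panelists = 1L, n_replicates = 1L,
                            chew_times = 6, bread_types = c(B0 = 0),
                            label_cv = 0.05, seed = sample.int(1e6, 1))
    make_sample_table(cfg)$mc
  })
  sched <- make_sample_table(tiny_config(chew_times = 6,
                                         bread_types = c(B0 = 0)))$mc[1]
  se <- sd(cell) / sqrt(length(cell))
  expect_lt(abs(mean(cell) - sched), 3 * se + 1e-12)
})

test_that("label consistency: stored labels equal field means through the map", {
  cfg <- tiny_config()
  tab <- make_sample_table(cfg)
  sc <- generate_scene(cfg, tab[4, ])
  expect_lt(abs(mean(sc$fields$water$values) - tab$mc[4]), 1e-9)
  expect_lt(abs(mean(sc$fields$starch_sugar$values) -
                  tab$rs_mg_per_g[4] / 100), 1e-9)
  expect_lt(abs(mean(sc$fields$fiber$values) -
                  tab$chewiness_N[4] / 100), 1e-9)
})

test_that("scene generation is deterministic and seed-sensitive", {
  cfg <- tiny_config(noise_sd = 0.01)
  tab <- make_sample_table(cfg)
  s1 <- generate_scene(cfg, tab[2, ])
  s2 <- generate_scene(cfg, tab[2, ])
  expect_identical(s1$raw_cube$data, s2$raw_cube$data)
  s3 <- generate_scene(cfg, tab[3, ])
  expect_false(identical(s1$raw_cube$data, s3$raw_cube$data))
})

test_that("config invariants are enforced", {
  expect_error(generator_config(n_bands = 4L), "n_bands")
  expect_error(generator_config(wavelength_start = 2000), "wavelength_start")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(generator_config(n_panelists = 0L), "counts")
  expect_error(generator_config(bread_types = c(2, 3)), "bread_types")
})
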