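pipeline_defaults <- function() {
  list(
    generator = list(),          # generator_config() overrides
    roi = list(height = NULL, width = NULL),   # NULL = centered half scene
    methods = c("SG", "GF", "N"),
    models = c("PLSR", "PCR"),
    split = list(method = "kennard_stone", cal_fraction = 0.75),
    max_k = 15L, folds = 10L,
    texture = list(levels = 64L, distance = 1L),
    render_maps = TRUE,
    seed = 1L
  )
}

#' Validate and default-fill a pipeline configuration
#'
#' Accepts a JSON file path or a nested list mirroring the config schema
#' (`generator`, `roi`, `methods`, `models`, `split`, `max_k`, `folds`,
#' `texture`, `render_maps`, `seed`). Unknown keys are errors, never
#' silently ignored; cross-field constraints (ROI inside the scene, at
#' least one method and model) are checked here, before any compute.
#'
#' @param config path to a JSON config, or a (possibly partial) list.
#' @return An object of class `pipeline_config`: the fully defaulted list
#'   plus a `generator_config` in `$generator`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(defs, config)
  gen_args <- cfg$generator
  if (is.data.frame(gen_args)) gen_args <- as.list(gen_args)
  if (!is.null(gen_args$bread_types)) gen_args$bread_types <- unlist(gen_args$bread_types)
  unknown_g <- setdiff(names(gen_args), names(formals(generator_config)))
  if (length(unknown_g))
    stopf("unknown generator key(s): %s", paste(unknown_g, collapse = ", "))
  cfg$generator <- do.call(generator_config, gen_args)
  if (length(cfg$methods) < 1L || length(cfg$models) < 1L)
    stopf("need at least one preprocessing method and one model")
  if (!all(cfg$methods %in% c("SG", "GF", "N", "none")))
    stopf("methods must be among SG, GF, N, none")
  if (!all(cfg$models %in% c("PLSR", "PCR")))
    stopf("models must be among PLSR, PCR")
  g <- cfg$generator
  if (is.null(cfg$roi$height)) cfg$roi$height <- g$n_rows %/% 2L
  if (is.null(cfg$roi$width)) cfg$roi$width <- g$n_cols %/% 2L
  if (cfg$roi$height > g$n_rows || cfg$roi$width > g$n_cols)
    stopf("ROI %dx%d exceeds scene %dx%d", cfg$roi$height, cfg$roi$width,
          g$n_rows, g$n_cols)
  cfg$roi_selection <- roi_selection(cfg$roi$height, cfg$roi$width)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes generate -> calibrate -> ROI -> preprocess -> fit/compare ->
#' map -> texture -> correlate on the synthetic experiment described by
#' the config, writing a comparison table, per-sample GLCM contrast
#' columns, pseudo-color maps for one representative bolus per bread x
#' chew time, a Spearman correlation matrix, and a machine-readable JSON
#' report. Two runs with the same config produce identical report hashes.
#'
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param outdir output directory.
#' @return The run report (list), invisibly; also written to
#'   `report.json` in `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  g <- cfg$generator

  table <- make_sample_table(g)
  X <- dataset_spectra(g, table, cfg$roi_selection)

  methods <- lapply(cfg$methods, function(m) preprocess_spec(m))
  Y <- data.frame(mc = table$mc, rs = table$rs_mg_per_g,
                  chewiness = table$chewiness_N)
  comp <- model_comparison_table(
    X, Y, methods = methods, models = cfg$models,
    cal_fraction = cfg$split$cal_fraction,
    split_method = cfg$split$method,
    max_k = cfg$max_k, folds = cfg$folds,
    seed = derive_seed(cfg$seed, "model"))
  write.csv(comp, file.path(outdir, "model_comparison.csv"),
            row.names = FALSE)

  ## refit the best pretreatment x model per analyte on its calibration set
  best_models <- list()
  for (a in names(Y)) {
    row <- comp[comp$analyte == a & comp$best, ][1, ]
    spec <- preprocess_spec(row$method)
    Xp <- apply_chain(X, spec)
    sp <- split_calibration_prediction(Xp, method = cfg$split$method,
                                       cal_fraction = cfg$split$cal_fraction,
                                       seed = derive_seed(cfg$seed, "model"))
    fit_fun <- if (row$model == "PLSR") fit_plsr else fit_pcr
    best_models[[a]] <- fit_fun(Xp[sp$cal, , drop = FALSE], Y[[a]][sp$cal],
                                row$n_components, preprocess = spec)
  }

  ## pixel-wise maps: contrast for every sample, PNGs for representatives
  endm <- make_endmembers(make_wavelength_grid(g))
  contrast_cols <- matrix(NA_real_, nrow(table), length(Y))
  colnames(contrast_cols) <- paste0("contrast_", names(Y))
  rep_mask <- table$panelist == 1L & table$replicate == 1L
  map_dir <- file.path(outdir, "maps")
  if (isTRUE(cfg$render_maps)) dir.create(map_dir, showWarnings = FALSE)
  all_maps <- lapply(stats::setNames(names(Y), names(Y)),
                     function(a) vector("list", nrow(table)))
  for (i in seq_len(nrow(table))) {
    sc <- generate_scene(g, table[i, ], endm)
    R <- calibrate_reflectance(sc$raw_cube, sc$dark_frame, sc$white_frame)
    roi_cube <- extract_roi(R, cfg$roi_selection)
    for (a in names(Y))
      all_maps[[a]][[i]] <- predict_pixelwise(roi_cube, best_models[[a]],
                                              analyte = a)
  }
  ## uniformity contrast on a per-analyte shared quantization range, so
  ## the statistic reflects absolute spatial spread (one color bar per
  ## indicator), not each map's own min-max
  for (a in names(Y)) {
    rng <- shared_scale(all_maps[[a]])
    contrast_cols[, paste0("contrast_", a)] <- vapply(
      all_maps[[a]], map_contrast, numeric(1),
      levels = cfg$texture$levels, distance = cfg$texture$distance,
      range = rng)
    if (isTRUE(cfg$render_maps)) {
      for (i in which(rep_mask)) {
        m <- all_maps[[a]][[i]]
        m$display_range <- rng
        render_pseudocolor(m, file.path(map_dir,
                                        sprintf("%s_%s.png", a,
                                                table$sample_id[i])))
      }
    }
  }
  table <- cbind(table, as.data.frame(contrast_cols))
  write.csv(table, file.path(outdir, "sample_table.csv"), row.names = FALSE)

  corr_df <- data.frame(mc = table$mc, rs = table$rs_mg_per_g,
                        chewiness = table$chewiness_N,
                        contrast_mc = table$contrast_mc,
                        contrast_rs = table$contrast_rs,
                        contrast_chewiness = table$contrast_chewiness)
  corr <- spearman_matrix(corr_df)
  write_correlation_csv(corr, file.path(outdir, "correlation"))

  cfg_echo <- config_echo(cfg)
  report <- list(
    config = cfg_echo,
    config_hash = hash_object(cfg_echo),
    n_samples = nrow(table),
    comparison = comp,
    best = comp[comp$best, c("analyte", "method", "model", "n_components",
                             "rp2", "rmsep")],
    correlation_rho = as.data.frame(corr$rho),
    correlation_p = as.data.frame(corr$p),
    seed = cfg$seed)
  report$report_hash <- hash_object(report)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

## Serializable echo of the effective configuration.
config_echo <- function(cfg) {
  g <- cfg$generator
  list(generator = unclass(g),
       roi = cfg$roi, methods = cfg$methods, models = cfg$models,
       split = cfg$split, max_k = cfg$max_k, folds = cfg$folds,
       texture = cfg$texture, render_maps = cfg$render_maps,
       seed = cfg$seed)
}

## md5 of the canonical JSON serialization.
hash_object <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Command-line entry point
#'
#' Subcommands: `generate` (sample table + optional ENVI scenes),
#' `validate` (config check), `run-all` (full pipeline). Universal flags:
#' `--config <json>`, `--outdir <dir>`, `--seed <int>`; `generate` also
#' takes `--scenes <n>` (number of scene cubes to write, default 0).
#' An executable wrapper lives in `inst/cli/bolushsi`.
#'
#' @param args character vector of CLI arguments (default: the process
#'   command line).
#' @return Exit status 0, invisibly; errors abort with a message.
#' @export
bolushsi_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L)
    stopf("usage: bolushsi <generate|validate|run-all> [--config F] [--outdir D] [--seed N] [--scenes N]")
  cmd <- args[1L]
  opts <- parse_cli_flags(args[-1L])
  cfg_in <- if (!is.null(opts$config)) opts$config else list()
  cfg <- validate_config(cfg_in)
  if (!is.null(opts$seed)) {
    cfg$seed <- as.integer(opts$seed)
    gen <- unclass(cfg$generator)
    gen$seed <- cfg$seed
    cfg$generator <- do.call(generator_config,
                             gen[names(formals(generator_config))])
  }
  outdir <- opts$outdir %||% "bolushsi_out"
  switch(cmd,
    validate = {
      message("config OK")
      message(jsonlite::toJSON(config_echo(cfg), auto_unbox = TRUE,
                               pretty = TRUE))
    },
    generate = {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      tab <- make_sample_table(cfg$generator)
      write.csv(tab[, c("sample_id", "bread_type", "chew_time_s",
                        "panelist", "replicate", "mc", "rs_mg_per_g",
                        "chewiness_N")],
                file.path(outdir, "sample_table.csv"), row.names = FALSE)
      n_scenes <- as.integer(opts$scenes %||% 0L)
      for (i in seq_len(min(n_scenes, nrow(tab)))) {
        sc <- generate_scene(cfg$generator, tab[i, ])
        write_scene(sc, file.path(outdir, tab$sample_id[i]))
      }
      message(sprintf("wrote %d records (%d scene cubes) to %s",
                      nrow(tab), min(n_scenes, nrow(tab)), outdir))
    },
    `run-all` = {
      rep <- run_pipeline(cfg, outdir)
      message(sprintf("pipeline done: %d samples, report %s",
                      rep$n_samples, file.path(outdir, "report.json")))
    },
    stopf("unknown subcommand `%s`", cmd))
  invisible(0L)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stopf("unexpected argument `%s`", args[i])
    key <- substring(args[i], 3L)
    if (i == length(args)) stopf("flag --%s needs a value", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  known <- c("config", "outdir", "seed", "scenes")
  bad <- setdiff(names(opts), known)
  if (length(bad)) stopf("unknown flag(s): %s", paste(bad, collapse = ", "))
  opts
}
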