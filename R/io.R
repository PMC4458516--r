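# float TIFF pages are stored scaled into [0,1]; the fixed scale is recorded
# in the manifest and undone on read
.tiff_scale <- 65535

#' Write a synthetic scene to a run directory
#'
#' Writes the channels as one multi-page float TIFF (one page per channel,
#' phase first), the ground-truth cell and bleb tables as tab-separated
#' text, the generator parameters as YAML, and a machine-readable JSON
#' manifest (file list, channel names, parameter hash, package version).
#'
#' @param scene A `rod_scene` from [render_scene()].
#' @param dir Output directory; must not exist unless `overwrite = TRUE`.
#' @param overwrite Allow writing into an existing directory.
#' @return The directory path, invisibly.
#' @export
write_scene <- function(scene, dir, overwrite = FALSE) {
  stopifnot(inherits(scene, "rod_scene"))
  if (dir.exists(dir) && !overwrite) {
    stop(sprintf("directory exists and overwrite = FALSE: %s", dir), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # shift each page to be nonnegative (noise can dip below zero), then scale
  # into [0, 1]; offsets and scale are recorded in the manifest
  offsets <- vapply(scene$images, function(m) min(0, floor(min(m))), 0)
  pages <- Map(function(m, o) (m - o) / .tiff_scale, scene$images, offsets)
  tiff::writeTIFF(pages, file.path(dir, "images.tif"), bits.per.sample = 32L)
  readr::write_tsv(scene$cells, file.path(dir, "cells.tsv"))
  readr::write_tsv(scene$blebs, file.path(dir, "blebs.tsv"))
  params <- list(
    pixel_size = scene$pixel_size,
    channels = names(scene$images),
    growth = unclass(scene$growth),
    defects = unclass(scene$defects)
  )
  yaml::write_yaml(params, file.path(dir, "params.yml"))
  manifest <- list(
    kind = "rod_scene",
    files = c("images.tif", "cells.tsv", "blebs.tsv", "params.yml"),
    channels = names(scene$images),
    intensity_scale = .tiff_scale,
    intensity_offsets = unname(offsets),
    n_cells = nrow(scene$cells),
    n_blebs = nrow(scene$blebs),
    param_hash = rlang::hash(params),
    package_version = as.character(utils::packageVersion("rodmapr"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a scene directory back
#'
#' @param dir A directory written by [write_scene()].
#' @return A list with `images` (named list of matrices), `cells`, `blebs`,
#'   `pixel_size`.
#' @export
read_scene <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) {
    stop(sprintf("no scene manifest found at %s", mf_path), call. = FALSE)
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "images.tif"), all = TRUE)
  offsets <- mf$intensity_offsets %||% rep(0, length(pages))
  images <- Map(function(p, o) p * mf$intensity_scale + o, pages, offsets)
  names(images) <- mf$channels
  params <- yaml::read_yaml(file.path(dir, "params.yml"))
  list(
    images = images,
    cells = readr::read_tsv(file.path(dir, "cells.tsv"), show_col_types = FALSE),
    blebs = readr::read_tsv(file.path(dir, "blebs.tsv"), show_col_types = FALSE),
    pixel_size = params$pixel_size
  )
}

#' Write the flat columns of a cell table
#'
#' Writes per-cell scalars (id, area, centroid, length, aspect) as
#' tab-separated text; list-column geometry is omitted.
#'
#' @param cells A `cell_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  flat <- cells[, !vapply(cells, is.list, TRUE)]
  readr::write_tsv(tibble::as_tibble(flat), path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Validated bundle of every tunable parameter of the pipeline, with the
#' defaults used throughout: pixel size 0.064 µm, 50 axial bins/columns, 10
#' age classes, 0.8 µm mid-cell window and flank, leakage quantile 0.98,
#' bleb brightness quantile 0.997, bleb area cutoff 4 µm², proximity cutoff
#' 0.3 µm.
#'
#' @param pixel_size Pixel size, micrometres.
#' @param n_bins Axial bins per cell.
#' @param n_cols Profile-map columns.
#' @param n_classes Age classes.
#' @param ring_window Mid-cell window, micrometres.
#' @param flank Baseline flank width, micrometres.
#' @param leakage_quantile Leakage calibration quantile.
#' @param bleb_quantile Bleb brightness calibration quantile.
#' @param bleb_area_max Maximum bleb area, square micrometres.
#' @param proximity_max Maximum bleb-to-cell distance, micrometres.
#' @param seed Integer seed for the simulation stage.
#' @param n_cells Number of cells in the simulated scene.
#' @param reference_n Size of the leaky reference population used to
#'   calibrate the leakage threshold.
#' @param growth,channels,defects Lists of arguments for [growth_model()],
#'   a list of [channel_model()] argument lists, and [defect_model()].
#' @param phase List: `background`, `depth`, `noise_sd` of the rendered
#'   phase channel.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(pixel_size = 0.064, n_bins = 50, n_cols = 50,
                       n_classes = 10, ring_window = 0.8, flank = 0.8,
                       leakage_quantile = 0.98, bleb_quantile = 0.997,
                       bleb_area_max = 4, proximity_max = 0.3,
                       seed = 1, n_cells = 150, reference_n = 100,
                       growth = list(), channels = list(list(kind = "contour")),
                       defects = list(), phase = list()) {
  cfg <- list(
    pixel_size = pixel_size, n_bins = n_bins, n_cols = n_cols,
    n_classes = n_classes, ring_window = ring_window, flank = flank,
    leakage_quantile = leakage_quantile, bleb_quantile = bleb_quantile,
    bleb_area_max = bleb_area_max, proximity_max = proximity_max,
    seed = seed, n_cells = n_cells, reference_n = reference_n,
    growth = growth, channels = channels, defects = defects,
    phase = utils::modifyList(list(background = 1000, depth = 0.7, noise_sd = 0),
                              phase)
  )
  for (nmq in c("pixel_size", "ring_window", "flank", "bleb_area_max",
                "proximity_max")) {
    if (!is.numeric(cfg[[nmq]]) || cfg[[nmq]] <= 0) {
      stop(sprintf("`%s` must be a positive number (got %s)", nmq,
                   format(cfg[[nmq]])), call. = FALSE)
    }
  }
  for (nmq in c("leakage_quantile", "bleb_quantile")) {
    if (cfg[[nmq]] <= 0 || cfg[[nmq]] >= 1) {
      stop(sprintf("`%s` must be inside (0, 1)", nmq), call. = FALSE)
    }
  }
  stopifnot(cfg$n_bins >= 2, cfg$n_cols >= 2, cfg$n_classes >= 2,
            cfg$n_cells >= 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#'
#' Reads a YAML file of [run_config()] fields and validates it before any
#' computation runs.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

.cfg_models <- function(cfg) {
  list(
    growth = do.call(growth_model, cfg$growth),
    channels = lapply(cfg$channels, function(a) do.call(channel_model, a)),
    defects = do.call(defect_model, cfg$defects)
  )
}

.log_line <- function(log_path, ...) {
  cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
}

#' Run the full analysis pipeline on one synthetic field
#'
#' Chains the stages: simulate (render a main scene plus a fully leaky
#' reference scene), segment, profile extraction, profile map and mid-cell
#' statistics, and defect classification. All outputs are plain delimited
#' text, YAML, JSON or TIFF under one run directory; every calibrated
#' threshold and flagged result count is logged to `run.log`.
#'
#' @param config A `run_config`.
#' @param out_dir Run directory (one per invocation); must not exist unless
#'   `overwrite = TRUE`.
#' @param stages Character vector of stages to run, subset of
#'   `c("simulate", "segment", "profile", "map", "defects")`, or `"all"`.
#' @param overwrite Allow reuse of an existing run directory.
#' @return A list of the principal results, invisibly: `scene`, `cells`,
#'   `profiles`, `table`, `map`, `stats`, `summary`, `leakage`, `blebs`.
#' @export
run_pipeline <- function(config, out_dir, stages = "all", overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "segment", "profile", "map", "defects")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  if (dir.exists(out_dir) && !overwrite) {
    stop(sprintf("run directory exists and overwrite = FALSE: %s", out_dir),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("rodmapr run %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = log_path)
  models <- .cfg_models(config)
  res <- list()

  scene_dir <- file.path(out_dir, "scene")
  ref_dir <- file.path(out_dir, "reference")
  if ("simulate" %in% stages) {
    pop <- sample_population(config$n_cells, models$growth, seed = config$seed)
    res$scene <- render_scene(pop, models$channels,
                              pixel_size = config$pixel_size,
                              defects = models$defects,
                              phase_background = config$phase$background,
                              phase_depth = config$phase$depth,
                              phase_noise_sd = config$phase$noise_sd,
                              seed = config$seed + 1L)
    write_scene(res$scene, scene_dir, overwrite = overwrite)
    # fully leaky reference population for leakage calibration
    ref_defects <- models$defects
    ref_defects$leak_fraction <- 1
    ref_defects$bleb_rate <- 0
    ref_pop <- sample_population(config$reference_n, models$growth,
                                 seed = config$seed + 2L)
    res$reference <- render_scene(ref_pop, models$channels,
                                  pixel_size = config$pixel_size,
                                  defects = ref_defects,
                                  phase_background = config$phase$background,
                                  phase_depth = config$phase$depth,
                                  phase_noise_sd = config$phase$noise_sd,
                                  seed = config$seed + 3L)
    write_scene(res$reference, ref_dir, overwrite = overwrite)
    .log_line(log_path, "simulate: %d cells, %d blebs (seed %d)",
              nrow(res$scene$cells), nrow(res$scene$blebs), config$seed)
  } else if (dir.exists(scene_dir)) {
    sc <- read_scene(scene_dir)
    res$scene <- list(images = sc$images, cells = sc$cells, blebs = sc$blebs,
                      pixel_size = sc$pixel_size)
  } else {
    stop(sprintf("no scene available: %s missing and 'simulate' not requested",
                 scene_dir), call. = FALSE)
  }
  images <- res$scene$images
  fluor_names <- setdiff(names(images), "phase")

  if ("segment" %in% stages) {
    res$cells <- segment_cells(images$phase, pixel_size = config$pixel_size,
                               n_bins = config$n_bins)
    write_cell_table(res$cells, file.path(out_dir, "cells.tsv"))
    .log_line(log_path, "segment: %d cells (%d without valid axis)",
              nrow(res$cells), sum(!res$cells$shape_ok))
  }

  if ("profile" %in% stages && !is.null(res$cells)) {
    res$profiles <- lapply(setNames(fluor_names, fluor_names), function(nm)
      axial_profiles(res$cells, images[[nm]], channel = nm))
    readr::write_tsv(dplyr::bind_rows(res$profiles),
                     file.path(out_dir, "profiles.tsv"))
    env <- fluor_names[vapply(models$channels, function(ch)
      ch$kind %in% c("contour", "periplasmic"), TRUE)]
    if (length(env) > 0) {
      res$traces <- contour_fluorescence(res$cells, images[[env[1]]],
                                         channel = env[1],
                                         spacing = config$pixel_size)
      readr::write_tsv(dplyr::select(res$traces, -"samples"),
                       file.path(out_dir, "contour_traces.tsv"))
    }
    .log_line(log_path, "profile: %d channels, background-subtracted", length(res$profiles))
  }

  if ("map" %in% stages && !is.null(res$profiles)) {
    usable <- res$cells[res$cells$shape_ok, ]
    res$table <- assign_ages(usable)
    main_ch <- fluor_names[1]
    res$map <- build_profile_map(res$profiles[[main_ch]], res$table,
                                 n_cols = config$n_cols)
    readr::write_tsv(tibble::as_tibble(res$map$map, .name_repair = "minimal"),
                     file.path(out_dir, "profile_map.tsv"), col_names = FALSE)
    readr::write_tsv(res$map$cells, file.path(out_dir, "profile_map_rows.tsv"))
    res$stats <- midcell_stats(res$profiles[[main_ch]], res$table,
                               window = config$ring_window, flank = config$flank)
    readr::write_tsv(tibble::as_tibble(res$stats), file.path(out_dir, "midcell_stats.tsv"))
    res$summary <- age_class_averages(res$profiles[[main_ch]], res$table,
                                      n_classes = config$n_classes,
                                      window = config$ring_window,
                                      flank = config$flank)
    readr::write_tsv(generics::tidy(res$summary),
                     file.path(out_dir, "age_classes.tsv"))
    init <- detect_initiation(res$summary)
    mom <- detect_moment(res$stats, n_classes = config$n_classes)
    res$timing <- tibble::tibble(initiation_age = init, moment_age = mom)
    readr::write_tsv(res$timing, file.path(out_dir, "timing.tsv"))
    .log_line(log_path,
              "map: %d cells mapped; initiation=%s moment=%s; %d cells with undefined FCplus",
              nrow(res$map$cells), format(init), format(mom),
              sum(!res$stats$fc_defined))
  }

  if ("defects" %in% stages && !is.null(res$cells)) {
    env <- fluor_names[vapply(models$channels, function(ch)
      ch$kind %in% c("contour", "periplasmic"), TRUE)]
    if (length(env) > 0 && !is.null(res$traces)) {
      if (dir.exists(ref_dir) || !is.null(res$reference)) {
        ref <- res$reference
        if (is.null(ref)) {
          rr <- read_scene(ref_dir)
          ref_cells <- segment_cells(rr$images$phase, pixel_size = config$pixel_size,
                                     n_bins = config$n_bins)
          ref_img <- rr$images[[env[1]]]
        } else {
          ref_cells <- segment_cells(ref$images$phase, pixel_size = config$pixel_size,
                                     n_bins = config$n_bins)
          ref_img <- ref$images[[env[1]]]
        }
        ref_traces <- contour_fluorescence(ref_cells, ref_img, channel = env[1],
                                           spacing = config$pixel_size)
        thr <- leakage_threshold(ref_traces, q = config$leakage_quantile)
        res$leakage <- classify_leakage(res$traces, thr)
        readr::write_tsv(tibble::as_tibble(res$leakage),
                         file.path(out_dir, "leakage_calls.tsv"))
        .log_line(log_path, "defects: leakage threshold %.4f (q=%.3f, n=%d reference cells)",
                  thr, config$leakage_quantile, attr(thr, "n"))
      }
      bthr <- brightness_reference(res$cells, images[[env[1]]],
                                   q = config$bleb_quantile)
      res$blebs <- detect_blebs(images[[env[1]]], res$cells, bthr,
                                area_max = config$bleb_area_max,
                                proximity_max = config$proximity_max,
                                pixel_size = config$pixel_size)
      readr::write_tsv(tibble::as_tibble(res$blebs),
                       file.path(out_dir, "bleb_calls.tsv"))
      res$defect_summary <- defect_summary(res$leakage, res$blebs)
      readr::write_tsv(res$defect_summary, file.path(out_dir, "defect_summary.tsv"))
      .log_line(log_path, "defects: brightness threshold %.4f (n=%d cells); %d blebs",
                bthr, attr(bthr, "n"), nrow(res$blebs))
    }
  }

  manifest <- list(
    kind = "rodmapr_run",
    stages = stages,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("rodmapr")),
    outputs = list.files(out_dir, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `inst/cli/rodmap.R` script:
#' `rodmap.R <subcommand> --config <yaml> --out <dir> [--overwrite]` with
#' subcommands `simulate`, `segment`, `profile`, `map`, `defects`, `all`.
#' Later stages reuse the artifacts earlier stages wrote into the run
#' directory.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly: 0 on success, 1 on run errors, 2 on
#'   usage errors.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: rodmap.R {simulate|segment|profile|map|defects|all} --config <yaml> --out <dir> [--overwrite]"
  subcommands <- c("simulate", "segment", "profile", "map", "defects", "all")
  if (length(args) < 1 || !(args[1] %in% subcommands)) {
    message(usage)
    return(invisible(2L))
  }
  sub <- args[1]
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
  }
  cfg_path <- opt("--config")
  out_dir <- opt("--out")
  overwrite <- "--overwrite" %in% args
  if (is.null(cfg_path) || is.null(out_dir)) {
    message(usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    cfg <- read_run_config(cfg_path)
    stages <- if (sub == "all") "all" else {
      # running a late stage alone implies its prerequisites are on disk;
      # segment/profile/map/defects re-run from the written scene
      switch(sub,
             simulate = "simulate",
             segment = "segment",
             profile = c("segment", "profile"),
             map = c("segment", "profile", "map"),
             defects = c("segment", "profile", "defects"))
    }
    run_pipeline(cfg, out_dir, stages = stages, overwrite = overwrite)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
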