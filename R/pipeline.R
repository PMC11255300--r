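# Configuration, table I/O and end-to-end orchestration:
# simulate -> track -> analyze -> report.

TABLE_SCHEMAS <- list(
  cells = c("cell_id", "lineage_id", "frame_index", "time", "centroid_x",
            "centroid_y", "orientation", "length", "width", "area",
            "parent_id", "old_pole_sign"),
  observations = c("obs_id", "cell_id", "lineage_id", "frame_index", "time",
                   "channel", "tag", "x", "y", "localization_sd"),
  truth = c("particle_id", "species", "locus_name", "cell_id", "lineage_id",
            "frame_index", "time", "tag", "x", "y", "state"),
  trajectories = c("obs_id", "cell_id", "lineage_id", "frame_index", "time",
                   "channel", "tag", "x", "y", "trajectory_id"),
  events = c("event_id", "cell_id", "lineage_id", "frame_index", "time",
             "area", "trajectory_ids"),
  landmarks = c("landmark_id", "x_ref", "y_ref", "x_mov", "y_mov")
)

#' Read / write the pipeline's delimited tables
#'
#' CSV round trips preserve full double precision. `read_tracks()` validates
#' the fixed column schema of each table kind and reports the offending
#' column (and first offending row for missing key values).
#'
#' @param path File path.
#' @param schema One of `r paste0('"', names(TABLE_SCHEMAS), '"', collapse = ", ")`,
#'   or `"generic"` for no validation.
#' @return A tibble.
#' @export
read_tracks <- function(path, schema = "generic") {
  if (!file.exists(path)) {
    abort(paste0("Missing table: ", path, " (run the upstream stage first)."))
  }
  # utils::read.csv parses doubles with strtod, so the write -> read round
  # trip is exact to the last bit (readr's shortest-round-trip writer pairs
  # with it)
  tbl <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (schema != "generic") {
    req <- TABLE_SCHEMAS[[schema]]
    if (is.null(req)) abort(paste0("Unknown schema `", schema, "`."))
    missing_cols <- setdiff(req, names(tbl))
    if (length(missing_cols)) {
      abort(paste0("Schema violation in ", basename(path), ": missing column(s) ",
                   paste(missing_cols, collapse = ", ")))
    }
    key <- intersect(c("cell_id", "frame_index"), req)
    for (k in key) {
      bad <- which(is.na(tbl[[k]]))
      if (length(bad)) {
        abort(paste0("Schema violation in ", basename(path), ": column `", k,
                     "` has a missing value at row ", bad[1], "."))
      }
    }
  }
  tbl
}

#' @rdname read_tracks
#' @param table Tibble to write.
#' @export
write_tracks <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' The full configuration of [run_pipeline()]: the generator section (see
#' [sim_config()]), the analysis parameters (linker gates, RMSD window,
#' binning, masking threshold, bootstrap size), and the seed.
#'
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    sim = unclass(sim_config()),
    analysis = list(
      max_disp = 0.5, max_gap = 2,
      min_lifetime = 5, exclusion_radius = 0.5, merge_frames = 1,
      rmsd_window = 20, lag_window = c(10, 20),
      doublet_gate = 0.3, pair_gate = 1.0,
      area_bin_width = 0.25, spatial_bin_size = 0.1,
      min_count_exclusive = 4, smoothing_window = 3, n_boot = 200,
      net_window = 15
    )
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' Plain-text structured (YAML) configuration. Unknown sections or keys are
#' rejected with the offending key named; the file round-trips losslessly.
#'
#' @param path Config file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  validate_pipeline_config(raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config` list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass_recursive(config), path, precision = 15)
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else x
}

validate_pipeline_config <- function(raw) {
  def <- default_config()
  bad <- setdiff(names(raw), names(def))
  if (length(bad)) abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
  cfg <- def
  if (!is.null(raw$seed)) cfg$seed <- raw$seed
  if (!is.null(raw$sim)) {
    cfg$sim <- unclass(do.call(sim_config, raw$sim))  # validates keys + values
  }
  if (!is.null(raw$analysis)) {
    bad_a <- setdiff(names(raw$analysis), names(def$analysis))
    if (length(bad_a)) {
      abort(paste0("Unknown config key(s) in `analysis`: ", paste(bad_a, collapse = ", ")))
    }
    cfg$analysis[names(raw$analysis)] <- raw$analysis
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Seeded end-to-end orchestration: `simulate` writes the synthetic tables,
#' `track` links foci and detects initiation events, `analyze` runs the
#' coordinate, RMSD, displacement and pairing analyses, `report` assembles
#' the summary. Later stages read the tables earlier stages wrote under
#' `outdir`, so stages can be re-run (or fed externally supplied tables)
#' independently; a missing upstream table raises a dependency error.
#' Identical config + seed give identical outputs.
#'
#' @param config A `pipeline_config` (see [default_config()]) or a path to a
#'   YAML config file.
#' @param outdir Output directory (created if needed).
#' @param stages Character subset of `simulate`, `track`, `analyze`,
#'   `report` (order is fixed internally).
#' @param seed Optional override of `config$seed`.
#'
#' @return Invisibly, the summary tibble (when `report` is among the
#'   stages), else `NULL`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempdir(),
                         stages = c("simulate", "track", "analyze", "report"),
                         seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  config <- validate_pipeline_config(unclass_recursive(config))
  if (!is.null(seed)) config$seed <- seed
  stages <- match.arg(stages, c("simulate", "track", "analyze", "report"),
                      several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  an <- config$analysis
  p <- function(...) file.path(outdir, ...)
  log_lines <- c(sprintf("replifoci pipeline, seed %s", config$seed),
                 sprintf("stages: %s", paste(stages, collapse = ", ")))

  if ("simulate" %in% stages) {
    sim_cfg <- do.call(sim_config, config$sim)
    ds <- simulate_dataset(sim_cfg, seed = config$seed)
    write_tracks(ds$cells, p("cells.csv"))
    write_tracks(ds$truth, p("truth.csv"))
    write_tracks(ds$observations, p("observations.csv"))
    write_tracks(ds$landmarks, p("landmarks.csv"))
    write_tracks(ds$events, p("events_truth.csv"))
    write_pipeline_config(config, p("config.yaml"))
    log_lines <- c(log_lines,
                   sprintf("simulate: %d lineages, %d cell-frames, %d observations",
                           sim_cfg$sim$n_lineages, nrow(ds$cells), nrow(ds$observations)))
  }

  if ("track" %in% stages) {
    obs <- read_tracks(p("observations.csv"), "observations")
    cells <- read_tracks(p("cells.csv"), "cells")
    linked <- link_foci(obs, max_disp = an$max_disp, max_gap = an$max_gap)
    events <- detect_initiation(linked[linked$channel == "replisome", ],
                                cells, min_lifetime = an$min_lifetime,
                                exclusion_radius = an$exclusion_radius,
                                merge_frames = an$merge_frames)
    write_tracks(linked, p("trajectories.csv"))
    write_tracks(events, p("events.csv"))
    log_lines <- c(log_lines,
                   sprintf("track: %d trajectories, %d initiation events",
                           length(unique(linked$trajectory_id)), nrow(events)))
  }

  summary_tbl <- NULL
  if (any(c("analyze", "report") %in% stages)) {
    cells <- read_tracks(p("cells.csv"), "cells")
    obs <- read_tracks(p("observations.csv"), "observations")
    linked <- read_tracks(p("trajectories.csv"), "trajectories")
    events <- read_tracks(p("events.csv"), "events")
    landmarks <- read_tracks(p("landmarks.csv"), "landmarks")

    transform <- fit_channel_transform(landmarks)
    obs_reg <- dplyr::bind_rows(
      obs[obs$channel == "replisome", ],
      apply_channel_transform(obs[obs$channel == "locus", ], transform)
    )
    area_bins <- default_area_bins(cells$area, an$area_bin_width)

    # initiation-aligned RMSD (replisome channel)
    aligned <- align_on_initiation(linked[linked$channel == "replisome", ],
                                   events, cells, window = an$rmsd_window)
    corrected <- subtract_net_drift(aligned)
    curve <- rmsd_curve(corrected)
    plateaus <- plateau_estimate(curve, an$lag_window)
    net <- net_movement_percent(aligned, window = an$net_window)

    # 1-s displacement statistics
    records <- compute_displacements(obs_reg, cells, max_link = an$doublet_gate)
    rec_loc <- records[records$channel == "locus", ]
    rec_rep <- records[records$channel == "replisome", ]
    prof_loc <- displacement_by_area(rec_loc, area_bins)
    prof_rep <- displacement_by_area(rec_rep, area_bins)
    minimum <- find_displacement_minimum(rec_loc, area_bins,
                                         smoothing_window = an$smoothing_window,
                                         n_boot = an$n_boot)
    smap <- spatial_displacement_map(rec_loc,
                                     min_count_exclusive = an$min_count_exclusive)

    # replisome-locus pairing
    firsts <- function(d) d[d$tag == "first", ]
    pairs <- match_foci(firsts(obs[obs$channel == "replisome", ]),
                        firsts(obs[obs$channel == "locus", ]),
                        transform = transform, max_distance = an$pair_gate,
                        cells = cells)
    dist_res <- distance_by_area(pairs, area_bins,
                                 smoothing_window = an$smoothing_window,
                                 n_boot = an$n_boot)

    if ("analyze" %in% stages) {
      write_tracks(as_tibble(curve), p("rmsd_curve.csv"))
      write_tracks(plateaus, p("rmsd_plateaus.csv"))
      write_tracks(net, p("net_movement.csv"))
      write_tracks(as_tibble(prof_loc), p("displacement_by_area_locus.csv"))
      write_tracks(as_tibble(prof_rep), p("displacement_by_area_replisome.csv"))
      write_tracks(minimum, p("displacement_minimum.csv"))
      write_tracks(as_tibble(smap), p("spatial_map.csv"))
      write_tracks(pairs, p("pairs.csv"))
      write_tracks(as_tibble(dist_res$profile), p("distance_by_area.csv"))
      write_tracks(dist_res$minimum, p("distance_minimum.csv"))
    }

    if ("report" %in% stages) {
      sim_cfg <- do.call(sim_config, config$sim)
      params <- replication_params(A_init = sim_cfg$initiation$A_init,
                                   T_d = sim_cfg$growth$T_d,
                                   C = sim_cfg$initiation$C)
      pred_area <- predicted_replication_area(sim_cfg$locus$alpha, params)
      summary_tbl <- tibble(
        quantity = c("initiation_area_um2", "rmsd_plateau_long_um",
                     "rmsd_plateau_short_um", "net_movement_pct_length",
                     "displacement_min_area_um2", "distance_min_area_um2",
                     "predicted_replication_area_um2"),
        value = c(mean(events$area), plateaus$plateau[1], plateaus$plateau[2],
                  net$pct_of_length, minimum$area_min,
                  dist_res$minimum$area_min, pred_area),
        uncertainty = c(sd(events$area) / sqrt(nrow(events)),
                        plateaus$sem[1], plateaus$sem[2], NA_real_,
                        (minimum$ci_upper - minimum$ci_lower) / 2,
                        (dist_res$minimum$ci_upper - dist_res$minimum$ci_lower) / 2,
                        NA_real_),
        n = c(nrow(events), plateaus$n_min[1], plateaus$n_min[2],
              net$n_trajectories, minimum$n_records,
              dist_res$minimum$n_records, NA_integer_)
      )
      write_tracks(summary_tbl, p("summary.csv"))
      log_lines <- c(log_lines, "report: summary.csv written")
    }
  }

  writeLines(log_lines, p("run.log"))
  invisible(summary_tbl)
}
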