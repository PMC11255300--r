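#' Project foci into the cell-internal coordinate system
#'
#' Joins detected foci to their cell-frame records and rotates/translates the
#' lab-frame positions into a coordinate system defined by the cell outline:
#' `long_offset` is the distance from mid-cell along the long axis, with the
#' positive direction toward the old pole (so the old pole "points up"), and
#' `short_offset` the perpendicular offset from the long axis. `rel_long` is
#' `long_offset / length`, in `[-0.5, 0.5]` for in-cell foci. Foci falling
#' outside the outline (localization noise) are kept as-is; clipping would
#' bias downstream SD estimates.
#'
#' @param foci Tibble with `cell_id`, `frame_index`, `x`, `y` (lab um).
#' @param cells Cell-frame tibble (see [simulate_lineage()]): `cell_id`,
#'   `frame_index`, `centroid_x`, `centroid_y`, `orientation`,
#'   `old_pole_sign`, `length`, `area`.
#'
#' @return The foci tibble with `long_offset`, `short_offset`, `rel_long`,
#'   `length`, `area` columns added. Foci whose `(cell_id, frame_index)` has
#'   no cell record raise an error.
#' @export
to_internal_coords <- function(foci, cells) {
  needed <- c("cell_id", "frame_index", "x", "y")
  if (!all(needed %in% names(foci))) {
    abort("`foci` must have columns cell_id, frame_index, x, y.")
  }
  geom <- cells %>%
    select("cell_id", "frame_index", "centroid_x", "centroid_y",
           "orientation", "old_pole_sign", "length", "area")
  out <- foci %>%
    left_join(geom, by = c("cell_id", "frame_index"))
  if (anyNA(out$centroid_x)) {
    abort("Some foci have no matching cell record for their (cell_id, frame_index).")
  }
  out %>%
    mutate(
      .ux = .data$old_pole_sign * cos(.data$orientation),
      .uy = .data$old_pole_sign * sin(.data$orientation),
      long_offset = (.data$x - .data$centroid_x) * .data$.ux +
        (.data$y - .data$centroid_y) * .data$.uy,
      short_offset = (.data$x - .data$centroid_x) * (-sin(.data$orientation)) +
        (.data$y - .data$centroid_y) * cos(.data$orientation),
      rel_long = .data$long_offset / .data$length
    ) %>%
    select(-".ux", -".uy", -"centroid_x", -"centroid_y", -"orientation",
           -"old_pole_sign")
}

# shared default binning: 0.1 um spatial bins, 0.25 um^2 area bins
default_spatial_bins <- function(positions, bin_size = 0.1) {
  r_long <- range(positions$long_offset)
  r_short <- range(positions$short_offset)
  list(
    long = seq(floor(r_long[1] / bin_size) * bin_size,
               ceiling(r_long[2] / bin_size) * bin_size + bin_size / 2, by = bin_size),
    short = seq(floor(r_short[1] / bin_size) * bin_size,
                ceiling(r_short[2] / bin_size) * bin_size + bin_size / 2, by = bin_size)
  )
}

default_area_bins <- function(areas, width = 0.25) {
  seq(floor(min(areas) / width) * width,
      ceiling(max(areas) / width) * width + width / 2, by = width)
}

check_bins <- function(edges, what) {
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    abort(paste0("`", what, "` must be strictly increasing bin edges."))
  }
  edges
}

bin_label <- function(x, edges) {
  # left-closed, right-open bins; values outside the edges get NA
  idx <- findInterval(x, edges, rightmost.closed = FALSE, left.open = FALSE)
  idx[x >= edges[length(edges)]] <- NA_integer_
  idx[idx == 0L] <- NA_integer_
  idx
}

bin_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Area-binned 2D location histograms
#'
#' Bins internal-coordinate focus positions into a fixed spatial grid, one
#' 2D histogram per cell-area bin, normalized to foci per cell per bin: each
#' count is divided by the number of cell-frame records whose area falls in
#' the area bin, so histograms from differently populated area bins are
#' comparable. All area bins share the same spatial bin size and positions.
#'
#' @param positions Output of [to_internal_coords()].
#' @param cells The cell-frame tibble used to count cells per area bin.
#' @param area_bins Area bin edges (um^2); default 0.25-wide bins spanning
#'   the data.
#' @param long_bins,short_bins Spatial bin edges (um); default 0.1-um bins
#'   spanning the data.
#'
#' @return A `location_histogram` object: tibble with `area_bin`,
#'   `area_mid`, `long_mid`, `short_mid`, `count`, `n_cells`, `value`
#'   (foci per cell per bin); bin edges stored as attributes. Empty area bins
#'   are reported with zero counts.
#' @export
build_location_histograms <- function(positions, cells, area_bins = NULL,
                                      long_bins = NULL, short_bins = NULL) {
  if (is.null(area_bins)) area_bins <- default_area_bins(cells$area)
  check_bins(area_bins, "area_bins")
  sp <- default_spatial_bins(positions)
  if (is.null(long_bins)) long_bins <- sp$long
  if (is.null(short_bins)) short_bins <- sp$short
  check_bins(long_bins, "long_bins"); check_bins(short_bins, "short_bins")

  n_cells <- cells %>%
    mutate(area_bin = bin_label(.data$area, .env$area_bins)) %>%
    filter(!is.na(.data$area_bin)) %>%
    group_by(.data$area_bin) %>%
    summarise(n_cells = dplyr::n_distinct(.data$cell_id, .data$frame_index),
              .groups = "drop")

  counts <- positions %>%
    mutate(
      area_bin = bin_label(.data$area, .env$area_bins),
      long_bin = bin_label(.data$long_offset, .env$long_bins),
      short_bin = bin_label(.data$short_offset, .env$short_bins)
    ) %>%
    filter(!is.na(.data$area_bin), !is.na(.data$long_bin), !is.na(.data$short_bin)) %>%
    dplyr::count(.data$area_bin, .data$long_bin, .data$short_bin, name = "count")

  grid <- tidyr::expand_grid(
    area_bin = seq_len(length(area_bins) - 1),
    long_bin = seq_len(length(long_bins) - 1),
    short_bin = seq_len(length(short_bins) - 1)
  ) %>%
    left_join(counts, by = c("area_bin", "long_bin", "short_bin")) %>%
    left_join(n_cells, by = "area_bin") %>%
    mutate(
      count = tidyr::replace_na(.data$count, 0L),
      n_cells = tidyr::replace_na(.data$n_cells, 0L),
      area_mid = bin_centers(.env$area_bins)[.data$area_bin],
      long_mid = bin_centers(.env$long_bins)[.data$long_bin],
      short_mid = bin_centers(.env$short_bins)[.data$short_bin],
      value = ifelse(.data$n_cells > 0, .data$count / .data$n_cells, NA_real_)
    )
  structure(grid, class = c("location_histogram", class(grid)),
            area_bins = area_bins, long_bins = long_bins, short_bins = short_bins)
}

#' 2D Normal fits of cluster location distributions per area bin
#'
#' Splits foci into the upper (`rel_long > 0`, old-pole side) and lower
#' clusters and fits an axis-independent 2D Normal per cluster and area bin
#' by maximum likelihood (sample mean and SD per axis). Cluster-bins with
#' fewer than `min_n` positions are flagged invalid and excluded from
#' averages. `sqrt(2)` times the average fitted SD is the expected RMSD
#' plateau of a confined particle whose position decorrelates within the
#' observation window.
#'
#' @param positions Output of [to_internal_coords()].
#' @param area_bins Area bin edges (um^2).
#' @param min_n Minimum positions per cluster-bin for a valid fit.
#'
#' @return Tibble with `area_bin`, `area_mid`, `cluster`, `n`, `mean_long`,
#'   `mean_short`, `sd_long`, `sd_short`, `valid`.
#' @export
fit_location_gaussian <- function(positions, area_bins = NULL, min_n = 10) {
  if (is.null(area_bins)) area_bins <- default_area_bins(positions$area)
  check_bins(area_bins, "area_bins")
  mle_sd <- function(x) sqrt(mean((x - mean(x))^2))  # ML (not n-1) estimate
  positions %>%
    mutate(
      area_bin = bin_label(.data$area, .env$area_bins),
      cluster = ifelse(.data$rel_long > 0, "upper", "lower")
    ) %>%
    filter(!is.na(.data$area_bin)) %>%
    group_by(.data$area_bin, .data$cluster) %>%
    summarise(
      n = dplyr::n(),
      mean_long = mean(.data$long_offset),
      mean_short = mean(.data$short_offset),
      sd_long = mle_sd(.data$long_offset),
      sd_short = mle_sd(.data$short_offset),
      .groups = "drop"
    ) %>%
    mutate(
      area_mid = bin_centers(.env$area_bins)[.data$area_bin],
      valid = .data$n >= .env$min_n
    ) %>%
    arrange(.data$area_bin, .data$cluster)
}

#' Classify cells into old-pole / new-pole locus subpopulations
#'
#' At slow growth, mid-replichore locus location distributions split into two
#' arrangements ("chromosome inversion"): the locus near the old pole in one
#' subpopulation and near the new pole in the other. Each cell is labelled by
#' the sign of the mean relative long-axis position of its locus foci at the
#' birth frame (the cell's first recorded frame): positive (or exactly zero,
#' by convention) is `old-pole`, negative `new-pole`. Cells with no locus
#' focus at birth are left unlabelled (dropped).
#'
#' @param positions Locus-channel output of [to_internal_coords()].
#' @param cells Cell-frame tibble.
#'
#' @return Tibble with `cell_id`, `birth_frame`, `mean_rel_long`, `side`.
#' @export
classify_birth_side <- function(positions, cells) {
  birth <- cells %>%
    group_by(.data$cell_id) %>%
    summarise(birth_frame = min(.data$frame_index), .groups = "drop")
  positions %>%
    inner_join(birth, by = "cell_id") %>%
    filter(.data$frame_index == .data$birth_frame) %>%
    group_by(.data$cell_id, .data$birth_frame) %>%
    summarise(mean_rel_long = mean(.data$rel_long), .groups = "drop") %>%
    mutate(side = ifelse(.data$mean_rel_long >= 0, "old-pole", "new-pole"))
}
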