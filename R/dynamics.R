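#' Align trajectories on their replication-initiation event
#'
#' Re-times each replisome (or locus) trajectory to minutes since its own
#' initiation event and projects positions into the cell-internal coordinate
#' system. Each trajectory must be spawned by exactly one event (the mapping
#' comes from the event's `trajectory_ids`); trajectories without an event
#' are excluded and logged in the `excluded` attribute. Points are kept over
#' `[0, window]` and only while the trajectory remains in the initiating
#' cell, so trajectories that divide early keep a missing tail. Each
#' trajectory is labelled `upper` or `lower` by the sign of its relative
#' long-axis position at aligned time 0 (the two replisome clusters).
#'
#' @param trajectories Output of [link_foci()].
#' @param events Output of [detect_initiation()].
#' @param cells Cell-frame tibble.
#' @param window Alignment window (min) after the event.
#'
#' @return An `aligned_trajectories` tibble: `event_id`, `trajectory_id`,
#'   `cluster`, `t_align`, `long_offset`, `short_offset`, `rel_long`,
#'   `length`, `area`, `cell_id`.
#' @export
align_on_initiation <- function(trajectories, events, cells, window = 20) {
  if (window <= 0) abort("`window` must be positive.")
  ev_map <- events %>%
    select("event_id", "cell_id", "time", "trajectory_ids") %>%
    rename(event_cell = "cell_id", t_event = "time") %>%
    mutate(trajectory_id = strsplit(.data$trajectory_ids, ",")) %>%
    tidyr::unnest("trajectory_id") %>%
    select(-"trajectory_ids")

  excluded <- setdiff(unique(trajectories$trajectory_id), ev_map$trajectory_id)

  pts <- trajectories %>%
    inner_join(ev_map, by = "trajectory_id") %>%
    to_internal_coords(cells) %>%
    mutate(t_align = .data$time - .data$t_event) %>%
    filter(.data$t_align >= -1e-9, .data$t_align <= window + 1e-9,
           .data$cell_id == .data$event_cell) %>%
    arrange(.data$trajectory_id, .data$t_align)

  aligned <- pts %>%
    group_by(.data$trajectory_id) %>%
    filter(dplyr::n() >= 1, abs(min(.data$t_align)) < 1e-9) %>%
    mutate(cluster = ifelse(first(.data$rel_long) > 0, "upper", "lower")) %>%
    ungroup() %>%
    select("event_id", "trajectory_id", "cluster", "t_align", "long_offset",
           "short_offset", "rel_long", "length", "area", "cell_id")
  structure(aligned, class = c("aligned_trajectories", class(aligned)),
            excluded = excluded, window = window)
}

#' Remove the net average movement from an aligned trajectory set
#'
#' Replisome distributions show a small net average movement away from
#' mid-cell as the cell grows; before estimating the RMSD this systematic
#' component is removed. Per cluster (upper/lower, so the mirrored outward
#' drifts are corrected with mirrored signs) and per aligned time point, the
#' across-trajectory mean displacement-from-start is subtracted from every
#' trajectory's displacement-from-start. After correction the ensemble mean
#' displacement-from-start is zero at every time point. Time points with
#' fewer than two trajectories reuse the last preceding valid mean and are
#' flagged.
#'
#' @param aligned An [align_on_initiation()] result.
#'
#' @return The input with displacement columns added: `d_long`, `d_short`
#'   (raw displacement from the trajectory's own start), `d_long_corr`,
#'   `d_short_corr` (drift-corrected), and a logical `drift_flagged`.
#' @export
subtract_net_drift <- function(aligned) {
  disp <- aligned %>%
    group_by(.data$trajectory_id) %>%
    arrange(.data$t_align, .by_group = TRUE) %>%
    mutate(d_long = .data$long_offset - first(.data$long_offset),
           d_short = .data$short_offset - first(.data$short_offset)) %>%
    ungroup()
  drift <- disp %>%
    group_by(.data$cluster, .data$t_align) %>%
    summarise(n_t = dplyr::n(),
              mean_dl = mean(.data$d_long), mean_ds = mean(.data$d_short),
              .groups = "drop") %>%
    arrange(.data$cluster, .data$t_align) %>%
    group_by(.data$cluster) %>%
    mutate(
      drift_flagged = .data$n_t < 2,
      mean_dl = carry_forward(ifelse(.data$drift_flagged, NA_real_, .data$mean_dl)),
      mean_ds = carry_forward(ifelse(.data$drift_flagged, NA_real_, .data$mean_ds))
    ) %>%
    ungroup()
  out <- disp %>%
    left_join(drift %>% select("cluster", "t_align", "mean_dl", "mean_ds",
                               "drift_flagged"),
              by = c("cluster", "t_align")) %>%
    mutate(d_long_corr = .data$d_long - .data$mean_dl,
           d_short_corr = .data$d_short - .data$mean_ds) %>%
    select(-"mean_dl", -"mean_ds")
  structure(out, class = c("aligned_trajectories", class(out)),
            excluded = attr(aligned, "excluded"), window = attr(aligned, "window"),
            drift_corrected = TRUE)
}

carry_forward <- function(x) {
  # last-observation-carried-forward; leading NAs become 0 (no correction)
  for (i in seq_along(x)) {
    if (is.na(x[i])) x[i] <- if (i > 1) x[i - 1] else 0
  }
  x
}

#' RMSD relative to the initiation event
#'
#' Root mean squared displacement per axis as a function of time since the
#' initiation event: `RMSD(t) = sqrt(mean_i (x_i(t) - x_i(0))^2)` over the
#' drift-corrected trajectory ensemble, with the standard error propagated
#' from the variance of the squared displacements
#' (`sem = sd(d^2) / (2 * RMSD * sqrt(n))`). For a stationary confined
#' particle the curve rises as `sigma * sqrt(2 * (1 - exp(-t / tau)))` and
#' plateaus at `sqrt(2) * sigma`.
#'
#' @param aligned A drift-corrected [subtract_net_drift()] result.
#'
#' @return An `rmsd_curve` tibble: `t_align`, `n`, `rmsd_long`, `sem_long`,
#'   `rmsd_short`, `sem_short`.
#' @export
rmsd_curve <- function(aligned) {
  if (!isTRUE(attr(aligned, "drift_corrected"))) {
    abort("`aligned` must be drift-corrected: call subtract_net_drift() first.")
  }
  curve <- aligned %>%
    group_by(.data$t_align) %>%
    summarise(
      n = dplyr::n(),
      rmsd_long = sqrt(mean(.data$d_long_corr^2)),
      sem_long = rmsd_sem(.data$d_long_corr),
      rmsd_short = sqrt(mean(.data$d_short_corr^2)),
      sem_short = rmsd_sem(.data$d_short_corr),
      .groups = "drop"
    ) %>%
    filter(.data$n > 0) %>%
    arrange(.data$t_align)
  structure(curve, class = c("rmsd_curve", class(curve)))
}

rmsd_sem <- function(d) {
  r <- sqrt(mean(d^2))
  if (r == 0 || length(d) < 2) return(0)
  sd(d^2) / (2 * r * sqrt(length(d)))
}

#' Plateau value of an RMSD curve
#'
#' Mean RMSD per axis over a late-lag window where the curve has saturated
#' (default 10-20 min, well past the confinement correlation time). The
#' reported uncertainty is the mean of the per-lag standard errors -- the
#' same trajectories enter every lag, so averaging the (correlated) lags
#' does not shrink the error.
#'
#' @param curve An [rmsd_curve()] result.
#' @param lag_window Length-2 numeric, min and max lag (min) to average over.
#'
#' @return Tibble with one row per axis: `axis`, `plateau`, `sem`, `n_lags`,
#'   `n_min` (smallest trajectory count among the averaged lags).
#' @export
plateau_estimate <- function(curve, lag_window = c(10, 20)) {
  stopifnot(length(lag_window) == 2, lag_window[1] <= lag_window[2])
  win <- curve %>%
    filter(.data$t_align >= lag_window[1] - 1e-9,
           .data$t_align <= lag_window[2] + 1e-9)
  if (nrow(win) == 0) abort("No RMSD points fall inside `lag_window`.")
  tibble(
    axis = c("long", "short"),
    plateau = c(mean(win$rmsd_long), mean(win$rmsd_short)),
    sem = c(mean(win$sem_long), mean(win$sem_short)),
    n_lags = nrow(win),
    n_min = min(win$n)
  )
}

#' Net replisome movement as a percentage of cell length
#'
#' The contrast quantity for locus translocation: over a window starting at
#' initiation (by default 30 percent of a 50-min generation, i.e. 15 min),
#' the ensemble-mean outward long-axis displacement of the replisome
#' clusters (outward = away from mid-cell, so the upper and lower clusters
#' contribute with mirrored signs), expressed as a percentage of the mean
#' cell length over the window. Loci that translocate move more than half
#' the cell length on this time scale; the replisomes move a few percent.
#'
#' @param aligned An [align_on_initiation()] result (drift-uncorrected; the
#'   net movement is exactly what is being measured).
#' @param window Window length (min) after initiation.
#'
#' @return Tibble: `pct_of_length` (absolute net movement, percent),
#'   `mean_outward_um`, `mean_length_um`, `n_trajectories`, `window`.
#' @export
net_movement_percent <- function(aligned, window = 15) {
  covered <- aligned %>%
    group_by(.data$trajectory_id) %>%
    filter(max(.data$t_align) >= window - 1e-9) %>%
    arrange(.data$t_align, .by_group = TRUE) %>%
    summarise(
      cluster = first(.data$cluster),
      d_long = .data$long_offset[which.min(abs(.data$t_align - window))] -
        first(.data$long_offset),
      .groups = "drop"
    ) %>%
    mutate(outward = ifelse(.data$cluster == "upper", 1, -1) * .data$d_long)
  if (nrow(covered) == 0) abort("No trajectory covers the requested window.")
  lens <- aligned %>%
    filter(.data$trajectory_id %in% covered$trajectory_id,
           .data$t_align <= window + 1e-9)
  mean_out <- mean(covered$outward)
  mean_len <- mean(lens$length)
  tibble(
    pct_of_length = 100 * abs(mean_out) / mean_len,
    mean_outward_um = mean_out,
    mean_length_um = mean_len,
    n_trajectories = nrow(covered),
    window = window
  )
}

#' One-second displacement records from doublet frames
#'
#' Pairs each focus detected in a first-tag frame with its partner in the
#' second frame acquired 1 s later (minimum-total-distance one-to-one
#' matching within cell, frame and channel, gated at `max_link`), and
#' records the displacement in internal coordinates: per-axis components,
#' Euclidean magnitude, the start position inside the cell and the cell
#' area. Unmatched doublet detections produce no record and are counted in
#' the `n_unmatched` attribute.
#'
#' @param observations Focus table with a `tag` column (`first`/`second`).
#' @param cells Cell-frame tibble.
#' @param max_link Doublet link gate (um); tighter than the frame-to-frame
#'   gate since little motion happens in 1 s.
#'
#' @return A tibble of displacement records: `channel`, `cell_id`,
#'   `lineage_id`, `frame_index`, `time`, `area`, `long_offset`,
#'   `short_offset`, `rel_long` (start point), `d_long`, `d_short`,
#'   `magnitude`.
#' @export
compute_displacements <- function(observations, cells, max_link = 0.3) {
  if (!"tag" %in% names(observations)) {
    abort("`observations` must carry a `tag` column marking the 1-s doublets.")
  }
  firsts <- observations %>% filter(.data$tag == "first")
  seconds <- observations %>% filter(.data$tag == "second")
  n_unmatched <- 0L
  pieces <- list()

  # fast path: frames with exactly one detection per tag pair trivially
  grp_n <- function(d) d %>%
    group_by(.data$cell_id, .data$frame_index, .data$channel) %>%
    mutate(.gn = dplyr::n()) %>% ungroup()
  firsts <- grp_n(firsts); seconds <- grp_n(seconds)
  f1 <- firsts %>% filter(.data$.gn == 1L)
  s1 <- seconds %>% filter(.data$.gn == 1L)
  singles <- f1 %>%
    inner_join(s1 %>% select("cell_id", "frame_index", "channel",
                             x2 = "x", y2 = "y"),
               by = c("cell_id", "frame_index", "channel"))
  if (nrow(singles) > 0) {
    singles <- singles %>%
      mutate(dx = .data$x2 - .data$x, dy = .data$y2 - .data$y,
             dist = sqrt(.data$dx^2 + .data$dy^2))
    ok1 <- singles$dist <= max_link
    n_unmatched <- n_unmatched + 2L * sum(!ok1)
    sg <- singles[ok1, , drop = FALSE]
    pieces[["singles"]] <- tibble(
      channel = sg$channel, cell_id = sg$cell_id, lineage_id = sg$lineage_id,
      frame_index = sg$frame_index, time = sg$time,
      x1 = sg$x, y1 = sg$y, dx = sg$dx, dy = sg$dy
    )
  }
  # singles whose partner frame has 0 or >1 detections, plus all multi-focus
  # frames, go through the assignment matcher
  single_keys <- singles %>% distinct(.data$cell_id, .data$frame_index, .data$channel)
  fm <- firsts %>% anti_join(single_keys, by = c("cell_id", "frame_index", "channel"))
  sm <- seconds %>% anti_join(single_keys, by = c("cell_id", "frame_index", "channel"))
  fm <- as.data.frame(fm); sm <- as.data.frame(sm)  # fast row subsetting
  fm$.row <- seq_len(nrow(fm)); sm$.row <- seq_len(nrow(sm))
  key_of <- function(d) interaction(d$cell_id, d$frame_index, d$channel, drop = TRUE)
  f_split <- split(fm[c("x", "y", ".row")], key_of(fm))
  s_split <- split(sm[c("x", "y", ".row")], key_of(sm))
  ia <- integer(0); ib <- integer(0)
  for (g in names(f_split)) {
    a <- f_split[[g]]; b <- s_split[[g]]
    if (is.null(b) || nrow(b) == 0) { n_unmatched <- n_unmatched + nrow(a); next }
    cost <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
    m <- match_min_cost(cost, gate = max_link)
    ok <- which(!is.na(m))
    n_unmatched <- n_unmatched + (nrow(a) - length(ok)) + (nrow(b) - length(ok))
    if (length(ok) == 0) next
    ia <- c(ia, a$.row[ok]); ib <- c(ib, b$.row[m[ok]])
  }
  if (length(ia) > 0) {
    pieces[["multi"]] <- tibble(
      channel = fm$channel[ia], cell_id = fm$cell_id[ia],
      lineage_id = fm$lineage_id[ia], frame_index = fm$frame_index[ia],
      time = fm$time[ia],
      x1 = fm$x[ia], y1 = fm$y[ia],
      dx = sm$x[ib] - fm$x[ia], dy = sm$y[ib] - fm$y[ia]
    )
  }
  if (length(pieces) == 0) {
    empty <- tibble(channel = character(), cell_id = character(),
                    lineage_id = character(), frame_index = integer(),
                    time = numeric(), area = numeric(), long_offset = numeric(),
                    short_offset = numeric(), rel_long = numeric(),
                    d_long = numeric(), d_short = numeric(), magnitude = numeric())
    return(structure(empty, n_unmatched = n_unmatched))
  }
  paired <- bind_rows(pieces)
  geom <- cells %>%
    select("cell_id", "frame_index", "centroid_x", "centroid_y", "orientation",
           "old_pole_sign", "length", "area")
  out <- paired %>%
    left_join(geom, by = c("cell_id", "frame_index")) %>%
    mutate(
      ux = .data$old_pole_sign * cos(.data$orientation),
      uy = .data$old_pole_sign * sin(.data$orientation),
      vx = -sin(.data$orientation), vy = cos(.data$orientation),
      long_offset = (.data$x1 - .data$centroid_x) * .data$ux +
        (.data$y1 - .data$centroid_y) * .data$uy,
      short_offset = (.data$x1 - .data$centroid_x) * .data$vx +
        (.data$y1 - .data$centroid_y) * .data$vy,
      rel_long = .data$long_offset / .data$length,
      d_long = .data$dx * .data$ux + .data$dy * .data$uy,
      d_short = .data$dx * .data$vx + .data$dy * .data$vy,
      magnitude = sqrt(.data$d_long^2 + .data$d_short^2)
    ) %>%
    select("channel", "cell_id", "lineage_id", "frame_index", "time", "area",
           "long_offset", "short_offset", "rel_long", "d_long", "d_short",
           "magnitude")
  structure(out, n_unmatched = n_unmatched)
}

#' Displacement statistics binned by cell area
#'
#' Empirical distribution summary of 1-s displacement magnitudes (or any
#' record value) per cell-area bin: count, mean, SD and SEM. Empty bins are
#' reported with zero count.
#'
#' @param records Displacement records from [compute_displacements()] (or
#'   focus pairs with a distance column).
#' @param area_bins Strictly increasing bin edges (um^2); default 0.25-wide
#'   bins spanning the data.
#' @param value Name of the value column (default `"magnitude"`).
#'
#' @return An `area_profile` tibble: `area_bin`, `area_mid`, `n`, `mean`,
#'   `sd`, `sem`.
#' @export
displacement_by_area <- function(records, area_bins = NULL, value = "magnitude") {
  if (!value %in% names(records)) {
    abort(paste0("`records` has no column `", value, "`."))
  }
  if (is.null(area_bins)) area_bins <- default_area_bins(records$area)
  check_bins(area_bins, "area_bins")
  stats_tbl <- records %>%
    mutate(area_bin = bin_label(.data$area, .env$area_bins)) %>%
    filter(!is.na(.data$area_bin)) %>%
    group_by(.data$area_bin) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sd = sd(.data[[value]]),
      .groups = "drop"
    )
  out <- tibble(area_bin = seq_len(length(area_bins) - 1)) %>%
    left_join(stats_tbl, by = "area_bin") %>%
    mutate(
      n = tidyr::replace_na(.data$n, 0L),
      area_mid = bin_centers(.env$area_bins)[.data$area_bin],
      sem = ifelse(.data$n > 1, .data$sd / sqrt(.data$n), NA_real_)
    ) %>%
    select("area_bin", "area_mid", "n", "mean", "sd", "sem")
  structure(out, class = c("area_profile", class(out)),
            area_bins = area_bins, value = value)
}

#' Spatially binned mean 1-s displacement map
#'
#' For each spatial bin of the cell-internal grid (and optionally each
#' cell-area bin), the mean magnitude of the 1-s displacements whose first
#' point lies inside the bin. A bin is reported only if it holds strictly
#' more than `min_count_exclusive` displacements (default 4: bins with four
#' or fewer are masked), so sparsely sampled bins show no value.
#'
#' @param records Displacement records from [compute_displacements()].
#' @param long_bins,short_bins Spatial bin edges (um), shared with the
#'   location histograms.
#' @param area_bins Optional area bin edges; `NULL` pools all areas.
#' @param min_count_exclusive Mask threshold: bins with `n <=` this count
#'   carry no value.
#'
#' @return A `spatial_displacement_map` tibble: `area_bin` (or `NA`),
#'   `long_bin`, `short_bin`, midpoints, `n`, `masked`, `mean_disp` (`NA`
#'   where masked).
#' @export
spatial_displacement_map <- function(records, long_bins = NULL,
                                     short_bins = NULL, area_bins = NULL,
                                     min_count_exclusive = 4) {
  sp <- if (nrow(records) > 0) default_spatial_bins(records) else
    list(long = seq(-2, 2, 0.1), short = seq(-0.6, 0.6, 0.1))
  if (is.null(long_bins)) long_bins <- sp$long
  if (is.null(short_bins)) short_bins <- sp$short
  check_bins(long_bins, "long_bins"); check_bins(short_bins, "short_bins")
  use_area <- !is.null(area_bins)
  if (use_area) check_bins(area_bins, "area_bins")

  rec <- records %>%
    mutate(
      long_bin = bin_label(.data$long_offset, .env$long_bins),
      short_bin = bin_label(.data$short_offset, .env$short_bins),
      area_bin = if (use_area) bin_label(.data$area, .env$area_bins) else NA_integer_
    ) %>%
    filter(!is.na(.data$long_bin), !is.na(.data$short_bin),
           if (use_area) !is.na(.data$area_bin) else TRUE)
  stats_tbl <- rec %>%
    group_by(.data$area_bin, .data$long_bin, .data$short_bin) %>%
    summarise(n = dplyr::n(), mean_raw = mean(.data$magnitude), .groups = "drop")

  grid <- tidyr::expand_grid(
    area_bin = if (use_area) seq_len(length(area_bins) - 1) else NA_integer_,
    long_bin = seq_len(length(long_bins) - 1),
    short_bin = seq_len(length(short_bins) - 1)
  ) %>%
    left_join(stats_tbl, by = c("area_bin", "long_bin", "short_bin")) %>%
    mutate(
      n = tidyr::replace_na(.data$n, 0L),
      long_mid = bin_centers(.env$long_bins)[.data$long_bin],
      short_mid = bin_centers(.env$short_bins)[.data$short_bin],
      area_mid = if (use_area) bin_centers(.env$area_bins)[.data$area_bin] else NA_real_,
      masked = .data$n <= .env$min_count_exclusive,
      mean_disp = ifelse(.data$masked, NA_real_, .data$mean_raw)
    ) %>%
    select(-"mean_raw")
  structure(grid, class = c("spatial_displacement_map", class(grid)),
            long_bins = long_bins, short_bins = short_bins,
            area_bins = if (use_area) area_bins else NULL,
            min_count_exclusive = min_count_exclusive)
}

#' Locate the cell-area minimum of a displacement (or distance) profile
#'
#' Smooths the per-area-bin mean profile with a centered moving average and
#' reports the bin center at the minimum, with a bootstrap confidence
#' interval obtained by resampling records within bins. The locus's
#' displacement minimum marks the cell area at which it is replicated; the
#' replisome-locus distance minimum falls at the same area.
#'
#' @param records Records with `area` and the value column.
#' @param area_bins Area bin edges (um^2).
#' @param value Value column name (default `"magnitude"`; use `"distance"`
#'   for focus pairs).
#' @param smoothing_window Moving-average width in bins (odd; 1 = none).
#' @param n_boot Bootstrap resamples for the percentile CI.
#'
#' @return Tibble: `area_min`, `ci_lower`, `ci_upper`, `n_records`,
#'   `n_bins`, `flagged` (TRUE when the profile is flat and the minimum
#'   undefined, in which case `area_min` is `NA`).
#' @export
find_displacement_minimum <- function(records, area_bins = NULL,
                                      value = "magnitude",
                                      smoothing_window = 3, n_boot = 200) {
  if (is.null(area_bins)) area_bins <- default_area_bins(records$area)
  check_bins(area_bins, "area_bins")
  prof <- displacement_by_area(records, area_bins, value = value)
  filled <- prof %>% filter(.data$n > 0)
  if (nrow(filled) < 3) abort("Need at least 3 non-empty area bins.")
  if (diff(range(filled$mean)) < 1e-12) {
    warn("Displacement profile is flat: minimum undefined.")
    return(tibble(area_min = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                  n_records = sum(filled$n), n_bins = nrow(filled), flagged = TRUE))
  }
  argmin_area <- function(means, mids) {
    sm <- moving_average(means, smoothing_window)
    mids[which.min(sm)]
  }
  est <- argmin_area(filled$mean, filled$area_mid)

  rec <- records %>%
    mutate(area_bin = bin_label(.data$area, .env$area_bins)) %>%
    filter(!is.na(.data$area_bin))
  by_bin <- split(rec[[value]], rec$area_bin)
  boot <- vapply(seq_len(n_boot), function(b) {
    means <- vapply(by_bin, function(v) mean(sample(v, length(v), replace = TRUE)),
                    numeric(1))
    mids <- bin_centers(area_bins)[as.integer(names(by_bin))]
    o <- order(mids)
    argmin_area(means[o], mids[o])
  }, numeric(1))
  ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
  tibble(area_min = est, ci_lower = ci[1], ci_upper = ci[2],
         n_records = nrow(rec), n_bins = nrow(filled), flagged = FALSE)
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  half <- floor(w / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}
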