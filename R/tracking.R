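#' Link per-frame foci into trajectories
#'
#' Frame-to-frame one-to-one linking within each lineage and channel:
#' successive frames are joined by the minimum-total-distance assignment
#' (see [match_min_cost()]), with links longer than `max_disp` per frame of
#' separation forbidden. Detections with no admissible antecedent start new
#' trajectories; trajectories unmatched for more than `max_gap` frames are
#' closed (gap closing re-links across up to `max_gap` missed frames, with
#' the gate scaled by the frame gap). A trajectory may cross a division into
#' the daughter holding its nearest next detection, since linking is scoped
#' by lineage, not by cell.
#'
#' @param observations Focus table with `lineage_id`, `channel`, `cell_id`,
#'   `frame_index`, `x`, `y` (and optionally `tag`; only `tag == "first"`
#'   rows are linked -- the 1-s doublet partners are handled by
#'   [compute_displacements()]).
#' @param max_disp Maximum link distance per frame of separation (um).
#' @param max_gap Maximum number of consecutive missed frames bridged.
#'
#' @return The linked observations with a `trajectory_id` column, ordered by
#'   trajectory and frame.
#' @export
link_foci <- function(observations, max_disp = 0.5, max_gap = 2) {
  obs <- observations
  if ("tag" %in% names(obs)) obs <- obs[obs$tag == "first", , drop = FALSE]
  if (nrow(obs) == 0) {
    return(dplyr::mutate(obs, trajectory_id = character(0)))
  }
  if (!all(c("lineage_id", "channel") %in% names(obs))) {
    abort("`observations` must have lineage_id and channel columns.")
  }
  obs %>%
    group_by(.data$lineage_id, .data$channel) %>%
    dplyr::group_modify(~ link_one_group(.x, .y, max_disp, max_gap)) %>%
    ungroup() %>%
    arrange(.data$trajectory_id, .data$frame_index)
}

link_one_group <- function(df, key, max_disp, max_gap) {
  df <- df[order(df$frame_index), , drop = FALSE]
  frames <- sort(unique(df$frame_index))
  n_obs <- nrow(df)
  traj <- rep(NA_character_, n_obs)
  # active track registry
  act_id <- character(0); act_x <- numeric(0); act_y <- numeric(0)
  act_frame <- integer(0)
  counter <- 0L
  prefix <- paste0(key$lineage_id, "_", substr(key$channel, 1, 3))
  for (f in frames) {
    idx <- which(df$frame_index == f)
    # retire tracks idle for more than max_gap frames
    live <- (f - act_frame) <= (max_gap + 1L)
    act_id <- act_id[live]; act_x <- act_x[live]; act_y <- act_y[live]
    act_frame <- act_frame[live]
    assigned <- rep(NA_integer_, length(idx))
    if (length(act_id) > 0) {
      dx <- outer(act_x, df$x[idx], "-")
      dy <- outer(act_y, df$y[idx], "-")
      cost <- sqrt(dx^2 + dy^2)
      gap <- f - act_frame
      gate_m <- matrix(max_disp * gap, nrow = length(act_id), ncol = length(idx))
      cost[cost > gate_m] <- Inf
      m <- match_min_cost(cost, gate = max_disp * (max_gap + 1L))
      for (t in seq_along(m)) {
        if (!is.na(m[t])) assigned[m[t]] <- t
      }
    }
    for (d in seq_along(idx)) {
      i <- idx[d]
      if (!is.na(assigned[d])) {
        t <- assigned[d]
        traj[i] <- act_id[t]
        act_x[t] <- df$x[i]; act_y[t] <- df$y[i]; act_frame[t] <- f
      } else {
        counter <- counter + 1L
        new_id <- sprintf("%s_t%03d", prefix, counter)
        traj[i] <- new_id
        act_id <- c(act_id, new_id)
        act_x <- c(act_x, df$x[i]); act_y <- c(act_y, df$y[i])
        act_frame <- c(act_frame, f)
      }
    }
  }
  df$trajectory_id <- traj
  df
}

#' Detect replication-initiation events from replisome trajectories
#'
#' A replication initiation is identified as the start of a replisome
#' trajectory: a trajectory qualifies if it persists at least `min_lifetime`
#' frames and no other replisome trajectory had a detection within
#' `exclusion_radius` in the preceding frame (suppressing re-detections
#' after transient focus splitting or missed frames). Because one initiation
#' spawns two replisome clusters, qualifying starts in the same cell within
#' `merge_frames` frames of each other are merged into a single event; the
#' event records the containing cell's area at the earliest start frame and
#' the trajectory ids spawned.
#'
#' @param trajectories Output of [link_foci()] for the replisome channel.
#' @param cells Cell-frame tibble (areas per cell and frame).
#' @param min_lifetime Minimum trajectory lifetime in frames.
#' @param exclusion_radius Radius (um) of the pre-existing-trajectory veto.
#' @param merge_frames Starts in the same cell within this many frames are
#'   one event.
#'
#' @return Tibble of events: `event_id`, `cell_id`, `lineage_id`,
#'   `frame_index`, `time`, `area`, `trajectory_ids` (comma-separated).
#' @export
detect_initiation <- function(trajectories, cells, min_lifetime = 5,
                              exclusion_radius = 0.5, merge_frames = 1) {
  if (nrow(trajectories) == 0) {
    return(tibble(event_id = character(), cell_id = character(),
                  lineage_id = character(), frame_index = integer(),
                  time = numeric(), area = numeric(), trajectory_ids = character()))
  }
  starts <- trajectories %>%
    group_by(.data$trajectory_id) %>%
    summarise(
      lineage_id = first(.data$lineage_id),
      start_frame = min(.data$frame_index),
      end_frame = max(.data$frame_index),
      cell_id = .data$cell_id[which.min(.data$frame_index)],
      x0 = .data$x[which.min(.data$frame_index)],
      y0 = .data$y[which.min(.data$frame_index)],
      time0 = .data$time[which.min(.data$frame_index)],
      .groups = "drop"
    ) %>%
    mutate(lifetime = .data$end_frame - .data$start_frame + 1L) %>%
    filter(.data$lifetime >= .env$min_lifetime)
  if (nrow(starts) == 0) {
    return(tibble(event_id = character(), cell_id = character(),
                  lineage_id = character(), frame_index = integer(),
                  time = numeric(), area = numeric(), trajectory_ids = character()))
  }

  # veto starts preceded by another trajectory's detection nearby
  keep <- vapply(seq_len(nrow(starts)), function(i) {
    s <- starts[i, ]
    prev <- trajectories %>%
      filter(.data$lineage_id == s$lineage_id,
             .data$frame_index == s$start_frame - 1L,
             .data$trajectory_id != s$trajectory_id)
    if (nrow(prev) == 0) return(TRUE)
    all(sqrt((prev$x - s$x0)^2 + (prev$y - s$y0)^2) > exclusion_radius)
  }, logical(1))
  starts <- starts[keep, , drop = FALSE]
  if (nrow(starts) == 0) {
    return(tibble(event_id = character(), cell_id = character(),
                  lineage_id = character(), frame_index = integer(),
                  time = numeric(), area = numeric(), trajectory_ids = character()))
  }

  events <- starts %>%
    arrange(.data$cell_id, .data$start_frame) %>%
    group_by(.data$cell_id) %>%
    mutate(event_grp = cumsum(c(1L, diff(.data$start_frame) > .env$merge_frames))) %>%
    group_by(.data$cell_id, .data$event_grp) %>%
    summarise(
      lineage_id = first(.data$lineage_id),
      frame_index = min(.data$start_frame),
      time = min(.data$time0),
      trajectory_ids = paste(.data$trajectory_id, collapse = ","),
      .groups = "drop"
    ) %>%
    select(-"event_grp") %>%
    left_join(cells %>% select("cell_id", "frame_index", "area"),
              by = c("cell_id", "frame_index")) %>%
    arrange(.data$lineage_id, .data$frame_index) %>%
    mutate(event_id = sprintf("evt_%04d", row_number())) %>%
    select("event_id", "cell_id", "lineage_id", "frame_index", "time",
           "area", "trajectory_ids")
  events
}
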