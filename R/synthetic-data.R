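# Synthetic mother-machine generator.
#
# One lineage = one microfluidic channel holding a single followed cell: the
# old pole is anchored at the top of the lane, growth extends the cell
# downward, and at division the old-pole (upper) daughter is kept while the
# sibling is discarded, as in a mother-machine experiment. Cell areas grow
# exponentially; division is a sizer at twice the birth area with lognormal
# noise; replication initiates when the area crosses a per-cycle threshold
# around A_init, spawning two replisome clusters confined about the +/- L/4
# long-axis points for one C-period. The labelled locus follows a
# home -> relocating -> replicating -> segregating -> home state machine tied
# to the replication-size model A(alpha) = A_init * exp(mu * C * alpha).

# Home long-axis fraction of an unreplicated locus: interpolates from the
# quarter position (alpha = 0) to the new pole (alpha = 1); `side` mirrors the
# whole arrangement (chromosome-inversion subpopulations).
locus_home_frac <- function(alpha, side = 1) {
  side * (0.25 - 0.75 * alpha)
}

#' Simulate one mother-machine lineage
#'
#' Generates the cell-geometry track of a single followed lineage: per-frame
#' cell records (geometry, area, lineage links, pole identity) plus the
#' division and replication-initiation event list and a per-cycle summary.
#' Cells grow exponentially in area with per-cycle rate noise, divide by a
#' sizer at twice the birth area (lognormal noise), and log an initiation
#' event when the area crosses a per-cycle threshold drawn around `A_init`.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed (set before any draws).
#' @param lineage_id Identifier for this lineage.
#' @param lane_x Lab-frame x position of the lane (um).
#'
#' @return A list with tibbles `cells` (one row per cell per frame: `cell_id`,
#'   `lineage_id`, `frame_index`, `time`, `centroid_x`, `centroid_y`,
#'   `orientation`, `length`, `width`, `area`, `parent_id`, `old_pole_sign`),
#'   `events` (`event`, `cell_id`, `lineage_id`, `frame_index`, `time`,
#'   `area`), and `cycles` (per-cell-cycle parameters used by the track
#'   simulators).
#' @export
simulate_lineage <- function(config = sim_config(), seed = NULL,
                             lineage_id = "lin1", lane_x = 0) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  g <- config$growth; ini <- config$initiation; sch <- config$schedule
  mu0 <- log(2) / g$T_d
  duration <- sch$duration
  dt <- sch$frame_interval

  # -- per-cycle schedule ---------------------------------------------------
  cycles <- list()
  t_birth <- 0
  A_birth <- g$A_birth * exp(rnorm(1, 0, g$division_cv))
  parent <- NA_character_
  k <- 0L
  while (t_birth < duration) {
    k <- k + 1L
    cell_id <- sprintf("%s_c%02d", lineage_id, k)
    mu_cell <- mu0 * exp(rnorm(1, 0, g$growth_rate_cv))
    A_div <- 2 * g$A_birth * exp(rnorm(1, 0, g$division_cv))
    if (A_div <= A_birth) A_div <- A_birth * 1.05  # degenerate draw guard
    t_div <- t_birth + log(A_div / A_birth) / mu_cell
    A_thresh <- ini$A_init * exp(rnorm(1, 0, ini$area_cv))
    t_init <- if (A_thresh >= A_div) {
      NA_real_  # initiation would fall after division: none this cycle
    } else {
      t_birth + log(max(A_thresh, A_birth) / A_birth) / mu_cell
    }
    side <- if (runif(1) < config$locus$side_prob) 1L else -1L
    cycles[[k]] <- tibble(
      cell_id = cell_id, parent_id = parent, lineage_id = lineage_id,
      cycle = k, t_birth = t_birth, t_div = t_div, mu_cell = mu_cell,
      A_birth = A_birth, A_div = A_div, A_init_thresh = A_thresh,
      t_init = t_init, side = side
    )
    parent <- cell_id
    A_birth <- A_div / 2
    t_birth <- t_div
  }
  cycles <- bind_rows(cycles) %>%
    mutate(side_next = dplyr::lead(.data$side, default = 1L))

  # -- per-frame cell records ----------------------------------------------
  frames <- tibble(frame_index = seq(0L, floor(duration / dt)), time = seq(0L, floor(duration / dt)) * dt)
  cells <- purrr::pmap_dfr(cycles, function(cell_id, parent_id, lineage_id, cycle,
                                            t_birth, t_div, mu_cell, A_birth, A_div,
                                            A_init_thresh, t_init, side, side_next) {
    fr <- frames[frames$time >= t_birth & frames$time < min(t_div, duration + dt / 2), ]
    if (nrow(fr) == 0) return(NULL)
    A <- A_birth * exp(mu_cell * (fr$time - t_birth))
    L <- A / config$growth$width
    tibble(
      cell_id = cell_id, lineage_id = lineage_id,
      frame_index = fr$frame_index, time = fr$time,
      centroid_x = lane_x, centroid_y = -L / 2,
      orientation = pi / 2, length = L, width = config$growth$width, area = A,
      parent_id = parent_id, old_pole_sign = 1L
    )
  })

  events <- bind_rows(
    cycles %>%
      filter(!is.na(.data$t_init)) %>%
      mutate(
        event = "initiation", time = .data$t_init,
        frame_index = as.integer(ceiling(.data$t_init / dt)),
        area = .data$A_birth * exp(.data$mu_cell * (.data$t_init - .data$t_birth))
      ) %>%
      select("event", "cell_id", "lineage_id", "frame_index", "time", "area"),
    cycles %>%
      filter(.data$t_div <= duration) %>%
      mutate(
        event = "division", time = .data$t_div,
        frame_index = as.integer(ceiling(.data$t_div / dt)),
        area = .data$A_div
      ) %>%
      select("event", "cell_id", "lineage_id", "frame_index", "time", "area")
  ) %>% arrange(.data$time)

  list(cells = cells, events = events, cycles = cycles)
}

# Geometry of the cell containing time t within a lineage (continuous-time).
# Returns centroid/orientation/length for mapping internal -> lab coordinates.
cell_geometry_at <- function(lineage, times, lane_x = 0, width = 1) {
  cyc <- lineage$cycles
  idx <- findInterval(times, cyc$t_birth)
  idx[idx < 1L] <- 1L
  A <- cyc$A_birth[idx] * exp(cyc$mu_cell[idx] * (times - cyc$t_birth[idx]))
  L <- A / width
  tibble(
    cell_id = cyc$cell_id[idx], time = times,
    centroid_x = lane_x, centroid_y = -L / 2,
    orientation = pi / 2, old_pole_sign = 1L, length = L, area = A
  )
}

# internal (long, short) -> lab (x, y) for given geometry rows
internal_to_lab <- function(geom, long, short) {
  u_x <- geom$old_pole_sign * cos(geom$orientation)
  u_y <- geom$old_pole_sign * sin(geom$orientation)
  v_x <- -sin(geom$orientation)
  v_y <- cos(geom$orientation)
  tibble(x = geom$centroid_x + long * u_x + short * v_x,
         y = geom$centroid_y + long * u_y + short * v_y)
}

# Frame/doublet sampling grid covering [t_from, t_to] within the lineage.
sample_grid <- function(config, t_from, t_to) {
  dt <- config$schedule$frame_interval
  f0 <- ceiling(t_from / dt - 1e-9)
  f1 <- floor(min(t_to, config$schedule$duration) / dt + 1e-9)
  if (f1 < f0) return(NULL)
  fr <- seq(f0, f1)
  tibble(frame_index = as.integer(fr), t_frame = fr * dt)
}

#' Simulate the two replisome tracks of one initiation event
#'
#' Each initiation spawns two replisome clusters whose home points track the
#' +/- L(t)/4 long-axis positions of the growing cell (this produces the
#' small outward net average movement), with stationary mean-reverting
#' fluctuations of SD `sigma_long` / `sigma_short` and correlation time `tau`
#' about the home point, simulated by exact discrete updates on the 1-min
#' frame grid; the 1-s doublet position is an exact conditional draw of the
#' same process. Tracks persist one C-period; if the cell divides first, the
#' old-pole-side cluster continues in the followed daughter (home at the
#' daughter's mid-cell) and the other cluster leaves with the discarded
#' sibling.
#'
#' @param event One row of a lineage's `cycles` tibble (a cycle with a
#'   non-missing `t_init`).
#' @param lineage A [simulate_lineage()] result.
#' @param config A [sim_config()].
#' @param lane_x Lab x of the lane.
#'
#' @return A tibble of ground-truth rows: `particle_id`, `species`,
#'   `locus_name`, `cell_id`, `lineage_id`, `frame_index`, `time`, `tag`
#'   (`first`/`second` of the 1-s doublet), `x`, `y`, `state`.
#' @export
simulate_replisome_track <- function(event, lineage, config = sim_config(),
                                     lane_x = 0) {
  stopifnot(!is.na(event$t_init))
  rep_cfg <- config$replisome
  t_end <- event$t_init + config$initiation$C
  grid <- sample_grid(config, event$t_init, t_end)
  if (is.null(grid)) return(NULL)
  d_off <- config$schedule$doublet_offset
  width <- config$growth$width

  out <- vector("list", 2L)
  for (i in 1:2) {
    sgn <- c(1, -1)[i]
    # after the initiating cell divides only the old-pole-side (+) cluster
    # stays in the followed daughter; single-round bookkeeping ends the
    # carried-over track no later than the daughter's own initiation
    g_t <- if (sgn > 0) {
      daughter <- lineage$cycles[which(lineage$cycles$parent_id == event$cell_id), ]
      t_stop <- if (nrow(daughter) == 1 && !is.na(daughter$t_init)) {
        daughter$t_init
      } else {
        Inf
      }
      grid[grid$t_frame < event$t_div | grid$t_frame < t_stop, ]
    } else {
      grid[grid$t_frame < event$t_div, ]
    }
    if (nrow(g_t) == 0) next
    geom1 <- cell_geometry_at(lineage, g_t$t_frame, lane_x, width)
    geom2 <- cell_geometry_at(lineage, g_t$t_frame + d_off, lane_x, width)
    in_mother <- geom1$cell_id == event$cell_id
    home_long1 <- ifelse(in_mother, sgn * geom1$length / 4, 0)
    in_mother2 <- geom2$cell_id == event$cell_id
    home_long2 <- ifelse(in_mother2, sgn * geom2$length / 4, 0)

    fl_long <- ou_simulate(g_t$t_frame, rep_cfg$sigma_long, rep_cfg$tau)
    fl_short <- ou_simulate(g_t$t_frame, rep_cfg$sigma_short, rep_cfg$tau)
    fl_long2 <- ou_offshoot(fl_long, rep_cfg$sigma_long, rep_cfg$tau, d_off)
    fl_short2 <- ou_offshoot(fl_short, rep_cfg$sigma_short, rep_cfg$tau, d_off)

    p1 <- internal_to_lab(geom1, home_long1 + fl_long, fl_short)
    p2 <- internal_to_lab(geom2, home_long2 + fl_long2, fl_short2)
    pid <- sprintf("%s_rep%s", event$cell_id, c("U", "D")[i])
    out[[i]] <- bind_rows(
      tibble(particle_id = pid, species = "replisome", locus_name = NA_character_,
             cell_id = geom1$cell_id, lineage_id = event$lineage_id,
             frame_index = g_t$frame_index, time = g_t$t_frame, tag = "first",
             x = p1$x, y = p1$y, state = "replicating"),
      tibble(particle_id = pid, species = "replisome", locus_name = NA_character_,
             cell_id = geom2$cell_id, lineage_id = event$lineage_id,
             frame_index = g_t$frame_index, time = g_t$t_frame + d_off, tag = "second",
             x = p2$x, y = p2$y, state = "replicating")
    )
  }
  bind_rows(out) %>% arrange(.data$particle_id, .data$time)
}

# Piecewise home-fraction schedule of the followed locus copy over one cycle.
# Returns a function frac(t) plus the state(t) labeller and fork info.
locus_cycle_schedule <- function(cyc, config, params) {
  lc <- config$locus
  h0 <- locus_home_frac(lc$alpha, cyc$side)
  r <- if (h0 >= 0) 0.25 else -0.25
  A_rep <- predicted_replication_area(lc$alpha, params) *
    (cyc$A_init_thresh / config$initiation$A_init)
  t_rep <- if (is.na(cyc$t_init)) Inf else
    cyc$t_birth + log(max(A_rep, cyc$A_birth) / cyc$A_birth) / cyc$mu_cell
  replicated <- is.finite(t_rep) && t_rep < cyc$t_div
  t_rs <- max(cyc$t_birth, t_rep - lc$relocation_lead)
  t_seg <- t_rep + lc$replication_dwell
  t_seg_end <- t_seg + lc$segregation_duration
  # segregation targets (mother-frame fractions): daughter birth homes, or
  # mid-cell anchoring for terminus-style loci
  if (lc$ter_anchor) {
    h_up <- 0; h_low <- 0
  } else {
    h_next <- locus_home_frac(lc$alpha, cyc$side_next)
    h_up <- h_next / 2 + 0.25
    h_low <- h_next / 2 - 0.25
  }
  ramp <- function(t, t0, t1, from, to) {
    if (t1 <= t0) return(rep(to, length(t)))
    w <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
    from + w * (to - from)
  }
  state_of <- function(t) {
    if (!replicated) {
      ifelse(t >= t_rs & is.finite(t_rep), "relocating", "home")
    } else {
      dplyr::case_when(
        t < t_rs ~ "home",
        t < t_rep ~ "relocating",
        t < t_seg ~ "replicating",
        t < t_seg_end ~ "segregating",
        TRUE ~ "home"
      )
    }
  }
  frac_followed <- function(t) {
    out <- rep(h0, length(t))
    if (is.finite(t_rep)) {
      rel <- t >= t_rs & t < t_rep
      out[rel] <- ramp(t[rel], t_rs, t_rep, h0, r)
      if (replicated) {
        out[t >= t_rep & t < t_seg] <- r
        seg <- t >= t_seg & t < t_seg_end
        out[seg] <- ramp(t[seg], t_seg, t_seg_end, r, h_up)
        out[t >= t_seg_end] <- h_up
      } else {
        # relocation abandoned at division: hold the ramp until t_div
        out[t >= t_rep] <- r
      }
    }
    out
  }
  frac_sibling <- function(t) {
    seg <- t >= t_seg & t < t_seg_end
    out <- rep(h_low, length(t))
    out[seg] <- ramp(t[seg], t_seg, t_seg_end, r, h_low)
    out
  }
  list(state_of = state_of, frac_followed = frac_followed,
       frac_sibling = frac_sibling, replicated = replicated,
       t_fork = t_seg, h0 = h0)
}

#' Simulate the labelled-locus tracks of a lineage
#'
#' Runs the locus state machine over every cell cycle of a lineage. The
#' followed copy sits at its home point (a long-axis fraction set by the
#' locus's genomic fraction `alpha` and the cycle's arrangement side), ramps
#' toward the nearest replisome home starting `relocation_lead` minutes
#' before the cell reaches the replication size `A(alpha)` scaled by the
#' cycle's initiation-threshold noise, dwells at the replisome with
#' replisome-level confinement for `replication_dwell` minutes, then forks:
#' the followed copy ramps to its position in the old-pole daughter while the
#' sibling copy ramps toward the discarded daughter and ends at division.
#' With `ter_anchor = TRUE` both copies ramp to mid-cell and stay there
#' (terminus behaviour). Positions carry a mean-reverting fluctuation whose
#' SD switches with the state; 1-s doublet positions displace the frame
#' position by the state's configured 1-s step SD per axis.
#'
#' @param lineage A [simulate_lineage()] result.
#' @param params A [replication_params()]; defaults to the config's growth and
#'   initiation sections.
#' @param config A [sim_config()].
#' @param lane_x Lab x of the lane.
#'
#' @return Ground-truth tibble in the same layout as
#'   [simulate_replisome_track()], `species = "locus"`.
#' @export
simulate_locus_track <- function(lineage, params = NULL, config = sim_config(),
                                 lane_x = 0) {
  lc <- config$locus
  if (is.null(params)) {
    params <- replication_params(A_init = config$initiation$A_init,
                                 T_d = config$growth$T_d,
                                 C = config$initiation$C)
  }
  d_off <- config$schedule$doublet_offset
  width <- config$growth$width
  bstep <- bound_step_sds(config)
  step_sd_for <- function(states, axis) {
    loose <- if (axis == "long") lc$step_sd_long else lc$step_sd_short
    bound <- bstep[[axis]]
    ifelse(states == "replicating", bound, loose)
  }
  sigma_for <- function(states, axis) {
    loose <- if (axis == "long") lc$sigma_long else lc$sigma_short
    bound <- if (axis == "long") config$replisome$sigma_long else config$replisome$sigma_short
    ifelse(states == "replicating", bound, loose)
  }

  # state-dependent mean-reverting recursion along a time grid
  sim_fluct <- function(times, sigmas, tau, x0 = NULL) {
    n <- length(times)
    x <- numeric(n)
    x[1] <- if (is.null(x0)) rnorm(1, 0, sigmas[1]) else x0
    if (n > 1) {
      dtv <- diff(times)
      decay <- exp(-dtv / tau)
      for (i in seq_len(n - 1)) {
        x[i + 1] <- x[i] * decay[i] +
          rnorm(1, 0, sigmas[i + 1] * sqrt(max(0, 1 - decay[i]^2)))
      }
    }
    x
  }

  rows <- list()
  fl_long_prev <- NULL; fl_short_prev <- NULL
  for (k in seq_len(nrow(lineage$cycles))) {
    cyc <- lineage$cycles[k, ]
    sched <- locus_cycle_schedule(cyc, config, params)
    grid <- sample_grid(config, cyc$t_birth, min(cyc$t_div - 1e-9, config$schedule$duration))
    if (is.null(grid) || nrow(grid) == 0) next
    st <- sched$state_of(grid$t_frame)
    geom1 <- cell_geometry_at(lineage, grid$t_frame, lane_x, width)
    geom2 <- cell_geometry_at(lineage, grid$t_frame + d_off, lane_x, width)

    fl_long <- sim_fluct(grid$t_frame, sigma_for(st, "long"), lc$tau, fl_long_prev)
    fl_short <- sim_fluct(grid$t_frame, sigma_for(st, "short"), lc$tau, fl_short_prev)
    fl_long_prev <- fl_long[length(fl_long)]
    fl_short_prev <- fl_short[length(fl_short)]

    long1 <- sched$frac_followed(grid$t_frame) * geom1$length + fl_long
    short1 <- fl_short
    long2 <- sched$frac_followed(grid$t_frame + d_off) * geom2$length + fl_long +
      rnorm(nrow(grid), 0, step_sd_for(st, "long"))
    short2 <- fl_short + rnorm(nrow(grid), 0, step_sd_for(st, "short"))

    pid <- sprintf("%s_loc", cyc$cell_id)
    p1 <- internal_to_lab(geom1, long1, short1)
    p2 <- internal_to_lab(geom2, long2, short2)
    rows[[length(rows) + 1L]] <- bind_rows(
      tibble(particle_id = pid, species = "locus", locus_name = lc$name,
             cell_id = geom1$cell_id, lineage_id = cyc$lineage_id,
             frame_index = grid$frame_index, time = grid$t_frame, tag = "first",
             x = p1$x, y = p1$y, state = st),
      tibble(particle_id = pid, species = "locus", locus_name = lc$name,
             cell_id = geom2$cell_id, lineage_id = cyc$lineage_id,
             frame_index = grid$frame_index, time = grid$t_frame + d_off, tag = "second",
             x = p2$x, y = p2$y, state = st)
    )

    # sibling copy: fork at segregation start, leaves at division
    if (sched$replicated && sched$t_fork < cyc$t_div) {
      sg <- grid[grid$t_frame >= sched$t_fork, ]
      if (nrow(sg) > 0) {
        i0 <- match(sg$frame_index[1], grid$frame_index)
        st_s <- ifelse(sg$t_frame < sched$t_fork + lc$segregation_duration,
                       "segregating", "home")
        fl_l <- sim_fluct(sg$t_frame, sigma_for(st_s, "long"), lc$tau, fl_long[i0])
        fl_s <- sim_fluct(sg$t_frame, sigma_for(st_s, "short"), lc$tau, fl_short[i0])
        g1 <- cell_geometry_at(lineage, sg$t_frame, lane_x, width)
        g2 <- cell_geometry_at(lineage, sg$t_frame + d_off, lane_x, width)
        l1 <- sched$frac_sibling(sg$t_frame) * g1$length + fl_l
        l2 <- sched$frac_sibling(sg$t_frame + d_off) * g2$length + fl_l +
          rnorm(nrow(sg), 0, step_sd_for(st_s, "long"))
        s1 <- fl_s
        s2 <- fl_s + rnorm(nrow(sg), 0, step_sd_for(st_s, "short"))
        pp1 <- internal_to_lab(g1, l1, s1)
        pp2 <- internal_to_lab(g2, l2, s2)
        sid <- sprintf("%s_locS", cyc$cell_id)
        rows[[length(rows) + 1L]] <- bind_rows(
          tibble(particle_id = sid, species = "locus", locus_name = lc$name,
                 cell_id = g1$cell_id, lineage_id = cyc$lineage_id,
                 frame_index = sg$frame_index, time = sg$t_frame, tag = "first",
                 x = pp1$x, y = pp1$y, state = st_s),
          tibble(particle_id = sid, species = "locus", locus_name = lc$name,
                 cell_id = g2$cell_id, lineage_id = cyc$lineage_id,
                 frame_index = sg$frame_index, time = sg$t_frame + d_off, tag = "second",
                 x = pp2$x, y = pp2$y, state = st_s)
        )
      }
    }
  }
  bind_rows(rows) %>% arrange(.data$particle_id, .data$time)
}

#' Render noisy focus observations from ground-truth tracks
#'
#' Every ground-truth position visible at a scheduled frame (or its 1-s
#' doublet) yields one detected focus with isotropic Gaussian localization
#' error of the channel's SD; detections are dropped independently with the
#' configured miss probability. The locus channel is additionally passed
#' through the chromatic map of the `registration` config section (scale +
#' offset), emulating the uncorrected second-camera-region coordinates that
#' landmark registration must undo.
#'
#' @param truth Ground-truth tibble (rows from the track simulators).
#' @param config A [sim_config()].
#' @param seed Optional seed.
#'
#' @return Observations tibble: `obs_id`, `cell_id`, `lineage_id`,
#'   `frame_index`, `time`, `channel`, `tag`, `x`, `y`, `localization_sd`,
#'   `particle_id` (ground-truth link, for benchmarking only).
#' @export
render_observations <- function(truth, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(truth) == 0) {
    return(tibble(obs_id = character(), cell_id = character(),
                  lineage_id = character(), frame_index = integer(),
                  time = numeric(), channel = character(), tag = character(),
                  x = numeric(), y = numeric(), localization_sd = numeric(),
                  particle_id = character()))
  }
  nz <- config$noise
  keep <- runif(nrow(truth)) >= nz$miss_prob
  obs <- truth[keep, , drop = FALSE]
  channel <- ifelse(obs$species == "replisome", "replisome", "locus")
  loc_sd <- ifelse(channel == "replisome",
                   nz$localization_sd_replisome, nz$localization_sd_locus)
  x <- obs$x + rnorm(nrow(obs), 0, loc_sd)
  y <- obs$y + rnorm(nrow(obs), 0, loc_sd)
  is_loc <- channel == "locus"
  reg <- config$registration
  x[is_loc] <- reg$scale_x * x[is_loc] + reg$offset_x
  y[is_loc] <- reg$scale_y * y[is_loc] + reg$offset_y
  tibble(
    obs_id = sprintf("obs_%07d", seq_len(nrow(obs))),
    cell_id = obs$cell_id, lineage_id = obs$lineage_id,
    frame_index = obs$frame_index, time = obs$time,
    channel = channel, tag = obs$tag, x = x, y = y,
    localization_sd = loc_sd, particle_id = obs$particle_id
  )
}

#' Simulate a complete synthetic dataset
#'
#' Runs [simulate_lineage()], [simulate_replisome_track()],
#' [simulate_locus_track()] and [render_observations()] over `n_lineages`
#' independent lanes, plus [simulate_landmarks()] for channel registration.
#' Each lineage draws from its own RNG substream derived from the root seed,
#' so adding lineages does not perturb existing ones, and identical config +
#' seed reproduce the tables exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer root seed.
#'
#' @return An object of class `sim_dataset`: list of tibbles `cells`,
#'   `truth`, `observations`, `landmarks`, `events`, plus the `config` and
#'   `seed` used.
#' @examples
#' ds <- simulate_dataset(sim_config(sim = list(n_lineages = 2),
#'                                   schedule = list(duration = 60)), seed = 1)
#' dplyr::count(ds$observations, channel)
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  validate_sim_config(config)
  params <- replication_params(A_init = config$initiation$A_init,
                               T_d = config$growth$T_d,
                               C = config$initiation$C)
  n <- config$sim$n_lineages
  res <- vector("list", n)
  for (i in seq_len(n)) {
    lin_seed <- lineage_seed(seed, i)
    set.seed(lin_seed)
    lane_x <- (i - 1) * config$sim$lane_spacing
    lid <- sprintf("lin%03d", i)
    lin <- simulate_lineage(config, seed = NULL, lineage_id = lid, lane_x = lane_x)
    init_cycles <- lin$cycles[!is.na(lin$cycles$t_init), ]
    rep_truth <- purrr::map_dfr(seq_len(nrow(init_cycles)), function(j) {
      simulate_replisome_track(init_cycles[j, ], lin, config, lane_x)
    })
    loc_truth <- simulate_locus_track(lin, params, config, lane_x)
    truth <- bind_rows(rep_truth, loc_truth)
    obs <- render_observations(truth, config, seed = NULL)
    res[[i]] <- list(cells = lin$cells, events = lin$events, truth = truth, obs = obs)
  }
  set.seed(lineage_seed(seed, 0L))
  landmarks <- simulate_landmarks(
    n = config$registration$n_landmarks,
    offset = c(config$registration$offset_x, config$registration$offset_y),
    scale = c(config$registration$scale_x, config$registration$scale_y),
    jitter_sd = config$registration$landmark_jitter_sd,
    fov = config$registration$fov
  )
  out <- list(
    cells = bind_rows(purrr::map(res, "cells")),
    truth = bind_rows(purrr::map(res, "truth")),
    observations = bind_rows(purrr::map(res, "obs")),
    landmarks = landmarks,
    events = bind_rows(purrr::map(res, "events")),
    config = config, seed = seed
  )
  class(out) <- "sim_dataset"
  out
}

# deterministic 31-bit substream seed per lineage
lineage_seed <- function(root, i) {
  as.integer((as.numeric(root) * 48271 + i * 16807) %% 2147483647)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic replisome/locus dataset: %d lineages, %d cell-frames, %d foci (%d replisome / %d locus), seed %d\n",
    length(unique(x$cells$lineage_id)), nrow(x$cells), nrow(x$observations),
    sum(x$observations$channel == "replisome"),
    sum(x$observations$channel == "locus"), x$seed
  ))
  invisible(x)
}
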