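# Independent oracles used across the suite.

# Exhaustive minimum-cost one-to-one matching with a gate: enumerates every
# injective partial assignment by recursion, scoring matched costs plus half
# the gate per unmatched particle (the same objective the package's matcher
# optimizes, implemented independently). Returns the optimal objective value.
brute_force_match_cost <- function(cost, gate = Inf) {
  nr <- nrow(cost); nc <- ncol(cost)
  skip <- if (is.finite(gate)) gate / 2 else max(cost) + 1
  best <- Inf
  recurse <- function(i, used, acc) {
    if (acc >= best) return(invisible())
    if (i > nr) {
      best <<- min(best, acc + skip * sum(!used))
      return(invisible())
    }
    # row i unmatched
    recurse(i + 1, used, acc + skip)
    for (j in seq_len(nc)) {
      if (!used[j] && cost[i, j] <= gate) {
        used[j] <- TRUE
        recurse(i + 1, used, acc + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nc), 0)
  best
}

# objective value achieved by a matching vector (row -> col or NA)
matching_cost <- function(cost, m, gate = Inf) {
  skip <- if (is.finite(gate)) gate / 2 else max(cost) + 1
  matched <- which(!is.na(m))
  sum(cost[cbind(matched, m[matched])]) +
    skip * (sum(is.na(m)) + (ncol(cost) - length(matched)))
}

# closed-form RMSD of the stationary mean-reverting process
ou_rmsd_closed <- function(t, sigma, tau) sigma * sqrt(2 * (1 - exp(-t / tau)))

# minimal axis-aligned cell table: one cell spanning the given frames
make_cells <- function(cell_id = "c1", frames = 0:10, length = 3, width = 1,
                       orientation = pi / 2, old_pole_sign = 1L,
                       centroid = c(0, 0), lineage_id = "lin1",
                       area = NULL, time = NULL) {
  n <- length(frames)
  tibble::tibble(
    cell_id = cell_id, lineage_id = lineage_id,
    frame_index = as.integer(frames),
    time = if (is.null(time)) as.numeric(frames) else time,
    centroid_x = centroid[1], centroid_y = centroid[2],
    orientation = orientation, length = length, width = width,
    area = if (is.null(area)) length * width else area,
    parent_id = NA_character_, old_pole_sign = old_pole_sign
  )
}

# noise-free generator config (deterministic growth/division/initiation)
noise_free_config <- function(...) {
  base <- list(
    growth = list(division_cv = 0, growth_rate_cv = 0),
    initiation = list(area_cv = 0),
    replisome = list(sigma_long = 0, sigma_short = 0),
    locus = list(sigma_long = 0, sigma_short = 0,
                 step_sd_long = 0, step_sd_short = 0,
                 bound_step_sd_long = 0, bound_step_sd_short = 0),
    noise = list(localization_sd_replisome = 0, localization_sd_locus = 0,
                 miss_prob = 0),
    registration = list(offset_x = 0, offset_y = 0)
  )
  extra <- list(...)
  for (sec in names(extra)) base[[sec]] <- utils::modifyList(base[[sec]] %||% list(), extra[[sec]])
  do.call(sim_config, base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
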