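#' Synthetic-data generator configuration
#'
#' Builds the nested parameter list that drives the synthetic mother-machine
#' generator. Defaults are the intermediate-growth study conditions: 50 min
#' doubling time, replication initiation at 2.05 um^2 with a 45 min C-period,
#' two replisome clusters confined about the +/- quarter long-axis positions
#' with stationary SDs 0.177 um (long axis) and 0.085 um (short axis) --
#' calibrated as plateau / sqrt(2) from the ~0.25 / ~0.12 um RMSD plateaus --
#' and a 1/min frame schedule with paired frames 1 s apart.
#'
#' Overrides are supplied as named lists per section and merged into the
#' defaults; unknown sections or keys are rejected.
#'
#' @param ... Named sections (`growth`, `initiation`, `replisome`, `locus`,
#'   `noise`, `registration`, `schedule`, `sim`), each a named list of
#'   overrides. See Details for every key.
#'
#' @details
#' \describe{
#'   \item{growth}{`T_d` doubling time (min); `A_birth` mean birth area
#'     (um^2); `division_cv` lognormal CV of the division-size sizer (divides
#'     at `2 * A_birth` on average); `growth_rate_cv` per-cycle lognormal CV
#'     of the growth rate; `width` constant cell width (um), areas map to
#'     lengths as `L = A / width`.}
#'   \item{initiation}{`A_init` mean initiation area (um^2); `area_cv`
#'     lognormal CV of the per-cycle initiation threshold; `C` C-period (min).}
#'   \item{replisome}{`sigma_long`, `sigma_short` stationary confinement SDs
#'     (um); `tau` correlation time (min).}
#'   \item{locus}{`name`, `alpha` genomic fraction; `side_prob` probability
#'     that a cycle adopts the majority (old-pole-side) arrangement;
#'     `sigma_long`, `sigma_short`, `tau` confinement of the unreplicated
#'     locus; `step_sd_long`, `step_sd_short` 1-s step SD per axis outside the
#'     replisome; `bound_step_sd_long`, `bound_step_sd_short` 1-s step SD
#'     while colocalized with the replisome (`NULL` = the replisome's own 1-s
#'     step SD); `relocation_lead` (min) head start of the ramp toward the
#'     replisome; `replication_dwell` (min) time spent colocalized;
#'     `segregation_duration` (min); `ter_anchor` logical, terminus-style
#'     post-replication anchoring at mid-cell.}
#'   \item{noise}{`localization_sd_replisome`, `localization_sd_locus`
#'     isotropic localization error SD (um); `miss_prob` detection miss
#'     probability.}
#'   \item{registration}{chromatic map applied to the locus channel:
#'     `offset_x`, `offset_y` (um), `scale_x`, `scale_y`; plus landmark-bead
#'     generation (`n_landmarks`, `landmark_jitter_sd`, `fov` um).}
#'   \item{schedule}{`frame_interval` (min), `doublet_offset` (min, default
#'     1/60 = 1 s), `duration` (min).}
#'   \item{sim}{`n_lineages`, `lane_spacing` (um between channels).}
#' }
#'
#' @return A nested list of class `sim_config`.
#' @examples
#' cfg <- sim_config(locus = list(name = "mid-arm", alpha = 0.5))
#' cfg$locus$alpha
#' @export
sim_config <- function(...) {
  defaults <- list(
    growth = list(
      T_d = 50, A_birth = 1.85, division_cv = 0.1,
      growth_rate_cv = 0.05, width = 1.0
    ),
    initiation = list(A_init = 2.05, area_cv = 0.03, C = 45),
    replisome = list(sigma_long = 0.177, sigma_short = 0.085, tau = 3),
    locus = list(
      name = "Ori", alpha = 0.014648858, side_prob = 1.0,
      sigma_long = 0.25, sigma_short = 0.12, tau = 3,
      step_sd_long = 0.05, step_sd_short = 0.03,
      bound_step_sd_long = NULL, bound_step_sd_short = NULL,
      relocation_lead = 10, replication_dwell = 5,
      segregation_duration = 10, ter_anchor = FALSE
    ),
    noise = list(
      localization_sd_replisome = 0.02, localization_sd_locus = 0.02,
      miss_prob = 0.02
    ),
    registration = list(
      offset_x = 0.08, offset_y = -0.05, scale_x = 1.0, scale_y = 1.0,
      n_landmarks = 25, landmark_jitter_sd = 0.005, fov = 40
    ),
    schedule = list(frame_interval = 1, doublet_offset = 1 / 60, duration = 300),
    sim = list(n_lineages = 20, lane_spacing = 5)
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("sim_config() overrides must be named sections.")
    }
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      abort(paste0("Unknown config section(s): ", paste(bad, collapse = ", ")))
    }
    for (sec in names(overrides)) {
      ov <- overrides[[sec]]
      if (!is.list(ov)) abort(paste0("Section `", sec, "` must be a named list."))
      bad_keys <- setdiff(names(ov), names(defaults[[sec]]))
      if (length(bad_keys)) {
        abort(paste0("Unknown key(s) in `", sec, "`: ", paste(bad_keys, collapse = ", ")))
      }
      defaults[[sec]][names(ov)] <- ov
    }
  }
  cfg <- structure(defaults, class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pos <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      abort(paste0("Config value `", what, "` must be a single positive number."))
    }
  }
  nonneg <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
      abort(paste0("Config value `", what, "` must be a single non-negative number."))
    }
  }
  with(cfg$growth, {
    pos(T_d, "growth$T_d"); pos(A_birth, "growth$A_birth"); pos(width, "growth$width")
    nonneg(division_cv, "growth$division_cv"); nonneg(growth_rate_cv, "growth$growth_rate_cv")
  })
  with(cfg$initiation, {
    pos(A_init, "initiation$A_init"); nonneg(area_cv, "initiation$area_cv")
    nonneg(C, "initiation$C")
  })
  with(cfg$replisome, {
    nonneg(sigma_long, "replisome$sigma_long"); nonneg(sigma_short, "replisome$sigma_short")
    pos(tau, "replisome$tau")
  })
  with(cfg$locus, {
    if (alpha < 0 || alpha > 1) abort("Config value `locus$alpha` must lie in [0, 1].")
    if (side_prob < 0 || side_prob > 1) abort("Config value `locus$side_prob` must lie in [0, 1].")
    nonneg(sigma_long, "locus$sigma_long"); nonneg(sigma_short, "locus$sigma_short")
    pos(tau, "locus$tau")
    nonneg(step_sd_long, "locus$step_sd_long"); nonneg(step_sd_short, "locus$step_sd_short")
    nonneg(relocation_lead, "locus$relocation_lead")
    nonneg(replication_dwell, "locus$replication_dwell")
    nonneg(segregation_duration, "locus$segregation_duration")
  })
  with(cfg$noise, {
    nonneg(localization_sd_replisome, "noise$localization_sd_replisome")
    nonneg(localization_sd_locus, "noise$localization_sd_locus")
    if (miss_prob < 0 || miss_prob >= 1) abort("Config value `noise$miss_prob` must lie in [0, 1).")
  })
  with(cfg$schedule, {
    pos(frame_interval, "schedule$frame_interval"); pos(duration, "schedule$duration")
    pos(doublet_offset, "schedule$doublet_offset")
    if (doublet_offset >= frame_interval) {
      abort("`schedule$doublet_offset` must be shorter than the frame interval.")
    }
  })
  pos(cfg$sim$n_lineages, "sim$n_lineages")
  invisible(cfg)
}

# 1-s step SD per axis while bound at the replisome: configured value, or the
# replisome confinement process's own displacement SD over the doublet lag.
bound_step_sds <- function(cfg) {
  dt <- cfg$schedule$doublet_offset
  c(
    long = cfg$locus$bound_step_sd_long %||%
      ou_step_sd(cfg$replisome$sigma_long, cfg$replisome$tau, dt),
    short = cfg$locus$bound_step_sd_short %||%
      ou_step_sd(cfg$replisome$sigma_short, cfg$replisome$tau, dt)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
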