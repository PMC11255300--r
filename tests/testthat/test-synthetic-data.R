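test_that("confinement process has the stated stationary SD and autocorrelation", {
  set.seed(101)
  sigma <- 0.177; tau <- 3
  # displacement SD over a lag saturates at sqrt(2) sigma
  expect_equal(ou_step_sd(sigma, tau, 1e9), sqrt(2) * sigma, tolerance = 1e-9)
  expect_equal(ou_step_sd(sigma, tau, 0), 0)
  x <- replifoci:::ou_simulate(seq(0, 2e4), sigma, tau)
  n_eff <- length(x) / (2 * tau)  # decorrelated sample count
  se_sd <- sigma / sqrt(2 * n_eff)
  expect_lt(abs(sd(x) - sigma), 3 * se_sd)
  # lag-tau autocorrelation is 1/e
  ac <- cor(x[-seq_len(tau)], x[seq_len(length(x) - tau)])
  expect_lt(abs(ac - exp(-1)), 0.03)
})

test_that("noise-free lineage divides as a sizer and logs initiation at the threshold", {
  cfg <- noise_free_config(growth = list(A_birth = 1.3),
                           initiation = list(A_init = 2.05))
  lin <- simulate_lineage(cfg, seed = 1)
  cyc <- lin$cycles
  # division exactly at twice the birth area; daughters reborn at A_birth
  expect_equal(cyc$A_div, rep(2.6, nrow(cyc)))
  expect_equal(cyc$A_birth, rep(1.3, nrow(cyc)))
  # division events carry the division area
  div <- lin$events[lin$events$event == "division", ]
  expect_equal(div$area, rep(2.6, nrow(div)))
  # initiation logged at the threshold crossing
  ini <- lin$events[lin$events$event == "initiation", ]
  expect_equal(ini$area, rep(2.05, nrow(ini)))
  # first frame at or after each initiation has area >= threshold
  for (i in seq_len(nrow(ini))) {
    f <- lin$cells[lin$cells$frame_index == ini$frame_index[i] &
                     lin$cells$cell_id == ini$cell_id[i], ]
    expect_gte(f$area, 2.05)
  }
  # areas follow exponential growth within each cycle
  c1 <- lin$cells[lin$cells$cell_id == cyc$cell_id[1], ]
  expect_equal(c1$area, 1.3 * exp(log(2) / 50 * c1$time), tolerance = 1e-12)
})

test_that("zero-confinement replisome tracks sit exactly on the quarter positions", {
  cfg <- noise_free_config()
  lin <- simulate_lineage(cfg, seed = 2)
  ev <- lin$cycles[!is.na(lin$cycles$t_init), ][1, ]
  tr <- simulate_replisome_track(ev, lin, cfg)
  firsts <- tr[tr$tag == "first", ]
  pos <- to_internal_coords(firsts, lin$cells)
  in_mother <- pos$cell_id == ev$cell_id
  expect_true(all(abs(abs(pos$rel_long[in_mother]) - 0.25) < 1e-9))
  expect_true(all(abs(pos$short_offset) < 1e-9))
  # two particles, spanning one C-period from initiation
  expect_equal(length(unique(tr$particle_id)), 2)
  expect_lte(max(tr$time) - ev$t_init, cfg$initiation$C + 1e-9)
})

test_that("replisome fluctuations recover the configured stationary SD", {
  # frozen home: near-zero growth so L(t)/4 is constant
  cfg <- sim_config(growth = list(T_d = 1e8, A_birth = 2.5, division_cv = 0,
                                  growth_rate_cv = 0),
                    initiation = list(area_cv = 0, C = 1e7),
                    schedule = list(duration = 5000),
                    noise = list(miss_prob = 0, localization_sd_replisome = 0,
                                 localization_sd_locus = 0))
  set.seed(3)
  lin <- simulate_lineage(cfg, lineage_id = "lf")
  ev <- lin$cycles[1, ]
  expect_false(is.na(ev$t_init))  # born above threshold: initiation at birth
  tr <- simulate_replisome_track(ev, lin, cfg)
  pos <- to_internal_coords(tr[tr$tag == "first", ], lin$cells)
  up <- pos[pos$rel_long > 0, ]
  resid <- up$long_offset - up$length / 4
  n_eff <- nrow(up) / (2 * cfg$replisome$tau)
  expect_lt(abs(sd(resid) - 0.177), 3 * 0.177 / sqrt(2 * n_eff))
  resid_s <- up$short_offset
  expect_lt(abs(sd(resid_s) - 0.085), 3 * 0.085 / sqrt(2 * n_eff))
})

test_that("rendering adds the configured localization noise on the doublet schedule", {
  cfg <- sim_config(sim = list(n_lineages = 10), schedule = list(duration = 200),
                    noise = list(miss_prob = 0, localization_sd_replisome = 0.03,
                                 localization_sd_locus = 0.02),
                    registration = list(offset_x = 0, offset_y = 0))
  ds <- simulate_dataset(cfg, seed = 4)
  # schedule contract: every first-tag observation has its ground-truth row
  # and doublets sit exactly 1 s (1/60 min) after the frame
  tr_first <- ds$truth[ds$truth$tag == "first", ]
  tr_second <- ds$truth[ds$truth$tag == "second", ]
  expect_equal(nrow(tr_first), nrow(tr_second))
  key <- function(d) paste(d$particle_id, d$frame_index)
  expect_setequal(key(tr_first), key(tr_second))
  ord1 <- order(key(tr_first)); ord2 <- order(key(tr_second))
  expect_equal(tr_second$time[ord2] - tr_first$time[ord1],
               rep(1 / 60, nrow(tr_first)), tolerance = 1e-9)
  # per-axis localization error SD recovered over >= 1e4 observations
  m <- merge(ds$observations, ds$truth,
             by = c("particle_id", "frame_index", "tag"))
  is_rep <- m$channel == "replisome"
  rep_err <- c(m$x.x[is_rep] - m$x.y[is_rep], m$y.x[is_rep] - m$y.y[is_rep])
  expect_gt(length(rep_err), 1e4)
  expect_lt(abs(sd(rep_err) - 0.03), 3 * 0.03 / sqrt(2 * length(rep_err)))
  loc_err <- m$y.x[!is_rep] - m$y.y[!is_rep]
  expect_lt(abs(sd(loc_err) - 0.02), 3 * 0.02 / sqrt(2 * length(loc_err)))
})

test_that("noise-free rendering reproduces ground truth exactly", {
  cfg <- noise_free_config(sim = list(n_lineages = 1),
                           schedule = list(duration = 60))
  ds <- simulate_dataset(cfg, seed = 5)
  m <- merge(ds$observations, ds$truth,
             by = c("particle_id", "frame_index", "tag"))
  expect_equal(nrow(m), nrow(ds$truth))
  expect_equal(m$x.x, m$x.y, tolerance = 1e-12)
  expect_equal(m$y.x, m$y.y, tolerance = 1e-12)
})

test_that("identical config and seed reproduce the dataset; extra lineages do not perturb earlier ones", {
  cfg2 <- sim_config(sim = list(n_lineages = 2), schedule = list(duration = 100))
  a <- simulate_dataset(cfg2, seed = 99)
  b <- simulate_dataset(cfg2, seed = 99)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  expect_identical(a$cells, b$cells)
  cfg3 <- sim_config(sim = list(n_lineages = 3), schedule = list(duration = 100))
  c3 <- simulate_dataset(cfg3, seed = 99)
  keep <- c3$observations$lineage_id %in% c("lin001", "lin002")
  expect_equal(
    c3$observations[keep, setdiff(names(c3$observations), "obs_id")],
    a$observations[, setdiff(names(a$observations), "obs_id")]
  )
})

test_that("locus state machine follows home-relocating-replicating-segregating order and forks once", {
  cfg <- sim_config(sim = list(n_lineages = 4), schedule = list(duration = 250),
                    locus = list(alpha = 0.5, name = "mid"))
  ds <- simulate_dataset(cfg, seed = 6)
  loc <- ds$truth[ds$truth$species == "locus" & ds$truth$tag == "first", ]
  order_rank <- c(home = 1, relocating = 2, replicating = 3, segregating = 4)
  followed <- loc[!grepl("locS$", loc$particle_id), ]
  for (pid in unique(followed$particle_id)) {
    st <- followed$state[followed$particle_id == pid]
    r <- order_rank[st]
    # within a cycle ranks rise then may reset to home (rank 1) after segregation
    jumps <- diff(r)
    expect_true(all(jumps >= 0 | r[-1] == 1))
  }
  # one sibling fork per completed replication
  per_cell <- split(loc, loc$cell_id)
  for (d in per_cell) {
    completed <- any(d$state == "segregating" & !grepl("locS$", d$particle_id))
    n_forks <- length(unique(d$particle_id[grepl("locS$", d$particle_id)]))
    if (completed) expect_equal(n_forks, 1)
  }
})

test_that("replisome cluster count is two between initiation and termination, else zero", {
  cfg <- sim_config(sim = list(n_lineages = 3), schedule = list(duration = 200),
                    noise = list(miss_prob = 0))
  ds <- simulate_dataset(cfg, seed = 7)
  reps <- ds$truth[ds$truth$species == "replisome" & ds$truth$tag == "first", ]
  counts <- table(reps$cell_id, reps$frame_index)
  ini <- ds$events[ds$events$event == "initiation", ]
  for (i in seq_len(nrow(ini))) {
    cid <- ini$cell_id[i]
    t0 <- ini$time[i]
    cell_frames <- ds$cells[ds$cells$cell_id == cid, ]
    active <- cell_frames$time >= t0 & cell_frames$time <= t0 + cfg$initiation$C
    n_at <- reps |>
      subset(cell_id == cid) |>
      with(table(factor(frame_index, levels = cell_frames$frame_index)))
    expect_true(all(n_at[active] == 2))
    before <- cell_frames$time < t0
    expect_true(all(n_at[before] %in% 0:2))  # possible carry-over from mother
  }
})
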