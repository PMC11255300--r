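# helper: wrap per-trajectory internal-coordinate time series into an
# aligned set without running the tracker (events at t = 0 by construction)
make_aligned <- function(long_mat, short_mat = NULL, cluster = NULL,
                         dt = 1) {
  n_traj <- nrow(long_mat); n_t <- ncol(long_mat)
  if (is.null(short_mat)) short_mat <- matrix(0, n_traj, n_t)
  if (is.null(cluster)) cluster <- rep("upper", n_traj)
  out <- tibble::tibble(
    event_id = rep(sprintf("e%03d", seq_len(n_traj)), each = n_t),
    trajectory_id = rep(sprintf("t%03d", seq_len(n_traj)), each = n_t),
    cluster = rep(cluster, each = n_t),
    t_align = rep(seq(0, by = dt, length.out = n_t), n_traj),
    long_offset = as.vector(t(long_mat)),
    short_offset = as.vector(t(short_mat)),
    rel_long = as.vector(t(long_mat)) / 3,
    length = 3, area = 3, cell_id = "c1"
  )
  structure(out, class = c("aligned_trajectories", class(out)), window = (n_t - 1) * dt)
}

test_that("alignment re-times trajectories to their own initiation event", {
  cells <- make_cells("c1", frames = 0:30, length = 2, area = 2)
  obs <- tibble::tibble(
    lineage_id = "lin1", channel = "replisome", cell_id = "c1",
    frame_index = 10:30, time = as.numeric(10:30), x = 0, y = 0.5)
  linked <- link_foci(obs)
  ev <- detect_initiation(linked, cells, min_lifetime = 5)
  al <- align_on_initiation(linked, ev, cells, window = 20)
  expect_equal(range(al$t_align), c(0, 20))
  expect_equal(unique(al$cluster), "upper")

  # a trajectory with no event is excluded and logged
  obs2 <- dplyr::bind_rows(obs, tibble::tibble(
    lineage_id = "lin1", channel = "replisome", cell_id = "c1",
    frame_index = 25:27, time = as.numeric(25:27), x = 0, y = -0.6))
  linked2 <- link_foci(obs2)
  ev2 <- detect_initiation(linked2, cells, min_lifetime = 5,
                           exclusion_radius = 0.5)
  al2 <- align_on_initiation(linked2, ev2, cells, window = 20)
  expect_equal(length(attr(al2, "excluded")), 1)
})

test_that("drift subtraction annihilates a shared deterministic drift", {
  t_grid <- 0:20
  drift <- 0.02 * t_grid^1.3
  base <- matrix(rep(0.5 + drift, 30), nrow = 30, byrow = TRUE)
  base <- base + runif(30, -0.2, 0.2)  # different starting offsets, same drift
  al <- make_aligned(base)
  co <- subtract_net_drift(al)
  expect_true(all(abs(co$d_long_corr) < 1e-12))
  cu <- rmsd_curve(co)
  expect_true(all(cu$rmsd_long < 1e-12))
  # postcondition: zero ensemble mean displacement-from-start at every lag
  chk <- dplyr::summarise(dplyr::group_by(co, t_align),
                          m = mean(d_long_corr))
  expect_true(all(abs(chk$m) < 1e-12))
})

test_that("upper and lower clusters are corrected with mirrored signs", {
  t_grid <- 0:10
  up <- matrix(rep(0.5 + 0.03 * t_grid, 10), nrow = 10, byrow = TRUE)
  dn <- -up
  al <- make_aligned(rbind(up, dn), cluster = rep(c("upper", "lower"), each = 10))
  co <- subtract_net_drift(al)
  expect_true(all(abs(co$d_long_corr) < 1e-12))
  # without cluster separation the mirrored drifts would cancel and survive:
  # the per-cluster means must equal the cluster's own drift
  raw <- dplyr::summarise(dplyr::group_by(co, cluster, t_align),
                          m = mean(d_long), .groups = "drop")
  expect_equal(raw$m[raw$cluster == "upper" & raw$t_align == 10], 0.3)
  expect_equal(raw$m[raw$cluster == "lower" & raw$t_align == 10], -0.3)
})

test_that("RMSD of the confined process matches the closed form within 3 SEM", {
  set.seed(41)
  sigma <- 0.177; tau <- 3
  n_traj <- 500; t_grid <- 0:20
  xs <- t(vapply(seq_len(n_traj),
                 function(i) replifoci:::ou_simulate(t_grid, sigma, tau),
                 numeric(length(t_grid))))
  al <- make_aligned(0.5 + xs)
  co <- subtract_net_drift(al)
  cu <- rmsd_curve(co)
  for (tt in c(tau, 5 * tau)) {
    row <- cu[cu$t_align == tt, ]
    expected <- ou_rmsd_closed(tt, sigma, tau)
    expect_lt(abs(row$rmsd_long - expected), 3 * row$sem_long)
  }
  # plateau over a window far beyond tau approaches sqrt(2) sigma
  pl <- plateau_estimate(cu, c(10, 20))
  expect_lt(abs(pl$plateau[pl$axis == "long"] - sqrt(2) * sigma),
            3 * pl$sem[pl$axis == "long"])
})

test_that("plateau of a constant curve is the constant", {
  cu <- structure(tibble::tibble(
    t_align = 0:20, n = 100,
    rmsd_long = 0.25, sem_long = 0.01,
    rmsd_short = 0.12, sem_short = 0.01), class = c("rmsd_curve", "tbl_df", "tbl", "data.frame"))
  pl <- plateau_estimate(cu, c(10, 20))
  expect_equal(pl$plateau, c(0.25, 0.12))
  expect_error(plateau_estimate(cu, c(30, 40)), "lag_window")
})

test_that("net movement percentage reflects the ensemble outward drift", {
  t_grid <- 0:15
  # upper cluster drifts +0.12 um over the window, lower mirrors it
  up <- matrix(rep(0.75 + 0.008 * t_grid, 8), nrow = 8, byrow = TRUE)
  dn <- -up
  al <- make_aligned(rbind(up, dn), cluster = rep(c("upper", "lower"), each = 8))
  nm <- net_movement_percent(al, window = 15)
  expect_equal(nm$mean_outward_um, 0.12, tolerance = 1e-12)
  expect_equal(nm$pct_of_length, 100 * 0.12 / 3, tolerance = 1e-12)
  expect_equal(nm$n_trajectories, 16)
})

test_that("doublet displacements are computed in internal coordinates", {
  cells <- make_cells("c1", frames = 0:1, length = 3, area = 3)
  obs <- tibble::tibble(
    lineage_id = "lin1", channel = "locus", cell_id = "c1",
    frame_index = c(0L, 0L), time = c(0, 1 / 60),
    tag = c("first", "second"),
    x = c(0, 0), y = c(0.2, 0.25))
  rec <- compute_displacements(obs, cells)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$d_long, 0.05)   # +y is toward the old pole here
  expect_equal(rec$d_short, 0)
  expect_equal(rec$magnitude, 0.05)
  expect_equal(rec$long_offset, 0.2)

  # identical doublet positions give magnitude zero
  obs0 <- obs; obs0$y <- c(0.2, 0.2)
  expect_equal(compute_displacements(obs0, cells)$magnitude, 0)

  # unmatched doublets produce no record but are counted
  obs_u <- obs; obs_u$y <- c(0.2, 0.9)
  rec_u <- compute_displacements(obs_u, cells, max_link = 0.3)
  expect_equal(nrow(rec_u), 0)
  expect_equal(attr(rec_u, "n_unmatched"), 2L)
})

test_that("isotropic Gaussian steps have Rayleigh mean magnitude", {
  set.seed(42)
  n <- 20000; s <- 0.05
  cells <- make_cells("c1", frames = seq_len(n) - 1L, length = 3, area = 3)
  obs <- tibble::tibble(
    lineage_id = "lin1", channel = "locus", cell_id = "c1",
    frame_index = rep(seq_len(n) - 1L, 2),
    time = c(seq_len(n) - 1, seq_len(n) - 1 + 1 / 60),
    tag = rep(c("first", "second"), each = n),
    x = c(rep(0, n), rnorm(n, 0, s)),
    y = c(rep(0, n), rnorm(n, 0, s)))
  rec <- compute_displacements(obs, cells, max_link = Inf)
  expected <- s * sqrt(pi / 2)
  sem <- sd(rec$magnitude) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$magnitude) - expected), 3 * sem)
})

test_that("displacement magnitudes are invariant under lab-frame rotation", {
  set.seed(43)
  cells1 <- make_cells("c1", frames = 0:9, length = 3, area = 3,
                       orientation = pi / 2)
  obs1 <- tibble::tibble(
    lineage_id = "lin1", channel = "locus", cell_id = "c1",
    frame_index = rep(0:9, 2),
    time = rep(0:9, 2) + rep(c(0, 1 / 60), each = 10),
    tag = rep(c("first", "second"), each = 10),
    x = rnorm(20, 0, 0.1), y = rnorm(20, 0, 0.3))
  th <- 1.1
  rotxy <- function(x, y) list(x = cos(th) * x - sin(th) * y,
                               y = sin(th) * x + cos(th) * y)
  cells2 <- cells1; cells2$orientation <- cells1$orientation + th
  obs2 <- obs1; r <- rotxy(obs1$x, obs1$y); obs2$x <- r$x; obs2$y <- r$y
  r1 <- compute_displacements(obs1, cells1)
  r2 <- compute_displacements(obs2, cells2)
  expect_equal(r1$magnitude, r2$magnitude, tolerance = 1e-12)
  expect_equal(r1$d_long, r2$d_long, tolerance = 1e-12)
})

test_that("area-binned displacement summaries recover constructed populations", {
  rec <- tibble::tibble(area = c(rep(2.1, 50), rep(3.1, 50)),
                        magnitude = c(rep(0.04, 50), rep(0.09, 50)))
  prof <- displacement_by_area(rec, area_bins = c(2, 2.5, 3, 3.5))
  expect_equal(prof$mean[prof$n > 0], c(0.04, 0.09))
  expect_equal(prof$n, c(50L, 0L, 50L))
})

test_that("spatial map masks bins with four or fewer displacements, exactly", {
  rec <- tibble::tibble(
    long_offset = c(rep(0.05, 4), rep(0.25, 5), rep(-0.15, 6)),
    short_offset = 0.05,
    magnitude = c(rep(0.1, 4), rep(0.07, 5), rep(0.2, 6)),
    area = 2.5)
  m <- spatial_displacement_map(rec, long_bins = seq(-0.3, 0.3, 0.1),
                                short_bins = c(0, 0.1),
                                min_count_exclusive = 4)
  mt <- tibble::as_tibble(m)
  # exactly 4 -> masked; 5 -> reported with its mean; 6 -> reported
  b4 <- mt[mt$n == 4, ]; b5 <- mt[mt$n == 5, ]; b6 <- mt[mt$n == 6, ]
  expect_true(b4$masked); expect_true(is.na(b4$mean_disp))
  expect_false(b5$masked); expect_equal(b5$mean_disp, 0.07)
  expect_equal(b6$mean_disp, 0.2)
  # the reported set is exactly the bins with count > 4
  expect_setequal(which(!mt$masked), which(mt$n > 4))
  # empty input -> fully masked map
  m0 <- spatial_displacement_map(rec[0, ], long_bins = c(0, 0.1),
                                 short_bins = c(0, 0.1))
  expect_true(all(tibble::as_tibble(m0)$masked))
})

test_that("displacement minimum finds constructed vertices and flags flat profiles", {
  # V-shaped profile with vertex in bin 7 of ten 0.25-wide bins
  bins <- seq(2, 4.5, by = 0.25)
  mids <- (bins[-1] + bins[-length(bins)]) / 2
  depth <- abs(seq_along(mids) - 7)
  rec <- dplyr::bind_rows(lapply(seq_along(mids), function(i) {
    tibble::tibble(area = mids[i], magnitude = 0.05 + 0.01 * depth[i] +
                     rep(0, 30))
  }))
  mn <- find_displacement_minimum(rec, bins, smoothing_window = 3, n_boot = 50)
  expect_equal(mn$area_min, mids[7])
  expect_false(mn$flagged)

  # noiseless quadratic: argmin at the analytic vertex bin
  quad <- dplyr::bind_rows(lapply(seq_along(mids), function(i) {
    tibble::tibble(area = mids[i], magnitude = 0.03 + 0.002 * (mids[i] - 3.1)^2)
  }))
  mq <- find_displacement_minimum(quad, bins, smoothing_window = 1, n_boot = 20)
  expect_equal(mq$area_min, mids[which.min(abs(mids - 3.1))])

  flat <- tibble::tibble(area = rep(mids[1:4], each = 10), magnitude = 0.05)
  expect_warning(mf <- find_displacement_minimum(flat, bins, n_boot = 10),
                 "flat")
  expect_true(mf$flagged)
  expect_true(is.na(mf$area_min))
  expect_error(find_displacement_minimum(rec[rec$area < 2.6, ], bins),
               "3 non-empty")
})
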