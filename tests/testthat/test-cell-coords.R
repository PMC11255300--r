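test_that("internal coordinates recover analytic rotations and pole convention", {
  # axis-aligned: centroid maps to (0,0), old-pole tip to +L/2
  cells <- make_cells(length = 3, orientation = pi / 2, centroid = c(1, 2))
  foci <- tibble::tibble(cell_id = "c1", frame_index = 0L,
                         x = c(1, 1), y = c(2, 2 + 1.5))
  p <- to_internal_coords(foci, cells)
  expect_equal(p$long_offset, c(0, 1.5))
  expect_equal(p$short_offset, c(0, 0))
  expect_equal(p$rel_long, c(0, 0.5))

  # rotated cell: displacement along the rotated long axis projects cleanly
  th <- 30 * pi / 180
  cells_r <- make_cells(orientation = th, centroid = c(0.5, -0.2))
  foci_r <- tibble::tibble(cell_id = "c1", frame_index = 0L,
                           x = 0.5 + 0.3 * cos(th), y = -0.2 + 0.3 * sin(th))
  p_r <- to_internal_coords(foci_r, cells_r)
  expect_equal(p_r$long_offset, 0.3, tolerance = 1e-12)
  expect_equal(p_r$short_offset, 0, tolerance = 1e-12)

  # flipping the pole sign negates long_offset exactly, short unchanged
  cells_f <- make_cells(orientation = th, centroid = c(0.5, -0.2),
                        old_pole_sign = -1L)
  p_f <- to_internal_coords(foci_r, cells_f)
  expect_equal(p_f$long_offset, -p_r$long_offset)
  expect_equal(p_f$short_offset, p_r$short_offset)

  expect_error(
    to_internal_coords(tibble::tibble(cell_id = "nope", frame_index = 0L,
                                      x = 0, y = 0), cells),
    "no matching cell"
  )
})

test_that("internal -> lab -> internal round trip is the identity", {
  set.seed(11)
  th <- runif(1, 0, 2 * pi)
  geom <- tibble::tibble(centroid_x = 1.3, centroid_y = -0.7, orientation = th,
                         old_pole_sign = -1L)
  long <- runif(20, -1.5, 1.5); short <- runif(20, -0.5, 0.5)
  lab <- replifoci:::internal_to_lab(geom, long, short)
  cells <- make_cells(length = 3, orientation = th, centroid = c(1.3, -0.7),
                      old_pole_sign = -1L, frames = 0)
  back <- to_internal_coords(
    tibble::tibble(cell_id = "c1", frame_index = 0L, x = lab$x, y = lab$y), cells)
  expect_equal(back$long_offset, long, tolerance = 1e-12)
  expect_equal(back$short_offset, short, tolerance = 1e-12)
})

test_that("location histograms conserve mass per area bin", {
  cells <- dplyr::bind_rows(
    make_cells("c1", frames = 0:3, length = 2, area = 2),
    make_cells("c2", frames = 0:3, length = 2, area = 2.1)
  )
  set.seed(12)
  n <- 60
  foci <- tibble::tibble(
    cell_id = sample(c("c1", "c2"), n, TRUE),
    frame_index = sample(0:3, n, TRUE),
    x = runif(n, -0.4, 0.4), y = runif(n, -0.9, 0.9)
  )
  pos <- to_internal_coords(foci, cells)
  h <- build_location_histograms(pos, cells, area_bins = c(1.75, 2.25, 2.75),
                                 long_bins = seq(-1, 1, 0.1),
                                 short_bins = seq(-0.5, 0.5, 0.1))
  tot <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(h), area_bin),
    s = sum(value * n_cells), n_cells = max(n_cells))
  # all 8 cell-frames and all foci fall in the first area bin
  expect_equal(tot$s[1], n)
  expect_equal(tot$n_cells[1], 8)
  # empty area bin reported, not dropped
  expect_true(2 %in% tibble::as_tibble(h)$area_bin)
  expect_equal(sum(tibble::as_tibble(h)$count[tibble::as_tibble(h)$area_bin == 2]), 0)

  # all-coincident foci occupy a single spatial bin per area bin
  foci1 <- tibble::tibble(cell_id = "c1", frame_index = 0:3, x = 0.01, y = 0.01)
  h1 <- build_location_histograms(to_internal_coords(foci1, cells), cells,
                                  area_bins = c(1.75, 2.25),
                                  long_bins = seq(-1, 1, 0.1),
                                  short_bins = seq(-0.5, 0.5, 0.1))
  expect_equal(sum(tibble::as_tibble(h1)$count > 0), 1)
  expect_error(build_location_histograms(pos, cells, area_bins = c(2, 2)),
               "strictly increasing")
})

test_that("uniform scatter yields a flat histogram within sampling error", {
  cells <- make_cells("c1", frames = 0, length = 2, area = 2)
  set.seed(13)
  n <- 40000
  foci <- tibble::tibble(cell_id = "c1", frame_index = 0L,
                         x = runif(n, -0.5, 0.5), y = runif(n, -1, 1))
  pos <- to_internal_coords(foci, cells)
  h <- build_location_histograms(pos, cells, area_bins = c(1.5, 2.5),
                                 long_bins = seq(-1, 1, 0.5),
                                 short_bins = seq(-0.5, 0.5, 0.5))
  counts <- tibble::as_tibble(h)$count
  expected <- n / length(counts)
  expect_true(all(abs(counts - expected) < 4 * sqrt(expected)))
})

test_that("2D Normal location fits recover cluster means and SDs", {
  set.seed(14)
  cells <- make_cells("c1", frames = 0:199, length = 2.4, area = 2.4)
  n <- 200
  pos <- tibble::tibble(
    cell_id = "c1", frame_index = 0:199,
    long_offset = c(rnorm(n / 2, 0.6, 0.05), rnorm(n / 2, -0.6, 0.05)),
    short_offset = rnorm(n, 0, 0.08),
    area = 2.4
  )
  pos$rel_long <- pos$long_offset / 2.4
  fits <- fit_location_gaussian(pos, area_bins = c(2.25, 2.5))
  up <- fits[fits$cluster == "upper", ]
  expect_lt(abs(up$mean_long - 0.6), 3 * 0.05 / sqrt(n / 2))
  expect_lt(abs(up$sd_long - 0.05), 3 * 0.05 / sqrt(n))
  expect_true(all(fits$valid))

  # degenerate cluster: identical points give sd 0; small clusters flagged
  pos2 <- tibble::tibble(cell_id = "c1", frame_index = 0:4,
                         long_offset = 0.5, short_offset = 0.1,
                         rel_long = 0.2, area = 2.4)
  f2 <- fit_location_gaussian(pos2, area_bins = c(2.25, 2.5), min_n = 10)
  expect_equal(f2$sd_long, 0)
  expect_false(f2$valid)
})

test_that("birth-side classification splits the two chromosome arrangements", {
  cells <- dplyr::bind_rows(
    make_cells("c1", frames = 5:8), make_cells("c2", frames = 3:6))
  pos <- tibble::tibble(
    cell_id = c("c1", "c2", "c2"), frame_index = c(5L, 3L, 4L),
    rel_long = c(0.3, -0.3, 0.5))  # c2's frame-4 focus is not at birth
  lab <- classify_birth_side(pos, cells)
  expect_equal(lab$side[lab$cell_id == "c1"], "old-pole")
  expect_equal(lab$side[lab$cell_id == "c2"], "new-pole")
  # tie convention: exactly zero is old-pole
  tie <- classify_birth_side(
    tibble::tibble(cell_id = "c1", frame_index = 5L, rel_long = 0), cells)
  expect_equal(tie$side, "old-pole")
})

test_that("a 50/50 arrangement mixture is recovered within binomial error", {
  cfg <- sim_config(sim = list(n_lineages = 10), schedule = list(duration = 260),
                    locus = list(alpha = 0.1, side_prob = 0.5, name = "inv"))
  ds <- simulate_dataset(cfg, seed = 21)
  tr <- fit_channel_transform(ds$landmarks)
  loc_obs <- apply_channel_transform(
    ds$observations[ds$observations$channel == "locus" &
                      ds$observations$tag == "first", ], tr)
  pos <- to_internal_coords(loc_obs, ds$cells)
  lab <- classify_birth_side(pos, ds$cells)
  truth_sides <- ds$truth  # generator truth: compare against configured p
  n <- nrow(lab)
  p_hat <- mean(lab$side == "old-pole")
  expect_gt(n, 30)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n))
})
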