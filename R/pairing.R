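#' Simulate landmark beads for two-channel registration
#'
#' A grid of fiducial beads imaged in both fluorescence channels: the
#' reference (replisome) channel sees the true positions, the moving (locus)
#' channel sees them through a chromatic affine map (`scale * x + offset`),
#' and both carry independent localization jitter.
#'
#' @param n Number of beads (arranged on a near-square grid).
#' @param offset Length-2 chromatic translation (um).
#' @param scale Length-2 per-axis scale of the chromatic map.
#' @param jitter_sd Localization jitter SD per axis and channel (um).
#' @param fov Field-of-view side length (um).
#' @param seed Optional seed.
#'
#' @return Tibble: `landmark_id`, `x_ref`, `y_ref`, `x_mov`, `y_mov`.
#' @export
simulate_landmarks <- function(n = 25, offset = c(0.08, -0.05),
                               scale = c(1, 1), jitter_sd = 0.005,
                               fov = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  side <- ceiling(sqrt(n))
  g <- tidyr::expand_grid(gx = seq_len(side), gy = seq_len(side))[seq_len(n), ]
  x <- (g$gx - 0.5) / side * fov
  y <- (g$gy - 0.5) / side * fov
  tibble(
    landmark_id = sprintf("bead_%02d", seq_len(n)),
    x_ref = x + rnorm(n, 0, jitter_sd),
    y_ref = y + rnorm(n, 0, jitter_sd),
    x_mov = scale[1] * x + offset[1] + rnorm(n, 0, jitter_sd),
    y_mov = scale[2] * y + offset[2] + rnorm(n, 0, jitter_sd)
  )
}

#' Fit the channel-to-channel affine registration
#'
#' Least-squares 2D affine map from the moving (locus) channel to the
#' reference (replisome) channel, estimated from landmark beads imaged in
#' both channels. The residual RMS is computed by leave-one-out: each bead
#' is mapped by the transform fitted without it.
#'
#' @param landmarks Tibble with `x_mov`, `y_mov`, `x_ref`, `y_ref` (>= 3
#'   non-collinear beads).
#'
#' @return A `channel_transform` object: list with `A` (2x2 linear part),
#'   `b` (translation), `residual_rms` (um, leave-one-out), `n_landmarks`.
#' @export
fit_channel_transform <- function(landmarks) {
  req <- c("x_mov", "y_mov", "x_ref", "y_ref")
  if (!all(req %in% names(landmarks))) {
    abort("`landmarks` needs columns x_mov, y_mov, x_ref, y_ref.")
  }
  n <- nrow(landmarks)
  if (n < 3) abort("Need at least 3 landmark pairs for an affine fit.")
  X <- cbind(1, landmarks$x_mov, landmarks$y_mov)
  if (qr(X)$rank < 3) abort("Landmarks are collinear: affine fit is degenerate.")
  fit_one <- function(lm_tbl) {
    Xo <- cbind(1, lm_tbl$x_mov, lm_tbl$y_mov)
    co <- qr.solve(Xo, cbind(lm_tbl$x_ref, lm_tbl$y_ref))
    list(A = t(co[2:3, , drop = FALSE]), b = co[1, ])
  }
  full <- fit_one(landmarks)
  if (abs(det(full$A)) < 1e-8) abort("Fitted linear part is singular.")
  loo <- vapply(seq_len(n), function(i) {
    sub <- landmarks[-i, , drop = FALSE]
    Xs <- cbind(1, sub$x_mov, sub$y_mov)
    if (qr(Xs)$rank < 3) return(NA_real_)
    f <- fit_one(sub)
    pred <- f$A %*% c(landmarks$x_mov[i], landmarks$y_mov[i]) + f$b
    sum((pred - c(landmarks$x_ref[i], landmarks$y_ref[i]))^2)
  }, numeric(1))
  structure(
    list(A = full$A, b = full$b,
         residual_rms = sqrt(mean(loo, na.rm = TRUE)),
         n_landmarks = n),
    class = "channel_transform"
  )
}

#' Apply a channel transform to focus coordinates
#'
#' @param foci Tibble with `x`, `y` columns (moving-channel coordinates).
#' @param transform A [fit_channel_transform()] result (or `NULL` for the
#'   identity).
#' @return `foci` with `x`, `y` mapped into the reference channel.
#' @export
apply_channel_transform <- function(foci, transform) {
  if (is.null(transform)) return(foci)
  stopifnot(inherits(transform, "channel_transform"))
  xy <- t(transform$A %*% rbind(foci$x, foci$y) + transform$b)
  foci$x <- xy[, 1]
  foci$y <- xy[, 2]
  foci
}

#' @export
print.channel_transform <- function(x, ...) {
  cat("Two-channel affine registration (moving -> reference)\n")
  cat(sprintf("  linear part: [%.6f %.6f; %.6f %.6f]\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2]))
  cat(sprintf("  translation: (%.4f, %.4f) um\n", x$b[1], x$b[2]))
  cat(sprintf("  leave-one-out residual RMS: %.4f um over %d landmarks\n",
              x$residual_rms, x$n_landmarks))
  invisible(x)
}

#' @export
tidy.channel_transform <- function(x, ...) {
  tibble(
    term = c("a11", "a12", "a21", "a22", "tx", "ty"),
    estimate = c(x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$b[1], x$b[2])
  )
}

#' @export
glance.channel_transform <- function(x, ...) {
  tibble(residual_rms = x$residual_rms, n_landmarks = x$n_landmarks,
         det_linear = det(x$A))
}

#' Pair replisome and locus foci within cells
#'
#' After mapping the locus channel into the replisome channel with the
#' landmark registration, foci from the two channels in the same cell and
#' frame are paired one-to-one: pairs are the closest foci to each other in
#' the minimum-total-distance sense (optimal assignment), each focus is
#' paired with at most one focus from the other channel, and pairs farther
#' apart than `max_distance` are not formed.
#'
#' @param replisome_foci,locus_foci Focus tables (`cell_id`, `frame_index`,
#'   `x`, `y`; an optional `tag` column restricts pairing to matching tags).
#' @param transform Optional [fit_channel_transform()] result applied to
#'   `locus_foci` first.
#' @param max_distance Pairing gate (um).
#' @param cells Optional cell-frame tibble; when given, pairs are annotated
#'   with the cell area.
#'
#' @return Tibble of pairs: `cell_id`, `frame_index`, `time` (if present),
#'   `replisome_obs`, `locus_obs`, `distance`, and `area` when `cells` is
#'   supplied.
#' @export
match_foci <- function(replisome_foci, locus_foci, transform = NULL,
                       max_distance = 1, cells = NULL) {
  loc <- apply_channel_transform(locus_foci, transform)
  key_cols <- intersect(c("cell_id", "frame_index", "tag"),
                        intersect(names(replisome_foci), names(loc)))
  if (!all(c("cell_id", "frame_index") %in% key_cols)) {
    abort("Both focus tables need cell_id and frame_index columns.")
  }
  rep_df <- as.data.frame(replisome_foci)
  loc_df <- as.data.frame(loc)
  rep_df$.row <- seq_len(nrow(rep_df)); loc_df$.row <- seq_len(nrow(loc_df))
  r_split <- split(rep_df[c("x", "y", ".row")], interaction(rep_df[key_cols], drop = TRUE))
  l_split <- split(loc_df[c("x", "y", ".row")], interaction(loc_df[key_cols], drop = TRUE))
  ia <- integer(0); ib <- integer(0); dd <- numeric(0)
  for (g in names(r_split)) {
    a <- r_split[[g]]; b <- l_split[[g]]
    if (is.null(b) || nrow(b) == 0) next
    cost <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
    m <- match_min_cost(cost, gate = max_distance)
    ok <- which(!is.na(m))
    if (length(ok) == 0) next
    ia <- c(ia, a$.row[ok]); ib <- c(ib, b$.row[m[ok]])
    dd <- c(dd, cost[cbind(ok, m[ok])])
  }
  out <- if (length(ia)) {
    tibble(
      cell_id = rep_df$cell_id[ia],
      frame_index = rep_df$frame_index[ia],
      time = if ("time" %in% names(rep_df)) rep_df$time[ia] else NA_real_,
      replisome_obs = if ("obs_id" %in% names(rep_df)) rep_df$obs_id[ia] else NA_character_,
      locus_obs = if ("obs_id" %in% names(loc_df)) loc_df$obs_id[ib] else NA_character_,
      distance = dd
    )
  } else {
    tibble(cell_id = character(), frame_index = integer(), time = numeric(),
           replisome_obs = character(), locus_obs = character(),
           distance = numeric())
  }
  if (!is.null(cells)) {
    out <- out %>%
      left_join(cells %>% select("cell_id", "frame_index", "area"),
                by = c("cell_id", "frame_index"))
  }
  out
}

#' Replisome-locus distance distributions by cell area
#'
#' Per-area-bin summary of registered 2D replisome-locus pair distances;
#' the area of the minimum (located as for the displacement profiles) marks
#' the cell size at which the locus is replicated.
#'
#' @param pairs Output of [match_foci()] with an `area` column.
#' @param area_bins Area bin edges (um^2).
#' @inheritParams find_displacement_minimum
#'
#' @return A list with `profile` (an `area_profile` over `distance`) and
#'   `minimum` (the [find_displacement_minimum()] row for the distances).
#' @export
distance_by_area <- function(pairs, area_bins = NULL, smoothing_window = 3,
                             n_boot = 200) {
  if (!"area" %in% names(pairs) || anyNA(pairs$area)) {
    abort("`pairs` must carry a complete `area` column (pass `cells` to match_foci()).")
  }
  if (is.null(area_bins)) area_bins <- default_area_bins(pairs$area)
  profile <- displacement_by_area(pairs, area_bins, value = "distance")
  minimum <- find_displacement_minimum(pairs, area_bins, value = "distance",
                                       smoothing_window = smoothing_window,
                                       n_boot = n_boot)
  list(profile = profile, minimum = minimum)
}
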