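#' Tidy an RMSD curve into long format
#'
#' @param x An [rmsd_curve()] result.
#' @param ... Unused.
#' @return Tibble with `axis`, `t_align`, `rmsd`, `sem`, `n`.
#' @export
tidy.rmsd_curve <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(c("rmsd_long", "rmsd_short"),
                        names_to = "axis", values_to = "rmsd",
                        names_prefix = "rmsd_") %>%
    mutate(sem = ifelse(.data$axis == "long", .data$sem_long, .data$sem_short)) %>%
    select("axis", "t_align", "rmsd", "sem", "n")
}

#' One-row summary of an RMSD curve
#'
#' Plateau estimates (mean over the default 10-20 min lag window) per axis.
#'
#' @param x An [rmsd_curve()] result.
#' @param lag_window Lag window passed to [plateau_estimate()].
#' @param ... Unused.
#' @return One-row tibble: `plateau_long`, `sem_long`, `plateau_short`,
#'   `sem_short`, `n_lags`, `n_min`.
#' @export
glance.rmsd_curve <- function(x, lag_window = c(10, 20), ...) {
  pl <- plateau_estimate(x, lag_window)
  tibble(
    plateau_long = pl$plateau[pl$axis == "long"],
    sem_long = pl$sem[pl$axis == "long"],
    plateau_short = pl$plateau[pl$axis == "short"],
    sem_short = pl$sem[pl$axis == "short"],
    n_lags = pl$n_lags[1], n_min = pl$n_min[1]
  )
}
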