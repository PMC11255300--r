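#' Exponential growth rate from a doubling time
#'
#' For exponentially growing cells the per-minute growth rate is
#' `mu = ln(2) / T_d`, where `T_d` is the average doubling (generation) time.
#'
#' @param T_d Doubling time in minutes. Must be positive.
#'
#' @return Growth rate in 1/min.
#' @examples
#' growth_rate_from_doubling(50)
#' @export
growth_rate_from_doubling <- function(T_d) {
  if (!is.numeric(T_d) || any(!is.finite(T_d)) || any(T_d <= 0)) {
    abort("`T_d` must be a positive, finite doubling time in minutes.")
  }
  log(2) / T_d
}

#' Genomic fraction of a locus along its replichore
#'
#' A chromosomal locus is indexed by `alpha`, its genomic distance from
#' *oriC* divided by half the chromosome length, so that `alpha = 0` is the
#' origin and `alpha = 1` the terminus. The offset must be the shorter-arc
#' distance, i.e. measured along the locus's own replichore.
#'
#' @param offset_kb Genomic distance from *oriC* in kb, along the shorter arc.
#' @param chromosome_kb Chromosome length in kb. Default 4642 (E. coli MG1655).
#'
#' @return Fraction in `[0, 1]`.
#' @examples
#' locus_alpha(34)          # the oriC-proximal label used throughout
#' locus_alpha(2321)        # terminus
#' @export
locus_alpha <- function(offset_kb, chromosome_kb = 4642) {
  if (!is.numeric(chromosome_kb) || length(chromosome_kb) != 1 || chromosome_kb <= 0) {
    abort("`chromosome_kb` must be a single positive length in kb.")
  }
  if (!is.numeric(offset_kb) || any(offset_kb < 0)) {
    abort("`offset_kb` must be non-negative.")
  }
  if (any(offset_kb > chromosome_kb / 2)) {
    abort("`offset_kb` exceeds half the chromosome: supply the shorter-arc distance.")
  }
  pmin(pmax(offset_kb / (chromosome_kb / 2), 0), 1)
}

#' Replication-size model parameters
#'
#' Bundles the three parameters of the exponential replication-size model
#' `A(alpha) = A_init * exp(mu * C * alpha)`: the cell area at replication
#' initiation, the average doubling time (from which the growth rate
#' `mu = ln(2)/T_d` is derived), and the C-period (the time to replicate the
#' chromosome). Defaults are the intermediate-growth values: initiation at
#' 2.05 um^2, 50 min doubling time, 45 min C-period.
#'
#' @param A_init Cell area at replication initiation (um^2). Positive.
#' @param T_d Average doubling time (min). Positive.
#' @param C C-period, duration of chromosome replication (min). Non-negative.
#'
#' @return An object of class `replication_params`: a list with fields
#'   `A_init`, `T_d`, `C` and the derived rate `mu` (1/min).
#' @examples
#' p <- replication_params()
#' p$mu  # ln(2)/50
#' @export
replication_params <- function(A_init = 2.05, T_d = 50, C = 45) {
  if (!is.numeric(A_init) || length(A_init) != 1 || A_init <= 0) {
    abort("`A_init` must be a single positive area (um^2).")
  }
  if (!is.numeric(C) || length(C) != 1 || C < 0) {
    abort("`C` must be a single non-negative duration (min).")
  }
  mu <- growth_rate_from_doubling(T_d)
  structure(
    list(A_init = A_init, T_d = T_d, C = C, mu = mu),
    class = "replication_params"
  )
}

#' @export
print.replication_params <- function(x, ...) {
  cat("Replication-size model A(alpha) = A_init * exp(mu * C * alpha)\n")
  cat(sprintf("  A_init = %.3f um^2\n  T_d    = %.1f min (mu = %.6f /min)\n  C      = %.1f min\n",
              x$A_init, x$T_d, x$mu, x$C))
  invisible(x)
}

#' Predicted cell area at which a locus is replicated
#'
#' Evaluates the exponential replication-size model
#' `A(alpha) = A_init * exp(mu * C * alpha)`: with initiation at area
#' `A_init` and replication forks progressing at constant rate for the
#' C-period while the cell grows exponentially at rate `mu`, a locus at
#' genomic fraction `alpha` is replicated when the cell reaches `A(alpha)`.
#'
#' @param alpha Genomic fraction(s) in `[0, 1]` (see [locus_alpha()]).
#' @param params A [replication_params()] object.
#'
#' @return Predicted cell area(s) in um^2, monotone non-decreasing in `alpha`.
#' @examples
#' predicted_replication_area(0)               # == A_init
#' predicted_replication_area(c(0, 0.5, 1))
#' @export
predicted_replication_area <- function(alpha, params = replication_params()) {
  stopifnot(inherits(params, "replication_params"))
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha < 0 | alpha > 1)) {
    abort("`alpha` must lie in [0, 1].")
  }
  params$A_init * exp(params$mu * params$C * alpha)
}

#' Default locus panel
#'
#' The locus panel used for synthetic studies: the oriC-proximal label
#' (34 kb from *oriC*), four loci per replichore arm at evenly spaced
#' genomic fractions, and a terminus-proximal label (47 kb from *dif*).
#' Exact genomic coordinates for the arm loci are a modelling choice;
#' only the origin- and terminus-proximal offsets are anchored.
#'
#' @param chromosome_kb Chromosome length in kb used to convert offsets.
#'
#' @return A tibble with columns `name`, `alpha`, `arm`.
#' @export
default_loci <- function(chromosome_kb = 4642) {
  half <- chromosome_kb / 2
  tibble(
    name  = c("Ori", paste0("L", 1:4), paste0("R", 1:4), "Ter"),
    alpha = c(locus_alpha(34, chromosome_kb),
              seq(0.2, 0.8, by = 0.2), seq(0.2, 0.8, by = 0.2),
              locus_alpha(half - 47, chromosome_kb)),
    arm   = c("origin", rep("left", 4), rep("right", 4), "terminus")
  )
}
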