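# Minimum-cost one-to-one matching with a distance gate.
#
# Used by both the frame-to-frame focus linker and the two-channel focus
# pairing. Rows and columns may stay unmatched; pairs above the gate are
# forbidden. The objective is the summed cost of matched pairs plus half the
# gate per unmatched particle, which (i) forms every pair that is cheaper
# than leaving both sides unmatched, hence maximizes the number of gated
# pairs, and (ii) among those, minimizes total distance -- the behaviour of
# standard unbalanced-assignment solvers. Solved exactly by dynamic
# programming over column subsets for up to MATCH_EXACT_LIMIT columns,
# greedily (global-nearest-first) beyond that; generator defaults never
# exceed the exact regime.

MATCH_EXACT_LIMIT <- 12L

#' Minimum-cost one-to-one matching of two point sets
#'
#' @param cost Numeric matrix of pair costs (rows = first set, columns =
#'   second set), e.g. Euclidean distances.
#' @param gate Maximum admissible pair cost; pairs above it are never formed.
#'
#' @return Integer vector of length `nrow(cost)`: for each row, the matched
#'   column index or `NA` if unmatched.
#' @keywords internal
#' @export
match_min_cost <- function(cost, gate = Inf) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L) return(integer(0))
  if (nc == 0L) return(rep(NA_integer_, nr))
  allowed <- is.finite(cost) & cost <= gate
  if (!any(allowed)) return(rep(NA_integer_, nr))
  skip <- if (is.finite(gate)) gate / 2 else max(cost[allowed]) + 1
  if (nc <= MATCH_EXACT_LIMIT && nr <= MATCH_EXACT_LIMIT) {
    match_dp(cost, allowed, skip)
  } else {
    match_greedy(cost, allowed)
  }
}

# exact DP over subsets of columns; f(i, mask) = best cost for rows i..nr
# given used-column mask, each row either skips (cost `skip`) or takes an
# allowed column; unmatched columns cost `skip` each (added at the end as a
# constant for counting, so it is folded into the row-skip symmetry).
match_dp <- function(cost, allowed, skip) {
  nr <- nrow(cost); nc <- ncol(cost)
  n_states <- bitwShiftL(1L, nc)
  INF <- .Machine$double.xmax / 4
  f <- matrix(INF, nrow = nr + 1L, ncol = n_states)
  # terminal: each unused column pays its skip penalty
  n_used <- vapply(0:(n_states - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(nc - 1L))) > 0), numeric(1))
  f[nr + 1L, ] <- (nc - n_used) * skip
  choice <- matrix(NA_integer_, nrow = nr, ncol = n_states)
  for (i in nr:1) {
    for (m in 0:(n_states - 1L)) {
      best <- skip + f[i + 1L, m + 1L]  # row i unmatched
      pick <- NA_integer_
      for (j in seq_len(nc)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(m, bit) == 0L && allowed[i, j]) {
          v <- cost[i, j] + f[i + 1L, bitwOr(m, bit) + 1L]
          if (v < best - 1e-12) { best <- v; pick <- j }
        }
      }
      f[i, m + 1L] <- best
      choice[i, m + 1L] <- pick
    }
  }
  out <- rep(NA_integer_, nr)
  m <- 0L
  for (i in seq_len(nr)) {
    j <- choice[i, m + 1L]
    if (!is.na(j)) {
      out[i] <- j
      m <- bitwOr(m, bitwShiftL(1L, j - 1L))
    }
  }
  out
}

match_greedy <- function(cost, allowed) {
  nr <- nrow(cost); nc <- ncol(cost)
  out <- rep(NA_integer_, nr)
  work <- cost
  work[!allowed] <- Inf
  used_r <- logical(nr); used_c <- logical(nc)
  repeat {
    if (all(used_r) || all(used_c) || !any(is.finite(work))) break
    ij <- arrayInd(which.min(work), dim(work))
    i <- ij[1]; j <- ij[2]
    if (!is.finite(work[i, j])) break
    out[i] <- j
    used_r[i] <- TRUE; used_c[j] <- TRUE
    work[i, ] <- Inf; work[, j] <- Inf
  }
  out
}
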