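#' Cohort trace over the three health states
#'
#' A `cohort_trace` records, for cycles `0 .. n_cycles`, the fraction of the
#' cohort in each of the three mutually exclusive states: progression-free
#' (`pfs`), progressed disease (`pd`) and `dead`. Every row sums to 1, `dead`
#' is non-decreasing, `pfs` is non-increasing and `pd` is non-negative;
#' cycle 0 is always `(1, 0, 0)`.
#'
#' Two constructions are provided, both driven by the arm's progression-free
#' and overall survival curves:
#'
#' * [build_partitioned_trace()] -- classical partitioned survival:
#'   `pfs = min(S_PFS, S_OS)`, `dead = 1 - S_OS`, `pd` the remainder. The
#'   `min` cap keeps `pd` non-negative should the fitted curves cross.
#' * [build_markov_trace()] -- a per-cycle Markov chain whose transition
#'   probabilities come from the same curves: every alive state faces the OS
#'   death probability `1 - S_OS(t+1)/S_OS(t)`, and PFS occupants additionally
#'   face the progression probability `1 - S_PFS(t+1)/S_PFS(t)`. In closed
#'   form `pfs = S_PFS * S_OS`, while `dead = 1 - S_OS` exactly as in the
#'   partitioned construction.
#'
#' @param pfs,os [llogis_params()] for the arm's PFS and OS curves.
#' @param n_cycles Number of 21-day cycles (>= 1).
#' @return A `cohort_trace` object: data frame with columns
#'   `cycle, pfs, pd, dead`.
#' @examples
#' tr <- build_partitioned_trace(llogis_params(-3.0531, 2.1872),
#'                               llogis_params(-3.2726, 1.4703), 260)
#' fraction_dead(tr, 260)
#' @export
build_partitioned_trace <- function(pfs, os, n_cycles) {
  s <- .trace_curves(pfs, os, n_cycles)
  occ_pfs <- pmin(s$pfs, s$os)
  .new_trace(n_cycles, occ_pfs, s$os - occ_pfs, 1 - s$os, method = "partitioned")
}

#' @rdname build_partitioned_trace
#' @export
build_markov_trace <- function(pfs, os, n_cycles) {
  s <- .trace_curves(pfs, os, n_cycles)
  occ_pfs <- s$pfs * s$os
  .new_trace(n_cycles, occ_pfs, s$os - occ_pfs, 1 - s$os, method = "markov")
}

#' @rdname build_partitioned_trace
#' @param method `"markov"` or `"partitioned"`.
#' @export
build_trace <- function(pfs, os, n_cycles,
                        method = c("markov", "partitioned")) {
  method <- match.arg(method)
  if (method == "markov") build_markov_trace(pfs, os, n_cycles)
  else build_partitioned_trace(pfs, os, n_cycles)
}

.trace_curves <- function(pfs, os, n_cycles) {
  stopifnot(inherits(pfs, "llogis_params"), inherits(os, "llogis_params"))
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1) {
    stop("`n_cycles` must be a count >= 1", call. = FALSE)
  }
  t <- 0:n_cycles
  list(pfs = llogis_survival(pfs, t), os = llogis_survival(os, t))
}

.new_trace <- function(n_cycles, pfs, pd, dead, method) {
  tr <- structure(
    data.frame(cycle = 0:n_cycles, pfs = pfs, pd = pd, dead = dead),
    class = c("cohort_trace", "data.frame"),
    method = method, n_cycles = as.integer(n_cycles))
  validate_trace(tr)
  tr
}

#' Validate the invariants of a cohort trace
#'
#' Checks row-sum conservation (within 1e-9), state ranges, monotonicity of
#' `dead` (non-decreasing) and `pfs` (non-increasing), and the cycle-0 state.
#'
#' @param trace A `cohort_trace`.
#' @return `trace`, invisibly; errors on violation.
#' @export
validate_trace <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  occ <- as.matrix(trace[c("pfs", "pd", "dead")])
  if (any(abs(rowSums(occ) - 1) > 1e-9)) {
    stop("trace rows do not sum to 1", call. = FALSE)
  }
  if (any(occ < -1e-12)) stop("negative state occupancy", call. = FALSE)
  if (any(diff(trace$dead) < -1e-12)) {
    stop("`dead` occupancy must be non-decreasing", call. = FALSE)
  }
  if (any(diff(trace$pfs) > 1e-12)) {
    stop("`pfs` occupancy must be non-increasing", call. = FALSE)
  }
  if (abs(trace$pfs[1] - 1) > 1e-12 || abs(trace$pd[1]) > 1e-12) {
    stop("cycle 0 must be (1, 0, 0)", call. = FALSE)
  }
  invisible(trace)
}

#' Fraction of the cohort dead at a given cycle
#'
#' @param trace A `cohort_trace`.
#' @param cycle Cycle index in `0 .. n_cycles`.
#' @return The `dead` occupancy at that cycle.
#' @export
fraction_dead <- function(trace, cycle) {
  stopifnot(inherits(trace, "cohort_trace"))
  n <- attr(trace, "n_cycles")
  if (!is.numeric(cycle) || length(cycle) != 1L || cycle < 0 || cycle > n) {
    stop("`cycle` out of range 0..", n, call. = FALSE)
  }
  trace$dead[trace$cycle == as.integer(cycle)]
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- attr(x, "n_cycles")
  cat(sprintf("cohort trace (%s), %d cycles of 21 days\n",
              attr(x, "method"), n))
  cat(sprintf("  dead at final cycle: %.4f\n", x$dead[nrow(x)]))
  show <- x[x$cycle %in% unique(round(seq(0, n, length.out = 6))), ]
  print.data.frame(show, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export a trace as CSV (`cycle,pfs,pd,dead`)
#'
#' @param trace A `cohort_trace`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
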