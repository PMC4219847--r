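#' Integrate the mean-field battle dynamics
#'
#' Solves the deterministic rate equations (see [ode_rhs()]) with a stiff-
#' capable adaptive solver.  The rate constants span about five orders of
#' magnitude, so tight tolerances and `lsoda`'s automatic stiff/non-stiff
#' switching are used.  Integration stops early once the dynamics are
#' stationary (infinity norm of the right-hand side below `stat_tol`),
#' which is how an absorbing state is detected long before `t_end`.
#'
#' @param initial non-negative initial abundances `(nA, nB, nAB, nABB,
#'   nABBB)`.
#' @param constants rate constants `k1..k15`.
#' @param t_end integration horizon in seconds (default `1e6`).
#' @param grid_step output grid spacing in seconds; default places 200
#'   points on `[0, t_end]`.
#' @param rtol,atol relative and absolute solver tolerances.
#' @param stat_tol stationarity tolerance on `max |d state / dt|`.
#' @return object of class `battle_trajectory`: a data frame with columns
#'   `time`, the five species, the cumulative casualty counters `deadA`
#'   and `deadB` (integrated alongside the state but not part of it),
#'   `totalA`, `totalB`, and attributes `constants`, `stationary`
#'   (logical: did the run reach stationarity before `t_end`).
#' @examples
#' tr <- battle_ode(c(10, 10, 0, 0, 0), battle_constants("expM"))
#' tail(tr, 1)[, c("totalA", "totalB")]   # B wiped out, A survives
#' @export
battle_ode <- function(initial, constants, t_end = 1e6, grid_step = NULL,
                       rtol = 1e-8, atol = 1e-10, stat_tol = 1e-10) {
  y0 <- as_state(initial)
  k <- as_constants(constants)
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) || t_end <= 0)
    stop("t_end must be a positive finite number of seconds")
  if (is.null(grid_step)) grid_step <- t_end / 200
  times <- unique(c(seq(0, t_end, by = grid_step), t_end))

  sol <- deSolve::lsodar(y = c(y0, deadA = 0, deadB = 0), times = times,
                         func = "battle_derivs",
                         rootfunc = "battle_root", nroot = 1,
                         dllname = "antbattle", initfunc = "battle_initparms",
                         parms = c(k, stat_tol), rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("ODE solver failed (istate = ", diagn[1], "); see deSolve diagnostics")
  stationary <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot")) > 0
  sol <- as.data.frame(sol)
  names(sol) <- c("time", SPECIES, "deadA", "deadB")
  # clip negative round-off
  sol[SPECIES] <- lapply(sol[SPECIES], pmax, 0)
  tot <- population_totals(sol[SPECIES])
  sol$totalA <- tot[, "totalA"]
  sol$totalB <- tot[, "totalB"]
  structure(sol,
            constants = k,
            stationary = stationary,
            class = c("battle_trajectory", "data.frame"))
}

#' @export
print.battle_trajectory <- function(x, ...) {
  fin <- x[nrow(x), ]
  cat("Mean-field battle trajectory:", nrow(x), "time points,",
      "t in [0, ", format(max(x$time)), "] s\n", sep = " ")
  cat(sprintf("  final totals: totalA = %.4g, totalB = %.4g%s\n",
              fin$totalA, fin$totalB,
              if (isTRUE(attr(x, "stationary"))) "  (stationary)" else ""))
  invisible(x)
}

#' Classify the asymptotic outcome of a battle trajectory
#'
#' The mean-field dynamics have no interior fixed points: every battle ends
#' in one of two absorbing states, extinction of the B total or of the A
#' total.  A species is called extinct when its total drops below
#' `threshold` (default 0.5 individuals, i.e. "less than one ant" in a
#' continuum description).
#'
#' @param trajectory a `battle_trajectory` from [battle_ode()].
#' @param threshold extinction threshold on the totals (individuals).
#' @param stat_tol stationarity tolerance on the final right-hand side
#'   (looser than the integrator's early-exit root so a run stopped at
#'   stationarity always classifies as stationary).
#' @return one of `"A_wins"`, `"B_wins"`, `"draw"` (both totals below
#'   threshold: the separatrix case), `"stalemate"` (stationary with both
#'   totals above threshold, e.g. all rates zero), `"undecided"` (the
#'   dynamics were still moving at the end of the trajectory).
#' @export
classify_outcome <- function(trajectory, threshold = 0.5, stat_tol = 1e-8) {
  if (!inherits(trajectory, "battle_trajectory") || nrow(trajectory) == 0L)
    stop("trajectory must be a non-empty battle_trajectory")
  fin <- trajectory[nrow(trajectory), ]
  state <- as.numeric(fin[SPECIES])
  k <- attr(trajectory, "constants")
  stationary <- isTRUE(attr(trajectory, "stationary")) ||
    max(abs(ode_rhs(state, k))) < stat_tol
  tA <- fin$totalA; tB <- fin$totalB
  if (tA >= threshold && tB < threshold) return("A_wins")
  if (tB >= threshold && tA < threshold) return("B_wins")
  if (tA < threshold && tB < threshold) return("draw")
  if (stationary) "stalemate" else "undecided"
}

#' Write / read a trajectory as CSV
#'
#' Columns `time,nA,nB,nAB,nABB,nABBB,totalA,totalB`.
#'
#' @param trajectory a `battle_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory)[c("time", SPECIES, "totalA", "totalB")],
                   path, row.names = FALSE)
  invisible(path)
}
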