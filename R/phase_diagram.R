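# Integrate one initial condition and return its classification together
# with the final totals.  The side comparator used by the separatrix
# bisection: a decided outcome wins outright; a draw/stalemate cell is
# assigned to the A side when the final totalA - totalB difference is
# non-negative (with symmetric duel constants the difference is conserved,
# so strict win/lose classification alone would leave a band of draws
# around the bisectrix).
classify_initial <- function(nA0, nB0, constants, t_end = 1e6,
                             threshold = 0.5) {
  tr <- battle_ode(c(nA0, nB0, 0, 0, 0), constants, t_end = t_end,
                   grid_step = t_end / 50)
  fin <- tr[nrow(tr), ]
  list(outcome = classify_outcome(tr, threshold = threshold),
       totalA = fin$totalA, totalB = fin$totalB)
}

a_side <- function(cl) {
  switch(cl$outcome,
         A_wins = TRUE, B_wins = FALSE,
         cl$totalA - cl$totalB >= 0)
}

#' Battle outcome over a grid of initial force sizes
#'
#' Integrates the mean-field model from every initial condition
#' `(nA0, nB0, 0, 0, 0)` on the integer grid and classifies the absorbing
#' outcome.  This is the raw material of the supremacy phase diagram.
#'
#' @param constants rate constants `k1..k15`.
#' @param nA_range,nB_range integer vectors of initial lone-fighter
#'   counts.
#' @param t_end integration horizon in seconds.
#' @param threshold extinction threshold (individuals).
#' @return data frame of class `outcome_grid`: `nA0`, `nB0`, `outcome`
#'   (factor; `"error"` marks a failed integration), `totalA`, `totalB`
#'   (final totals).
#' @export
outcome_grid <- function(constants, nA_range, nB_range, t_end = 1e6,
                         threshold = 0.5) {
  k <- as_constants(constants)
  cells <- expand.grid(nA0 = nA_range, nB0 = nB_range)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- tryCatch(classify_initial(cells$nA0[i], cells$nB0[i], k,
                                    t_end = t_end, threshold = threshold),
                   error = function(e) list(outcome = "error",
                                            totalA = NA, totalB = NA))
    data.frame(nA0 = cells$nA0[i], nB0 = cells$nB0[i],
               outcome = cl$outcome, totalA = cl$totalA, totalB = cl$totalB)
  })
  out <- do.call(rbind, res)
  class(out) <- c("outcome_grid", "data.frame")
  out
}

#' Critical initial A force against a given B force (separatrix point)
#'
#' For a fixed `nB0`, bisects on the real-valued initial `nA0` (the
#' mean-field is a continuum, so fractional initial forces are meaningful)
#' until the bracket around the boundary between the A-winning and
#' B-winning regions is narrower than `tol`.  The set of these critical
#' values over `nB0` forms the separatrix of the supremacy phase diagram.
#'
#' @param constants rate constants.
#' @param nB0 initial B force.
#' @param nA_bracket length-2 bracket on `nA0` whose endpoints fall on
#'   opposite sides.
#' @param tol bracket-width tolerance (default 0.01 individuals).
#' @param t_end integration horizon.
#' @return the critical `nA0*` (bracket midpoint at termination).
#' @export
separatrix_point <- function(constants, nB0, nA_bracket = c(0.1, 4 * nB0),
                             tol = 0.01, t_end = 1e6) {
  k <- as_constants(constants)
  lo <- nA_bracket[1]; hi <- nA_bracket[2]
  side_lo <- a_side(classify_initial(lo, nB0, k, t_end))
  side_hi <- a_side(classify_initial(hi, nB0, k, t_end))
  if (side_lo == side_hi)
    stop("invalid bracket: both endpoints fall on the same side")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (a_side(classify_initial(mid, nB0, k, t_end)) == side_hi) hi <- mid
    else lo <- mid
  }
  (lo + hi) / 2
}

#' Separatrix of the supremacy phase diagram
#'
#' Computes the critical initial A force for each B force in `nB_values`.
#'
#' @param constants rate constants.
#' @param nB_values initial B forces to scan.
#' @param tol bisection tolerance.
#' @param t_end integration horizon.
#' @return data frame of class `separatrix`: `nB0`, `nA0_crit`.
#' @export
separatrix <- function(constants, nB_values, tol = 0.01, t_end = 1e6) {
  crit <- vapply(nB_values, function(b)
    separatrix_point(constants, b, tol = tol, t_end = t_end), numeric(1))
  out <- data.frame(nB0 = nB_values, nA0_crit = crit)
  class(out) <- c("separatrix", "data.frame")
  out
}

#' Project a trajectory onto the plane of population totals
#'
#' Although the dynamical state is five-dimensional, projected onto the
#' `(totalB, totalA)` plane the deterministic trajectories never
#' intersect, which is what makes the two-dimensional phase portrait
#' meaningful.
#'
#' @param trajectory a `battle_trajectory`.
#' @return data frame with columns `totalB`, `totalA` (parametrised by
#'   time, in trajectory order).
#' @export
totals_projection <- function(trajectory) {
  if (!inherits(trajectory, "battle_trajectory"))
    stop("need a battle_trajectory")
  data.frame(totalB = trajectory$totalB, totalA = trajectory$totalA)
}

#' Do two projected trajectories cross?
#'
#' Pairwise proper-intersection test between the segments of two planar
#' curves (shared endpoints of consecutive segments of the same curve are
#' ignored).
#'
#' @param p1,p2 data frames from [totals_projection()].
#' @return logical.
#' @export
curves_cross <- function(p1, p2) {
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- cross2(b2 - b1, a1 - b1)
    d2 <- cross2(b2 - b1, a2 - b1)
    d3 <- cross2(a2 - a1, b1 - a1)
    d4 <- cross2(a2 - a1, b2 - a1)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  m1 <- as.matrix(p1); m2 <- as.matrix(p2)
  for (i in seq_len(nrow(m1) - 1L)) {
    for (j in seq_len(nrow(m2) - 1L)) {
      if (seg_int(m1[i, ], m1[i + 1L, ], m2[j, ], m2[j + 1L, ])) return(TRUE)
    }
  }
  FALSE
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Linearity diagnostics of a separatrix
#'
#' Least-squares line `nA0_crit ~ nB0` through the separatrix points and
#' its coefficient of determination.  Above roughly ten individuals per
#' side the separatrix is essentially linear, which justifies treating a
#' large battle as a superposition of small local sub-battles; below ten,
#' group-fighting nonlinearity bends it.
#'
#' @param sep a `separatrix` data frame (>= 3 points).
#' @return list: `intercept`, `slope`, `r_squared`, `fit` (the `lm`
#'   object).
#' @export
separatrix_linearity <- function(sep) {
  if (nrow(sep) < 3L) stop("need at least 3 separatrix points")
  fit <- stats::lm(nA0_crit ~ nB0, data = sep)
  ss_tot <- sum((sep$nA0_crit - mean(sep$nA0_crit))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r_squared = r2,
       fit = fit)
}

#' Plot a supremacy phase diagram
#'
#' Flux lines (projected trajectories from a fan of initial conditions),
#' the separatrix, and the bisectrix `totalA = totalB`.
#'
#' @param constants rate constants (default: the optimized `"expM"` set).
#' @param nB_values B forces for the separatrix scan.
#' @param fan list of `c(nA0, nB0)` initial conditions for flux lines, or
#'   `NULL` to skip.
#' @param t_end integration horizon.
#' @param tol separatrix tolerance.
#' @return invisibly, a list with the `separatrix` and the list of
#'   projected trajectories.
#' @export
plot_phase_diagram <- function(constants = battle_constants("expM"),
                               nB_values = 2:20, fan = NULL, t_end = 1e6,
                               tol = 0.05) {
  sep <- separatrix(constants, nB_values, tol = tol, t_end = t_end)
  if (is.null(fan))
    fan <- lapply(seq(2, 20, by = 3), function(a)
      lapply(c(0.6, 1, 1.6), function(f) c(a, max(1, round(f * a)))))
  fan <- if (is.list(fan[[1]])) unlist(fan, recursive = FALSE) else fan
  projs <- lapply(fan, function(ic)
    totals_projection(battle_ode(c(ic[1], ic[2], 0, 0, 0), constants,
                                 t_end = t_end, grid_step = t_end / 400)))
  rng <- c(0, max(nB_values, vapply(fan, max, numeric(1))))
  plot(NA, xlim = rng, ylim = rng, xlab = "total B", ylab = "total A",
       main = "Supremacy phase diagram")
  for (p in projs) graphics::lines(p$totalB, p$totalA, col = "grey60")
  graphics::abline(0, 1, col = "darkgreen", lty = 3)
  graphics::lines(sep$nB0, sep$nA0_crit, col = "red", lty = 2, lwd = 2)
  graphics::legend("topleft", c("flux lines", "separatrix", "bisectrix"),
                   col = c("grey60", "red", "darkgreen"), lty = c(1, 2, 3),
                   bty = "n")
  invisible(list(separatrix = sep, projections = projs))
}
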