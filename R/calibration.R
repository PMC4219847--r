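# Integrate the mean-field model and return the states exactly at `times`.
# Plain lsoda (no stationarity root): calibration needs values on the data
# grid.  Used by the objective, so it must be cheap and robust.
integrate_states <- function(initial, k, times, rtol = 1e-8, atol = 1e-10) {
  t0 <- times
  prepend <- t0[1] > 0
  if (prepend) t0 <- c(0, t0)
  sol <- deSolve::lsoda(y = as_state(initial), times = t0,
                        func = "battle_derivs", dllname = "antbattle",
                        initfunc = "battle_initparms",
                        parms = c(as_constants(k), 0),
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("ODE solver failed during calibration")
  m <- unname(sol[, -1, drop = FALSE])
  if (prepend) m <- m[-1, , drop = FALSE]
  m[m < 0] <- 0
  colnames(m) <- SPECIES
  m
}

#' Sample-and-hold an event series onto a time grid
#'
#' Battle logs are event-driven; calibration needs values on a common
#' grid.  The held value at grid time t is the state at the latest event
#' at or before t (zero-order hold, right-continuous: a grid point exactly
#' at an event time takes that event's row).  Grid points before the first
#' logged row take the first row (the series' initial state).
#'
#' @param series an `event_series`.
#' @param grid increasing vector of times (seconds).
#' @return a `gridded_series`: data frame with `time` and the five species
#'   columns.
#' @export
sample_and_hold <- function(series, grid) {
  if (is.null(series) || nrow(series) == 0L) stop("empty event series")
  if (any(diff(grid) <= 0)) stop("grid times must increase")
  held <- hold_states(series, grid)
  df <- data.frame(time = grid, held)
  names(df) <- c("time", SPECIES)
  class(df) <- c("gridded_series", "data.frame")
  df
}

#' Average replicate battle logs on a common grid
#'
#' Pointwise arithmetic mean of the sample-and-held replicates — the
#' "time-average of all experimental data" used for the headline
#' interaction fit.
#'
#' @param series_list list of `event_series`.
#' @param grid common time grid (seconds).
#' @return a `gridded_series` of replicate means.
#' @export
average_series <- function(series_list, grid) {
  if (length(series_list) < 1L) stop("need at least one series")
  acc <- matrix(0, length(grid), 5)
  for (s in series_list) acc <- acc + hold_states(s, grid)
  df <- data.frame(time = grid, acc / length(series_list))
  names(df) <- c("time", SPECIES)
  class(df) <- c("gridded_series", "data.frame")
  df
}

#' Weighted least-squares calibration error
#'
#' The error of a candidate rate-constant set against gridded observations:
#' \deqn{E(\theta) = \sum_{t} \sum_{s} w_{t,s} (x_{t,s} - y_{t,s})^2}
#' where x are the observed values, y the mean-field model values obtained
#' by integrating from `initial`, and w the weight.  Three weight modes:
#' `"none"` (w = 1), `"observed"` (w = x, the mode that gave the lowest
#' calibration error on the experimental data; zeros are lifted to 1 so
#' extinction observations still count), and `"derivative"`
#' (w = |dx/dt| by finite differences).
#'
#' @param constants rate constants `k1..k15`.
#' @param data a `gridded_series` (five species columns), or any data
#'   frame with a `time` column plus observed columns among
#'   `nA,nB,nAB,nABB,nABBB,totalA,totalB`.
#' @param weight one of `"observed"`, `"none"`, `"derivative"`.
#' @param initial initial state for the model integration; defaults to the
#'   first data row when all five species are observed.
#' @return non-negative scalar error.
#' @export
battle_objective <- function(constants, data,
                             weight = c("observed", "none", "derivative"),
                             initial = NULL) {
  weight <- match.arg(weight)
  k <- as_constants(constants)
  if (nrow(data) == 0L) stop("no data to fit")
  data <- data[order(data$time), , drop = FALSE]   # order-invariant error
  obs_cols <- intersect(c(SPECIES, "totalA", "totalB"), names(data))
  if (length(obs_cols) == 0L) stop("data contains no observed species columns")
  if (is.null(initial)) {
    if (!all(SPECIES %in% obs_cols))
      stop("initial state required when the five species are not all observed")
    initial <- as.numeric(data[1, SPECIES])
  }
  y <- integrate_states(initial, k, data$time)
  tot <- population_totals(y)
  ymat <- cbind(y, tot)[, obs_cols, drop = FALSE]
  xmat <- as.matrix(data[obs_cols])
  w <- objective_weights(xmat, data$time, weight)
  sum(w * (xmat - ymat)^2)
}

objective_weights <- function(xmat, times, weight) {
  switch(weight,
    none = array(1, dim(xmat)),
    observed = pmax(xmat, 1),
    derivative = {
      w <- apply(xmat, 2, function(x) {
        n <- length(x)
        if (n < 2) return(rep(0, n))
        d <- numeric(n)
        d[1] <- (x[2] - x[1]) / (times[2] - times[1])
        d[n] <- (x[n] - x[n - 1]) / (times[n] - times[n - 1])
        if (n > 2)
          d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (times[3:n] - times[1:(n - 2)])
        abs(d)
      })
      matrix(w, nrow(xmat), ncol(xmat))
    })
}

#' Fit the battle model to observed data
#'
#' Estimates rate constants by minimising [battle_objective()] with a
#' Nelder--Mead simplex in log10-parameter space (which enforces
#' positivity).  Two modes:
#' \describe{
#'   \item{`"interaction"`}{data is a `gridded_series` over all five
#'     chemical species (typically an averaged 1-hour battle log); by
#'     default all 15 constants are free.}
#'   \item{`"mortality"`}{data is a mortality table
#'     (`time_s,survivors_A,survivors_B`); only the five casualty
#'     constants (channels 3, 4, 7, 8, 13) are free by default, the rest
#'     are held at `fixed` — mortality experiments are recorded at too low
#'     a temporal resolution to constrain the interaction channels.}
#' }
#' When `initial_guess` is `NULL` a seeded multistart is used: `n_starts`
#' log-uniform draws in `start_range`, keeping the best fit.
#'
#' @param data observed data (see above).
#' @param mode `"interaction"` or `"mortality"`.
#' @param fixed full rate-constant vector supplying the values of the
#'   channels that are not free (required for mortality mode; defaults to
#'   `initial_guess` or zeros in interaction mode).
#' @param free integer indices (1..15) of the constants to optimise.
#' @param initial_guess starting values for the free constants (full
#'   15-vector or one value per free index), or `NULL` for multistart.
#' @param weight weight mode of [battle_objective()].
#' @param initial initial state for model integration (defaults from the
#'   data in interaction mode; mortality mode starts at
#'   `(survivors_A[1], survivors_B[1], 0, 0, 0)`).
#' @param control list of optimisation controls: `maxit` (default 1e5
#'   function evaluations), `reltol` (default 1e-8, the simplex collapse
#'   tolerance in log space), `n_starts` (default 20), `start_range`
#'   (default `c(1e-7, 1e-1)`), `seed` (multistart seed, default 1).
#' @return an object of class `battle_fit` with components `constants`
#'   (all 15, fitted and fixed), `objective`, `weight_mode`,
#'   `n_evaluations`, `converged`, `free_indices`, plus the data, mode and
#'   settings used.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`, `simulate`, `residuals`.
#' @examples
#' \donttest{
#' k <- battle_constants("expT")
#' logs <- generate_interaction_dataset(k, n_experiments = 5, seed = 1)
#' avg <- average_series(logs, seq(0, 3600, by = 120))
#' fit <- fit_battle(avg, free = c(1, 2), initial_guess = k,
#'                   control = list(maxit = 400))
#' coef(fit)[1:2]
#' }
#' @export
fit_battle <- function(data, mode = c("interaction", "mortality"),
                       fixed = NULL, free = NULL, initial_guess = NULL,
                       weight = "observed", initial = NULL,
                       control = list()) {
  mode <- match.arg(mode)
  ctrl <- utils::modifyList(list(maxit = 1e5, reltol = 1e-8, n_starts = 20,
                                 start_range = c(1e-7, 1e-1), seed = 1),
                            control)
  if (mode == "mortality") {
    if (is.null(free)) free <- c(3L, 4L, 7L, 8L, 13L)
    if (is.null(fixed)) stop("mortality mode needs `fixed` interaction constants")
    if (!all(c("time_s", "survivors_A", "survivors_B") %in% names(data)))
      stop("mortality data must have columns time_s,survivors_A,survivors_B")
    if (is.null(initial))
      initial <- c(data$survivors_A[1], data$survivors_B[1], 0, 0, 0)
    data <- data.frame(time = data$time_s, totalA = data$survivors_A,
                       totalB = data$survivors_B)
  } else {
    if (is.null(free)) free <- 1:15
    if (!all(SPECIES %in% names(data)))
      stop("interaction data must observe all five chemical species")
    if (is.null(initial)) initial <- as.numeric(data[1, SPECIES])
  }
  free <- sort(unique(as.integer(free)))
  if (any(free < 1L | free > 15L)) stop("free indices must be in 1..15")
  base_k <- if (!is.null(fixed)) as_constants(fixed)
            else if (!is.null(initial_guess) && length(initial_guess) == 15L)
              as_constants(initial_guess)
            else as_constants(rep(0, 15))

  n_eval <- 0L
  obj_free <- function(logk_free) {
    n_eval <<- n_eval + 1L
    k <- base_k
    k[free] <- 10^logk_free
    tryCatch(battle_objective(k, data, weight = weight, initial = initial),
             error = function(e) Inf)
  }

  starts <- if (!is.null(initial_guess)) {
    g <- if (length(initial_guess) == 15L) as_constants(initial_guess)[free]
         else as.numeric(initial_guess)
    if (length(g) != length(free)) stop("initial_guess does not match free indices")
    if (any(g <= 0)) stop("starting values for free constants must be positive")
    list(log10(g))
  } else {
    set.seed(as.integer(ctrl$seed))
    lr <- log10(ctrl$start_range)
    lapply(seq_len(ctrl$n_starts),
           function(i) stats::runif(length(free), lr[1], lr[2]))
  }

  best <- NULL
  for (p0 in starts) {
    f0 <- obj_free(p0)
    res <- if (length(free) == 1L) {
      # optim's Nelder-Mead is unreliable in 1-D; golden-section refine
      o <- stats::optimize(obj_free, interval = p0 + c(-4, 4), tol = 1e-10)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(p0, obj_free, method = "Nelder-Mead",
                   control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
    }
    if (!is.finite(res$value)) res$value <- f0
    if (is.null(best) || res$value < best$value) best <- res
  }

  k_hat <- base_k
  k_hat[free] <- 10^best$par
  fitted_states <- tryCatch(integrate_states(initial, k_hat, data$time),
                            error = function(e) NULL)
  structure(list(constants = k_hat,
                 objective = best$value,
                 weight_mode = weight,
                 n_evaluations = n_eval,
                 converged = identical(best$convergence, 0L) ||
                             isTRUE(best$convergence == 0),
                 free_indices = free,
                 mode = mode,
                 data = data,
                 initial = initial,
                 fitted_states = fitted_states,
                 control = ctrl,
                 n_starts = length(starts)),
            class = "battle_fit")
}

#' @export
print.battle_fit <- function(x, ...) {
  cat("Battle-model fit (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  free constants : %s\n",
              paste0("k", x$free_indices, collapse = ", ")))
  cat(sprintf("  objective      : %.6g (weight: %s)\n", x$objective, x$weight_mode))
  cat(sprintf("  evaluations    : %d  converged: %s\n",
              x$n_evaluations, x$converged))
  invisible(x)
}

#' @export
summary.battle_fit <- function(object, ...) {
  cat("Fitted rate constants (s^-1 per reactant combination):\n")
  reg <- reaction_registry()
  for (i in 1:15) {
    tag <- if (i %in% object$free_indices) "fitted" else "fixed "
    cat(sprintf("  k%-2d %-20s %s  %.4e\n", i, reg[[i]]$label, tag,
                object$constants[i]))
  }
  cat(sprintf("objective %.6g (%s weights), %d evaluations\n",
              object$objective, object$weight_mode, object$n_evaluations))
  invisible(object)
}

#' @export
coef.battle_fit <- function(object, ...) object$constants

#' @export
residuals.battle_fit <- function(object, ...) {
  obs_cols <- intersect(c(SPECIES, "totalA", "totalB"), names(object$data))
  y <- cbind(object$fitted_states, population_totals(object$fitted_states))
  as.matrix(object$data[obs_cols]) - y[, obs_cols, drop = FALSE]
}

#' Predict a mean-field trajectory from a fitted battle model
#'
#' @param object a `battle_fit`.
#' @param initial initial state (default: the fit's own).
#' @param t_end,grid_step forwarded to [battle_ode()].
#' @param ... unused.
#' @return a `battle_trajectory`.
#' @export
predict.battle_fit <- function(object, initial = object$initial,
                               t_end = max(object$data$time),
                               grid_step = NULL, ...) {
  battle_ode(initial, object$constants, t_end = t_end, grid_step = grid_step)
}

#' Simulate stochastic battles from a fitted model
#'
#' @param object a `battle_fit`.
#' @param nsim number of Gillespie runs.
#' @param seed master seed.
#' @param initial integer initial state (default: the fit's own, rounded).
#' @param t_max horizon in seconds.
#' @param ... unused.
#' @return a single `event_series` if `nsim = 1`, else a list of them.
#' @export
simulate.battle_fit <- function(object, nsim = 1, seed = NULL,
                                initial = round(object$initial),
                                t_max = max(object$data$time), ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, nsim)
  runs <- lapply(seeds, function(s)
    ssa_run(initial, object$constants, t_max = t_max, seed = s))
  if (nsim == 1) runs[[1]] else runs
}

#' @export
plot.battle_fit <- function(x, ...) {
  obs_cols <- intersect(c(SPECIES, "totalA", "totalB"), names(x$data))
  y <- cbind(x$fitted_states, population_totals(x$fitted_states))
  cols <- grDevices::hcl.colors(length(obs_cols), "Dark 3")
  graphics::matplot(x$data$time, as.matrix(x$data[obs_cols]), pch = 1,
                    col = cols, xlab = "time [s]", ylab = "abundance", ...)
  graphics::matlines(x$data$time, y[, obs_cols, drop = FALSE], lty = 1,
                     col = cols)
  graphics::legend("topright", legend = obs_cols, col = cols, lty = 1,
                   pch = 1, bty = "n")
  invisible(x)
}

#' Serialise a fit to JSON
#'
#' Writes constants, objective, free indices and settings as a JSON
#' object.
#'
#' @param fit a `battle_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(list(constants = as.list(fit$constants),
                            objective = fit$objective,
                            weight_mode = fit$weight_mode,
                            free_indices = fit$free_indices,
                            n_evaluations = fit$n_evaluations,
                            converged = fit$converged,
                            mode = fit$mode),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
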