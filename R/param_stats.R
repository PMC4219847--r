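#' Refit an ensemble of stochastic battles
#'
#' The error-propagation scheme for the calibrated constants: run `n_runs`
#' seeded Gillespie simulations at the given constants, grid each run, and
#' refit the mean-field model to every run individually.  The spread of
#' the refitted constants across runs estimates the (intrinsic-noise)
#' sampling distribution of each parameter.  Individual fit failures are
#' excluded and counted.
#'
#' @param constants generating rate constants `k1..k15`.
#' @param n_runs number of stochastic replicates (the reference analysis
#'   uses 100).
#' @param initial integer initial state (default 10 vs 10).
#' @param t_max horizon in seconds (default 3600, the interaction-
#'   experiment duration).
#' @param fit_options list passed to the per-run fits: `free` (indices to
#'   refit, default all 15), `grid_step` (default 60 s), `weight`, and a
#'   `control` list for [fit_battle()].  Each fit starts at the generating
#'   constants.
#' @param seed master seed.
#' @return list of class `param_sample`: `samples` (matrix, successful
#'   runs x 15 constants), `free`, `n_failed`, `seed`.
#' @export
ensemble_refit <- function(constants, n_runs, initial = c(10, 10, 0, 0, 0),
                           t_max = 3600, fit_options = list(), seed = NULL) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  k <- as_constants(constants)
  opts <- utils::modifyList(list(free = 1:15, grid_step = 60,
                                 weight = "observed",
                                 control = list(maxit = 2000)),
                            fit_options)
  if (!is.null(seed)) set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, n_runs)
  grid <- seq(0, t_max, by = opts$grid_step)
  samples <- matrix(NA_real_, n_runs, 15,
                    dimnames = list(NULL, paste0("k", 1:15)))
  failed <- 0L
  for (r in seq_len(n_runs)) {
    res <- tryCatch({
      es <- ssa_run(initial, k, t_max = t_max, seed = seeds[r])
      if (nrow(es) < 2L) stop("degenerate run: no events")
      gs <- sample_and_hold(es, grid)
      fit <- fit_battle(gs, mode = "interaction", free = opts$free,
                        fixed = k, initial_guess = k,
                        weight = opts$weight, control = opts$control)
      fit$constants
    }, error = function(e) e)
    if (inherits(res, "error")) failed <- failed + 1L
    else samples[r, ] <- res
  }
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  if (nrow(samples) == 0L)
    stop("all ", n_runs, " ensemble refits failed (last cause: degenerate ",
         "or failed runs); check the constants")
  structure(list(samples = samples, free = opts$free, n_failed = failed,
                 seed = seed),
            class = "param_sample")
}

#' Maximum-likelihood fit of a parametric family to a parameter sample
#'
#' Fits a lognormal, exponential or Weibull distribution by maximum
#' likelihood; the lognormal is the family that best describes the
#' refitted rate constants, and the log-likelihoods allow a direct
#' comparison of the three candidates.
#'
#' @param x positive sample values (at least 3, not all equal).
#' @param family `"lognormal"`, `"exponential"` or `"weibull"`.
#' @return list of class `distribution_fit`: `family`, `estimate` (named
#'   parameter vector), `loglik`.
#' @export
fit_parametric <- function(x, family = c("lognormal", "exponential", "weibull")) {
  family <- match.arg(family)
  x <- as.numeric(x)
  if (length(x) < 3L) stop("need at least 3 values")
  if (any(!is.finite(x) | x <= 0)) stop("sample values must be positive")
  if (diff(range(x)) == 0) stop("degenerate sample: all values equal")
  dist <- switch(family, lognormal = "lnorm", exponential = "exp",
                 weibull = "weibull")
  f <- fitdistrplus::fitdist(x, dist)
  structure(list(family = family, estimate = f$estimate, loglik = f$loglik),
            class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(x$family, "fit:",
      paste(names(x$estimate), signif(x$estimate, 4), sep = " = ",
            collapse = ", "),
      sprintf(" (logLik %.4f)\n", x$loglik))
  invisible(x)
}

# Log-likelihood of a sample under a fitted family.
loglik_under <- function(x, fit) {
  p <- fit$estimate
  switch(fit$family,
    lognormal  = sum(stats::dlnorm(x, p["meanlog"], p["sdlog"], log = TRUE)),
    exponential = sum(stats::dexp(x, p["rate"], log = TRUE)),
    weibull    = sum(stats::dweibull(x, p["shape"], p["scale"], log = TRUE)))
}

#' Split-half likelihood validation
#'
#' Splits a parameter sample into two halves by run index, fits the family
#' on the first half, and evaluates (i) the first half's own log-likelihood
#' and (ii) the second half's log-likelihood under the first-half fit.
#' Similar values per observation indicate that one half predicts the
#' other, i.e. the family is an adequate description.
#'
#' @param x positive sample of even size >= 6.
#' @param family as in [fit_parametric()].
#' @return named vector `c(L_first, L_second)` with attribute `fit` (the
#'   first-half fit).
#' @export
split_half_likelihood <- function(x, family = "lognormal") {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 6L || n %% 2L != 0L) stop("need an even-sized sample of >= 6 values")
  first <- x[seq_len(n / 2L)]
  second <- x[(n / 2L + 1L):n]
  fit <- fit_parametric(first, family)
  structure(c(L_first = fit$loglik, L_second = loglik_under(second, fit)),
            fit = fit)
}

#' Two-sided Wilcoxon rank-sum comparison with 0/1 coding
#'
#' Tests whether two parameter samples come from the same distribution.
#' Coding follows the validation tables: 0 = the null hypothesis of a
#' common distribution is accepted at level `alpha`, 1 = rejected.  The
#' exact distribution is used for small samples (both sides below 8),
#' otherwise the normal approximation with tie correction.
#'
#' @param x,y numeric samples.
#' @param alpha significance level (default 0.05).
#' @return list: `decision` (0 or 1), `statistic`, `p_value`.
#' @export
rank_sum_decision <- function(x, y, alpha = 0.05) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  exact <- length(x) < 8L && length(y) < 8L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(decision = as.integer(wt$p.value < alpha),
       statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Lognormal average of a parameter sample
#'
#' The ensemble summaries of the refitted constants are computed
#' "according to the lognormal distribution": with log-moments
#' `mu = mean(log x)` and `s2 = var(log x)` (unbiased, n-1 denominator),
#' the lognormal mean is `exp(mu + s2/2)` (default) and the lognormal
#' median `exp(mu)`.
#'
#' @param x positive values, n >= 2.
#' @param type `"mean"` or `"median"`.
#' @return positive scalar.
#' @export
lognormal_average <- function(x, type = c("mean", "median")) {
  type <- match.arg(type)
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 values")
  if (any(!is.finite(x) | x <= 0)) stop("sample values must be positive")
  lx <- log(x)
  mu <- mean(lx)
  if (type == "median") return(exp(mu))
  exp(mu + stats::var(lx) / 2)
}

#' Split-half and rank-sum validation report
#'
#' Runs the full per-reaction validation pipeline over two parameter
#' ensembles (a "simulated" one, e.g. 100 stochastic refits, and an
#' "experimental" one, e.g. 20 per-replicate refits): split-half
#' likelihoods for each ensemble and the four cross rank-sum decisions
#' (first/first, second/second, first/second, second/first halves of the
#' simulated vs experimental ensembles).
#'
#' @param sim a `param_sample` (or matrix runs x 15) of simulated refits.
#' @param exp_ a `param_sample` (or matrix) of experimental refits.
#' @param family distribution family for the likelihoods.
#' @param reactions channel indices to report (default: all with positive,
#'   non-degenerate samples in both ensembles).
#' @param alpha rank-sum significance level.
#' @return data frame, one row per reaction: `reaction`, `L_sim1`,
#'   `L_sim2`, `L_exp1`, `L_exp2`, `W1`..`W4`.
#' @export
validation_report <- function(sim, exp_, family = "lognormal",
                              reactions = 1:15, alpha = 0.05) {
  simm <- if (inherits(sim, "param_sample")) sim$samples else as.matrix(sim)
  expm <- if (inherits(exp_, "param_sample")) exp_$samples else as.matrix(exp_)
  rows <- lapply(reactions, function(i) {
    xs <- simm[, i]; xe <- expm[, i]
    ok <- function(v) all(v > 0) && diff(range(v)) > 0
    if (!ok(xs) || !ok(xe)) {
      return(data.frame(reaction = i, L_sim1 = NA, L_sim2 = NA,
                        L_exp1 = NA, L_exp2 = NA,
                        W1 = NA, W2 = NA, W3 = NA, W4 = NA))
    }
    Ls <- split_half_likelihood(xs, family)
    Le <- split_half_likelihood(xe, family)
    h <- function(v) split(v, rep(1:2, each = length(v) / 2))
    hs <- h(xs); he <- h(xe)
    data.frame(reaction = i,
               L_sim1 = unname(Ls[1]), L_sim2 = unname(Ls[2]),
               L_exp1 = unname(Le[1]), L_exp2 = unname(Le[2]),
               W1 = rank_sum_decision(hs[[1]], he[[1]], alpha)$decision,
               W2 = rank_sum_decision(hs[[2]], he[[2]], alpha)$decision,
               W3 = rank_sum_decision(hs[[1]], he[[2]], alpha)$decision,
               W4 = rank_sum_decision(hs[[2]], he[[1]], alpha)$decision)
  })
  do.call(rbind, rows)
}
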