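#' @useDynLib antbattle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Species order used throughout the package.  A and B are lone fighters of
# the two species; AB, ABB and ABBB are gripping fight groups of one A with
# one, two or three B's.
SPECIES <- c("nA", "nB", "nAB", "nABB", "nABBB")

# Weight of each dynamical species in the two population totals:
#   totalA = nA + nAB + nABB + nABBB
#   totalB = nB + nAB + 2 nABB + 3 nABBB
WEIGHT_A <- c(1, 0, 1, 1, 1)
WEIGHT_B <- c(0, 1, 1, 2, 3)

#' The 15-channel reaction registry
#'
#' Enumerates the reaction channels of the battle model in canonical order.
#' Channels 1--2 are the reversible formation of a duel group
#' (`A + B <-> AB`); 3--4 its two lethal outcomes (death of A, death of B);
#' 5--10 involve the three-member group `ABB` (formation, detachment, death
#' of one B, death of the A, and the bloodless two-B dissolution/attack
#' pair); 11--15 involve the four-member group `ABBB` (formation, single
#' detachment, death of the A, and the two-B detachment/attack pair).  The
#' five casualty channels are 3, 8 and 13 (an A dies) and 4 and 7 (a B
#' dies).
#'
#' @return A list of class `reaction_registry` with 15 elements, one per
#'   channel, each a list with components:
#'   \describe{
#'     \item{index}{channel number, 1..15.}
#'     \item{label}{human-readable reaction equation.}
#'     \item{reactants, products}{named integer stoichiometries over the
#'       five species `nA, nB, nAB, nABB, nABBB`.}
#'     \item{nu}{net state change `products - reactants` (integer vector of
#'       length 5).}
#'     \item{order}{total reactant multiplicity (1, 2 or 3).}
#'     \item{deltaDeadA, deltaDeadB}{0/1 casualty increments.}
#'   }
#' @examples
#' reg <- reaction_registry()
#' length(reg)          # 15
#' reg[[10]]$label      # two B attack a lone A
#' @export
reaction_registry <- function() {
  sto <- function(...) {
    v <- integer(5)
    names(v) <- SPECIES
    args <- list(...)
    for (nm in names(args)) v[nm] <- as.integer(args[[nm]])
    v
  }
  ch <- function(index, label, reactants, products, dA = 0L, dB = 0L) {
    list(index = index, label = label,
         reactants = reactants, products = products,
         nu = products - reactants,
         order = sum(reactants),
         deltaDeadA = dA, deltaDeadB = dB)
  }
  reg <- list(
    ch(1L,  "A + B -> AB",       sto(nA = 1, nB = 1),           sto(nAB = 1)),
    ch(2L,  "AB -> A + B",       sto(nAB = 1),                  sto(nA = 1, nB = 1)),
    ch(3L,  "AB -> B (A dies)",  sto(nAB = 1),                  sto(nB = 1),  dA = 1L),
    ch(4L,  "AB -> A (B dies)",  sto(nAB = 1),                  sto(nA = 1),  dB = 1L),
    ch(5L,  "AB + B -> ABB",     sto(nAB = 1, nB = 1),          sto(nABB = 1)),
    ch(6L,  "ABB -> AB + B",     sto(nABB = 1),                 sto(nAB = 1, nB = 1)),
    ch(7L,  "ABB -> AB (B dies)", sto(nABB = 1),                sto(nAB = 1), dB = 1L),
    ch(8L,  "ABB -> 2B (A dies)", sto(nABB = 1),                sto(nB = 2),  dA = 1L),
    ch(9L,  "ABB -> A + 2B",     sto(nABB = 1),                 sto(nA = 1, nB = 2)),
    ch(10L, "A + 2B -> ABB",     sto(nA = 1, nB = 2),           sto(nABB = 1)),
    ch(11L, "ABB + B -> ABBB",   sto(nABB = 1, nB = 1),         sto(nABBB = 1)),
    ch(12L, "ABBB -> ABB + B",   sto(nABBB = 1),                sto(nABB = 1, nB = 1)),
    ch(13L, "ABBB -> 3B (A dies)", sto(nABBB = 1),              sto(nB = 3),  dA = 1L),
    ch(14L, "ABBB -> AB + 2B",   sto(nABBB = 1),                sto(nAB = 1, nB = 2)),
    ch(15L, "AB + 2B -> ABBB",   sto(nAB = 1, nB = 2),          sto(nABBB = 1))
  )
  class(reg) <- "reaction_registry"
  reg
}

#' @export
print.reaction_registry <- function(x, ...) {
  cat("Battle reaction registry:", length(x), "channels\n")
  for (r in x) {
    death <- if (r$deltaDeadA) "  [A dies]" else if (r$deltaDeadB) "  [B dies]" else ""
    cat(sprintf("  R%-2d  %-20s order %d%s\n", r$index, r$label, r$order, death))
  }
  invisible(x)
}

# 5 x 15 net stoichiometry matrix (rows = species, columns = channels).
# Memoised: it is evaluated inside ODE right-hand sides.
stoich_matrix <- local({
  cache <- NULL
  function(registry = NULL) {
    if (!is.null(registry)) {
      S <- vapply(registry, `[[`, numeric(5), "nu")
      rownames(S) <- SPECIES
      return(S)
    }
    if (is.null(cache)) {
      S <- vapply(reaction_registry(), `[[`, numeric(5), "nu")
      rownames(S) <- SPECIES
      cache <<- S
    }
    cache
  }
})

# Indices of channels where one A (resp. one B) dies.
CASUALTY_A <- c(3L, 8L, 13L)
CASUALTY_B <- c(4L, 7L)

#' Validate and normalise a state vector
#'
#' @param state numeric vector of length 5 (order `nA, nB, nAB, nABB,
#'   nABBB`), or a named vector containing those names.
#' @param integer_counts require integer values (stochastic engine).
#' @return named numeric vector of length 5.
#' @keywords internal
as_state <- function(state, integer_counts = FALSE) {
  if (!is.null(names(state)) && all(SPECIES %in% names(state)))
    state <- state[SPECIES]
  if (length(state) != 5L || !is.numeric(state))
    stop("state must be a numeric vector of length 5 (nA, nB, nAB, nABB, nABBB)")
  state <- as.numeric(state)
  names(state) <- SPECIES
  if (any(!is.finite(state)))
    stop("state contains non-finite values")
  if (any(state < 0))
    stop("state contains negative abundances")
  if (integer_counts && any(state != round(state)))
    stop("stochastic engine requires integer counts")
  state
}

#' Validate a rate-constant vector
#'
#' @param k numeric vector of 15 non-negative, finite rate constants
#'   (`k1..k15`), optionally named.
#' @return named numeric vector `k1..k15`.
#' @keywords internal
as_constants <- function(k) {
  knames <- paste0("k", 1:15)
  if (!is.null(names(k)) && all(knames %in% names(k))) k <- k[knames]
  if (length(k) != 15L || !is.numeric(k))
    stop("rate constants must be a numeric vector of length 15 (k1..k15)")
  k <- as.numeric(k)
  if (any(!is.finite(k))) stop("rate constants must be finite")
  if (any(k < 0)) stop("rate constants must be non-negative")
  names(k) <- knames
  k
}

#' Mass-action propensities of the 15 channels
#'
#' Channel i fires at rate `k_i` times the product of its reactant counts
#' raised to their multiplicities (e.g. channel 10 at `k10 * nA * nB^2`),
#' with a feasibility guard: the propensity is zero whenever the state does
#' not contain the full integer stoichiometry of the reactants (channel 10
#' needs at least two free B's).
#'
#' @param state integer, non-negative counts of the five species.
#' @param constants rate constants `k1..k15` (units: s^-1 per reactant
#'   combination).
#' @return numeric vector of 15 non-negative rates.
#' @examples
#' k <- rep(0, 15); k[1] <- 1.0063e-3
#' propensities(c(1, 1, 0, 0, 0), k)   # only channel 1 can fire
#' @export
propensities <- function(state, constants) {
  state <- as_state(state, integer_counts = TRUE)
  k <- as_constants(constants)
  reg <- reaction_registry()
  a <- numeric(15)
  for (r in reg) {
    if (any(state < r$reactants)) next    # feasibility guard
    a[r$index] <- k[r$index] * prod(state^r$reactants)
  }
  a
}

#' Mean-field right-hand side of the battle ODE system
#'
#' The deterministic rate equations induced by the registry under mass
#' action, for real-valued (continuous) abundances.  Writing `a = nA`,
#' `b = nB`, `c1 = nAB`, `c2 = nABB`, `c3 = nABBB`, the channel rates are
#' `r1 = k1 a b`, `r2 = k2 c1`, ..., `r10 = k10 a b^2`, `r15 = k15 c1 b^2`,
#' and the derivative of each species is the stoichiometry-weighted sum of
#' the rates.  Two exact casualty identities follow:
#' `d(totalA)/dt = -(k3 c1 + k8 c2 + k13 c3)` and
#' `d(totalB)/dt = -(k4 c1 + k7 c2)`.
#'
#' @param state non-negative real abundances of the five species.
#' @param constants rate constants `k1..k15`.
#' @return named numeric vector of derivatives (per second).
#' @examples
#' k <- rep(0, 15); k[1] <- 1.0063e-3
#' ode_rhs(c(10, 10, 0, 0, 0), k)   # dAB/dt = +0.10063
#' @export
ode_rhs <- function(state, constants) {
  state <- as_state(state)
  k <- as_constants(constants)
  drop(stoich_matrix() %*% channel_rates(state, k))
}

# Real-valued mass-action channel rates WITHOUT the integer feasibility
# guard; shared by ode_rhs and the structural-consistency tests.
channel_rates <- function(state, k) {
  a <- state[[1]]; b <- state[[2]]
  c1 <- state[[3]]; c2 <- state[[4]]; c3 <- state[[5]]
  c(k[1] * a * b,   k[2] * c1,  k[3] * c1,  k[4] * c1,
    k[5] * c1 * b,  k[6] * c2,  k[7] * c2,  k[8] * c2,  k[9] * c2,
    k[10] * a * b^2, k[11] * c2 * b, k[12] * c3, k[13] * c3,
    k[14] * c3, k[15] * c1 * b^2)
}

#' Population totals of a state or trajectory
#'
#' `totalA = nA + nAB + nABB + nABBB` counts every living A individual,
#' whether fighting or free; `totalB = nB + nAB + 2 nABB + 3 nABBB`
#' likewise for B.
#'
#' @param state a length-5 state vector, or a matrix/data frame with the
#'   five species columns.
#' @return for a single state, named vector `c(totalA, totalB)`; otherwise
#'   a two-column matrix.
#' @export
population_totals <- function(state) {
  if (is.matrix(state) || is.data.frame(state)) {
    m <- as.matrix(as.data.frame(state)[SPECIES])
    cbind(totalA = drop(m %*% WEIGHT_A), totalB = drop(m %*% WEIGHT_B))
  } else {
    state <- as_state(state)
    c(totalA = sum(state * WEIGHT_A), totalB = sum(state * WEIGHT_B))
  }
}
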