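# Shared helpers for the test suite.

# Constants with a single active channel.
only_k <- function(i, value) {
  k <- rep(0, 15)
  k[i] <- value
  k
}

# Symmetric duel-only model: reversible pairing plus equal death rates.
duel_constants <- function(k1 = 1e-3, k2 = 1e-2, kdeath = 1e-4) {
  k <- rep(0, 15)
  k[1] <- k1; k[2] <- k2; k[3] <- kdeath; k[4] <- kdeath
  k
}

# Wrap a time x species matrix as a gridded_series.
as_gridded <- function(times, states) {
  df <- data.frame(time = times, states)
  names(df) <- c("time", "nA", "nB", "nAB", "nABB", "nABBB")
  class(df) <- c("gridded_series", "data.frame")
  df
}

# Noise-free mean-field observations on a grid.
ode_dataset <- function(constants, initial = c(10, 10, 0, 0, 0),
                        times = seq(0, 3600, 60)) {
  as_gridded(times, antbattle:::integrate_states(initial, constants, times))
}

species_cols <- c("nA", "nB", "nAB", "nABB", "nABBB")
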