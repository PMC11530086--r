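# Brute-force oracles and shared fixtures for the exposure-metric tests.

# Smallest threshold T (among observed values) such that MAP stayed <= T for
# at least `w` consecutive ticks: direct run-length scan over all candidates.
oracle_sustained <- function(x, w) {
  for (T in sort(unique(x))) {
    r <- rle(x <= T)
    if (any(r$lengths[r$values] >= w)) return(T)
  }
  NA_real_
}

# Smallest threshold T such that total time with MAP <= T reaches w ticks.
oracle_cumulative <- function(x, w) {
  for (T in sort(unique(x))) if (sum(x <= T) >= w) return(T)
  NA_real_
}

# Random MAP grids: half continuous-valued, half coarse-valued (many ties).
random_grid <- function(n) {
  if (stats::runif(1) < 0.5) round(stats::runif(n, 40, 100), 1)
  else sample(seq(40, 100, by = 5), n, replace = TRUE)
}

# The worked 8-tick example grid used throughout the documentation.
worked_grid <- c(80, 80, 70, 65, 62, 62, 66, 75)

# A small quick CV scheme for desk-scale tests.
quick <- list(k = 5L, reps = 2L)

# Short-surgery generator settings used by desk-scale cohort tests: the BP
# dynamics are unchanged, surgeries are just shorter so records stay small.
short_config <- function(n, seed, ...) {
  truth_config(n, seed = seed, duration_median_min = 40,
               duration_sdlog = 0.3, ...)
}
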