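# Shared fixtures built in code.

# Fully balanced noise-free dataset: X, e1, C1 each crossed over {0,1} /
# {-1,1} / {-1,1}, M = 0.59 X + 0.3 C1 + e1, Y = 0.2 X + 0.59 M.
# Every regression on it recovers its generating coefficients exactly, and
# the total effect is 0.2 + 0.59 * 0.59 = 0.5481.
noise_free_dataset <- function() {
  grid <- expand.grid(X = c(0, 1), e1 = c(-1, 1), C1 = c(-1, 1))
  grid$M <- 0.59 * grid$X + 0.3 * grid$C1 + grid$e1
  grid$Y <- 0.2 * grid$X + 0.59 * grid$M
  grid[, c("X", "C1", "M", "Y")]
}

# Small stochastic dataset under a named condition, for smoke tests.
small_dataset <- function(seed = 101, n = 300,
                          coefs = path_coefficients(a = 0.39, b = 0.59,
                                                    c_prime = 0.14, d = 0.59,
                                                    f = 0.59, g = 0.14,
                                                    h = 0.14)) {
  generate_dataset(coefs, seed = seed, sample_size = n)
}

one_condition_grid <- function(coefs, sample_size = 500, id = "c1") {
  structure(list(simulation_condition(id, coefs, sample_size)),
            class = "condition_grid")
}
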