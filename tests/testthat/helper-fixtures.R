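# Shared fixtures and independent oracles for the test suite.

# Independent brute-force theta sum for genus 1: plain double loop over the
# lattice, written without reusing any package internals.
brute_theta_g1 <- function(z, omega, alpha, beta, radius = 10) {
  total <- 0 + 0i
  for (n in -radius:radius) {
    total <- total + exp(1i * pi * (n + alpha)^2 * omega +
                         2i * pi * (z + beta) * (n + alpha))
  }
  total
}

# Seeded random pulse train: n_pulses well-separated sech pulses with
# distinct parameters. Peak times spread over (0.1, 0.9) * duration.
random_train <- function(n_pulses, duration, seed) {
  set.seed(seed)
  tpk <- sort(stats::runif(n_pulses, 0.1 * duration, 0.9 * duration))
  # enforce separation of at least 8% of the record
  while (n_pulses > 1 && min(diff(tpk)) < 0.08 * duration) {
    tpk <- sort(stats::runif(n_pulses, 0.1 * duration, 0.9 * duration))
  }
  b <- stats::runif(n_pulses, 2, 6)
  V0 <- stats::runif(n_pulses, 0.6, 1.4)
  pulses <- lapply(seq_len(n_pulses), function(j)
    pinch_pulse(a = b[j], b = b[j], c = b[j] * tpk[j], V0 = V0[j]))
  soliton_train(pulses)
}

true_params <- function(train) {
  do.call(rbind, lapply(train$pulses, function(p)
    data.frame(a = p$a, b = p$b, c = p$c, V0 = p$V0)))
}

# Trapezoidal quadrature on a uniform grid.
trapz <- function(x, y) {
  dx <- diff(x)
  sum(dx * (y[-1] + y[-length(y)]) / 2)
}
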