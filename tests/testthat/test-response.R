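test_that("Green's function is causal, symmetric and oscillatory", {
  basis <- modal_basis(3)
  expect_equal(greens_function(basis, 1, 2, 1.2, 2), 0)
  expect_equal(greens_function(basis, 1, 1, 1.2, 2), 0)   # t < t'
  expect_equal(greens_function(basis, 0.7, 3, 1.9, 1),
               greens_function(basis, 1.9, 3, 0.7, 1))
  # single-mode basis solves the free oscillator equation away from t = t'
  b1 <- modal_basis(1)
  om <- b1$omega[1]
  h <- 1e-4
  t0 <- 2.3
  g <- function(t) greens_function(b1, 0.5, t, 1.1, 1)
  d2 <- (g(t0 + h) - 2 * g(t0) + g(t0 - h)) / h^2
  expect_equal(d2, -om^2 * g(t0), tolerance = 1e-5)
})

test_that("modal response is zero for zero input and linear in amplitude", {
  basis <- modal_basis(3)
  z0 <- 1.1
  null_in <- input_signal("transient", z0 = z0, V0 = 0)
  r0 <- respond(basis, null_in, t_final = 5)
  expect_equal(max(abs(r0$field)), 0)
  in1 <- input_signal("oscillatory", z0 = z0, V0 = 1, omega0 = 2)
  in3 <- input_signal("oscillatory", z0 = z0, V0 = 3, omega0 = 2)
  r1 <- respond(basis, in1, t_final = 10)
  r3 <- respond(basis, in3, t_final = 10)
  expect_equal(r3$field, 3 * r1$field, tolerance = 1e-10)
  expect_error(respond(basis, in1, t_final = -1), "positive")
})

test_that("the response is causal with respect to the input window", {
  basis <- modal_basis(2)
  inp <- input_signal("oscillatory", z0 = 1.3, omega0 = 3, t_on = 4)
  r <- respond(basis, inp, t_final = 8)
  before <- r$t < 4
  expect_equal(max(abs(r$field[, before])), 0)
  expect_gt(max(abs(r$field[, !before])), 0)
})

test_that("a transient input excites each mode through its point overlap", {
  basis <- modal_basis(4)
  z0 <- 0.9; a0 <- 0.7
  inp <- input_signal("transient", z0 = z0, V0 = 1, rate = a0,
                      width = 0.005)
  r <- respond(basis, inp, t_final = 6, dt = 0.002)
  # closed-form single-mode response to c_n V0 exp(-a t):
  # q_n(t) = c_n Im[ e^{i om t} (1 - e^{-(a + i om) t}) / (a + i om) ]
  tF <- max(r$t)
  i_end <- length(r$t)
  for (k in 1:4) {
    om <- basis$omega[k]
    cn <- sqrt(2 / pi) * cos((2 * k - 1/2) * z0)
    closed <- cn / om * Im(exp(1i * om * tF) *
                      (1 - exp(-(a0 + 1i * om) * tF)) / (a0 + 1i * om))
    expect_equal(r$mode_amplitude[k, i_end], closed, tolerance = 1e-3)
  }
})

test_that("resonant driving selects its own mode by a wide margin", {
  basis <- modal_basis(3)
  k <- 2
  om_res <- basis$omega[k]
  om_off <- (basis$omega[k] + basis$omega[k + 1]) / 2
  t_final <- 50 * 2 * pi / om_res
  z0 <- 0.6   # keep away from zeros of the mode profiles
  r_res <- respond(basis, input_signal("oscillatory", z0 = z0,
                                       omega0 = om_res), t_final = t_final)
  r_off <- respond(basis, input_signal("oscillatory", z0 = z0,
                                       omega0 = om_off), t_final = t_final)
  tail_idx <- r_res$t > 0.9 * t_final
  amp_res <- max(abs(r_res$mode_amplitude[k, tail_idx]))
  amp_off <- max(abs(r_off$mode_amplitude[k, tail_idx]))
  expect_gt(amp_res / amp_off, 10)
  # at resonance, mode k dominates every other mode
  others <- setdiff(seq_len(3), k)
  for (j in others)
    expect_gt(amp_res / max(abs(r_res$mode_amplitude[j, tail_idx])), 10)
})

test_that("blocking excitation is transient and conserves its weight", {
  expect_equal(blocking_excitation(-0.5, pi/2, 0), 0)
  v0 <- blocking_excitation(1e-9, pi/2, 0, theta0 = pi/2, phi0 = 0,
                            width = 0.01)
  expect_equal(v0, stats::dnorm(0, sd = 0.01)^2, tolerance = 1e-6)
  # spatial integral of each mollified point mass is width-independent
  for (w in c(0.05, 0.02, 0.01)) {
    th <- seq(pi/2 - 1, pi/2 + 1, length.out = 4001)
    line <- blocking_excitation(1e-9, th, 0, theta0 = pi/2, phi0 = 0,
                                Delta = 10, width = w)  # shift far away
    mass <- trapz(th, line) / stats::dnorm(0, sd = w)
    expect_equal(mass, 1, tolerance = 1e-4)
  }
  # after the window 1/alpha only the first (enveloped) term survives
  late <- blocking_excitation(3, pi/2 + 0.2, 0.2, Delta = 0.2, alpha = 1,
                              omega_n = 1)
  expect_equal(late, blocking_excitation(3, pi/2 + 0.2, 0.2, Delta = 0.2,
                                         alpha = 1e6, omega_n = 1))
})

test_that("K-complex has the biphasic lobes and a continuous glue", {
  A <- 2; n <- 1L; T <- 5
  expect_equal(kcomplex_waveform(0, A, n, T), -A / n)
  t1 <- seq(-T + 1e-3, T - 1e-3, length.out = 2000)
  t2 <- seq(T + 1e-3, 3 * T - 1e-3, length.out = 2000)
  expect_lt(min(kcomplex_waveform(t1, A, n, T)), -0.9 * A / n)
  expect_gt(max(kcomplex_waveform(t2, A, n, T)), 0.9 * A / n)
  # glue contract: continuity across t = T
  d <- abs(kcomplex_waveform(T - 1e-12, A, n, T) -
           kcomplex_waveform(T + 1e-12, A, n, T))
  expect_lt(d, 1e-9 * A)
  expect_equal(kcomplex_waveform(c(-T - 0.1, 3 * T + 0.1), A, n, T),
               c(0, 0))
})

test_that("spindle pair carries frequencies omega0 and 2 omega0", {
  sp0 <- spindle_modulation(0)
  expect_equal(c(sp0$dV, sp0$dV2), c(0, 0))
  # envelope zeros at t = k pi
  expect_equal(abs(spindle_modulation(pi)$dV), 0, tolerance = 1e-12)
  # outside [0, T] the modulation vanishes
  expect_equal(spindle_modulation(7, T = 6)$dV, 0)
  # FFT peak ratio 1:2 within one bin over one envelope arch [0, pi]
  # (the sin(t) envelope splits each carrier into lines at omega0 +- 1;
  # a pi-long record merges the pair into a single peak at omega0)
  dt <- 0.005
  t <- seq(0, pi - dt, by = dt)
  omega0 <- 12
  sp <- spindle_modulation(t, omega0 = omega0, T = 6)
  peak_bin <- function(x) {
    sp_est <- Mod(stats::fft(x))[1:(length(x) %/% 2)]
    which.max(sp_est) - 1L
  }
  df <- 1 / (length(t) * dt)
  b1 <- peak_bin(sp$dV); b2 <- peak_bin(sp$dV2)
  expect_lte(abs(b1 * df - omega0 / (2 * pi)), df)
  expect_lte(abs(b2 * df - 2 * omega0 / (2 * pi)), df)
  expect_lte(abs(b2 - 2 * b1), 1)
})

test_that("spindle threshold is strict in the electron energy", {
  N <- 1e3; om <- 10; hbar <- 1e-27
  expect_true(spindle_threshold(2 * N * hbar * om, N, om, hbar))
  expect_false(spindle_threshold(N * hbar * om, N, om, hbar))
  # threshold energy scale: 1e-23 erg for these inputs
  expect_equal(N * hbar * om, 1e-23)
})

test_that("dendrite twist triples select the matching tiling class", {
  d8 <- dendrite_twists_to_tiling(2, 2, 8)
  expect_equal(d8$name, "dihedral")
  expect_equal(d8$frequency, 8)
  d40 <- dendrite_twists_to_tiling(2, 2, 40)
  expect_equal(d40$frequency, 40)
  expect_equal(d40$band, "gamma")
  expect_null(dendrite_twists_to_tiling(3, 3, 3))
  expect_equal(dendrite_twists_to_tiling(2, 3, 5)$name, "icosahedron")
  expect_equal(dendrite_twists_to_tiling(3, 2, 4)$name, "octahedron")
  expect_equal(dendrite_twists_to_tiling(2, 3, 3)$name, "tetrahedron")
})
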