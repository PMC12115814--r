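test_that("Schwarz triples are exactly the spherical ones", {
  tr <- enumerate_schwarz_triples(30)
  has <- function(p, q, r) any(tr$p == p & tr$q == q & tr$r == r)
  expect_true(has(2, 3, 5))
  expect_false(has(2, 3, 6))   # angle sum exactly pi: flat, no tile
  expect_false(has(3, 3, 3))
  non_dih <- tr[!tr$dihedral, ]
  expect_equal(nrow(non_dih), 3L)
  expect_equal(non_dih$r, c(3L, 4L, 5L))
  # dihedral family present for every n up to r_max
  expect_true(all(vapply(2:30, function(n) has(2, 2, n), logical(1))))
  expect_error(enumerate_schwarz_triples(1), ">= 2")
})

test_that("spherical triangle area is the excess formula", {
  expect_equal(spherical_triangle_area(pi/2, pi/2, pi/2), pi / 2)
  for (n in c(2, 5, 11))
    expect_equal(spherical_triangle_area(pi/2, pi/2, pi / (2 * n)),
                 pi / (2 * n))
  expect_equal(8 * spherical_triangle_area(pi/2, pi/2, pi/2), 4 * pi)
  # radius scaling
  expect_equal(spherical_triangle_area(pi/2, pi/2, pi/2, R = 3),
               9 * pi / 2)
  expect_error(spherical_triangle_area(pi/3, pi/3, pi/3), "exceed pi")
})

test_that("reflection copies of each Schwarz triangle fill the sphere", {
  # |reflection group| = 4 pi / triangle area must be an even integer
  tr <- enumerate_schwarz_triples(20)
  for (i in seq_len(nrow(tr))) {
    area <- spherical_triangle_area(pi / tr$p[i], pi / tr$q[i],
                                    pi / tr$r[i])
    copies <- 4 * pi / area
    expect_equal(copies, round(copies), tolerance = 1e-9)
  }
  # dihedral wedges: 2n wedges of two triangles each cover the sphere
  for (n in 2:20) {
    wedge <- 2 * spherical_triangle_area(pi/2, pi/2, pi / n)
    expect_equal(2 * n * wedge, 4 * pi)
  }
})

test_that("hypergeometric parameters invert to the tile angles", {
  for (i in seq_len(nrow(enumerate_schwarz_triples(8)))) {
    tr <- enumerate_schwarz_triples(8)[i, ]
    par <- hypergeometric_params(tr$p, tr$q, tr$r)
    expect_equal(sort(schwarz_angles(par)),
                 sort(1 / c(tr$p, tr$q, tr$r)), tolerance = 1e-12)
    # the exponent differences are genuinely non-integer
    diffs <- c(par[["c"]], par[["c"]] - par[["a"]] - par[["b"]],
               par[["a"]] - par[["b"]])
    expect_true(all(abs(diffs - round(diffs)) > 1e-9))
  }
  par <- hypergeometric_params(2, 2, 4)
  expect_equal(unname(schwarz_angles(par)), c(1/2, 1/2, 1/4))
  # permuting the triple permutes which singular point carries which angle
  p1 <- sort(schwarz_angles(hypergeometric_params(2, 3, 4)))
  expect_error(hypergeometric_params(2, 3, 7), "Schwarz")
  expect_equal(p1, c(1/4, 1/3, 1/2))
})

test_that("band table implements the inverse amplitude-frequency law", {
  tab <- platonic_tiling_table()
  expect_equal(tab$frequency, c(1, 4, 6, 8, 12, 20, 40))
  expect_equal(tab$amplitude, c(200, 50, 33, 25, 17, 10, 5))
  expect_equal(tab$band,
               c("delta", "theta", "alpha", "alpha", "beta", "beta",
                 "gamma"))
  # frequency x amplitude stays within rounding of the base product
  expect_true(all(abs(tab$frequency * tab$amplitude - 200) <=
                  tab$frequency / 2))
  # scales propagate linearly
  tab2 <- platonic_tiling_table(base_frequency = 2, base_amplitude = 100)
  expect_equal(tab2$frequency, 2 * tab$frequency)
  expect_equal(tab2$amplitude[1], 100)
  expect_equal(platonic_tiling_table(dihedral_n = 4)$frequency[7], 8)
})

test_that("mode eigenvalue is (2n)^2 - 1/4 = nu(nu+1)", {
  expect_equal(mode_eigenvalue(1), 3.75)
  n <- 1:10
  expect_equal(mode_eigenvalue(n), (2 * n - 1/2) * (2 * n + 1/2))
  expect_error(mode_eigenvalue(0), ">= 1")
})

test_that("the closed-form mode solves the Legendre ODE at its eigenvalue", {
  # symbolic-differentiation oracle: residual of
  # g'' + cot(th) g' + (lam - mu^2/sin^2 th) g for g = P_nu^{-1/2}(cos th)
  g_expr <- quote(sqrt(2 / (pi * sin(th))) * sin((nu + 1/2) * th) /
                  (nu + 1/2))
  d1 <- D(g_expr, "th")
  d2 <- D(d1, "th")
  th <- seq(0.3, pi - 0.3, length.out = 41)
  for (n in c(1, 2, 5, 10)) {
    nu <- 2 * n - 1/2
    env <- list2env(list(th = th, nu = nu))
    g <- eval(g_expr, env); g1 <- eval(d1, env); g2 <- eval(d2, env)
    lam <- mode_eigenvalue(n)
    resid <- g2 + cos(th) / sin(th) * g1 + (lam - 0.25 / sin(th)^2) * g
    expect_lt(max(abs(resid)) / max(abs(lam * g)), 1e-8)
  }
})

test_that("fractional Legendre closed forms agree with the series", {
  x <- seq(-0.9, 0.9, by = 0.15)
  expect_equal(fractional_legendre(1, 0, x), x, tolerance = 1e-12)
  for (nu in c(1.5, 2 * 1 - 0.5, 2 * 3 - 0.5)) {
    for (mu in c(-1/2, 1/2)) {
      closed <- fractional_legendre(nu, mu, x)
      series <- fractional_legendre(nu, mu, x, force_series = TRUE)
      expect_equal(closed, series, tolerance = 1e-10)
    }
  }
  # mu = 1/2 profile has the cos((nu+1/2) theta) reflection structure
  nu <- 3.5
  th <- seq(0.2, 1.4, by = 0.2)
  lhs <- fractional_legendre(nu, 1/2, cos(pi - th)) * sqrt(sin(pi - th))
  rhs <- cos((nu + 1/2) * (pi - th)) * sqrt(2 / pi)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(fractional_legendre(1, 0, 1), "inside")
})

test_that("mode norm quadrature converges and normalises the mode", {
  for (n in 1:10) expect_gt(mode_norm(n)$value, 0)
  # Richardson check: halving the step barely moves the value
  v1 <- mode_norm(3, n_grid = 1024L)$value
  v2 <- mode_norm(3, n_grid = 2048L)$value
  expect_lt(abs(v1 - v2), 1e-8)
  # analytic value 1/(4 n^2); normalised mode then has unit norm
  for (n in c(1, 4)) {
    nm <- mode_norm(n)
    expect_equal(nm$value, 1 / (4 * n^2), tolerance = 1e-10)
    expect_equal(nm$value / nm$value, 1)
    # the signed mixed-order integral vanishes identically
    expect_lt(abs(nm$product_integral), 1e-10)
    # the printed closed form disagrees; the discrepancy is reported
    expect_gt(nm$rel_discrepancy, 0)
  }
})

test_that("fractional harmonic has phi-independent modulus and known values", {
  th <- pi / 2
  mods <- Mod(fractional_harmonic(1, th, seq(-3, 3, by = 0.5)))
  expect_lt(diff(range(mods)), 1e-14)
  N1 <- 1 / sqrt(mode_norm(1)$value)
  expect_equal(Mod(fractional_harmonic(1, pi/2, 0)),
               N1 * (8 * pi)^(-1/2) * abs(cos(3 * pi / 4)),
               tolerance = 1e-12)
  # zeros where cos((2n - 1/2) theta) = 0
  n <- 2
  th0 <- (pi / 2) / (2 * n - 1/2)
  expect_lt(Mod(fractional_harmonic(n, th0, 0.3)), 1e-13)
  expect_error(fractional_harmonic(1, 0, 0), "singularity")
})

test_that("tiling solution vanishes on the triangle boundary only", {
  for (n in 1:10) {
    phis <- seq(-pi / (2 * n), pi / (2 * n), length.out = 21)
    expect_lt(max(abs(tiling_solution(n, pi / 2, phis))), 1e-12)
    ths <- seq(0.05, pi / 2, length.out = 21)
    expect_lt(max(abs(tiling_solution(n, ths, pi / (2 * n)))), 1e-12)
    expect_lt(max(abs(tiling_solution(n, ths, -pi / (2 * n)))), 1e-12)
  }
  # nodal structure comes from the cosine factors alone: no azimuthal sign
  # change strictly inside the tile, and a single sign radially within the
  # first lobe (before the first zero of the radial cosine)
  n <- 3
  first_zero <- pi / (2 * (4 * n - 1))
  th <- seq(0.03, first_zero - 0.02, length.out = 30)
  ph <- seq(-pi / (2 * n) + 0.02, pi / (2 * n) - 0.02, length.out = 30)
  grid <- expand.grid(th = th, ph = ph)
  vals <- tiling_solution(n, grid$th, grid$ph)
  expect_true(all(vals > 0) || all(vals < 0))
  # fixing theta in the first lobe, the sign never flips across phi
  signs <- sign(tiling_solution(n, rep(th[5], length(ph)), ph))
  expect_true(all(signs == signs[1]))
  expect_error(tiling_solution(2, pi, 0), "theta_p")
  expect_error(tiling_solution(2, 0.5, pi), "phi_p")
})
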