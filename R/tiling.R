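#' Enumerate Schwarz triples that tile the sphere
#'
#' A spherical triangle with angles \eqn{(\pi/p, \pi/q, \pi/r)}, integers
#' \eqn{p \le q \le r \ge 2}, tiles the sphere by reflections exactly when
#' \eqn{1/p + 1/q + 1/r > 1}. Besides the infinite dihedral family
#' (2, 2, n) there are only three solutions: (2, 3, 3), (2, 3, 4) and
#' (2, 3, 5), the tetrahedral, octahedral and icosahedral classes.
#'
#' @param r_max largest value of r scanned (>= 2).
#' @return A data frame with columns `p`, `q`, `r` and the logical
#'   `dihedral` (TRUE for the (2, 2, n) family).
#' @examples
#' enumerate_schwarz_triples(6)
#' @export
enumerate_schwarz_triples <- function(r_max) {
  r_max <- as.integer(r_max)
  if (r_max < 2L) stop("'r_max' must be >= 2")
  out <- list()
  for (p in 2:r_max) for (q in p:r_max) for (r in q:r_max) {
    if (1 / p + 1 / q + 1 / r > 1)
      out[[length(out) + 1L]] <- c(p, q, r)
  }
  m <- do.call(rbind, out)
  df <- data.frame(p = m[, 1L], q = m[, 2L], r = m[, 3L])
  df$dihedral <- df$p == 2L & df$q == 2L
  df[order(df$p, df$q, df$r), , drop = FALSE]
}

#' Area of a spherical triangle
#'
#' Spherical excess formula: a triangle with interior angles
#' \eqn{(\alpha, \beta, \gamma)} on a sphere of radius R has area
#' \eqn{A = R^2 (\alpha + \beta + \gamma - \pi)}. Requires angle sum
#' strictly greater than \eqn{\pi} (the flat/hyperbolic case carries no
#' spherical tile).
#'
#' @param alpha,beta,gamma interior angles in radians.
#' @param R sphere radius (default 1).
#' @return The triangle area.
#' @examples
#' spherical_triangle_area(pi/2, pi/2, pi/2)  # one octant: pi/2
#' @export
spherical_triangle_area <- function(alpha, beta, gamma, R = 1) {
  excess <- alpha + beta + gamma - pi
  if (any(excess <= 0))
    stop("angle sum must exceed pi: flat or hyperbolic triangle")
  R^2 * excess
}

#' Hypergeometric parameters of a Schwarz triple
#'
#' The radial equation on the tiled sphere is hypergeometric with regular
#' singular points at 0, 1 and infinity; the solution triangle has angles
#' \eqn{\pi|1-c|, \pi|c-a-b|, \pi|a-b|}. Given a Schwarz triple this
#' returns one parameter set on the documented branch
#' \eqn{1 - c = 1/p}, \eqn{c - a - b = 1/q}, \eqn{a - b = 1/r} with
#' \eqn{a \ge b}; any branch reproduces the same angle multiset.
#'
#' @param p,q,r a Schwarz triple (integers >= 2 with 1/p+1/q+1/r > 1).
#' @return Named numeric vector `c(a =, b =, c =)`.
#' @examples
#' hypergeometric_params(2, 2, 4)
#' @export
hypergeometric_params <- function(p, q, r) {
  if (any(c(p, q, r) < 2)) stop("p, q, r must be >= 2")
  if (1 / p + 1 / q + 1 / r <= 1)
    stop("not a spherical (Schwarz) triple: 1/p + 1/q + 1/r must exceed 1")
  cc <- 1 - 1 / p
  apb <- cc - 1 / q
  amb <- 1 / r
  c(a = (apb + amb) / 2, b = (apb - amb) / 2, c = cc)
}

#' Triangle angles realised by hypergeometric parameters
#'
#' Inverse map of [hypergeometric_params()]: the angles (as fractions of
#' \eqn{\pi}) carried by the three singular points.
#'
#' @param params named vector with entries `a`, `b`, `c`.
#' @return Numeric vector `(|1-c|, |c-a-b|, |a-b|)`.
#' @export
schwarz_angles <- function(params) {
  a <- params[["a"]]; b <- params[["b"]]; cc <- params[["c"]]
  c(abs(1 - cc), abs(cc - a - b), abs(a - b))
}

# Table 1 band label for a tile count
band_for_count <- function(count) {
  if (count <= 1) "delta"
  else if (count <= 5) "theta"
  else if (count <= 9) "alpha"
  else if (count <= 30) "beta"
  else "gamma"
}

#' Predicted EEG band table of sphere tilings
#'
#' Each tiling class covers the sphere with `N` identical tiles; the mode
#' confined to one tile oscillates with frequency proportional to `N` and,
#' by the inverse amplitude-frequency law \eqn{a_N \nu_N = \mathrm{const}},
#' with amplitude `base_amplitude / N`. Scales are fixed by assigning the
#' uniform (delta) excitation of the whole sphere frequency
#' `base_frequency` and amplitude `base_amplitude` microvolts. Rows cover
#' the sphere, the five Platonic classes and one dihedral class with `2n`
#' orange-segment tiles.
#'
#' @param base_frequency frequency of the whole-sphere mode (default 1).
#' @param base_amplitude amplitude of the whole-sphere mode in microvolts
#'   (default 200).
#' @param dihedral_n dihedral index n; the class has `2n` tiles
#'   (default 20, the 40-tile gamma-band class).
#' @return Data frame with columns `name`, `tile_count`, `frequency`,
#'   `band`, `amplitude` (rounded to the nearest microvolt).
#' @examples
#' platonic_tiling_table()
#' @export
platonic_tiling_table <- function(base_frequency = 1, base_amplitude = 200,
                                  dihedral_n = 20L) {
  if (base_frequency <= 0 || base_amplitude <= 0)
    stop("scales must be positive")
  counts <- c(sphere = 1L, tetrahedron = 4L, cube = 6L, octahedron = 8L,
              dodecahedron = 12L, icosahedron = 20L)
  counts <- c(counts, dihedral = 2L * as.integer(dihedral_n))
  data.frame(
    name = names(counts),
    tile_count = as.integer(counts),
    frequency = counts * base_frequency,
    band = vapply(counts, band_for_count, character(1)),
    amplitude = round(base_amplitude / counts),
    row.names = NULL
  )
}

#' Eigenvalue of the n-th dihedral tiling mode
#'
#' The fractional Legendre mode of index n has degree
#' \eqn{\nu = 2n - 1/2} and Laplace eigenvalue
#' \eqn{\lambda_n = \nu(\nu+1) = (2n)^2 - 1/4}.
#'
#' @param n mode index (positive integer, vectorised).
#' @return \eqn{(2n)^2 - 1/4}.
#' @examples
#' mode_eigenvalue(1)  # 3.75
#' @export
mode_eigenvalue <- function(n) {
  if (any(n < 1)) stop("'n' must be >= 1")
  (2 * n)^2 - 1 / 4
}

# Gauss hypergeometric series 2F1(a, b; c; w), |w| < 1
hyp2f1_series <- function(a, b, cc, w, tol = 1e-14, max_terms = 5000L) {
  term <- 1
  total <- 1
  for (k in 0:(max_terms - 1L)) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * w
    total <- total + term
    if (abs(term) < tol * max(1, abs(total))) return(total)
  }
  warning("hypergeometric series did not converge to tolerance")
  total
}

#' Associated Legendre function of fractional degree
#'
#' Evaluates \eqn{P_\nu^\mu(x)} for real degree \eqn{\nu} and order
#' \eqn{\mu} on \eqn{-1 < x < 1}. For \eqn{\mu = \pm 1/2} the trigonometric
#' closed forms are used (with \eqn{x = \cos\theta}):
#' \deqn{P_\nu^{-1/2}(\cos\theta) = \sqrt{2/(\pi\sin\theta)}\,
#'   \frac{\sin((\nu+1/2)\theta)}{\nu+1/2}, \qquad
#'   P_\nu^{1/2}(\cos\theta) = \sqrt{2/(\pi\sin\theta)}\,
#'   \cos((\nu+1/2)\theta).}
#' Otherwise the defining hypergeometric representation
#' \eqn{P_\nu^\mu(x) = \frac{1}{\Gamma(1-\mu)}
#' \left(\frac{1+x}{1-x}\right)^{\mu/2} {}_2F_1(-\nu, \nu+1; 1-\mu;
#' (1-x)/2)} is summed term by term.
#'
#' @param nu real degree.
#' @param mu real order; \eqn{1 - \mu} must not be a non-positive integer.
#' @param x evaluation points in (-1, 1), vectorised.
#' @param force_series evaluate by the series even when a closed form
#'   exists (used for cross-checking).
#' @return Numeric vector of function values.
#' @examples
#' fractional_legendre(1, 0, 0.3)  # ordinary Legendre P1 = x
#' @export
fractional_legendre <- function(nu, mu, x, force_series = FALSE) {
  if (any(abs(x) >= 1)) stop("'x' must lie strictly inside (-1, 1)")
  if (!force_series && mu %in% c(-1/2, 1/2)) {
    theta <- acos(x)
    pref <- sqrt(2 / (pi * sin(theta)))
    if (mu == -1/2)
      return(pref * sin((nu + 1/2) * theta) / (nu + 1/2))
    return(pref * cos((nu + 1/2) * theta))
  }
  if (1 - mu <= 0 && abs(1 - mu - round(1 - mu)) < 1e-12)
    stop("order 'mu' makes 1 - mu a non-positive integer")
  vapply(x, function(xi) {
    ((1 + xi) / (1 - xi))^(mu / 2) / gamma(1 - mu) *
      Re(hyp2f1_series(-nu, nu + 1, 1 - mu, (1 - xi) / 2))
  }, numeric(1))
}

#' Quadrature norm of a dihedral tiling mode
#'
#' The n-th mode has angular profile \eqn{P_{2n-1/2}^{-1/2}(\cos\theta)};
#' its squared norm \eqn{\int_0^\pi \sin\theta\,
#' |P_{2n-1/2}^{-1/2}(\cos\theta)|^2 \, d\theta} is computed by composite
#' Simpson quadrature and equals \eqn{1/(4n^2)} analytically. A printed
#' closed-form expression built from \eqn{\Gamma(3/4)\Gamma(5/4)} factors
#' circulates for this quantity with an ambiguous grouping; it is evaluated
#' alongside and the relative discrepancy reported. The signed product
#' integral \eqn{\int \sin\theta\, P_\nu^{1/2} P_\nu^{-1/2}\, d\theta},
#' sometimes quoted as the definition, is identically zero (its integrand
#' is proportional to \eqn{\sin 4n\theta}) and is also reported.
#'
#' @param n mode index (>= 1).
#' @param n_grid number of quadrature intervals (even; default 2048).
#' @return List with `value` (the quadrature L2 norm, normative),
#'   `closed_form` (the printed Gamma-factor expression),
#'   `rel_discrepancy` between them, and `product_integral` (the signed
#'   mixed-order integral).
#' @export
mode_norm <- function(n, n_grid = 2048L) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  n_grid <- as.integer(n_grid)
  if (n_grid %% 2L) n_grid <- n_grid + 1L
  nu <- 2 * n - 1 / 2
  theta <- seq(0, pi, length.out = n_grid + 1L)
  # sin(theta) * |P^{-1/2}|^2 = (2/pi) sin^2((nu+1/2) theta)/(nu+1/2)^2
  f2 <- (2 / pi) * sin((nu + 1/2) * theta)^2 / (nu + 1/2)^2
  # sin(theta) * P^{1/2} P^{-1/2} = (1/pi) sin(2(nu+1/2) theta)/(nu+1/2)
  fp <- (1 / pi) * sin(2 * (nu + 1/2) * theta) / (nu + 1/2)
  simpson <- function(y, h) h / 3 * sum(y * c(1, rep(c(4, 2), length.out =
    length(y) - 2L), 1))
  h <- pi / n_grid
  value <- simpson(f2, h)
  closed <- 2 * pi * gamma(3/4) * gamma(5/4) *
    (4 * n + 2) / ((2 * n + 1/2) * (2 * n + 3/4))
  list(value = value,
       closed_form = closed,
       rel_discrepancy = abs(value - closed) / abs(closed),
       product_integral = simpson(fp, h))
}

#' Fractional spherical harmonic of the dihedral family
#'
#' Evaluates \deqn{Y_n(\theta, \phi) = N(n)\, e^{-i\phi/2}\,
#' (8\pi\sin\theta)^{-1/2} \cos((2n - 1/2)\theta),} the degree
#' \eqn{2n - 1/2}, order \eqn{-1/2} analogue of a spherical harmonic. The
#' normalisation \eqn{N(n) = 1/\sqrt{\mathrm{mode\_norm}(n)}} makes the
#' associated Legendre profile unit-norm. The modulus is independent of
#' \eqn{\phi}; the coordinate singularities \eqn{\theta \in \{0, \pi\}}
#' are rejected.
#'
#' @param n mode index (>= 1).
#' @param theta colatitude in (0, pi), vectorised.
#' @param phi azimuth in (-pi, pi], vectorised (recycled against theta).
#' @return Complex values of the harmonic.
#' @export
fractional_harmonic <- function(n, theta, phi) {
  if (any(n < 1)) stop("'n' must be >= 1")
  if (any(theta <= 0 | theta >= pi))
    stop("theta = 0 or pi is a coordinate singularity of the harmonic")
  N <- 1 / sqrt(mode_norm(n)$value)
  N * exp(-1i * phi / 2) * (8 * pi * sin(theta))^(-1/2) *
    cos((2 * n - 1/2) * theta)
}

#' Tiling solution on the fundamental spherical triangle
#'
#' In the primed coordinates \eqn{\theta' = \theta/2 \in (0, \pi/2]},
#' \eqn{\phi' = \phi/(2n) \in [-\pi/(2n), \pi/(2n)]}, the mode confined to
#' one dihedral tile is
#' \deqn{S(\theta', \phi') = \frac{1}{n} \cos(n\phi')\,
#'   \cos((4n-1)\theta')\, w(\theta'), \qquad w(\theta') =
#'   \sqrt{\sin\theta'},}
#' which vanishes on all three sides of the triangle
#' (\eqn{\theta' = \pi/2} and \eqn{\phi' = \pm\pi/(2n)}) through the two
#' cosine factors; the bounded radial weight w leaves those zeros intact.
#' The interior of the fundamental tile carries a single sign: the mode is
#' a localized bump, not an interior-nodal oscillation.
#'
#' @param n dihedral index (>= 1).
#' @param theta_p primed colatitude in (0, pi/2].
#' @param phi_p primed azimuth in \eqn{[-\pi/(2n), \pi/(2n)]}.
#' @return Numeric values of the tile mode.
#' @examples
#' tiling_solution(2, pi/4, 0)
#' @export
tiling_solution <- function(n, theta_p, phi_p) {
  if (any(n < 1)) stop("'n' must be >= 1")
  if (any(theta_p <= 0 | theta_p > pi / 2))
    stop("theta_p must lie in (0, pi/2]")
  if (any(abs(phi_p) > pi / (2 * n) + 1e-15))
    stop("phi_p must lie in [-pi/(2n), pi/(2n)]")
  (1 / n) * cos(n * phi_p) * cos((4 * n - 1) * theta_p) * sqrt(sin(theta_p))
}
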