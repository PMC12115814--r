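#' Modal basis of dihedral tiling modes
#'
#' The dihedral tiling modes form a complete set on the sphere; on the
#' meridian arc \eqn{z = \theta \in [0, \pi]} their angular profiles
#' reduce to \eqn{\phi_n(z) = \sqrt{2/\pi}\, \cos((2n - 1/2) z)}, an
#' orthonormal family in \eqn{L^2(0, \pi)}, with wave-equation
#' frequencies \eqn{\omega_n = \sqrt{\lambda_n} = \sqrt{(2n)^2 - 1/4}}
#' (scaled units). Both the eigenvalue \eqn{\lambda_n} and its square
#' root are carried: the band table of [platonic_tiling_table()] uses the
#' tile-count scale, the wave operator uses \eqn{\omega_n}.
#'
#' @param n_max number of modes (>= 1).
#' @return Object of class `"modal_basis"`: list with `n`, `eigenvalue`,
#'   `omega` (strictly increasing) and the mode function factory `phi`
#'   (`phi(n)` returns a vectorised function of z).
#' @export
modal_basis <- function(n_max) {
  n_max <- as.integer(n_max)
  if (n_max < 1L) stop("'n_max' must be >= 1")
  n <- seq_len(n_max)
  structure(list(
    n = n,
    eigenvalue = mode_eigenvalue(n),
    omega = sqrt(mode_eigenvalue(n)),
    phi = function(k) {
      force(k)
      function(z) sqrt(2 / pi) * cos((2 * k - 1 / 2) * z)
    }),
    class = "modal_basis")
}

#' @export
print.modal_basis <- function(x, ...) {
  cat("Dihedral modal basis with", length(x$n), "modes\n")
  cat("  omega:", paste(format(x$omega, digits = 5), collapse = ", "), "\n")
  invisible(x)
}

#' Causal Green's function of the surface wave operator
#'
#' Eigenfunction expansion of the retarded Green's function of
#' \eqn{\partial_t^2 + \lambda} on the modal basis:
#' \deqn{G(z, t; z', t') = \sum_n \phi_n(z) \phi_n(z')
#'   \frac{\sin(\omega_n (t - t'))}{\omega_n}, \quad t \ge t',}
#' and 0 for t < t' (causality). Symmetric under \eqn{z \leftrightarrow
#' z'}; away from t = t' each term solves the free oscillator equation.
#'
#' @param basis a [modal_basis()].
#' @param z,zp field and source positions on the arc \eqn{[0, \pi]}.
#' @param t,tp field and source times.
#' @return The Green's function value (scalar; `z`, `zp` may be vectors of
#'   equal length for elementwise evaluation).
#' @export
greens_function <- function(basis, z, t, zp, tp) {
  stopifnot(inherits(basis, "modal_basis"))
  if (t < tp) return(0 * (z + zp))
  out <- 0
  for (k in basis$n) {
    f <- basis$phi(k)
    out <- out + f(z) * f(zp) * sin(basis$omega[k] * (t - tp)) /
      basis$omega[k]
  }
  out
}

#' Localized input signal on the sphere arc
#'
#' A point-like source at arc position `z0`, mollified to a narrow
#' Gaussian of width `width` for quadrature, with one of three time
#' courses: `"transient"` \eqn{V_0 e^{-a_0 t}}, `"oscillatory"`
#' \eqn{V_0 \cos(\omega_0 t)} or `"blocking"` (a Gaussian envelope, see
#' [blocking_excitation()] for the two-point surface version). The
#' source acts inside the window `(t_on, t_off)` and vanishes outside.
#'
#' @param kind `"transient"`, `"oscillatory"` or `"blocking"`.
#' @param z0 source arc position in \eqn{(0, \pi)}.
#' @param V0 amplitude.
#' @param rate decay rate a0 (transient) or Gaussian rate (blocking).
#' @param omega0 drive frequency (oscillatory).
#' @param t_on,t_off activity window.
#' @param width mollifier width in radians (default 0.01).
#' @return Object of class `"input_signal"`.
#' @export
input_signal <- function(kind = c("transient", "oscillatory", "blocking"),
                         z0 = pi / 2, V0 = 1, rate = 1, omega0 = 1,
                         t_on = 0, t_off = Inf, width = 0.01) {
  kind <- match.arg(kind)
  structure(list(kind = kind, z0 = z0, V0 = V0, rate = rate,
                 omega0 = omega0, t_on = t_on, t_off = t_off,
                 width = width),
            class = "input_signal")
}

# normalised Gaussian mollifier of a point source
mollified_delta <- function(z, z0, width) {
  stats::dnorm(z, mean = z0, sd = width)
}

input_time_course <- function(input, t) {
  f <- switch(input$kind,
    transient = input$V0 * exp(-input$rate * pmax(t, 0)),
    oscillatory = input$V0 * cos(input$omega0 * t),
    blocking = input$V0 * exp(-(input$rate * t)^2))
  f * (t >= input$t_on & t <= input$t_off)
}

#' Modal response of the tiling basis to an input signal
#'
#' Evaluates the field \eqn{m(z, t) = \int dt' \int dz'\,
#' G(z, t; z', t')\, s(z', t')} by projecting the source onto the modal
#' basis and convolving each modal coefficient with
#' \eqn{\sin(\omega_n (t - t'))/\omega_n} on a uniform time grid
#' (trapezoidal quadrature). Zero input gives a zero field; the response
#' is linear in the input amplitude; an oscillatory input resonant with
#' mode k pumps that mode's amplitude linearly in time while off-resonant
#' modes stay bounded.
#'
#' @param basis a [modal_basis()].
#' @param input an [input_signal()].
#' @param z_grid arc positions at which the field is returned.
#' @param t_final end time (> 0).
#' @param dt time step; default \eqn{2\pi / (20\, \omega_{max})}.
#' @return List with `z` (grid), `t` (time grid), `field` (matrix, rows =
#'   z, cols = t) and `mode_amplitude` (matrix, rows = modes, cols = t:
#'   the modal coefficients \eqn{q_n(t)}).
#' @export
respond <- function(basis, input, z_grid = seq(0.05, pi - 0.05,
                    length.out = 64L), t_final,
                    dt = 2 * pi / (20 * max(basis$omega))) {
  stopifnot(inherits(basis, "modal_basis"), inherits(input, "input_signal"))
  if (t_final <= 0) stop("'t_final' must be positive")
  t <- seq(0, t_final, by = dt)
  nt <- length(t)

  # spatial projection of the mollified point source onto each mode
  zq <- seq(0, pi, length.out = 2001L)
  wq <- rep(zq[2L] - zq[1L], length(zq)); wq[c(1L, length(zq))] <- wq[1L] / 2
  gz <- mollified_delta(zq, input$z0, input$width)
  cn <- vapply(basis$n, function(k) sum(basis$phi(k)(zq) * gz * wq),
               numeric(1))

  f <- input_time_course(input, t)
  trap <- rep(dt, nt); trap[c(1L, nt)] <- dt / 2
  q <- matrix(0, nrow = length(basis$n), ncol = nt)
  for (k in seq_along(basis$n)) {
    om <- basis$omega[k]
    # q_k(t_i) = sum_j<=i sin(om (t_i - t_j))/om * c_k f(t_j) w_j
    S <- sin(om * outer(t, t, "-")) / om
    S[outer(t, t, "<")] <- 0
    q[k, ] <- as.vector(S %*% (cn[k] * f * trap))
  }
  phi_z <- vapply(basis$n, function(k) basis$phi(k)(z_grid),
                  numeric(length(z_grid)))
  list(z = z_grid, t = t, field = phi_z %*% q, mode_amplitude = q)
}

#' Blocking excitation on the sphere surface
#'
#' A localized transient at \eqn{(\theta_0, \phi_0)} with Gaussian
#' envelope \eqn{e^{-(\omega_n t)^2}} switched on at t = 0, minus a
#' finite-window term of duration \eqn{1/\alpha} at the shifted location
#' \eqn{(\theta_0 + \Delta, \phi_0 + \Delta)}. Point sources are
#' mollified to narrow Gaussians whose spatial integral is 1
#' independently of the width.
#'
#' @param t time(s).
#' @param theta,phi evaluation point on the sphere.
#' @param theta0,phi0 excitation centre.
#' @param Delta location shift of the blocking term (>= 0).
#' @param alpha inverse duration of the blocking window (> 0).
#' @param omega_n envelope frequency.
#' @param width mollifier width in radians.
#' @return Excitation value(s); identically 0 for t < 0.
#' @export
blocking_excitation <- function(t, theta, phi, theta0 = pi / 2, phi0 = 0,
                                Delta = 0.2, alpha = 1, omega_n = 1,
                                width = 0.01) {
  if (Delta < 0) stop("'Delta' must be >= 0")
  if (alpha <= 0) stop("'alpha' must be positive")
  g <- function(th, ph, th0, ph0)
    mollified_delta(th, th0, width) * mollified_delta(ph, ph0, width)
  term1 <- g(theta, phi, theta0, phi0) * exp(-(omega_n * t)^2) * (t >= 0)
  term2 <- g(theta, phi, theta0 + Delta, phi0 + Delta) *
    (t >= 0 & t <= 1 / alpha)
  term1 - term2
}

#' K-complex waveform
#'
#' A biphasic deep-sleep transient modelled as two Gaussian-windowed
#' cosines of mode frequency \eqn{\omega_n = \sqrt{(2n)^2 - 1/4}}:
#' \deqn{M_1(t) = -\frac{A}{n} e^{-(\omega_n t)^2} \cos(\omega_n t),
#'   \; -T < t < T, \qquad
#'   M_2(t) = +\frac{A}{n} e^{-(\omega_n (t - 2T))^2} \cos(\omega_n t),
#'   \; T < t < 3T,}
#' glued continuously at t = T by a raised-cosine taper on
#' \eqn{(T - \epsilon, T + \epsilon)}, \eqn{\epsilon = 0.05 T}. Outside
#' \eqn{(-T, 3T)} the waveform is 0.
#'
#' @param t time(s), vectorised.
#' @param A amplitude scale.
#' @param n mode index (>= 1).
#' @param T half-window (s, > 0).
#' @param eps_frac taper half-width as a fraction of T (default 0.05).
#' @return Waveform value(s).
#' @examples
#' kcomplex_waveform(0, A = 1, n = 1, T = 5)  # -A/n
#' @export
kcomplex_waveform <- function(t, A = 1, n = 1L, T = 5, eps_frac = 0.05) {
  if (T <= 0) stop("'T' must be positive")
  om <- sqrt(mode_eigenvalue(n))
  m1 <- -(A / n) * exp(-(om * t)^2) * cos(om * t)
  m2 <- (A / n) * exp(-(om * (t - 2 * T))^2) * cos(om * t)
  eps <- eps_frac * T
  s <- ifelse(t <= T - eps, 0,
       ifelse(t >= T + eps, 1,
              (1 - cos(pi * (t - (T - eps)) / (2 * eps))) / 2))
  out <- (1 - s) * m1 + s * m2
  out * (t > -T & t < 3 * T)
}

#' Sleep-spindle modulation pair
#'
#' The resonant excitation of a memory structure by a high-voltage slow
#' wave modulates the surface potential as
#' \deqn{\Delta V = N_s \frac{\mu B}{e} \sin(t) \sin(\omega_0 t),
#' \quad 0 \le t \le T,} with the slow-wave scale set to unit frequency.
#' The paired-spin secondary structure contributes \eqn{\Delta V_2} of
#' the same form at frequency \eqn{2\omega_0} and twice the amplitude.
#' Both vanish outside `[0, T]`.
#'
#' @param t time(s), vectorised.
#' @param Ns cluster size (number of contributing spins/pulses).
#' @param mu_B_product interaction energy \eqn{\mu B} (erg).
#' @param omega0 memory excitation frequency (rad/s).
#' @param T spindle duration (s).
#' @param e_charge elementary charge (esu) converting energy to voltage.
#' @return List with vectors `dV` and `dV2`.
#' @export
spindle_modulation <- function(t, Ns = 1000, mu_B_product = 1e-26,
                               omega0 = 12, T = 6,
                               e_charge = 4.8e-10) {
  inside <- t >= 0 & t <= T
  amp <- Ns * mu_B_product / e_charge
  dv <- amp * sin(t) * sin(omega0 * t) * inside
  dv2 <- 2 * amp * sin(t) * sin(2 * omega0 * t) * inside
  list(dV = dv, dV2 = dv2)
}

#' Spindle excitation threshold
#'
#' A slow wave excites the memory structure only if the energy it gives a
#' surface electron exceeds the structure's quantum:
#' `electron_energy > N * hbar * omega0` (strict).
#'
#' @param electron_energy energy delivered to the electron (erg).
#' @param N number of electrons in the memory structure.
#' @param omega0 memory frequency (rad/s).
#' @param hbar reduced Planck constant (erg s).
#' @return Logical: is the threshold exceeded?
#' @export
spindle_threshold <- function(electron_energy, N, omega0, hbar = 1e-27) {
  if (any(c(electron_energy, N, omega0, hbar) <= 0))
    stop("all inputs must be positive")
  electron_energy > N * hbar * omega0
}

#' Map dendrite twist numbers to a tiling class
#'
#' Three input spin topology numbers entering a neuron's three primary
#' dendrites fix the boundary phases of the surface oscillation. The
#' triple (2, 2, 2n) selects the dihedral tiling of frequency 2n; the
#' triples (2, 3, 3), (2, 3, 4) and (2, 3, 5) select the tetrahedral,
#' octahedral and icosahedral classes ((2, 3, 4) is the shared symmetry
#' of cube and octahedron and is reported as the octahedron row). Any
#' other triple matches no spherical tiling and returns `NULL`.
#'
#' @param w1,w2,w3 positive integer twist numbers.
#' @param base_frequency,base_amplitude scales passed to the band table.
#' @return A one-row data frame (a [platonic_tiling_table()] row, with a
#'   dihedral row rebuilt at the matching n), or `NULL`.
#' @examples
#' dendrite_twists_to_tiling(2, 2, 8)
#' @export
dendrite_twists_to_tiling <- function(w1, w2, w3, base_frequency = 1,
                                      base_amplitude = 200) {
  w <- sort(as.integer(c(w1, w2, w3)))
  if (any(w < 1)) stop("twist numbers must be positive integers")
  tab <- platonic_tiling_table(base_frequency, base_amplitude)
  if (w[1L] == 2L && w[2L] == 2L && w[3L] >= 2L && w[3L] %% 2L == 0L) {
    n <- w[3L] %/% 2L
    tab <- platonic_tiling_table(base_frequency, base_amplitude,
                                 dihedral_n = n)
    return(tab[tab$name == "dihedral", , drop = FALSE])
  }
  key <- paste(w, collapse = ",")
  name <- switch(key,
                 "2,3,3" = "tetrahedron",
                 "2,3,4" = "octahedron",
                 "2,3,5" = "icosahedron",
                 return(NULL))
  tab[tab$name == name, , drop = FALSE]
}
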