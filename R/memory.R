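#' Physical constants of the spin-memory model (CGS)
#'
#' All memory computations are done in CGS units, the convention in which
#' the model's order-of-magnitude ledger is stated. Defaults: proton
#' magnetic moment \eqn{\mu = 10^{-23}} erg/gauss, \eqn{\hbar = 10^{-27}}
#' erg s, speed of light in the medium \eqn{c = 10^{10}} cm/s,
#' inter-proton spacing \eqn{d = 10^{-8}} cm, axon circumference
#' \eqn{2\pi r_a = 10^{-3}} cm, pulse duration \eqn{\Delta t = 10^{-3}} s,
#' thermal energy \eqn{kT = 10^{-14}} erg, elementary charge
#' \eqn{e = 4.8\times 10^{-10}} esu.
#'
#' @param mu proton magnetic moment (erg/gauss).
#' @param hbar reduced Planck constant (erg s).
#' @param c_light speed of light in the medium (cm/s).
#' @param d inter-proton spacing (cm).
#' @param circumference axon circumference 2 pi r_a (cm).
#' @param dt_pulse duration of one pulse (s).
#' @param kT thermal energy at body temperature (erg).
#' @param e_charge elementary charge (esu).
#' @return Object of class `"memory_constants"`.
#' @export
memory_constants <- function(mu = 1e-23, hbar = 1e-27, c_light = 1e10,
                             d = 1e-8, circumference = 1e-3,
                             dt_pulse = 1e-3, kT = 1e-14,
                             e_charge = 4.8e-10) {
  vals <- list(mu = mu, hbar = hbar, c_light = c_light, d = d,
               circumference = circumference, dt_pulse = dt_pulse,
               kT = kT, e_charge = e_charge)
  if (any(unlist(vals) <= 0)) stop("all constants must be positive")
  structure(vals, class = "memory_constants")
}

#' @export
print.memory_constants <- function(x, ...) {
  cat("Memory-model constants (CGS):\n")
  for (nm in names(x)) cat(sprintf("  %-13s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Counts describing one memory strand
#'
#' `Nc` proton spins sit on one circle of the axon surface and are aligned
#' together; each pulse carries `N0` charge units; `Ns` pulses contribute
#' to the strand; `B0` is the magnetic field per unit charge (default
#' \eqn{10^{-9}} gauss, the field of a unit charge moving at signal speed
#' at axon radius).
#'
#' @param Nc spins per circle (positive integer).
#' @param N0 charge units per pulse (positive integer).
#' @param Ns number of pulses (positive integer).
#' @param B0 field per unit charge (gauss).
#' @return Object of class `"memory_strand"`.
#' @export
memory_strand <- function(Nc = 1e5, N0 = 10, Ns = 1000, B0 = 1e-9) {
  if (any(c(Nc, N0, Ns, B0) <= 0)) stop("all strand numbers must be positive")
  structure(list(Nc = Nc, N0 = N0, Ns = Ns, B0 = B0),
            class = "memory_strand")
}

#' Helical magnetic field of a moving charge pulse
#'
#' A charge Q moving at speed v along a tube of radius r produces a field
#' of magnitude \eqn{B = Q v / (c r^2)} (CGS), tangential to the surface
#' and winding helically: components
#' \eqn{(B\cos(2\pi z/r), B\sin(2\pi z/r), 0)} with period r in z.
#'
#' @param Q charge (esu).
#' @param v speed (cm/s).
#' @param r tube radius (cm, > 0).
#' @param z position(s) along the tube (cm).
#' @param consts a [memory_constants()] (supplies c).
#' @return Matrix with one row per z value and columns `Bx`, `By`, `Bz`
#'   (gauss); attribute `magnitude` holds B.
#' @export
helical_field <- function(Q, v, r, z, consts = memory_constants()) {
  if (r <= 0) stop("'r' must be positive")
  B <- Q * v / (consts$c_light * r^2)
  out <- cbind(Bx = B * cos(2 * pi * z / r),
               By = B * sin(2 * pi * z / r),
               Bz = rep(0, length(z)))
  attr(out, "magnitude") <- B
  out
}

#' Number of proton spins on one axon circle
#'
#' \eqn{N_c = } circumference / spacing, rounded to the nearest integer:
#' with the default \eqn{2\pi r_a = 10^{-3}} cm and \eqn{d = 10^{-8}} cm,
#' \eqn{N_c = 10^5}.
#'
#' @param consts a [memory_constants()].
#' @return Integer-valued count (returned as numeric to allow 1e5-scale
#'   values).
#' @export
spins_per_circle <- function(consts = memory_constants()) {
  round(consts$circumference / consts$d)
}

#' Memory excitation frequency
#'
#' The aligned-spin structure created by pulses of charge `N0` resonates
#' at \eqn{\omega = N_c \mu N_0 B_0 / \hbar}; the naturally paired-spin
#' secondary structure resonates at twice that frequency. With the default
#' constants and N0 = 10 the base frequency is 10 Hz, inside the EEG
#' alpha/spindle range.
#'
#' @param strand a [memory_strand()].
#' @param consts a [memory_constants()].
#' @return List with `omega` (Hz) and `omega_paired = 2 * omega`.
#' @export
memory_frequency <- function(strand = memory_strand(),
                             consts = memory_constants()) {
  omega <- strand$Nc * consts$mu * strand$N0 * strand$B0 / consts$hbar
  list(omega = omega, omega_paired = 2 * omega)
}

#' Spin-alignment threshold
#'
#' Aligning a spin requires the accumulated interaction
#' \eqn{N_s N_0 N_c \mu B_0 \Delta t} to exceed \eqn{\hbar}, i.e.
#' \eqn{N_s N_0 > \hbar / (N_c \mu B_0 \Delta t)}. With the default
#' constants the threshold on the product is \eqn{10^3}: a single pulse
#' cannot align spins unless it carries a thousand charge units.
#'
#' @param strand a [memory_strand()].
#' @param consts a [memory_constants()].
#' @return List with `threshold` (on the product Ns * N0), `product`
#'   (= Ns * N0) and logical `satisfied`.
#' @export
alignment_threshold <- function(strand = memory_strand(),
                                consts = memory_constants()) {
  thr <- consts$hbar / (strand$Nc * consts$mu * strand$B0 * consts$dt_pulse)
  prod <- strand$Ns * strand$N0
  list(threshold = thr, product = prod, satisfied = prod > thr)
}

#' Helical spin structure written by a pulse train
#'
#' The transient field of moving pulses leaves the unit-modulus phase
#' profile \eqn{S(z) = e^{-i\kappa z} S_L} along the traversed path,
#' \eqn{0 \le z \le L}, with wavenumber
#' \eqn{\kappa = N_c \mu N_0 B / (\hbar v)} and helical pitch
#' \eqn{2\pi/\kappa}. The identity \eqn{\kappa v = \omega} ties the
#' spatial winding to the memory excitation frequency when B = B0.
#'
#' @param strand a [memory_strand()].
#' @param v pulse speed (cm/s, > 0).
#' @param B acting magnetic field (gauss; default the strand's B0).
#' @param L path length (cm).
#' @param S_L initial spin orientation at z = 0 (complex, unit modulus).
#' @param consts a [memory_constants()].
#' @return Object of class `"spin_structure"`: list with `phase` (a
#'   function of z returning complex unit-modulus values), `kappa`,
#'   `pitch` and `L`.
#' @export
spin_structure <- function(strand = memory_strand(), v, B = strand$B0,
                           L = 1, S_L = 1 + 0i,
                           consts = memory_constants()) {
  if (v <= 0) stop("'v' must be positive")
  kappa <- strand$Nc * consts$mu * strand$N0 * B / (consts$hbar * v)
  structure(list(
    phase = function(z) {
      if (any(z < 0 | z > L)) stop("z must lie in [0, L]")
      exp(-1i * kappa * z) * S_L
    },
    kappa = kappa, pitch = 2 * pi / kappa, L = L, S_L = S_L),
    class = "spin_structure")
}

#' @export
print.spin_structure <- function(x, ...) {
  cat(sprintf(
    "Helical spin structure: kappa = %.4g /cm, pitch = %.4g cm, L = %g cm\n",
    x$kappa, x$pitch, x$L))
  invisible(x)
}

#' Thermal stability of the aligned-spin structure
#'
#' Blocks of `Nc` spins aligned as a unit interact with binding energy
#' \eqn{E = (N_c \mu)^2 / d^3}; the structure survives body-temperature
#' fluctuations when E > kT. With the defaults,
#' \eqn{E = 10^{-12}} erg against \eqn{kT = 10^{-14}} erg.
#'
#' @param strand a [memory_strand()].
#' @param consts a [memory_constants()].
#' @return List with `binding` (erg) and logical `stable`.
#' @export
thermal_stability <- function(strand = memory_strand(),
                              consts = memory_constants()) {
  binding <- (strand$Nc * consts$mu)^2 / consts$d^3
  list(binding = binding, stable = binding > consts$kT)
}

#' Does an MRI field disrupt the memory structure?
#'
#' The disruptive energy of an external field acting on a cluster of
#' aligned spins is `cluster * mu * B_mri`; it destroys the structure only
#' if it exceeds the spin-spin binding energy of [thermal_stability()].
#' For any clinical field strength this energy is orders of magnitude
#' below the binding, so MRI can perturb but not erase the structure.
#'
#' @param consts a [memory_constants()].
#' @param B_mri applied field (gauss, > 0); 3 T = 3e4 gauss.
#' @param cluster number of spins acted on coherently (default 1).
#' @param strand a [memory_strand()] (for the binding energy).
#' @return List with `disruption` (erg), `binding` (erg) and logical
#'   `destroys`.
#' @export
mri_disruption <- function(consts = memory_constants(), B_mri = 3e4,
                           cluster = 1, strand = memory_strand()) {
  if (B_mri <= 0) stop("'B_mri' must be positive")
  disruption <- cluster * consts$mu * B_mri
  binding <- thermal_stability(strand, consts)$binding
  list(disruption = disruption, binding = binding,
       destroys = disruption > binding)
}

#' Engram size and creation time
#'
#' A topologically stable memory needs a non-zero spin topology number W,
#' realised by an assembly of `Ne = W - 1` neurons linked by looped
#' pathways. One strand of `Ns` pulses takes \eqn{\tau_s = N_s t_{pulse}}
#' to write; the full engram takes \eqn{\tau_e = W \tau_s}. Aligned spins
#' with W = 0 form no loop and represent short-term memories: the metrics
#' are replaced by a short-term flag.
#'
#' @param W spin topology number (integer >= 0).
#' @param strand a [memory_strand()] (supplies Ns).
#' @param t_pulse time to produce one pulse (s).
#' @return For W >= 1, list with `Ne`, `tau_s`, `tau_e` and
#'   `short_term = FALSE`; for W = 0, list with `short_term = TRUE`.
#' @export
engram_metrics <- function(W, strand = memory_strand(), t_pulse = 1e-3) {
  W <- as.integer(W)
  if (W < 0) stop("'W' must be a non-negative integer")
  if (strand$Ns < 1) stop("'Ns' must be >= 1")
  if (W < 1L)
    return(list(short_term = TRUE,
                note = "W = 0: no loop, not topologically stable"))
  tau_s <- strand$Ns * t_pulse
  list(Ne = W - 1L, tau_s = tau_s, tau_e = W * tau_s, short_term = FALSE)
}

#' Neurons firing when a composite engram activates
#'
#' A composite memory built from k independent clusters of sizes
#' \eqn{N_1, \dots, N_k} fires \eqn{N = \prod_i N_i} neurons when
#' activated.
#'
#' @param cluster_sizes positive integer vector.
#' @return The product of the cluster sizes.
#' @examples
#' engram_firing_count(c(2, 3, 4))
#' @export
engram_firing_count <- function(cluster_sizes) {
  if (!length(cluster_sizes) || any(cluster_sizes <= 0))
    stop("'cluster_sizes' must be a non-empty vector of positive integers")
  prod(cluster_sizes)
}

#' Full stability ledger of the spin-memory model
#'
#' Reproduces the model's table of numbers in one call: field per pulse,
#' spin-field interaction, alignment condition, excitation frequency,
#' spin-spin binding versus kT, and the engram metrics. Each entry is
#' reported as an exact float together with its order of magnitude
#' (power of ten) for comparison with approximate quoted values.
#'
#' @param strand a [memory_strand()].
#' @param consts a [memory_constants()].
#' @param W spin topology number of the engram (default 5).
#' @return A list of class `"memory_ledger"` with components `field`,
#'   `interaction`, `alignment`, `frequency`, `thermal`, `mri`, `engram`
#'   and `constants`.
#' @export
memory_ledger <- function(strand = memory_strand(),
                          consts = memory_constants(), W = 5L) {
  oom <- function(x) floor(log10(abs(x)))
  field <- strand$N0 * strand$B0
  interaction <- strand$Ns * strand$Nc * strand$N0 * consts$mu * strand$B0
  action <- interaction * consts$dt_pulse
  align <- alignment_threshold(strand, consts)
  freq <- memory_frequency(strand, consts)
  therm <- thermal_stability(strand, consts)
  mri <- mri_disruption(consts, strand = strand)
  eng <- engram_metrics(W, strand, consts$dt_pulse)
  structure(list(
    field = list(B_per_pulse = field, oom = oom(field)),
    interaction = list(H = interaction, action = action,
                       oom = oom(interaction)),
    alignment = align,
    frequency = freq,
    thermal = therm,
    mri = mri,
    engram = eng,
    Nc = spins_per_circle(consts),
    strand = strand, constants = consts),
    class = "memory_ledger")
}

#' @export
print.memory_ledger <- function(x, ...) {
  cat("Spin-memory stability ledger (CGS)\n")
  cat(sprintf("  spins per circle Nc      %g\n", x$Nc))
  cat(sprintf("  field per pulse          %.3g gauss (10^%d)\n",
              x$field$B_per_pulse, x$field$oom))
  cat(sprintf("  spin-field interaction   %.3g erg (10^%d)\n",
              x$interaction$H, x$interaction$oom))
  cat(sprintf("  alignment Ns*N0 = %g vs threshold %g: %s\n",
              x$alignment$product, x$alignment$threshold,
              if (x$alignment$satisfied) "aligned" else "not aligned"))
  cat(sprintf("  excitation frequency     %.3g Hz (paired %.3g Hz)\n",
              x$frequency$omega, x$frequency$omega_paired))
  cat(sprintf("  spin-spin binding        %.3g erg vs kT %.3g erg: %s\n",
              x$thermal$binding, x$constants$kT,
              if (x$thermal$stable) "stable" else "unstable"))
  cat(sprintf("  MRI disruption           %.3g erg: %s\n",
              x$mri$disruption,
              if (x$mri$destroys) "destroys" else "does not destroy"))
  if (isTRUE(x$engram$short_term)) {
    cat("  engram: W = 0, short-term memory (no loop)\n")
  } else {
    cat(sprintf("  engram: Ne = %d neurons, tau_s = %g s, tau_e = %g s\n",
                x$engram$Ne, x$engram$tau_s, x$engram$tau_e))
  }
  invisible(x)
}
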