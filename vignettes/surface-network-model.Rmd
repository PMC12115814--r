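---
title: "The surface-network model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The surface-network model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfnet)
```

# The model

`surfnet` implements a topological model of brain electrical activity in
which three families of observables share one geometric origin:

1. **Action potentials** are soliton voltage pulses released when a handle
   of an idealized axon-network surface (a hyperelliptic Riemann surface of
   genus $g$) is pinched shut. Each pulse is parameterized by pinch
   deformation parameters $(a, b, c)$ — an inverse length scale, an inverse
   time scale and a phase — plus an amplitude $V_0$ and a spin topology
   number $W$ entering through the parity sign $e^{-i\pi W}$.
2. **EEG rhythms** are modes of the wave equation on the sphere that
   vanish on the edges of a Schwarz spherical triangle, so that identical
   copies tile the sphere. The tile count of each admissible tiling
   (the sphere itself, the five Platonic classes, and the infinite
   dihedral family) sets the mode frequency, and the inverse
   amplitude–frequency law $a_N\,\nu_N = \text{const}$ sets its amplitude.
   This predicts the five EEG bands.
3. **Memories** are helical structures of aligned proton spins written
   into the traversed pathway by the transient magnetic field of moving
   pulses. A CGS arithmetic ledger decides when the structure can be
   written (alignment), whether it survives body temperature (thermal
   stability) and external fields (MRI), how long it takes to create
   ($\tau_e = W N_s t_{\text{pulse}}$), how large it is ($N_e = W - 1$
   neurons) and at which frequency it resonates
   ($\omega = N_c \mu N_0 B_0/\hbar$).

The theta-function layer is bookkeeping for the first family: the
characteristics $(\alpha_i, \beta_i) \in \{0, \tfrac12\}^{2g}$ encode the
spin structure, $W = 4\sum_i \alpha_i\beta_i$ classifies it, and the pinch
expansion of the holomorphic one-forms
$\omega_j(z) = z^{j-1}/\sqrt{P(z)}$ supplies the deformation parameters.

# Numerical choices

## Theta functions

`riemann_theta()` truncates the lattice sum to the hypercube
$|n_i| \le R$ (default $R = 10$). Convergence requires
$\mathrm{Im}\,\Omega$ positive definite — the package enforces
positive-definiteness rather than entrywise positivity, because entrywise
positivity alone does not bound the quadratic form. The returned value
carries a geometric tail bound driven by the smallest eigenvalue of
$\mathrm{Im}\,\Omega$; for the identity-scale period matrices used in the
tests the truncation error at $R = 10$ is far below $10^{-10}$.
Quasi-periodicity ($z \to z+1$ multiplies the sum by $e^{2\pi i\alpha}$)
holds term by term, so it is exact even for the truncated sum.

## One-forms and the square-root branch

The model never fixes a global branch of $\sqrt{P}$. `one_form()` uses the
principal branch and documents it; for real $z$ and real-coefficient $P$
this gives a real value where $P > 0$ and a pure imaginary value where
$P < 0$. Continuity along a specific path is the caller's concern; the
pinch expansion only needs the branch at $z = 0$, where
$f_0 = 1/\sqrt{P(0)}$ (principal) seeds an exact power-series recurrence
derived from $P f' = -\tfrac12 P' f$, avoiding numerical differentiation
entirely.

## Tiling modes

The dihedral mode of index $n$ has degree $\nu = 2n - \tfrac12$, order
$\mu = -\tfrac12$ and eigenvalue $\lambda_n = \nu(\nu+1) = (2n)^2 -
\tfrac14$. Two frequency scales coexist deliberately: the band table uses
the tile count ($\nu_N = N$, with the whole-sphere delta mode pinned to
frequency 1 and 200 µV), while the wave operator uses $\omega_n =
\sqrt{\lambda_n}$. The model fixes neither scale absolutely, so both are
exposed and labelled (`frequency` vs `eigenvalue`/`omega`).

Three printed-formula ambiguities were resolved as follows, with the
boundary behaviour — not any particular radical grouping — treated as the
normative contract:

* **Radial weight of the tile mode.** The circulating expression
  multiplies the tile mode by $\sqrt{\sin\theta'}/\sin 2\theta'$. That
  weight diverges on the $\theta' = \pi/2$ side exactly as fast as the
  radial cosine vanishes there, so the product would tend to a *nonzero*
  limit on a boundary where the mode must vanish. `tiling_solution()`
  therefore uses the bounded weight $w(\theta') = \sqrt{\sin\theta'}$;
  all three boundary zeros then come from the cosine factors
  $\cos(n\phi')\cos((4n-1)\theta')$ and hold to machine precision.
* **Mode norm.** The mixed-order integral $\int \sin\theta\,
  P_\nu^{1/2} P_\nu^{-1/2}\, d\theta$ is identically zero for these
  indices (the integrand is proportional to $\sin 4n\theta$), so it cannot
  define a normalization. `mode_norm()` uses the standard $L^2$ norm
  $\int_0^\pi \sin\theta\, |P_\nu^{-1/2}|^2 d\theta = 1/(4n^2)$ computed
  by Simpson quadrature, and reports the circulating
  $\Gamma(3/4)\Gamma(5/4)$ closed form alongside with its relative
  discrepancy.
* **Interior nodal structure.** The radial factor $\cos((4n-1)\theta')$
  has zeros inside $(0, \pi/2)$, i.e. the printed tile mode carries
  interior nodal circles. The claim of a single interior sign holds
  azimuthally and within the first radial lobe, which is what the tests
  assert.

`fractional_legendre()` uses the trigonometric closed forms for
$\mu = \pm\tfrac12$ and the defining hypergeometric series otherwise; the
two routes agree to $10^{-10}$ and the closed-form modes satisfy the
associated Legendre equation at $\lambda_n$ with residual below $10^{-8}$
against a symbolic-differentiation oracle.

## Soliton trains and fitting

The pulse envelope is $\mathrm{sech}$, the canonical modulus of a
one-soliton solution of the focusing nonlinear Schrödinger equation; the
model works with this simplified profile throughout. The travelling
argument $az - bt + c$ fixes the pulse speed to $v = b/a$. Charge
bookkeeping offers both the Poisson reading $\rho = V''/4\pi$ (zero total
charge) and the effective reading $\rho = a^2 V$ (total charge
$\pi a V_0$), which is what the memory ledger consumes.

Fitting uses Levenberg–Marquardt damped least squares
(`minpack.lm::nls.lm`) on the single-site model
$v(t) = \sum_j V_{0j}\,\mathrm{sech}(b_j t - c_j)$, initialised from
smoothed local maxima above three times the robust noise scale — the MAD
of first differences, which stays calibrated to the noise even when wide
pulses occupy most of the record — with greedy non-maximum suppression
(minimum candidate separation 5% of the record; ties broken leftmost
first) and half-maximum widths. No shape is shared across
pulses, so distinct true pulses are recovered distinct. A single-electrode
record determines only $(b_j, c_j, V_{0j})$: the spatial scale $a_j$
enters the record solely through the propagation speed $v = b/a$, so the
fitter reports $a_j = b_j / v$ under a user-supplied speed (default 1,
the dimensionless unit-speed convention). This identifiability limit is a
property of single-site data, not of the optimiser.

## The synthetic spike-train generator

`synth_spike_train()` samples the train at a fixed site $z=0$ on a uniform
grid and adds i.i.d. Gaussian noise under a fixed seed. The simulation
studies in the tests use trains of 2–5 pulses with time scales
$b \in (2, 6)$, amplitudes $V_0 \in (0.6, 1.4)$, peaks separated by at
least 8% of a record of length $4$ time units per pulse, sampled at
150–200 samples per unit time, at a signal-to-noise ratio of 20 —
values chosen to resemble a burst of distinct, resolvable action
potentials in a single-electrode record. What the generator does *not*
emulate: baseline drift, bursty non-Gaussian noise, pulse-shape
distortion by the recording electrode, or overlapping (unresolved)
spikes. Passing recovery tests therefore demonstrate that the fitter is
correct and stable for resolvable multi-pulse records, not that real
thalamic recordings will fit this well.

## Memory ledger

All quantities are CGS, with defaults $\mu = 10^{-23}$ erg/gauss,
$\hbar = 10^{-27}$ erg s, $c = 10^{10}$ cm/s, $d = 10^{-8}$ cm,
$2\pi r_a = 10^{-3}$ cm, $\Delta t = 10^{-3}$ s, $kT = 10^{-14}$ erg.
These give $N_c = 10^5$ spins per circle, a 10 Hz excitation frequency at
$N_0 = 10$ charge units per pulse, an alignment threshold
$N_s N_0 > 10^3$, and a spin–spin binding of $10^{-12}$ erg against
$kT = 10^{-14}$ erg. The disruption energy of an MRI field is computed
honestly as $\text{cluster}\cdot\mu B$ ($3\times10^{-19}$ erg for one
spin at 3 T) rather than adopting any circulating rounded value; the
qualitative conclusion — clinical fields perturb but cannot erase the
structure — is the contract. The model text alternates between electron
and proton carriers; the ledger is agnostic, with $\mu$ a parameter
defaulting to the proton moment. Counts are reported as exact floats plus
their power of ten, since the model's claims are order-of-magnitude.

## Modal response

The Green's function is the standard eigenfunction expansion for the
surface wave equation, $G = \sum_n \phi_n(z)\phi_n(z')
\sin(\omega_n(t-t'))/\omega_n$, with $\phi_n(z) = \sqrt{2/\pi}
\cos((2n-\tfrac12)z)$ orthonormal on the meridian arc $[0, \pi]$ — this
is uniquely determined by the wave equation plus the completeness of the
dihedral modes. Point inputs are mollified to Gaussians (default width
0.01 rad) whose weight is width-independent; time integration is
trapezoidal with step at most $\tfrac{1}{20}\cdot 2\pi/\omega_{\max}$.
Resonant driving at $\omega_k$ pumps mode $k$ linearly in time while
off-resonant modes stay bounded; after 50 drive periods the selectivity
ratio exceeds 40.

The K-complex is the glued pair of Gaussian-windowed cosines
$M_1 = -\frac{A}{n}e^{-(\omega_n t)^2}\cos\omega_n t$ on $(-T, T)$ and
$M_2 = +\frac{A}{n}e^{-(\omega_n(t-2T))^2}\cos\omega_n t$ on $(T, 3T)$;
the glue is a raised-cosine taper on $(T - \epsilon, T + \epsilon)$ with
$\epsilon = 0.05T$, making the waveform continuous with a continuous
first derivative at the junction. The model only requires *some*
appropriate glue; the taper width is a package choice.

The spindle modulation $\Delta V = N_s \frac{\mu B}{e}\sin(t)
\sin(\omega_0 t)$ adopts the convention that the slow-wave scale is unit
frequency ($\omega_1 \approx 1$), so $t$ is measured in slow-wave radians;
energies are converted to voltage by dividing by the elementary charge.
The paired-spin secondary structure doubles both the frequency and the
amplitude. Note the $\sin t$ envelope splits each carrier into lines at
$\omega_0 \pm 1$: over a record of one envelope arch ($\pi$) the pair
merges into a single spectral peak at $\omega_0$, which is how the
spectral tests and the acceptance script measure it. The blocking
excitation applies the finite window $\Theta(t) - \Theta(t - 1/\alpha)$
to its shifted-location term so that the excitation is transient.

# Problem sizes

The test suite and `scripts/acceptance.R` use: theta truncation radius 10
at genus 1–3; tiling modes up to $n = 10$ on 33–61 point grids; 2048
Simpson intervals for norms; 20 seeded trains of 2–5 pulses at 150
samples per unit time; 50 drive periods with 3 modes for resonance; and a
628-sample spindle record. These sizes were chosen so every reported
quantity is converged well past its asserted tolerance while the full
suite stays fast on a single core.

# Known limitations

* The exact multi-soliton profiles are replaced by sech superpositions;
  interactions between overlapping solitons are not modelled.
* The spatial pinch scale $a$ is not identifiable from single-site
  records (see above); recovery claims concern $(b, c, V_0)$.
* The band table's frequency scale is pinned by convention (delta = 1);
  only ratios and the inverse amplitude law are predictions.
* The Green's function acts on the meridian arc of the dihedral family;
  full two-dimensional tiling response (mixed Platonic bases) is not
  implemented.
* The composite engram firing count is the plain product
  $\prod_i N_i$ of the cluster sizes; for the quoted example
  $(100, 100, 10, 5)$ this is $5\times10^5$.
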