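#' Single soliton pulse with pinch parameters
#'
#' One travelling sech-profile voltage pulse
#' \eqn{V(z, t) = \cos(\pi W)\, V_0\, \mathrm{sech}(a z - b t + c)}. The
#' deformation (pinch) parameters are the inverse length scale `a`, the
#' inverse time scale `b` and the phase offset `c`; all variables are
#' dimensionless (z in units of a length scale z0, t in units of a time
#' scale t0). The spin topology number `W` enters only through the parity
#' sign \eqn{e^{-i\pi W} = \cos(\pi W)}. The sech envelope is the canonical
#' modulus of a one-soliton solution of the focusing nonlinear
#' Schroedinger equation, used here as a simplified representation of the
#' pulse profile.
#'
#' @param a inverse length scale (> 0).
#' @param b inverse time scale.
#' @param c phase offset.
#' @param V0 peak amplitude (voltage units, default 1).
#' @param W integer spin topology number (default 0).
#' @return Object of class `"pinch_pulse"` with the given fields plus the
#'   derived effective width `Delta = 1/a` and total effective charge
#'   `Q = pi * a * V0`.
#' @examples
#' p <- pinch_pulse(a = 1, b = 2, c = 0)
#' pulse_speed(p)
#' @export
pinch_pulse <- function(a, b, c, V0 = 1, W = 0L) {
  if (a <= 0) stop("'a' must be positive")
  structure(list(a = a, b = b, c = c, V0 = V0, W = as.integer(W),
                 Delta = 1 / a, Q = pi * a * V0),
            class = "pinch_pulse")
}

#' @export
print.pinch_pulse <- function(x, ...) {
  cat(sprintf(
    "Soliton pulse: a = %.4g, b = %.4g, c = %.4g, V0 = %.4g, W = %d\n",
    x$a, x$b, x$c, x$V0, x$W))
  cat(sprintf("  speed b/a = %.4g, width 1/a = %.4g, charge pi*a*V0 = %.4g\n",
              x$b / x$a, x$Delta, x$Q))
  invisible(x)
}

#' Train of soliton pulses
#'
#' @param ... `pinch_pulse` objects, or a single list of them.
#' @return Object of class `"soliton_train"` (a list of pulses).
#' @export
soliton_train <- function(...) {
  pulses <- list(...)
  if (length(pulses) == 1L && !inherits(pulses[[1L]], "pinch_pulse"))
    pulses <- pulses[[1L]]
  if (!length(pulses)) stop("a soliton train must contain at least one pulse")
  if (!all(vapply(pulses, inherits, logical(1), "pinch_pulse")))
    stop("all elements must be 'pinch_pulse' objects")
  structure(list(pulses = pulses), class = "soliton_train")
}

#' @export
print.soliton_train <- function(x, ...) {
  cat("Soliton train with", length(x$pulses), "pulse(s)\n")
  for (p in x$pulses) print(p)
  invisible(x)
}

sech <- function(x) 1 / cosh(x)

#' Voltage of a single pulse
#'
#' \eqn{V = \cos(\pi W)\, V_0\, \mathrm{sech}(a z - b t + c)}: even about
#' its peak, with peak value \eqn{\pm V_0} according to the parity of W.
#'
#' @param p a [pinch_pulse()].
#' @param z position(s), dimensionless.
#' @param t time(s), dimensionless.
#' @return Voltage value(s).
#' @export
pulse_voltage <- function(p, z, t) {
  stopifnot(inherits(p, "pinch_pulse"))
  cos(pi * p$W) * p$V0 * sech(p$a * z - p$b * t + p$c)
}

#' Speed of a travelling pulse
#'
#' The argument \eqn{a z - b t + c} is constant along \eqn{z = (b/a) t},
#' so the pulse travels at \eqn{v = b/a} (units of z0/t0). Invariant under
#' joint rescaling of a and b.
#'
#' @param p a [pinch_pulse()].
#' @return The dimensionless speed b/a.
#' @export
pulse_speed <- function(p) {
  stopifnot(inherits(p, "pinch_pulse"))
  if (p$a == 0) stop("degenerate pulse: a = 0")
  p$b / p$a
}

#' Equivalent charge density of a pulse
#'
#' Two bookkeeping conventions for replacing the voltage profile by a
#' charge density. `"poisson"` applies the one-dimensional Poisson
#' relation \eqn{\rho = V''/(4\pi)} (second z-derivative, computed
#' analytically from the sech profile; integrates to zero over the line).
#' `"effective"` uses the width-scaled profile \eqn{\rho = a^2 V}, whose
#' total charge \eqn{\int \rho\, dz = \pi a V_0} defines the pulse charge
#' Q used by the memory ledger.
#'
#' @param p a [pinch_pulse()].
#' @param z,t position and time, dimensionless.
#' @param mode `"poisson"` or `"effective"`.
#' @return Charge density value(s).
#' @export
charge_density <- function(p, z, t, mode = c("effective", "poisson")) {
  stopifnot(inherits(p, "pinch_pulse"))
  mode <- match.arg(mode)
  u <- p$a * z - p$b * t + p$c
  s <- sech(u)
  v <- cos(pi * p$W) * p$V0 * s
  if (mode == "effective") return(p$a^2 * v)
  # d2/dz2 sech(u) = a^2 sech(u) (1 - 2 sech(u)^2)
  p$a^2 * v * (1 - 2 * s^2) / (4 * pi)
}

#' Voltage of a soliton train
#'
#' Linear superposition \eqn{\sum_j V_j(z, t)} of the member pulses.
#'
#' @param train a [soliton_train()].
#' @param z,t position and time, dimensionless (vectorised).
#' @return Voltage value(s).
#' @export
train_voltage <- function(train, z, t) {
  stopifnot(inherits(train, "soliton_train"))
  Reduce(`+`, lapply(train$pulses, pulse_voltage, z = z, t = t))
}

#' Sample a noisy spike train
#'
#' Samples the train voltage at a fixed recording site z = 0 on a uniform
#' time grid and adds i.i.d. Gaussian noise, emulating a single-electrode
#' record of a multi-pulse action-potential burst. Reproducible under
#' `seed`.
#'
#' @param train a [soliton_train()].
#' @param fs sampling rate (samples per unit time, > 0).
#' @param duration record length (time units, > 0).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer RNG seed.
#' @param z recording position (default 0).
#' @return A `"time_series"` data frame with columns `t`, `v` and a `meta`
#'   attribute (fs, seed, noise_sd, z, provenance).
#' @export
synth_spike_train <- function(train, fs, duration, noise_sd = 0,
                              seed = 1L, z = 0) {
  stopifnot(inherits(train, "soliton_train"))
  if (fs <= 0 || duration <= 0) stop("'fs' and 'duration' must be positive")
  t <- seq(0, duration, by = 1 / fs)
  v <- train_voltage(train, z = z, t = t)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
      globalenv()) else NULL
    set.seed(as.integer(seed))
    v <- v + stats::rnorm(length(t), sd = noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  time_series(t, v, meta = list(fs = fs, seed = as.integer(seed),
                                noise_sd = noise_sd, z = z,
                                provenance = "synth_spike_train"))
}

#' Construct a sampled time series
#'
#' @param t strictly increasing sample times.
#' @param v voltages, same length as `t`.
#' @param meta optional list of metadata (sampling rate, seed, provenance).
#' @return A data frame of class `"time_series"`.
#' @export
time_series <- function(t, v, meta = list()) {
  if (length(t) != length(v)) stop("'t' and 'v' must have equal length")
  if (length(t) < 2L || any(diff(t) <= 0))
    stop("'t' must be strictly increasing with at least 2 samples")
  structure(data.frame(t = t, v = v), meta = meta,
            class = c("time_series", "data.frame"))
}

# local maxima of a lightly smoothed copy, above 3 * MAD, with greedy
# non-maximum suppression so each pulse contributes one candidate;
# ties broken leftmost first
detect_peaks <- function(v, mad_mult = 3, min_sep = NULL) {
  n <- length(v)
  k <- min(9L, max(3L, n %/% 100L))
  if (k %% 2L == 0L) k <- k + 1L
  vs <- stats::filter(v, rep(1 / k, k), sides = 2)
  vs[is.na(vs)] <- v[is.na(vs)]
  vs <- as.numeric(vs)
  # noise scale from first differences: robust when wide pulses occupy
  # much of the record and would inflate the plain MAD of v
  noise <- stats::mad(diff(v)) / sqrt(2)
  thr <- mad_mult * noise
  idx <- which(vs > thr)
  idx <- idx[idx > 1L & idx < n]
  idx <- idx[vs[idx] >= vs[idx - 1L] & vs[idx] >= vs[idx + 1L]]
  if (!length(idx)) return(which.max(vs))
  if (is.null(min_sep)) min_sep <- max(3L, n %/% 20L)
  ord <- idx[order(vs[idx], -idx, decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) || min(abs(keep - i)) >= min_sep)
      keep <- c(keep, i)
  }
  sort(keep)
}

#' Fit a multi-pulse soliton train to a recorded series
#'
#' Damped (Levenberg-Marquardt) nonlinear least squares of the model
#' \eqn{v(t) = \sum_{j=1}^{N} V_{0j}\, \mathrm{sech}(b_j t - c_j)} to a
#' single-site recording. Each pulse carries its own parameters: no shared
#' shape is imposed, so distinct true pulses are recovered distinct.
#' Initialisation detects smoothed local maxima above 3 times the robust
#' noise scale (MAD of first differences; ties broken leftmost first) and
#' seeds `b` from the half-maximum width.
#'
#' A single-site record determines the temporal scale `b`, phase `c` and
#' amplitude `V0` of each pulse; the spatial pinch scale `a` enters the
#' record only through the propagation speed v = b/a, so the fitted
#' `a = b / speed` is reported under the supplied propagation speed
#' (default 1, the dimensionless unit-speed convention).
#'
#' @param series a `time_series` (from [synth_spike_train()] or
#'   [read_timeseries()]).
#' @param n_pulses number of pulses N to fit (>= 1).
#' @param speed assumed propagation speed used to convert the fitted time
#'   scale b into the spatial scale a (default 1).
#' @param maxit maximum Levenberg-Marquardt iterations.
#' @return List with `train` (the fitted [soliton_train()]),
#'   `parameters` (data frame with one row per pulse: a, b, c, V0),
#'   `rms` residual root-mean-square, `converged` flag and `n_iter`.
#'   Non-convergence is flagged, the best iterate is returned.
#' @export
fit_spike_train <- function(series, n_pulses, speed = 1, maxit = 200L) {
  stopifnot(inherits(series, "time_series"))
  n_pulses <- as.integer(n_pulses)
  if (n_pulses < 1L) stop("'n_pulses' must be >= 1")
  t <- series$t; v <- series$v
  if (length(t) < 10L * n_pulses)
    stop("series too short: need at least 10 samples per pulse")

  pk <- detect_peaks(v)
  pk <- pk[order(v[pk], decreasing = TRUE)]
  if (length(pk) >= n_pulses) pk <- sort(pk[seq_len(n_pulses)])
  # pad missing peaks on an even grid
  while (length(pk) < n_pulses)
    pk <- sort(c(pk, round(stats::quantile(seq_along(t),
      (length(pk) + 0.5) / n_pulses))))

  init_b <- vapply(pk, function(i) {
    half <- v[i] / 2
    l <- i; while (l > 1L && v[l] > half) l <- l - 1L
    r <- i; while (r < length(t) && v[r] > half) r <- r + 1L
    w <- max(t[r] - t[l], 2 * (t[2L] - t[1L]))
    2 * acosh(2) / w     # sech(x) = 1/2 at x = acosh(2)
  }, numeric(1))
  start <- c(rbind(init_b, init_b * t[pk], pmax(v[pk], 1e-3)))
  names(start) <- paste0(rep(c("b", "c", "V0"), n_pulses),
                         rep(seq_len(n_pulses), each = 3L))

  model <- function(par, t) {
    out <- 0
    for (j in seq_len(n_pulses)) {
      b <- par[3L * j - 2L]; cc <- par[3L * j - 1L]; V0 <- par[3L * j]
      out <- out + V0 * sech(b * t - cc)
    }
    out
  }
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(par) v - model(par, t),
    control = minpack.lm::nls.lm.control(maxiter = maxit, ftol = 1e-12,
                                         ptol = 1e-12))
  par <- fit$par
  converged <- fit$info %in% 1:4
  ord <- order(vapply(seq_len(n_pulses),
                      function(j) par[3L * j - 1L] / par[3L * j - 2L],
                      numeric(1)))       # sort by peak time c/b
  rows <- lapply(ord, function(j) {
    b <- abs(par[3L * j - 2L]); cc <- par[3L * j - 1L]; V0 <- par[3L * j]
    if (par[3L * j - 2L] < 0) cc <- -cc  # sech is even in its argument
    data.frame(a = b / speed, b = b, c = cc, V0 = V0)
  })
  pars <- do.call(rbind, rows)
  train <- soliton_train(lapply(seq_len(nrow(pars)), function(i)
    pinch_pulse(a = pars$a[i], b = pars$b[i], c = pars$c[i],
                V0 = pars$V0[i])))
  list(train = train, parameters = pars,
       rms = sqrt(mean(fit$fvec^2)), converged = converged,
       n_iter = fit$niter)
}
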