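#' Theta-function characteristics
#'
#' A set of half-integer characteristics \eqn{(\alpha_i, \beta_i)},
#' \eqn{i = 1, \dots, g}, attached to the \eqn{2g} homology loops of a genus-g
#' surface. Each entry is 0 or 1/2; together they encode the spin structure of
#' the surface and determine the spin topology number
#' \eqn{W = 4\sum_i \alpha_i \beta_i}.
#'
#' Arithmetic on characteristics is reduction mod 1 of the half-integer
#' labels: traversing a loop an even number of times contributes 0, an odd
#' number of times contributes the label itself.
#'
#' @param alpha,beta numeric vectors of equal length with entries in
#'   \{0, 1/2\}.
#' @return An object of class `"characteristics"` with fields `alpha`,
#'   `beta` and the genus `g`.
#' @examples
#' ch <- characteristics(c(1/2, 0), c(1/2, 1/2))
#' spin_topology_number(ch)
#' @export
characteristics <- function(alpha, beta) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  if (length(alpha) != length(beta) || length(alpha) < 1L)
    stop("'alpha' and 'beta' must be non-empty vectors of equal length")
  ok <- function(x) all(x %in% c(0, 0.5))
  if (!ok(alpha) || !ok(beta))
    stop("characteristic entries must be 0 or 1/2")
  structure(list(alpha = alpha, beta = beta, g = length(alpha)),
            class = "characteristics")
}

#' @export
print.characteristics <- function(x, ...) {
  cat("Theta characteristics, genus g =", x$g, "\n")
  cat("  alpha:", paste(format(x$alpha), collapse = " "), "\n")
  cat("  beta: ", paste(format(x$beta), collapse = " "), "\n")
  cat("  W =", spin_topology_number(x), "(", characteristic_parity(x), ")\n")
  invisible(x)
}

#' Reduce integer multiples of characteristics mod 1
#'
#' Multiplying a half-integer characteristic by an integer `n` corresponds to
#' traversing its loop `n` times: the result is 0 for even `n` and the label
#' itself for odd `n`, i.e. reduction mod 1.
#'
#' @param chars a [characteristics()] object.
#' @param n integer multiplier.
#' @return A new `characteristics` object.
#' @export
characteristic_multiple <- function(chars, n) {
  stopifnot(inherits(chars, "characteristics"))
  n <- as.integer(n)
  characteristics((n * chars$alpha) %% 1, (n * chars$beta) %% 1)
}

#' Spin topology number
#'
#' Computes \eqn{W = 4 \sum_{i=1}^g \alpha_i \beta_i}, the integer that
#' classifies the spin structure carried by the characteristics. `W` is
#' additive over concatenation of characteristic blocks; its parity decides
#' whether the associated theta function is even or odd. In the memory model
#' `W` is the effective genus of an engram, whose neuron count is `W - 1`.
#'
#' @param chars a [characteristics()] object.
#' @return A non-negative integer.
#' @export
spin_topology_number <- function(chars) {
  stopifnot(inherits(chars, "characteristics"))
  w <- 4 * sum(chars$alpha * chars$beta)
  as.integer(round(w))
}

#' Parity of a set of characteristics
#'
#' A set of characteristics is even or odd according to the sign of
#' \eqn{e^{i\pi W}}: `"even"` when `W` is even, `"odd"` when `W` is odd. Odd
#' characteristics force the theta function to vanish at the origin.
#'
#' @param chars a [characteristics()] object.
#' @return `"even"` or `"odd"`.
#' @export
characteristic_parity <- function(chars) {
  if (spin_topology_number(chars) %% 2L == 0L) "even" else "odd"
}

#' Validate a period matrix
#'
#' A period matrix \eqn{\Omega} must be complex symmetric with
#' positive-definite imaginary part; positive definiteness (rather than
#' entrywise positivity) is the condition that makes the theta lattice sum
#' converge.
#'
#' @param omega a square complex (or numeric) matrix.
#' @param tol tolerance for the symmetry check (max-norm of
#'   \eqn{\Omega - \Omega^T}).
#' @return `TRUE` if symmetric to `tol` with positive-definite imaginary
#'   part, else `FALSE`.
#' @examples
#' validate_period_matrix(diag(2) * 1i)
#' @export
validate_period_matrix <- function(omega, tol = 1e-10) {
  if (!is.matrix(omega) || nrow(omega) != ncol(omega))
    stop("'omega' must be a square matrix")
  omega <- matrix(as.complex(omega), nrow(omega))
  if (max(Mod(omega - t(omega))) > tol) return(FALSE)
  im <- Im(omega)
  im <- (im + t(im)) / 2
  ev <- eigen(im, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > 0
}

#' Riemann theta function with characteristics
#'
#' Evaluates the truncated lattice sum
#' \deqn{\Theta_{\alpha,\beta}(\Omega, z) = \sum_{n} \exp\left[i\pi
#'   (n+\alpha)^T \Omega (n+\alpha) + 2\pi i (z+\beta)^T (n+\alpha)\right]}
#' over all integer vectors with \eqn{|n_i| \le R}. The tail of the full sum
#' is bounded geometrically by the smallest eigenvalue of
#' \eqn{\mathrm{Im}\,\Omega}; the returned value carries the bound as the
#' attribute `"tail_bound"`.
#'
#' @param z complex vector of length g.
#' @param omega g-by-g period matrix (validated).
#' @param chars a [characteristics()] object with matching genus.
#' @param radius truncation radius R (each lattice index runs over
#'   \eqn{-R, \dots, R}); default 10, adequate for \eqn{g \le 3} at the
#'   identity-scale period matrices used here.
#' @return A complex scalar with attribute `tail_bound`.
#' @examples
#' ch <- characteristics(0, 0)
#' riemann_theta(0, matrix(1i), ch)  # sum of exp(-pi n^2)
#' @export
riemann_theta <- function(z, omega, chars, radius = 10L) {
  stopifnot(inherits(chars, "characteristics"))
  radius <- as.integer(radius)
  if (radius < 1L) stop("'radius' must be >= 1")
  g <- chars$g
  if (length(z) != g) stop("length(z) must equal the genus g")
  if (!is.matrix(omega)) omega <- matrix(omega, g, g)
  if (nrow(omega) != g) stop("period matrix dimension does not match genus")
  if (!validate_period_matrix(omega)) stop("invalid period matrix")
  omega <- matrix(as.complex(omega), g, g)
  z <- as.complex(z)

  idx <- do.call(expand.grid, rep(list(seq(-radius, radius)), g))
  n <- as.matrix(idx)                     # (2R+1)^g x g
  na <- sweep(n, 2L, chars$alpha, "+")    # n + alpha
  quad <- rowSums((na %*% omega) * na)    # (n+a)' Omega (n+a)
  lin <- as.vector(na %*% (z + chars$beta))
  val <- sum(exp(1i * pi * quad + 2i * pi * lin))

  # geometric tail bound: terms decay like exp(-pi * lam_min * |n|^2)
  lam <- min(eigen((Im(omega) + t(Im(omega))) / 2,
                   symmetric = TRUE, only.values = TRUE)$values)
  m <- radius + 1 - max(abs(chars$alpha))
  r1 <- exp(-pi * lam * (2 * m - 1))
  tail <- if (r1 < 1) {
    2 * g * (2 * radius + 3)^(g - 1) * exp(-pi * lam * m^2) / (1 - r1)
  } else Inf
  attr(val, "tail_bound") <- tail
  val
}

#' Hyperelliptic curve from its branch points
#'
#' Represents the curve \eqn{w^2 = P(z) = \prod_{i=1}^{2g+2} (z - x_i)}. The
#' roots must be real or occur in complex-conjugate pairs (checked to
#' tolerance), so that P has real coefficients.
#'
#' @param roots complex vector of length 2g+2.
#' @param tol tolerance for the conjugate-pair check.
#' @return An object of class `"hyperelliptic_curve"` with fields `roots`,
#'   `g` (genus) and `coef` (polynomial coefficients of P, ascending).
#' @examples
#' hyperelliptic_curve(c(-1, 1, -2, 2))
#' @export
hyperelliptic_curve <- function(roots, tol = 1e-8) {
  roots <- as.complex(roots)
  m <- length(roots)
  if (m < 4L || m %% 2L != 0L)
    stop("'roots' must have even length 2g+2 >= 4")
  cx <- roots[abs(Im(roots)) > tol]
  if (length(cx)) {
    pool <- Conj(cx)
    for (r in cx) {
      hit <- which(abs(pool - r) < tol)
      if (!length(hit)) stop("complex roots must occur in conjugate pairs")
      pool <- pool[-hit[1L]]
    }
  }
  coef <- c(1 + 0i)
  for (r in roots) coef <- c(0i, coef) - c(r * coef, 0i)  # multiply by (z - r)
  structure(list(roots = roots, g = m / 2L - 1L, coef = coef),
            class = "hyperelliptic_curve")
}

#' @export
print.hyperelliptic_curve <- function(x, ...) {
  cat("Hyperelliptic curve w^2 = P(z), genus g =", x$g, "\n")
  cat("  roots:", paste(format(x$roots, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# evaluate P(z) for a hyperelliptic curve (ascending coefficients)
curve_poly <- function(curve, z) {
  z <- as.complex(z)
  out <- rep(0i, length(z))
  for (k in rev(seq_along(curve$coef))) out <- out * z + curve$coef[k]
  out
}

#' Holomorphic one-form of a hyperelliptic curve
#'
#' Evaluates \eqn{\omega_j(z) = z^{j-1} / \sqrt{P(z)}}, the j-th of the g
#' holomorphic one-forms of the curve. The square root uses the principal
#' branch (`sqrt` of a complex number with argument in \eqn{(-\pi, \pi]});
#' for real z with P(z) > 0 the result is real, for P(z) < 0 it is pure
#' imaginary. Continuity along a path can be enforced by the caller by
#' tracking sign flips across branch cuts; the principal branch is the
#' documented default convention.
#'
#' @param curve a [hyperelliptic_curve()].
#' @param j one-form index, \eqn{1 \le j \le g}.
#' @param z evaluation point(s); must not be a root of P.
#' @return Complex value(s) \eqn{z^{j-1}/\sqrt{P(z)}}.
#' @examples
#' cv <- hyperelliptic_curve(c(-1, 1, -2, 2))
#' one_form(cv, 1, 0)  # 1/sqrt(4) = 0.5
#' @export
one_form <- function(curve, j, z) {
  stopifnot(inherits(curve, "hyperelliptic_curve"))
  j <- as.integer(j)
  if (j < 1L || j > curve$g) stop("'j' must be between 1 and the genus g")
  z <- as.complex(z)
  p <- curve_poly(curve, z)
  if (any(abs(p) == 0)) stop("z coincides with a branch point of the curve")
  z^(j - 1) / sqrt(p)
}

#' Pinch-expansion coefficients of a one-form
#'
#' Taylor coefficients of \eqn{\omega_j(z) = z^{j-1}/\sqrt{P(z)}} about
#' z = 0, the algebraic face of a pinch deformation: shrinking a handle loop
#' to a point is encoded by these distortion parameters. Computed exactly by
#' the power-series recurrence for \eqn{P^{-1/2}} (from
#' \eqn{P f' = -\tfrac12 P' f}), then shifted by \eqn{z^{j-1}}.
#'
#' @param curve a [hyperelliptic_curve()] with \eqn{P(0) \neq 0}.
#' @param j one-form index.
#' @param order highest power of z retained.
#' @return Complex vector of length `order + 1`: coefficients of
#'   \eqn{z^0, \dots, z^{order}}.
#' @export
pinch_expansion <- function(curve, j, order) {
  stopifnot(inherits(curve, "hyperelliptic_curve"))
  j <- as.integer(j); order <- as.integer(order)
  if (j < 1L || j > curve$g) stop("'j' must be between 1 and the genus g")
  if (order < 0L) stop("'order' must be non-negative")
  p <- curve$coef
  if (abs(p[1L]) == 0)
    stop("P(0) = 0: the pinch point sits on a branch point (pole at pinch)")
  deg <- length(p) - 1L
  pad <- function(k) if (k <= deg) p[k + 1L] else 0i
  f <- rep(0i, order + 2L)
  f[1L] <- 1 / sqrt(p[1L])               # principal branch at z = 0
  for (s in 0:order) {
    # p0 (s+1) f_{s+1} = -1/2 sum_{k>=1} k p_k f_{s+1-k}
    #                    - sum_{k>=1} p_k (s-k+1) f_{s-k+1}
    rhs <- 0i
    for (k in 1:(s + 1L)) rhs <- rhs - 0.5 * k * pad(k) * f[s + 2L - k]
    if (s >= 1L)
      for (k in 1:s) rhs <- rhs - pad(k) * (s - k + 1L) * f[s - k + 2L]
    f[s + 2L] <- rhs / (pad(0L) * (s + 1L))
  }
  f <- f[seq_len(order + 1L)]            # series of P^{-1/2}
  if (j > 1L) f <- c(rep(0i, j - 1L), f)[seq_len(order + 1L)]
  f
}
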