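#' Kimura drift-distribution parameters
#'
#' Bundles the two parameters of the Kimura distribution of allele frequency
#' under pure random genetic drift: the initial heteroplasmy fraction `p` and
#' the bottleneck parameter `b`. The distribution consists of point masses at
#' 0 (loss of the mutant) and 1 (fixation of the mutant) plus a continuous
#' density on (0, 1). `b` compounds all drift accumulated through the
#' germline bottleneck: `b` near 1 means essentially no drift, `b` near 0
#' complete fixation; under a Wright-Fisher bottleneck of `N` segregating
#' units for `g` generations, `b = (1 - 1/N)^g`. The variance of the
#' distribution is `p(1-p)(1-b)`.
#'
#' @param p Initial (founder) heteroplasmy fraction, strictly in (0, 1).
#' @param b Bottleneck/drift parameter, strictly in (0, 1).
#' @return An object of class `kimura_params`.
#' @examples
#' kimura_params(0.337, 0.72)
#' @export
kimura_params <- function(p, b) {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (p <= 0 || p >= 1)
    stop("`p` must lie strictly in (0, 1); got ", p, call. = FALSE)
  if (b <= 0 || b >= 1)
    stop("`b` must lie strictly in (0, 1); got ", b, call. = FALSE)
  structure(list(p = p, b = b), class = "kimura_params")
}

#' @export
print.kimura_params <- function(x, ...) {
  cat(sprintf("Kimura drift distribution: p = %g, b = %g\n", x$p, x$b))
  invisible(x)
}

as_kimura_params <- function(params) {
  if (inherits(params, "kimura_params")) return(params)
  if (is.numeric(params) && length(params) == 2L)
    return(kimura_params(params[[1L]], params[[2L]]))
  stop("`params` must be a kimura_params object or a numeric (p, b) pair",
       call. = FALSE)
}

# Series engine for the Kimura distribution.
#
# The continuous density is
#   phi(x) = sum_{i>=1} i(i+1)(2i+1) p q F_i(p) F_i(x) b^{i(i+1)/2},
# with q = 1-p and F_i(x) = 2F1(1-i, i+2; 2; x), a degree-(i-1) polynomial.
# The point masses are
#   f0 = q - sum_{i>=1} (2i+1) p q F_i(p) b^{i(i+1)/2}
#   f1 = p + sum_{i>=1} (-1)^i (2i+1) p q F_i(p) b^{i(i+1)/2}.
# F_i is evaluated through the Jacobi polynomial identity
#   F_i(x) = P_{i-1}^{(1,1)}(1 - 2x) / i,
# whose three-term recurrence is stable on [-1, 1]; generic hypergeometric
# evaluation of the alternating polynomial would cancel catastrophically for
# large i. The antiderivative of the density term reduces to Legendre
# polynomials via d/dz P_i(z) = ((i+1)/2) P_{i-1}^{(1,1)}(z):
#   int_0^x F_i(t) dt = (1 - P_i(1 - 2x)) / (i (i + 1)),
# so the continuous part of the CDF is
#   sum_i (2i+1) p q F_i(p) b^{i(i+1)/2} (1 - P_i(1 - 2x)).
#
# Vectorised over parameter vectors (p, b) of common length R, with an
# optional n x R matrix X of evaluation points (column r evaluated under
# (p[r], b[r])). Terms are summed until every running series has seen `run`
# consecutive increments below `tol` (hard cap `imax`); b^{i(i+1)/2}
# guarantees rapid decay for b away from 1.
kimura_series <- function(p, b, X = NULL, what = c("cdf", "pdf"),
                          tol = 1e-12, run = 50L, imax = 500L) {
  what <- match.arg(what)
  R <- max(length(p), length(b))
  p <- rep_len(p, R); b <- rep_len(b, R)
  q <- 1 - p
  zp <- 1 - 2 * p
  f0 <- q
  f1 <- p
  have_x <- !is.null(X)
  if (have_x) {
    X <- as.matrix(X)
    if (ncol(X) != R) {
      if (ncol(X) == 1L) X <- X[, rep(1L, R), drop = FALSE]
      else stop("X must have one column per (p, b) pair", call. = FALSE)
    }
    ZX <- 1 - 2 * X
    vals <- array(0, dim(X))
    if (what == "cdf") { Lm2 <- array(1, dim(X)); Lm1 <- ZX }  # Legendre P0, P1
    else { Km2 <- NULL; Km1 <- NULL }                          # Jacobi(1,1) rows at ZX
  }
  Jm2 <- NULL; Jm1 <- NULL
  logb <- log(b)
  small <- 0L
  for (i in seq_len(imax)) {
    n <- i - 1L  # Jacobi degree at the founder frequency
    J <- if (n == 0L) rep(1, R)
    else if (n == 1L) 2 * zp
    else ((2 * n + 1) * (n + 1) * zp * Jm1 - n * (n + 1) * Jm2) / (n * (n + 2))
    Jm2 <- Jm1; Jm1 <- J
    w <- (2 * i + 1) * p * q * (J / i) * exp((i * (i + 1) / 2) * logb)
    f0 <- f0 - w
    f1 <- f1 + (if (i %% 2L == 0L) w else -w)
    inc <- max(abs(w))
    if (have_x) {
      if (what == "cdf") {
        L <- if (i == 1L) ZX
        else ((2 * i - 1) * ZX * Lm1 - (i - 1) * Lm2) / i
        if (i > 1L) { Lm2 <- Lm1; Lm1 <- L }
        term <- (1 - L) * rep(w, each = nrow(X))
      } else {
        K <- if (n == 0L) array(1, dim(X))
        else if (n == 1L) 2 * ZX
        else ((2 * n + 1) * (n + 1) * ZX * Km1 - n * (n + 1) * Km2) /
          (n * (n + 2))
        Km2 <- Km1; Km1 <- K
        term <- (i + 1) * K * rep(w, each = nrow(X))
      }
      vals <- vals + term
      inc <- max(inc, max(abs(term)))
    }
    if (inc < tol) {
      small <- small + 1L
      if (small >= run) break
    } else small <- 0L
    if (i == imax)
      stop(sprintf(paste0("Kimura series did not converge within %d terms ",
                          "(tol = %g) for p in [%g, %g], b in [%g, %g]; ",
                          "b this close to 1 is outside the series' reach"),
                   imax, tol, min(p), max(p), min(b), max(b)), call. = FALSE)
  }
  # round-off can push the masses a hair outside [0, 1]
  f0 <- pmin(pmax(f0, 0), 1)
  f1 <- pmin(pmax(f1, 0), 1)
  list(f0 = f0, f1 = f1, vals = if (have_x) vals else NULL)
}

#' Fixation masses of the Kimura distribution
#'
#' Probability that drift has driven heteroplasmy all the way to 0 (loss of
#' the mutant, fixation on wild-type) or to 1 (fixation on the mutant),
#' together with the probability mass left on the continuous interior.
#'
#' @param params A [kimura_params()] object (or numeric `c(p, b)`).
#' @param tol Series truncation tolerance.
#' @return A list of class `kimura_masses` with elements `f0`, `f1` and
#'   `continuous_mass` (`= 1 - f0 - f1`).
#' @examples
#' kimura_masses(kimura_params(0.337, 0.72))
#' @export
kimura_masses <- function(params, tol = 1e-12) {
  params <- as_kimura_params(params)
  s <- kimura_series(params$p, params$b, tol = tol)
  structure(list(f0 = s$f0, f1 = s$f1,
                 continuous_mass = max(0, 1 - s$f0 - s$f1)),
            class = "kimura_masses")
}

#' @export
print.kimura_masses <- function(x, ...) {
  cat(sprintf("P(loss) f0 = %.6g   P(fixation) f1 = %.6g   continuous = %.6g\n",
              x$f0, x$f1, x$continuous_mass))
  invisible(x)
}

#' Continuous density of the Kimura distribution
#'
#' Density of the continuous part on the open interval (0, 1). The point
#' masses at 0 and 1 are not part of the density; query them with
#' [kimura_masses()].
#'
#' @param x Vector of heteroplasmy fractions, each strictly in (0, 1).
#' @inheritParams kimura_masses
#' @return Density values (unitless), same length as `x`.
#' @details Truncation of the alternating series can leave values a tiny
#'   distance below zero; magnitudes under `1e-10` are clipped to 0, anything
#'   more negative raises an error (it would indicate a genuine evaluation
#'   problem rather than round-off).
#' @export
kimura_pdf <- function(x, params, tol = 1e-12) {
  params <- as_kimura_params(params)
  if (length(x) == 0L) return(numeric(0))
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop("`x` must lie strictly in (0, 1); point masses at 0 and 1 are ",
         "queried via kimura_masses()", call. = FALSE)
  s <- kimura_series(params$p, params$b, X = matrix(x, ncol = 1L),
                     what = "pdf", tol = tol)
  d <- drop(s$vals)
  neg <- d < 0
  if (any(d[neg] < -1e-10))
    stop("Kimura density evaluated substantially negative (min ",
         min(d), "); evaluation failed", call. = FALSE)
  d[neg] <- 0
  d
}

#' Cumulative distribution function of the Kimura distribution
#'
#' Right-continuous CDF on `[0, 1]`, honouring the point masses:
#' `kimura_cdf(0, params)` equals the loss probability `f0` and
#' `kimura_cdf(1, params)` equals 1.
#'
#' @param x Vector of heteroplasmy fractions in `[0, 1]`.
#' @inheritParams kimura_masses
#' @return Probabilities `P(X <= x)`, same length as `x`.
#' @export
kimura_cdf <- function(x, params, tol = 1e-12) {
  params <- as_kimura_params(params)
  if (length(x) == 0L) return(numeric(0))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("`x` must lie in [0, 1]", call. = FALSE)
  s <- kimura_series(params$p, params$b, X = matrix(x, ncol = 1L),
                     what = "cdf", tol = tol)
  out <- s$f0 + drop(s$vals) + s$f1 * (x >= 1)
  pmin(pmax(out, 0), 1)
}

#' Upper-tail probability of the Kimura distribution
#'
#' `P(X > threshold)`, the probability that an offspring's mutant load
#' exceeds a clinical threshold (by default the 60% load customarily
#' associated with disease expression for m.3243A>G).
#'
#' @param threshold Fraction in `[0, 1]`.
#' @inheritParams kimura_masses
#' @return `1 - kimura_cdf(threshold, params)`; in particular the value at
#'   `threshold = 1` is 0 (the upper tail beyond 1 is empty).
#' @export
kimura_tail <- function(threshold, params, tol = 1e-12) {
  1 - kimura_cdf(threshold, params, tol = tol)
}

#' Mean and variance of the Kimura distribution
#'
#' Closed forms under pure drift: the mean stays at the founder fraction
#' `p` and the variance is `p(1-p)(1-b)` (hence the normalized variance
#' `V / (p(1-p))` equals `1 - b`).
#'
#' @inheritParams kimura_masses
#' @return List with `mean` and `variance`.
#' @export
kimura_moments <- function(params) {
  params <- as_kimura_params(params)
  list(mean = params$p,
       variance = params$p * (1 - params$p) * (1 - params$b))
}

# Inverse-CDF sampler state: grid of the continuous part, built once and
# reused for repeated draws from the same parameters.
kimura_sampler <- function(params, grid_size = 4097L, tol = 1e-12) {
  params <- as_kimura_params(params)
  m <- kimura_masses(params, tol = tol)
  if (m$continuous_mass < 1e-12) {
    return(list(params = params, masses = m, xg = NULL, Fg = NULL))
  }
  xg <- seq_len(grid_size) / (grid_size + 1)
  Fc <- (kimura_cdf(xg, params, tol = tol) - m$f0) / m$continuous_mass
  xg <- c(0, xg, 1)
  Fc <- cummax(pmin(pmax(c(0, Fc, 1), 0), 1))
  keep <- !duplicated(Fc)
  list(params = params, masses = m, xg = xg[keep], Fg = Fc[keep])
}

kimura_sampler_draw <- function(sampler, n) {
  u <- stats::runif(n)
  m <- sampler$masses
  out <- numeric(n)
  lo <- u < m$f0
  hi <- u > 1 - m$f1
  mid <- !(lo | hi)
  out[hi] <- 1
  if (any(mid)) {
    if (is.null(sampler$xg)) {
      # essentially no continuous mass: nearest atom
      out[mid] <- as.numeric(u[mid] > m$f0 + m$continuous_mass / 2)
    } else {
      v <- (u[mid] - m$f0) / m$continuous_mass
      out[mid] <- stats::approx(sampler$Fg, sampler$xg, xout = v,
                                ties = "ordered", rule = 2)$y
    }
  }
  out
}

#' Draw random heteroplasmy values from the Kimura distribution
#'
#' I.i.d. sampling honouring the fixation masses: a draw is exactly 0 with
#' probability `f0`, exactly 1 with probability `f1`, and otherwise comes
#' from the continuous part by inverse-CDF interpolation on a fine grid.
#'
#' @inheritParams kimura_masses
#' @param n Number of draws.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @param grid_size Number of interior grid points for the inverse-CDF table
#'   (default 4097; interpolation error is far below Monte-Carlo error at
#'   any realistic replicate count).
#' @return Numeric vector of `n` heteroplasmy fractions in `[0, 1]`.
#' @examples
#' x <- kimura_sample(kimura_params(0.337, 0.72), 1000, seed = 3243)
#' mean(x)
#' @export
kimura_sample <- function(params, n, seed = NULL, grid_size = 4097L,
                          tol = 1e-12) {
  stopifnot(n >= 1)
  sampler <- kimura_sampler(params, grid_size = grid_size, tol = tol)
  with_preserved_seed(seed, kimura_sampler_draw(sampler, n))
}
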