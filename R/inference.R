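#' Fit the Kimura drift distribution to offspring mutant loads
#'
#' Moment-based fit: the mean mutation level `p0` is the sample mean, the
#' variance `V` the sample variance (n-1 denominator), the normalized
#' variance is `V / (p0 (1 - p0))` and the bottleneck parameter is
#' `b = 1 - normalized_variance` (the drift relationship
#' `V = p(1-p)(1-b)` inverted). Fixation probabilities and the upper-tail
#' probability are then evaluated from the Kimura distribution at the point
#' estimates `(p0, b)`.
#'
#' Loads reported as exactly 0 (below the assay detection threshold) enter
#' the fit as 0 by default: under drift they are genuine candidate
#' fixations on wild-type, and excluding them would bias both `p0` and `V`.
#' Set `exclude_zeros = TRUE` as a sensitivity analysis.
#'
#' @param loads Numeric vector of mutant-load fractions in `[0, 1]`
#'   (convert percent at the boundary, e.g. via [read_measurements()]).
#' @param exceedance_threshold Threshold for the reported tail probability
#'   `P(X > threshold)`; default 0.6, the mutant load customarily linked to
#'   clinical expression of m.3243A>G.
#' @param exclude_zeros Drop exact-zero measurements before fitting.
#' @return An object of class `kimura_fit` with elements `n`, `p0`, `V`,
#'   `normalized_variance`, `b`, `f0`, `f1`, `tail_prob`,
#'   `exceedance_threshold`, `loads`, and (after
#'   [mc_confidence_intervals()]) `ci`, `ci_reps`, `seed`.
#' @examples
#' x <- kimura_sample(kimura_params(0.3, 0.8), 35, seed = 1)
#' fit_kimura(x)
#' @export
fit_kimura <- function(loads, exceedance_threshold = 0.6,
                       exclude_zeros = FALSE) {
  stopifnot(is.numeric(loads))
  if (any(!is.finite(loads)) || any(loads < 0) || any(loads > 1))
    stop("`loads` must be fractions in [0, 1]", call. = FALSE)
  if (exclude_zeros) loads <- loads[loads > 0]
  n <- length(loads)
  if (n < 3L)
    stop("need at least 3 measurements to fit (got ", n, ")", call. = FALSE)
  if (length(unique(loads)) < 2L)
    stop("all measurements identical: sample variance is 0, which puts the ",
         "fit on the no-drift boundary b = 1", call. = FALSE)
  p0 <- mean(loads)
  if (p0 <= 0 || p0 >= 1)
    stop("sample mean must lie strictly in (0, 1); got ", p0, call. = FALSE)
  V <- stats::var(loads)
  fit <- kimura_fit_from_moments(p0, V, n)
  fit$loads <- loads
  fit$exceedance_threshold <- exceedance_threshold
  fit <- kimura_fit_add_probs(fit)
  fit
}

#' Fit the Kimura distribution from printed summary statistics
#'
#' The same estimator as [fit_kimura()], applied to a published
#' `(p0, V, n)` summary when the raw measurements are not available (for
#' example a table reporting only the mean mutation level and its
#' variance). Confidence intervals are available through
#' [mc_confidence_intervals()]; the goodness-of-fit test requires raw data.
#'
#' @param p0 Mean mutation level (fraction, strictly in (0, 1)).
#' @param V Mutation-level variance (fraction squared, > 0).
#' @param n Sample size the summary was computed from.
#' @inheritParams fit_kimura
#' @return A `kimura_fit` object (with `loads = NULL`).
#' @examples
#' fit_kimura_summary(p0 = 0.337, V = 0.06, n = 35)
#' @export
fit_kimura_summary <- function(p0, V, n, exceedance_threshold = 0.6) {
  stopifnot(is.numeric(p0), length(p0) == 1L,
            is.numeric(V), length(V) == 1L, n >= 3)
  if (p0 <= 0 || p0 >= 1)
    stop("`p0` must lie strictly in (0, 1)", call. = FALSE)
  if (V <= 0)
    stop("`V` must be positive; V = 0 puts the fit on the no-drift ",
         "boundary b = 1", call. = FALSE)
  fit <- kimura_fit_from_moments(p0, V, as.integer(n))
  fit$exceedance_threshold <- exceedance_threshold
  kimura_fit_add_probs(fit)
}

kimura_fit_from_moments <- function(p0, V, n) {
  nv <- V / (p0 * (1 - p0))
  if (nv >= 1)
    stop(sprintf(paste0("normalized variance %.4g >= 1: the sample is more ",
                        "dispersed than complete fixation allows; no Kimura ",
                        "distribution fits"), nv), call. = FALSE)
  structure(list(n = n, p0 = p0, V = V, normalized_variance = nv,
                 b = 1 - nv, f0 = NA_real_, f1 = NA_real_,
                 tail_prob = NA_real_, exceedance_threshold = 0.6,
                 loads = NULL, ci = NULL, ci_reps = NULL, seed = NULL),
            class = "kimura_fit")
}

kimura_fit_add_probs <- function(fit) {
  s <- kimura_series(fit$p0, fit$b,
                     X = matrix(fit$exceedance_threshold, 1L, 1L),
                     what = "cdf")
  fit$f0 <- s$f0
  fit$f1 <- s$f1
  fit$tail_prob <- 1 - min(1, max(0, s$f0 + s$vals[1L] +
                                    s$f1 * (fit$exceedance_threshold >= 1)))
  fit
}

#' @export
print.kimura_fit <- function(x, digits = 4, ...) {
  ci_of <- function(stat) {
    if (is.null(x$ci)) return("")
    row <- x$ci[x$ci$statistic == stat, ]
    if (nrow(row) == 0L) return("")
    sprintf("  (%.4g-%.4g)", row$lower, row$upper)
  }
  cat("Kimura drift-distribution fit\n")
  cat(sprintf("  Sample size (n)                 %d\n", x$n))
  cat(sprintf("  Mean mutation level (p0)        %.4g%s\n", x$p0, ci_of("p0")))
  cat(sprintf("  Mutation level variance (V)     %.4g%s\n", x$V, ci_of("V")))
  cat(sprintf("  Normalized variance V/(p0(1-p0)) %.4g%s\n",
              x$normalized_variance, ci_of("normalized_variance")))
  cat(sprintf("  Bottleneck parameter (b)        %.4g%s\n", x$b, ci_of("b")))
  cat(sprintf("  P(fixing on wild-type) f0       %.4g%s\n", x$f0, ci_of("f0")))
  cat(sprintf("  P(fixing on the mutant) f1      %.4g%s\n", x$f1, ci_of("f1")))
  cat(sprintf("  P(load > %.0f%%)                  %.4g%s\n",
              100 * x$exceedance_threshold, x$tail_prob, ci_of("tail_prob")))
  if (!is.null(x$ci_reps))
    cat(sprintf("  95%% CIs from %d Monte-Carlo refits (seed %s)\n",
                x$ci_reps, format(x$seed)))
  invisible(x)
}

# Vectorised refit of Monte-Carlo replicate samples: columns of `draws` are
# replicate cohorts. Returns per-replicate statistics with NA where the
# refit fails (degenerate variance or dispersion beyond complete fixation).
refit_replicates <- function(draws, exceedance_threshold) {
  n <- nrow(draws)
  m <- colMeans(draws)
  V <- (colSums(draws^2) - n * m^2) / (n - 1)
  V <- pmax(V, 0)
  ok <- m > 0 & m < 1 & V > 0
  nv <- rep(NA_real_, ncol(draws))
  nv[ok] <- V[ok] / (m[ok] * (1 - m[ok]))
  ok <- ok & !is.na(nv) & nv < 1 & nv > 0
  out <- list(p0 = m, V = V, normalized_variance = ifelse(ok, nv, NA),
              b = ifelse(ok, 1 - nv, NA),
              f0 = rep(NA_real_, ncol(draws)), f1 = rep(NA_real_, ncol(draws)),
              tail_prob = rep(NA_real_, ncol(draws)), ok = ok)
  if (any(ok)) {
    s <- kimura_series(m[ok], 1 - nv[ok],
                       X = matrix(exceedance_threshold, 1L, sum(ok)),
                       what = "cdf")
    out$f0[ok] <- s$f0
    out$f1[ok] <- s$f1
    tail <- 1 - clamp01(s$f0 + drop(s$vals) +
                          s$f1 * (exceedance_threshold >= 1))
    out$tail_prob[ok] <- tail
  }
  out$p0[!ok] <- NA
  out$V[!ok] <- NA
  out
}

#' Monte-Carlo confidence intervals for a Kimura fit
#'
#' Sample-size uncertainty by parametric resampling: draw `reps` replicate
#' cohorts of the fitted sample size from the fitted Kimura distribution,
#' refit every statistic on each replicate, and take the 2.5th/97.5th
#' percentiles across replicates as the 95% interval. Replicates whose
#' refit fails (all values identical, or dispersion beyond the
#' complete-fixation bound) are counted and excluded; more than 50%
#' failures aborts.
#'
#' @param fit A `kimura_fit`.
#' @param reps Number of replicate cohorts (default 10000).
#' @param seed Optional integer seed (RNG state preserved).
#' @param level Interval level (default 0.95).
#' @param statistics `"full"` refits every Table-style statistic including
#'   the fixation and tail probabilities; `"moments"` restricts to
#'   `p0`, `V`, normalized variance and `b` (cheaper, e.g. for coverage
#'   experiments on the mean).
#' @return The fit with `ci` (a tibble of statistic/lower/upper), `ci_reps`,
#'   `ci_failed` and `seed` populated.
#' @examples
#' fit <- fit_kimura_summary(0.337, 0.06, 35)
#' mc_confidence_intervals(fit, reps = 500, seed = 1)
#' @export
mc_confidence_intervals <- function(fit, reps = 10000L, seed = NULL,
                                    level = 0.95,
                                    statistics = c("full", "moments")) {
  stopifnot(inherits(fit, "kimura_fit"), reps >= 2)
  statistics <- match.arg(statistics)
  sampler <- kimura_sampler(kimura_params(fit$p0, fit$b))
  draws <- with_preserved_seed(
    seed, matrix(kimura_sampler_draw(sampler, fit$n * reps), fit$n, reps))
  if (statistics == "full") {
    st <- refit_replicates(draws, fit$exceedance_threshold)
    stats_names <- c("p0", "V", "normalized_variance", "b",
                     "f0", "f1", "tail_prob")
  } else {
    n <- nrow(draws)
    m <- colMeans(draws)
    V <- pmax((colSums(draws^2) - n * m^2) / (n - 1), 0)
    ok <- m > 0 & m < 1 & V > 0
    nv <- ifelse(ok, V / (m * (1 - m)), NA)
    ok <- ok & !is.na(nv) & nv < 1
    st <- list(p0 = ifelse(m > 0 & m < 1, m, NA), V = ifelse(V > 0, V, NA),
               normalized_variance = ifelse(ok, nv, NA),
               b = ifelse(ok, 1 - nv, NA), ok = ok)
    stats_names <- c("p0", "V", "normalized_variance", "b")
  }
  failed <- sum(!st$ok)
  if (failed > reps / 2)
    stop(failed, " of ", reps, " replicate refits failed; the fitted ",
         "distribution is too close to a boundary for resampling",
         call. = FALSE)
  alpha <- (1 - level) / 2
  ci <- do.call(rbind, lapply(stats_names, function(nm) {
    qs <- stats::quantile(st[[nm]], c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
    tibble::tibble(statistic = nm, lower = qs[1L], upper = qs[2L])
  }))
  fit$ci <- ci
  fit$ci_reps <- as.integer(reps)
  fit$ci_failed <- as.integer(failed)
  fit$seed <- seed
  fit
}

# Kolmogorov-Smirnov statistic of `loads` against a fitted Kimura
# distribution with atoms at 0 and 1: the sup distance is attained either at
# a data point or just before one. Ties (the atoms produce exact repeats)
# require the SIGNED one-sided maxima - D+ is attained at the end of a tie
# block and D- (against the left limit, CDF minus the atom) at its start;
# taking absolute values at every sorted index would manufacture spurious
# distance inside tie blocks.
ks_statistic_kimura <- function(loads, p, b, f0 = NULL, f1 = NULL) {
  x <- sort(loads)
  n <- length(x)
  s <- kimura_series(p, b, X = matrix(x, ncol = 1L), what = "cdf")
  if (is.null(f0)) f0 <- s$f0
  if (is.null(f1)) f1 <- s$f1
  Fx <- clamp01(f0 + drop(s$vals) + f1 * (x >= 1))
  atom <- f0 * (x == 0) + f1 * (x == 1)
  Fleft <- Fx - atom
  i <- seq_len(n)
  max(i / n - Fx, Fleft - (i - 1) / n, 0)
}

#' Monte-Carlo Kolmogorov-Smirnov test of the drift hypothesis
#'
#' Tests whether a cohort of mutant loads is consistent with the Kimura
#' distribution fitted to it - the null hypothesis that heteroplasmy
#' segregated by pure random genetic drift. The KS statistic `D` is the sup
#' distance between the empirical CDF and the fitted CDF, honouring the
#' fixation atoms at 0 and 1. Because the null parameters are estimated
#' from the same data, the p-value comes from a parametric bootstrap with
#' re-estimation: each replicate draws `n` values from the fitted
#' distribution, refits, and computes its own `D*`; the p-value is
#' `(1 + #\{D* >= D\}) / (valid replicates + 1)`. Replicates whose refit
#' fails are excluded.
#'
#' @param loads Mutant-load fractions (as for [fit_kimura()]).
#' @param reps Bootstrap replicates (default 2000).
#' @param seed Optional integer seed (RNG state preserved).
#' @param exclude_zeros Passed to [fit_kimura()].
#' @return An object of class `kimura_gof`: `D`, `p_value`, `reps`
#'   (requested), `reps_valid`, `seed` and the underlying `fit`.
#' @examples
#' x <- kimura_sample(kimura_params(0.3, 0.8), 35, seed = 7)
#' ks_test_mc(x, reps = 199, seed = 7)
#' @export
ks_test_mc <- function(loads, reps = 2000L, seed = NULL,
                       exclude_zeros = FALSE) {
  stopifnot(reps >= 1)
  fit <- fit_kimura(loads, exclude_zeros = exclude_zeros)
  D <- ks_statistic_kimura(fit$loads, fit$p0, fit$b, fit$f0, fit$f1)
  n <- fit$n
  sampler <- kimura_sampler(kimura_params(fit$p0, fit$b))
  Dstar <- with_preserved_seed(seed, {
    draws <- matrix(kimura_sampler_draw(sampler, n * reps), n, reps)
    draws <- apply(draws, 2L, sort)
    st <- refit_replicates(draws, fit$exceedance_threshold)
    ok <- st$ok
    out <- rep(NA_real_, reps)
    if (any(ok)) {
      s <- kimura_series(st$p0[ok], st$b[ok], X = draws[, ok, drop = FALSE],
                         what = "cdf")
      Fm <- s$vals + rep(st$f0[ok], each = n)
      Fm <- Fm + (draws[, ok, drop = FALSE] >= 1) * rep(st$f1[ok], each = n)
      Fm <- clamp01(Fm)
      atom <- (draws[, ok, drop = FALSE] == 0) * rep(st$f0[ok], each = n) +
        (draws[, ok, drop = FALSE] == 1) * rep(st$f1[ok], each = n)
      i_n <- seq_len(n) / n
      out[ok] <- pmax(apply(i_n - Fm, 2L, max),
                      apply((Fm - atom) - (i_n - 1 / n), 2L, max), 0)
    }
    out
  })
  valid <- sum(!is.na(Dstar))
  if (valid == 0L)
    stop("all bootstrap replicates failed to refit", call. = FALSE)
  p_value <- (1 + sum(Dstar >= D, na.rm = TRUE)) / (valid + 1)
  structure(list(D = D, p_value = p_value, reps = as.integer(reps),
                 reps_valid = as.integer(valid), seed = seed, fit = fit),
            class = "kimura_gof")
}

#' @export
print.kimura_gof <- function(x, ...) {
  cat(sprintf(paste0("Monte-Carlo KS test against the fitted Kimura ",
                     "distribution\n  D = %.4f, p-value = %.3f ",
                     "(%d bootstrap replicates%s)\n"),
              x$D, x$p_value, x$reps_valid,
              if (x$reps_valid < x$reps)
                sprintf(", %d failed refits excluded", x$reps - x$reps_valid)
              else ""))
  invisible(x)
}
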