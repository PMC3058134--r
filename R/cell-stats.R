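#' Per-pool summaries of single-cell mutant loads
#'
#' Summarises single-cell heteroplasmy measurements grouped into pools
#' (one pool = the cells isolated from one tissue sample of one
#' individual): per-pool mean, SD (n-1 denominator), minimum and maximum.
#' The cell-weighted grand mean across all pools is attached as attribute
#' `grand_mean` - the quantity compared against the whole-sample load to
#' check that a pool of isolated cells represents its tissue.
#'
#' @param cells A data frame with one row per cell, containing at least a
#'   pool identifier column and a mutant-load column (fractions in
#'   `[0, 1]`).
#' @param pool Name of the pool identifier column (default `"pool_id"`).
#' @param load Name of the mutant-load column (default `"load"`).
#' @param tissue Optional name of a tissue-label column carried through.
#' @return A tibble with columns `pool_id`, (`tissue`,) `n_cells`,
#'   `mean_load`, `sd_load`, `min_load`, `max_load`, attribute
#'   `grand_mean`. Singleton pools are kept (their `sd_load` is `NA`) but
#'   flagged with a warning; [mean_sd_regression()] excludes them.
#' @examples
#' cells <- tibble::tibble(pool_id = rep(c("a", "b"), each = 3),
#'                         load = c(0.1, 0.2, 0.3, 0.5, 0.6, 0.7))
#' summarize_pools(cells)
#' @export
summarize_pools <- function(cells, pool = "pool_id", load = "load",
                            tissue = NULL) {
  cells <- as.data.frame(cells)
  if (nrow(cells) == 0L) stop("no cells to summarise", call. = FALSE)
  for (col in c(pool, load, tissue))
    if (!col %in% names(cells))
      stop("column `", col, "` not found", call. = FALSE)
  x <- cells[[load]]
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("loads must be fractions in [0, 1]", call. = FALSE)
  groups <- split(seq_len(nrow(cells)), cells[[pool]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    xi <- x[groups[[g]]]
    tibble::tibble(
      pool_id = g,
      tissue = if (is.null(tissue)) NA_character_
               else as.character(cells[[tissue]][groups[[g]][1L]]),
      n_cells = length(xi),
      mean_load = mean(xi),
      sd_load = if (length(xi) >= 2L) stats::sd(xi) else NA_real_,
      min_load = min(xi),
      max_load = max(xi))
  }))
  if (is.null(tissue)) out$tissue <- NULL
  if (any(out$n_cells == 1L))
    warning(sum(out$n_cells == 1L), " singleton pool(s): SD undefined; ",
            "excluded from mean-SD regression", call. = FALSE)
  attr(out, "grand_mean") <- mean(x)
  out
}

#' Regression of single-cell dispersion on pool mean load
#'
#' Across pools of single cells, regresses the per-pool SD of mutant load
#' on the per-pool mean (unweighted ordinary least squares) and reports the
#' Pearson correlation with its two-sided p-value. A positive slope -
#' higher tissue mutant load accompanied by wider single-cell dispersion -
#' is the pattern expected from binomial-like intracellular sampling of
#' mtDNA below 50% load. Weighted least squares (weights = cell counts) is
#' available for unequal pool sizes.
#'
#' @param pools A pool-summary table from [summarize_pools()] (or any data
#'   frame with `mean_load`, `sd_load` and optionally `n_cells`).
#' @param weighted Use `n_cells` as OLS weights (default `FALSE`,
#'   matching the conventional unweighted treatment).
#' @return A list of class `mean_sd_regression`: `r`, `p_value` (of the
#'   correlation), `slope`, `slope_se`, `intercept`, `n_pools`.
#' @export
mean_sd_regression <- function(pools, weighted = FALSE) {
  pools <- as.data.frame(pools)
  keep <- is.finite(pools$mean_load) & is.finite(pools$sd_load)
  pools <- pools[keep, , drop = FALSE]
  if (nrow(pools) < 3L)
    stop("mean-SD regression needs at least 3 pools with defined SD (got ",
         nrow(pools), ")", call. = FALSE)
  w <- if (weighted) pools$n_cells else NULL
  fit <- stats::lm(sd_load ~ mean_load, data = pools, weights = w)
  co <- summary(fit)$coefficients
  r <- stats::cor(pools$mean_load, pools$sd_load)
  p <- if (abs(r) < 1) {
    stats::cor.test(pools$mean_load, pools$sd_load)$p.value
  } else 0
  structure(list(r = r, p_value = p,
                 slope = unname(co["mean_load", "Estimate"]),
                 slope_se = unname(co["mean_load", "Std. Error"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 n_pools = nrow(pools)),
            class = "mean_sd_regression")
}

#' @export
print.mean_sd_regression <- function(x, ...) {
  cat(sprintf(paste0("SD-on-mean regression across %d cell pools\n",
                     "  r = %.2f (p = %.3g); slope = %.2f +/- %.2f, ",
                     "intercept = %.3f\n"),
              x$n_pools, x$r, x$p_value, x$slope, x$slope_se, x$intercept))
  invisible(x)
}

#' One-way random-effects intraclass correlation
#'
#' Agreement of replicate measurements within groups (for instance
#' replicate blastomeres within an embryo) as the one-way random-effects
#' ICC: with between-group and within-group mean squares `MSB`, `MSW` from
#' the one-way ANOVA and the unbalanced-design average group size
#' `k0 = (sum(k) - sum(k^2)/sum(k)) / (g - 1)`,
#' `ICC = (MSB - MSW) / (MSB + (k0 - 1) MSW)`. An ICC near 1 means the
#' measurements within a group agree far more closely than groups differ
#' from one another.
#'
#' @param value Numeric vector of measurements.
#' @param group Group identifier, same length as `value`.
#' @return A list of class `icc_result`: `icc`, `n_groups`,
#'   `replicates_per_group` (named counts), `k0`, `ms_between`,
#'   `ms_within`. Groups with a single measurement are dropped with a
#'   warning (the ICC needs replication); if fewer than two groups remain,
#'   an error is raised.
#' @examples
#' icc_oneway(c(0.20, 0.21, 0.60, 0.59, 0.40, 0.41),
#'            rep(c("e1", "e2", "e3"), each = 2))
#' @export
icc_oneway <- function(value, group) {
  stopifnot(is.numeric(value), length(value) == length(group))
  keep <- is.finite(value)
  value <- value[keep]; group <- as.character(group)[keep]
  k <- table(group)
  if (any(k < 2L)) {
    warning(sum(k < 2L), " group(s) with a single replicate dropped",
            call. = FALSE)
    ok <- names(k)[k >= 2L]
    keep <- group %in% ok
    value <- value[keep]; group <- group[keep]
    k <- table(group)
  }
  g <- length(k)
  if (g < 2L)
    stop("ICC needs at least 2 groups with >= 2 replicates each",
         call. = FALSE)
  N <- sum(k)
  gm <- mean(value)
  mi <- tapply(value, group, mean)
  ssb <- sum(k * (mi - gm)^2)
  ssw <- sum((value - mi[group])^2)
  msb <- ssb / (g - 1)
  msw <- ssw / (N - g)
  k0 <- (N - sum(k^2) / N) / (g - 1)
  icc <- if (msw == 0 && msb == 0) NA_real_
  else (msb - msw) / (msb + (k0 - 1) * msw)
  structure(list(icc = icc, n_groups = g,
                 replicates_per_group = as.integer(k),
                 k0 = k0, ms_between = msb, ms_within = msw),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(paste0("One-way random-effects ICC = %.4f ",
                     "(%d groups, %s replicates each)\n"),
              x$icc, x$n_groups,
              if (length(unique(x$replicates_per_group)) == 1L)
                x$replicates_per_group[1L]
              else paste0(min(x$replicates_per_group), "-",
                          max(x$replicates_per_group))))
  invisible(x)
}

#' Transmission rate of a heteroplasmic mutation to offspring
#'
#' Fraction of offspring in which the mutation is detectable: a measured
#' load at or above the assay detection threshold counts as a carrier (the
#' threshold is the smallest detectable proportion, so a load exactly at it
#' is detected). Reports an exact binomial (Clopper-Pearson) 95% CI.
#' Raising the threshold can only reclassify carriers as non-carriers, so
#' the rate is monotone nonincreasing in the threshold.
#'
#' @param loads Offspring measured mutant-load fractions.
#' @param detection_threshold Detection limit as a fraction (default 0.02).
#' @return A list of class `transmission_rate`: `carriers`, `total`,
#'   `rate`, `ci_lower`, `ci_upper`, `detection_threshold`.
#' @examples
#' transmission_rate(c(rep(0.3, 29), rep(0, 6)))  # 29 of 35 -> 83%
#' @export
transmission_rate <- function(loads, detection_threshold = 0.02) {
  stopifnot(is.numeric(loads), length(loads) >= 1,
            detection_threshold >= 0, detection_threshold < 1)
  if (any(!is.finite(loads)) || any(loads < 0) || any(loads > 1))
    stop("`loads` must be fractions in [0, 1]", call. = FALSE)
  carriers <- sum(loads >= detection_threshold)
  total <- length(loads)
  bt <- stats::binom.test(carriers, total)
  structure(list(carriers = carriers, total = total,
                 rate = carriers / total,
                 ci_lower = bt$conf.int[1L], ci_upper = bt$conf.int[2L],
                 detection_threshold = detection_threshold),
            class = "transmission_rate")
}

#' @export
print.transmission_rate <- function(x, ...) {
  cat(sprintf(paste0("Transmission rate: %d of %d offspring carry the ",
                     "mutation (%.0f%%; exact 95%% CI %.0f-%.0f%%) at ",
                     "detection threshold %g%%\n"),
              x$carriers, x$total, 100 * x$rate,
              100 * x$ci_lower, 100 * x$ci_upper,
              100 * x$detection_threshold))
  invisible(x)
}
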