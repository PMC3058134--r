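#' Configuration for the Wright-Fisher bottleneck simulator
#'
#' Collects the settings for simulating an offspring cohort of a
#' heteroplasmic carrier: the founder mutant-load fraction, a Wright-Fisher
#' bottleneck of `N` segregating mtDNA units iterated for `g` germline
#' generations, and the measurement model of the mutant-load assay
#' (additive Gaussian replicate noise, truncation to `[0, 1]`, and a
#' detection threshold below which a measurement reports 0). The biology of
#' the bottleneck (copy-number restriction in primordial germ cells versus
#' segregation-unit selection) is deliberately abstracted into the single
#' compound drift parameter `b = (1 - 1/N)^g`, the only quantity the
#' cohort-level statistics identify.
#'
#' Defaults mirror the assay characterised for m.3243A>G quantification:
#' replicate SD below 1.7% and a 2% detection limit, with roughly 150 mtDNA
#' copies in a lymphocyte (blastomeres carry 11,000-449,000 and oocytes
#' 200,000-800,000; pass `copies_per_cell` accordingly).
#'
#' @param p Founder heteroplasmy fraction, strictly in (0, 1).
#' @param N Segregating units per generation (integer >= 2).
#' @param g Generations of drift (integer >= 0).
#' @param n_offspring Cohort size.
#' @param copies_per_cell mtDNA copy number used by [simulate_single_cells()].
#' @param noise_sd Assay replicate SD on the fraction scale (default 0.017).
#' @param detection_threshold Fraction below which the assay reports 0
#'   (default 0.02); a load exactly at the threshold is detected.
#' @param seed Integer seed recorded with every simulated cohort
#'   (default 3243, mnemonic for the mutation position).
#' @return An object of class `drift_sim_config`; its `b_implied` element
#'   carries `(1 - 1/N)^g`.
#' @examples
#' drift_sim_config(p = 0.3, N = 30, g = 10, n_offspring = 35)
#' @export
drift_sim_config <- function(p, N, g, n_offspring,
                             copies_per_cell = 150L,
                             noise_sd = 0.017,
                             detection_threshold = 0.02,
                             seed = 3243L) {
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p < 1)
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("`N` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(g) || length(g) != 1L || g < 0 || g != round(g))
    stop("`g` must be an integer >= 0", call. = FALSE)
  stopifnot(n_offspring >= 1, copies_per_cell >= 1,
            noise_sd >= 0, detection_threshold >= 0, detection_threshold < 1)
  b <- (1 - 1 / N)^g
  structure(list(p = p, N = as.integer(N), g = as.integer(g),
                 n_offspring = as.integer(n_offspring),
                 copies_per_cell = as.integer(copies_per_cell),
                 noise_sd = noise_sd,
                 detection_threshold = detection_threshold,
                 seed = as.integer(seed), b_implied = b),
            class = "drift_sim_config")
}

#' @export
print.drift_sim_config <- function(x, ...) {
  cat(sprintf(paste0("Wright-Fisher bottleneck: p = %g, N = %d units, ",
                     "g = %d generations (b = %.4f)\n",
                     "cohort n = %d; assay noise SD = %g, detection ",
                     "threshold = %g; seed = %d\n"),
              x$p, x$N, x$g, x$b_implied, x$n_offspring,
              x$noise_sd, x$detection_threshold, x$seed))
  invisible(x)
}

#' Simulate an offspring cohort under a germline bottleneck
#'
#' Each offspring's heteroplasmy starts at the founder fraction and is
#' resampled through `g` binomial Wright-Fisher steps of `N` segregating
#' units; the final frequency is the true mutant load. The measured load
#' adds Gaussian assay noise (`noise_sd`), truncates to `[0, 1]` and censors
#' values below the detection threshold to 0, mirroring a report of "no
#' detectable mutation".
#'
#' @param config A [drift_sim_config()] object.
#' @return An object of class `synthetic_cohort`: a list with `true_loads`,
#'   `measured_loads`, `replicates` (populated by
#'   [simulate_blastomere_replicates()]), `b_implied` and the `config`.
#' @examples
#' cohort <- simulate_offspring(drift_sim_config(0.3, N = 30, g = 10,
#'                                               n_offspring = 35))
#' mean(cohort$true_loads)
#' @export
simulate_offspring <- function(config) {
  stopifnot(inherits(config, "drift_sim_config"))
  with_preserved_seed(config$seed, {
    f <- rep(config$p, config$n_offspring)
    for (t in seq_len(config$g))
      f <- stats::rbinom(config$n_offspring, config$N, f) / config$N
    measured <- censor_below(
      clamp01(f + stats::rnorm(config$n_offspring, sd = config$noise_sd)),
      config$detection_threshold)
    structure(list(true_loads = f, measured_loads = measured,
                   replicates = NULL, b_implied = config$b_implied,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic offspring cohort: n = %d, founder p = %g, ",
                     "b = %.4f\n  measured loads: mean %.3f, SD %.3f, ",
                     "%d below detection\n"),
              length(x$true_loads), x$config$p, x$b_implied,
              mean(x$measured_loads), stats::sd(x$measured_loads),
              sum(x$measured_loads == 0)))
  if (!is.null(x$replicates))
    cat(sprintf("  %d replicate measurements per offspring (within-SD %g)\n",
                ncol(x$replicates), attr(x$replicates, "within_sd")))
  invisible(x)
}

#' Simulate single-cell mutant loads within one tissue pool
#'
#' Within a pool of cells from one individual, each cell's mutant load is
#' modelled as a binomial draw of its mtDNA molecules at the pool frequency:
#' `Binomial(copies_per_cell, p) / copies_per_cell`, plus optional assay
#' noise, truncated to `[0, 1]`. With the ~150 copies of a lymphocyte the
#' binomial spread is substantial; with the 10^5-scale copy numbers of
#' oocytes it vanishes.
#'
#' @param p Pool-level mutant-load fraction in `[0, 1]`.
#' @param copies_per_cell mtDNA copy number per cell (>= 1).
#' @param n_cells Number of cells to draw.
#' @param noise_sd Assay noise SD (fraction); 0 disables noise.
#' @param seed Optional seed (RNG state preserved).
#' @return Vector of `n_cells` mutant-load fractions.
#' @export
simulate_single_cells <- function(p, copies_per_cell, n_cells,
                                  noise_sd = 0, seed = NULL) {
  stopifnot(p >= 0, p <= 1, copies_per_cell >= 1, n_cells >= 1, noise_sd >= 0)
  with_preserved_seed(seed, {
    loads <- stats::rbinom(n_cells, copies_per_cell, p) / copies_per_cell
    if (noise_sd > 0)
      loads <- clamp01(loads + stats::rnorm(n_cells, sd = noise_sd))
    loads
  })
}

#' Add replicate blastomere measurements to a simulated cohort
#'
#' Emulates measuring `k` single blastomeres per embryo: every replicate is
#' the embryo's true load plus independent within-embryo noise of SD
#' `within_sd`, truncated to `[0, 1]`. The default `within_sd = 0.015` is a
#' calibration such that cohorts with a between-embryo SD around 0.23 yield
#' a one-way intraclass correlation near 0.994 - the agreement regime in
#' which replicate blastomeres of an embryo differ by at most a few percent
#' while embryos differ by tens of percent.
#'
#' @param cohort A `synthetic_cohort` from [simulate_offspring()].
#' @param k Replicates per offspring (>= 2).
#' @param within_sd Within-embryo measurement SD (fraction, >= 0).
#' @param seed Optional seed (RNG state preserved).
#' @return The cohort with a `replicates` element: an
#'   `n_offspring x k` matrix of replicate loads.
#' @export
simulate_blastomere_replicates <- function(cohort, k = 2L, within_sd = 0.015,
                                           seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"), k >= 2, within_sd >= 0)
  n <- length(cohort$true_loads)
  reps <- with_preserved_seed(seed, {
    clamp01(matrix(cohort$true_loads, n, k) +
              matrix(stats::rnorm(n * k, sd = within_sd), n, k))
  })
  attr(reps, "within_sd") <- within_sd
  cohort$replicates <- reps
  cohort
}
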