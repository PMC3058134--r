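# Composite-Simpson quadrature of f on (0, 1) over `n` panels (n even).
# Independent numerical-integration oracle for densities and moments.
simpson01 <- function(f, n = 2000L) {
  x <- seq(0, 1, length.out = n + 1L)
  # open interval: nudge the endpoints inward for densities undefined at 0/1
  x[1L] <- 1e-12
  x[n + 1L] <- 1 - 1e-12
  y <- f(x)
  h <- 1 / n
  h / 3 * (y[1L] + y[n + 1L] +
             4 * sum(y[seq(2L, n, by = 2L)]) +
             2 * sum(y[seq(3L, n - 1L, by = 2L)]))
}

# Closed-form OLS of y on x through the normal equations; algebraic oracle
# for the regression route.
ols_hand <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# Wright-Fisher sample in the diffusion regime: independent oracle for the
# Kimura distribution at b = (1 - 1/N)^g.
wf_sample <- function(p, N, g, n, seed) {
  cfg <- drift_sim_config(p = p, N = N, g = g, n_offspring = n,
                          noise_sd = 0, detection_threshold = 0, seed = seed)
  simulate_offspring(cfg)$true_loads
}

# fresh scratch path with the requested extension
temp_file <- function(name) {
  tempfile(fileext = paste0(".", tools::file_ext(name)))
}
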