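test_that("pool summaries give the textbook statistics per pool", {
  cells <- tibble::tibble(pool_id = rep("a", 3), load = c(0.1, 0.2, 0.3))
  s <- summarize_pools(cells)
  expect_equal(s$mean_load, 0.2)
  expect_equal(s$sd_load, 0.1)
  expect_equal(s$min_load, 0.1)
  expect_equal(s$max_load, 0.3)
  expect_equal(s$n_cells, 3L)
  expect_error(summarize_pools(cells[0, ]), "no cells")
})

test_that("the grand mean equals the cell-weighted mean of pool means", {
  set.seed(5)
  cells <- tibble::tibble(
    pool_id = rep(c("a", "b", "c"), times = c(7, 19, 30)),
    load = runif(56, 0, 0.9))
  s <- summarize_pools(cells)
  expect_equal(attr(s, "grand_mean"),
               sum(s$mean_load * s$n_cells) / sum(s$n_cells),
               tolerance = 1e-12)
  expect_equal(attr(s, "grand_mean"), mean(cells$load), tolerance = 1e-12)
})

test_that("singleton pools are flagged and excluded from the regression", {
  cells <- tibble::tibble(pool_id = c("a", "a", "b", "b", "c", "d", "d"),
                          load = c(0.1, 0.2, 0.3, 0.5, 0.4, 0.6, 0.9))
  expect_warning(s <- summarize_pools(cells), "singleton")
  expect_true(is.na(s$sd_load[s$pool_id == "c"]))
  expect_equal(suppressWarnings(mean_sd_regression(s))$n_pools, 3L)
})

test_that("regression recovers exact collinear structure and hand OLS", {
  pools <- tibble::tibble(mean_load = c(0.1, 0.2, 0.3, 0.4, 0.5),
                          sd_load = 0.5 * c(0.1, 0.2, 0.3, 0.4, 0.5),
                          n_cells = 10L)
  r <- suppressWarnings(mean_sd_regression(pools))  # lm flags the exact fit
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$slope, 0.5, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  # algebraic oracle on an arbitrary 5-pool table
  pools2 <- tibble::tibble(mean_load = c(0.16, 0.34, 0.52, 0.08, 0.71),
                           sd_load = c(0.09, 0.13, 0.11, 0.04, 0.18),
                           n_cells = c(20L, 18L, 25L, 7L, 14L))
  r2 <- mean_sd_regression(pools2)
  hand <- ols_hand(pools2$mean_load, pools2$sd_load)
  expect_equal(r2$slope, unname(hand["slope"]), tolerance = 1e-12)
  expect_equal(r2$intercept, unname(hand["intercept"]), tolerance = 1e-12)
  expect_error(mean_sd_regression(pools2[1:2, ]), "at least 3")
})

test_that("regression is invariant to pool order and rescales with units", {
  pools <- tibble::tibble(mean_load = c(0.16, 0.34, 0.52, 0.08, 0.71),
                          sd_load = c(0.09, 0.13, 0.11, 0.04, 0.18),
                          n_cells = 10L)
  r1 <- mean_sd_regression(pools)
  r2 <- mean_sd_regression(pools[sample(5), ])
  expect_equal(r1$r, r2$r)
  expect_equal(r1$slope, r2$slope)
  # percent scale: correlation and slope unchanged, intercept scales
  pct <- tibble::tibble(mean_load = 100 * pools$mean_load,
                        sd_load = 100 * pools$sd_load, n_cells = 10L)
  r3 <- mean_sd_regression(pct)
  expect_equal(r3$r, r1$r, tolerance = 1e-12)
  expect_equal(r3$slope, r1$slope, tolerance = 1e-12)
  expect_equal(r3$intercept, 100 * r1$intercept, tolerance = 1e-10)
})

test_that("binomial single-cell pools show dispersion growing with load", {
  means <- seq(0.05, 0.45, length.out = 8)
  pools <- summarize_pools(tibble::tibble(
    pool_id = rep(sprintf("p%d", seq_along(means)), each = 30),
    load = unlist(lapply(seq_along(means), function(i)
      simulate_single_cells(means[i], 150, 30, seed = 600 + i)))))
  r <- mean_sd_regression(pools)
  expect_gt(r$slope, 0)
  expect_lt(r$p_value, 0.05)
})

test_that("one-way ICC matches the ANOVA decomposition", {
  # balanced table: against stats::aov mean squares (independent route)
  set.seed(9)
  g <- rep(sprintf("e%02d", 1:12), each = 3)
  y <- rep(runif(12, 0.1, 0.8), each = 3) + rnorm(36, sd = 0.02)
  res <- icc_oneway(y, g)
  ms <- summary(stats::aov(y ~ factor(g)))[[1]][["Mean Sq"]]
  expect_equal(res$ms_between, ms[1], tolerance = 1e-10)
  expect_equal(res$ms_within, ms[2], tolerance = 1e-10)
  expect_equal(res$icc, (ms[1] - ms[2]) / (ms[1] + (3 - 1) * ms[2]),
               tolerance = 1e-10)
  # unbalanced: k0 correction against the explicit formula
  g2 <- rep(c("a", "b", "c"), times = c(2, 5, 11))
  y2 <- rep(c(0.2, 0.5, 0.7), times = c(2, 5, 11)) + rnorm(18, sd = 0.03)
  res2 <- icc_oneway(y2, g2)
  k <- c(2, 5, 11)
  expect_equal(res2$k0, (18 - sum(k^2) / 18) / 2, tolerance = 1e-12)
})

test_that("ICC reaches 1 for perfect replicates and 1/2 at equal variances", {
  expect_equal(icc_oneway(rep(c(0.2, 0.5, 0.8), each = 4),
                          rep(c("a", "b", "c"), each = 4))$icc, 1)
  set.seed(10)
  gg <- rep(seq_len(300), each = 4)
  yy <- rep(rnorm(300), each = 4) + rnorm(1200)   # sigma_b = sigma_w
  expect_equal(icc_oneway(yy, gg)$icc, 0.5, tolerance = 0.05)
})

test_that("singleton groups are dropped from the ICC with a warning", {
  expect_warning(res <- icc_oneway(c(0.2, 0.21, 0.5, 0.52, 0.9),
                                   c("a", "a", "b", "b", "c")),
                 "single replicate")
  expect_equal(res$n_groups, 2L)
  expect_error(suppressWarnings(icc_oneway(c(0.1, 0.2, 0.3),
                                           c("a", "b", "c"))),
               "at least 2 groups")
})

test_that("transmission rates reproduce the printed offspring counts", {
  r <- transmission_rate(c(runif(29, 0.05, 0.8), rep(0, 6)))
  expect_equal(r$carriers, 29L)
  expect_equal(r$rate, 29 / 35)
  expect_equal(sprintf("%.0f", 100 * r$rate), "83")
  r2 <- transmission_rate(c(runif(49, 0.04, 0.8), rep(0, 9)))
  expect_equal(sprintf("%.0f", 100 * r2$rate), "84")
  expect_true(r$ci_lower < r$rate && r$rate < r$ci_upper)
  expect_equal(transmission_rate(rep(0, 10))$rate, 0)
})

test_that("the transmission rate is monotone nonincreasing in the threshold", {
  set.seed(12)
  loads <- c(rep(0, 4), runif(30, 0.01, 0.6))
  rates <- vapply(c(0, 0.01, 0.02, 0.05, 0.1, 0.5),
                  function(th) transmission_rate(loads, th)$rate, numeric(1))
  expect_true(all(diff(rates) <= 0))
  # a load exactly at the threshold counts as detected
  expect_equal(transmission_rate(c(0.02, 0.5), 0.02)$carriers, 2L)
})
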