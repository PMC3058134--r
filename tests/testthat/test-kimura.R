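test_that("parameter constructor rejects boundary and invalid values", {
  expect_s3_class(kimura_params(0.5, 0.5), "kimura_params")
  expect_error(kimura_params(0, 0.5), "strictly")
  expect_error(kimura_params(1, 0.5), "strictly")
  expect_error(kimura_params(0.5, 0), "strictly")
  expect_error(kimura_params(0.5, 1), "strictly")
  expect_error(kimura_params(c(0.2, 0.3), 0.5))
})

test_that("fixation masses agree with drift theory at the fitted parameters", {
  # patient-2 regime: loss ~8.4%, mutant fixation a few per mille
  m <- kimura_masses(kimura_params(0.337, 0.72))
  expect_equal(m$f0, 0.084, tolerance = 0.01)
  expect_gt(m$f1, 0)
  expect_lt(m$f1, 0.02)          # inside the published interval 0-2%
  expect_equal(m$f0 + m$f1 + m$continuous_mass, 1, tolerance = 1e-12)
  # published-oocyte regime: loss ~14%, mutant fixation negligible
  m2 <- kimura_masses(kimura_params(0.126, 0.87))
  expect_equal(m2$f0, 0.14, tolerance = 0.05)
  expect_lt(m2$f1, 1e-6)
  # complete fixation limit b -> 0+: masses go to 1-p and p
  m3 <- kimura_masses(kimura_params(0.3, 1e-6))
  expect_equal(m3$f0, 0.7, tolerance = 1e-5)
  expect_equal(m3$f1, 0.3, tolerance = 1e-5)
  expect_lt(m3$continuous_mass, 1e-5)
})

test_that("masses and density are symmetric under mutant/wild-type relabel", {
  grid <- expand.grid(p = c(0.1, 0.3, 0.5, 0.7), b = c(0.2, 0.5, 0.8))
  for (r in seq_len(nrow(grid))) {
    p <- grid$p[r]; b <- grid$b[r]
    m <- kimura_masses(kimura_params(p, b))
    mm <- kimura_masses(kimura_params(1 - p, b))
    expect_equal(m$f0, mm$f1, tolerance = 1e-8)
    x <- c(0.1, 0.25, 0.6, 0.9)
    expect_equal(kimura_pdf(x, kimura_params(p, b)),
                 kimura_pdf(1 - x, kimura_params(1 - p, b)),
                 tolerance = 1e-8)
  }
})

test_that("density normalises and reproduces the closed-form moments", {
  for (p in c(0.1, 0.3, 0.5, 0.9)) {
    for (b in c(0.1, 0.5, 0.8, 0.95)) {
      params <- kimura_params(p, b)
      m <- kimura_masses(params)
      total <- m$f0 + m$f1 + simpson01(function(x) kimura_pdf(x, params))
      expect_equal(total, 1, tolerance = 1e-6)
      mean_q <- simpson01(function(x) x * kimura_pdf(x, params)) + m$f1
      expect_equal(mean_q, p, tolerance = 1e-5)
      m2 <- simpson01(function(x) x^2 * kimura_pdf(x, params)) + m$f1
      expect_equal(m2 - mean_q^2, p * (1 - p) * (1 - b), tolerance = 1e-5)
    }
  }
})

test_that("density is nonnegative and rejects out-of-domain points", {
  params <- kimura_params(0.3, 0.7)
  x <- seq(0.001, 0.999, length.out = 500)
  expect_true(all(kimura_pdf(x, params) >= 0))
  expect_error(kimura_pdf(0, params), "strictly")
  expect_error(kimura_pdf(1, params), "strictly")
  expect_error(kimura_pdf(-0.1, params), "strictly")
})

test_that("cdf honours the atoms, is monotone, and matches quadrature", {
  params <- kimura_params(0.337, 0.72)
  m <- kimura_masses(params)
  expect_equal(kimura_cdf(0, params), m$f0, tolerance = 1e-10)
  expect_equal(kimura_cdf(1, params), 1, tolerance = 1e-10)
  xs <- seq(0.01, 0.99, by = 0.01)
  Fx <- kimura_cdf(xs, params)
  expect_true(all(diff(Fx) >= -1e-12))
  # quadrature oracle at each grid point
  quad <- vapply(xs, function(u) {
    n <- 400L
    g <- seq(1e-12, u, length.out = n + 1L)
    y <- kimura_pdf(g, params)
    h <- (u - 1e-12) / n
    h / 3 * (y[1L] + y[n + 1L] + 4 * sum(y[seq(2L, n, 2L)]) +
               2 * sum(y[seq(3L, n - 1L, 2L)]))
  }, numeric(1))
  expect_equal(Fx, m$f0 + quad, tolerance = 1e-6)
})

test_that("cdf of the oocyte fit puts ~14% mass at zero", {
  expect_equal(kimura_cdf(0, kimura_params(0.126, 0.87)), 0.14,
               tolerance = 0.05)
})

test_that("tail probability complements the cdf and hits the fitted values", {
  p2 <- kimura_params(0.337, 0.72)
  expect_equal(kimura_tail(0.6, p2), 0.17, tolerance = 0.01)
  # oocyte regime: a 0.2% chance of exceeding 60% mutant load, well inside
  # the published interval 0.02-0.8% (the deep tail is hypersensitive to
  # rounding of the inputs, so only the bracket is a stable statement)
  oo_tail <- kimura_tail(0.6, kimura_params(0.126, 0.87))
  expect_gt(oo_tail, 0.0002)
  expect_lt(oo_tail, 0.008)
  expect_equal(kimura_tail(1, p2), 0)
  expect_equal(kimura_tail(0, p2), 1 - kimura_masses(p2)$f0,
               tolerance = 1e-10)
})

test_that("closed-form moments follow the drift identities", {
  mo <- kimura_moments(kimura_params(0.126, 0.87))
  expect_equal(mo$mean, 0.126)
  expect_equal(mo$variance, 0.126 * 0.874 * 0.13, tolerance = 1e-12)
  expect_equal(mo$variance, 0.0143, tolerance = 0.01)
  # no drift: variance vanishes
  expect_lt(kimura_moments(kimura_params(0.3, 1 - 1e-9))$variance, 1e-9)
})

test_that("sampling reproduces the distribution and is seed-reproducible", {
  params <- kimura_params(0.337, 0.72)
  x <- kimura_sample(params, 1e5, seed = 11)
  expect_true(all(x >= 0 & x <= 1))
  expect_lt(abs(mean(x) - 0.337), 0.003)
  expect_lt(abs(var(x) - 0.337 * 0.663 * 0.28), 0.003)
  m <- kimura_masses(params)
  expect_lt(abs(mean(x == 0) - m$f0), 0.003)
  expect_lt(abs(mean(x == 1) - m$f1), 0.002)
  expect_identical(x, kimura_sample(params, 1e5, seed = 11))
  expect_false(identical(x[1:10], kimura_sample(params, 10, seed = 12)))
  # seeded sampling leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(kimura_sample(params, 10, seed = 5))
  expect_identical(runif(1), before)
})

test_that("the series reports non-convergence for b too close to 1", {
  expect_error(kimura_masses(kimura_params(0.3, 1 - 1e-6)), "converge")
})
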