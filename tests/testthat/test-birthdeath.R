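test_that("survival probability matches closed forms and the progeny pmf", {
  expect_equal(survival_probability(bd_params(0.3, 0), c(1, 50, 400)),
               c(1, 1, 1))
  expect_equal(survival_probability(bd_params(0.1, 0.1), 10), 0.5)
  # survival = 1 - P(N = 0)
  p <- bd_params(0.2, 0.1)
  expect_equal(survival_probability(p, 30),
               1 - progeny_pmf(p, 30, 0), tolerance = 1e-12)
  # strictly decreasing in t and in mu when mu > 0
  expect_true(all(diff(survival_probability(p, c(1, 5, 20, 80))) < 0))
  svals <- vapply(c(0.05, 0.1, 0.15), function(m)
    survival_probability(bd_params(0.2, m), 30), numeric(1))
  expect_true(all(diff(svals) < 0))
  expect_error(survival_probability(p, -1), "non-negative")
})

test_that("expected richness covers balanced, conditioned and unconditioned cases", {
  # balanced process calibrated to 10,000 species at t = 100
  expect_equal(expected_richness(bd_params(99.99, 99.99), 100,
                                 conditioned = TRUE), 10000)
  expect_equal(expected_richness(bd_params(0.5, 0.2), 0), 1)
  expect_equal(expected_richness(bd_params(0.1, 0.02), 50,
                                 conditioned = FALSE, n0 = 3),
               3 * exp(0.08 * 50))
  # conditioning inflates the expectation iff extinction is possible
  p <- bd_params(0.1, 0.05)
  expect_gt(expected_richness(p, 40, TRUE),
            expected_richness(p, 40, FALSE))
  p0 <- bd_params(0.1, 0)
  expect_equal(expected_richness(p0, 40, TRUE),
               expected_richness(p0, 40, FALSE))
  # continuity across r = 0: near-balanced vs balanced forms
  lam <- 0.1
  near <- expected_richness(bd_params(lam + 1e-13, lam), 10, TRUE)
  bal <- expected_richness(bd_params(lam, lam), 10, TRUE)
  expect_equal(near, bal, tolerance = 1e-8)
  expect_equal(bal, 1 + lam * 10)
  # negative net diversification (mu > lambda) stays valid
  pneg <- bd_params(0.05, 0.1)
  expect_lt(expected_richness(pneg, 50, FALSE), 1)
  expect_gte(expected_richness(pneg, 50, TRUE), 1)
})

test_that("progeny pmf has the geometric-tail form and normalizes analytically", {
  expect_equal(progeny_pmf(bd_params(0.1, 0), 10, 1), exp(-1),
               tolerance = 1e-12)
  for (pars in list(bd_params(0.2, 0.1), bd_params(0.1, 0.1),
                    bd_params(0.05, 0.12))) {
    head <- sum(progeny_pmf(pars, 25, 0:2000))
    ab <- agediv:::bd_ab(pars, 25)
    tail <- (1 - ab$a) * ab$b^2000      # analytic geometric tail beyond 2000
    expect_equal(head + tail, 1, tolerance = 1e-12)
    # conditioned variant renormalizes over n >= 1
    headc <- sum(progeny_pmf(pars, 25, 1:2000, conditioned = TRUE))
    expect_equal(headc + tail / (1 - ab$a), 1, tolerance = 1e-12)
  }
  # pmf mean equals the closed-form expectation (analytic geometric moments)
  p <- bd_params(0.15, 0.08)
  ab <- agediv:::bd_ab(p, 30)
  mean_uncond <- (1 - ab$a) / (1 - ab$b)
  expect_equal(mean_uncond, expected_richness(p, 30, FALSE), tolerance = 1e-9)
  expect_equal(1 / (1 - ab$b), expected_richness(p, 30, TRUE),
               tolerance = 1e-9)
  # log-space evaluation survives huge counts
  expect_true(is.finite(progeny_pmf(p, 30, 1e7, log = TRUE)))
  expect_error(progeny_pmf(p, 30, 0, conditioned = TRUE), "n = 1")
})

test_that("progeny pmf matches a truncated CTMC matrix-exponential oracle", {
  lam <- 0.15; mu <- 0.12; t <- 40
  oracle <- ctmc_progeny(lam, mu, t, n_max = 500)
  mine <- progeny_pmf(bd_params(lam, mu), t, 0:50)
  expect_equal(mine, oracle[1:51], tolerance = 1e-8)
})

test_that("progeny sampler is an exact draw from the pmf", {
  expect_equal(sample_progeny(bd_params(0, 0), 10, size = 5),
               rep(1, 5))
  set.seed(42)
  a <- sample_progeny(bd_params(0.2, 0.1), 30, size = 100, conditioned = TRUE)
  set.seed(42)
  b <- sample_progeny(bd_params(0.2, 0.1), 30, size = 100, conditioned = TRUE)
  expect_identical(a, b)
  # chi-square goodness of fit against the pmf, pooled upper tail
  p <- bd_params(0.1, 0.06)
  set.seed(7)
  x <- sample_progeny(p, 20, size = 1e5)
  brk <- c(0:15, Inf)
  obs <- table(cut(x, breaks = c(-0.5, 0:15 + 0.5, Inf)))
  expp <- c(progeny_pmf(p, 20, 0:15),
            1 - sum(progeny_pmf(p, 20, 0:15)))
  gof <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = expp))
  expect_gt(gof$p.value, 0.001)
})

test_that("constant-rate ML recovers rates and flags degenerate data", {
  # fixed-epsilon fit against a brute-force grid on one clade
  fit <- fit_constant_rate_ml(ages = 50, richness = 100, epsilon = 0)
  grid <- seq(0.01, 0.2, by = 1e-5)
  ll <- vapply(grid, function(r)
    progeny_pmf(bd_params(r, 0), 50, 100, conditioned = TRUE, log = TRUE),
    numeric(1))
  expect_equal(fit$params$r, grid[which.max(ll)], tolerance = 1e-4)
  # two-parameter recovery on simulated data
  set.seed(11)
  ages <- runif(300, 20, 120)
  rich <- sample_progeny(bd_params(0.12, 0.06), ages, size = 300,
                         conditioned = TRUE)
  fit2 <- fit_constant_rate_ml(ages, rich)
  expect_true(fit2$convergence)
  expect_equal(fit2$params$r, 0.06, tolerance = 0.35)
  # no growth signal: boundary flagged
  fit3 <- fit_constant_rate_ml(ages = rep(50, 20), richness = rep(1, 20))
  expect_true(fit3$boundary)
})
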