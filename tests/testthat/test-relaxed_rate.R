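test_that("richness log-likelihood matches closed forms and the core pmf", {
  # pure birth (epsilon = 0): conditioned geometric with b = 1 - e^{-rt}
  r <- 0.07; t <- 42; n <- 19
  closed <- log(exp(-r * t) * (1 - exp(-r * t))^(n - 1))
  expect_equal(richness_loglik(n, t, r, epsilon = 0), closed,
               tolerance = 1e-12)
  # equals the survival-conditioned progeny pmf by construction
  set.seed(1)
  for (i in 1:20) {
    eps <- runif(1, 0, 0.95); rr <- runif(1, 0.01, 0.3)
    tt <- runif(1, 5, 150); nn <- sample(1:5000, 1)
    lam <- rr / (1 - eps)
    expect_equal(richness_loglik(nn, tt, rr, eps),
                 progeny_pmf(bd_params(lam, eps * lam), tt, nn,
                             conditioned = TRUE, log = TRUE),
                 tolerance = 1e-10)
  }
  expect_error(richness_loglik(0, 10, 0.1), "n >= 1")
  # normalizes over n >= 1 via the analytic geometric tail
  eps <- 0.6; rr <- 0.05; tt <- 60
  lam <- rr / (1 - eps)
  ab <- agediv:::bd_ab(bd_params(lam, eps * lam), tt)
  head <- sum(exp(richness_loglik(1:5000, rep(tt, 5000), rr, eps)))
  expect_equal(head + ab$b^5000, 1, tolerance = 1e-10)
})

test_that("MCMC is reproducible and recovers generating hyperparameters", {
  set.seed(2)
  g <- generate_clade_dataset(generator_spec(
    n_tips = 100, backbone_lambda = 0.05, seed = 12,
    richness_model = "lognormal_relaxed",
    model_params = list(m = -2.5, s = 0.5, epsilon = 0)))
  p1 <- run_mcmc(g$dataset, epsilon = 0, n_iter = 3000, n_chains = 2,
                 burnin = 1500, thin = 5, seed = 9)
  p2 <- run_mcmc(g$dataset, epsilon = 0, n_iter = 3000, n_chains = 2,
                 burnin = 1500, thin = 5, seed = 9)
  expect_identical(p1$draws, p2$draws)
  ci_m <- stats::quantile(p1$draws[, "m"], c(0.025, 0.975))
  ci_s <- stats::quantile(p1$draws[, "s"], c(0.025, 0.975))
  expect_true(ci_m[1] < -2.5 && -2.5 < ci_m[2])
  expect_true(ci_s[1] < 0.5 && 0.5 < ci_s[2])
  expect_true(all(is.finite(p1$ess)))
  expect_true(all(exp(p1$draws[, -(1:2)]) > 0))
})

test_that("a collapsing rate spread recovers the constant-rate ML estimate", {
  set.seed(3)
  ds <- toy_dataset(seed = 13, n_tips = 80, lambda = 0.1, mu = 0)
  # prior forcing s -> 0 shrinks all clade rates to a common value
  post <- run_mcmc(ds, epsilon = 0, n_iter = 4000, n_chains = 1,
                   burnin = 2000, thin = 5, seed = 5,
                   priors = list(m_mean = 0, m_sd = 10, s_scale = 1e-4))
  shared_r <- exp(mean(post$draws[, "m"]))
  ml <- fit_constant_rate_ml(ds, epsilon = 0)
  expect_equal(shared_r, ml$params$r, tolerance = 0.15)
  expect_lt(stats::median(post$draws[, "s"]), 0.1)
})

test_that("posterior-predictive simulation honours conditioning and the model", {
  set.seed(4)
  g <- generate_clade_dataset(generator_spec(
    n_tips = 60, backbone_lambda = 0.05, seed = 14,
    richness_model = "lognormal_relaxed",
    model_params = list(m = -2.8, s = 0.4, epsilon = 0)))
  post <- run_mcmc(g$dataset, epsilon = 0, n_iter = 2000, n_chains = 1,
                   burnin = 1000, thin = 5, seed = 6)
  set.seed(7)
  sims <- posterior_predictive(g$dataset, post, n_draws = 150)
  expect_true(all(sims >= 1))
  expect_equal(dim(sims), c(150, 60))
  set.seed(7)
  sims2 <- posterior_predictive(g$dataset, post, n_draws = 150)
  expect_identical(sims, sims2)
  # age-richness coupling implied by the model: predictive mean richness
  # increases with stem age (rank correlation across clades)
  mu_clade <- colMeans(log(sims))
  expect_gt(spearman_rho(g$dataset$records$stem_age, mu_clade), 0.3)
})

test_that("standardized effect sizes score slopes against the predictive cloud", {
  set.seed(5)
  g <- generate_clade_dataset(generator_spec(
    n_tips = 60, backbone_lambda = 0.05, seed = 15,
    richness_model = "lognormal_relaxed",
    model_params = list(m = -2.8, s = 0.4, epsilon = 0)))
  post <- run_mcmc(g$dataset, epsilon = 0, n_iter = 2000, n_chains = 1,
                   burnin = 1000, thin = 5, seed = 8)
  sims <- posterior_predictive(g$dataset, post, n_draws = 120)
  ses <- standardized_effect_size(g$dataset, sims)
  expect_equal(ses$ses,
               (ses$beta_obs - ses$beta_sim_mean) / ses$beta_sim_sd,
               tolerance = 1e-12)
  expect_true(ses$tail_probability >= 0 && ses$tail_probability <= 1)
  # moving the observed slope to the simulated mean gives SES 0; two sd
  # below gives SES -2
  s0 <- standardized_effect_size(g$dataset, sims,
                                 beta_obs = ses$beta_sim_mean)
  expect_equal(s0$ses, 0, tolerance = 1e-12)
  s2 <- standardized_effect_size(g$dataset, sims,
                                 beta_obs = ses$beta_sim_mean -
                                   2 * ses$beta_sim_sd)
  expect_equal(s2$ses, -2, tolerance = 1e-12)
  # the observed data are a draw from the fitted family: SES near 0
  expect_lt(abs(ses$ses), 3)
  # fewer than 100 simulated datasets is refused
  expect_error(standardized_effect_size(g$dataset, sims[1:50, ]), "100")
  # predictive slopes are positive on average (the age-richness coupling
  # that real data fail to show)
  expect_gt(ses$beta_sim_mean, 0)
})
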