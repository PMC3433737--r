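test_that("PGLS with star or identity covariance reproduces OLS exactly", {
  set.seed(1)
  ds <- toy_dataset(seed = 1)
  ols <- pgls_fit(ds, covariance = "identity")
  lmfit <- stats::lm(log(richness) ~ stem_age, data = ds$records)
  expect_equal(ols$beta, unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(ols$p_value, summary(lmfit)$coefficients[2, 4],
               tolerance = 1e-10)
  # on a star tree BM covariance is proportional to the identity
  star <- star_tree(12, height = 20)
  rich <- c(3, 50, 7, 1, 120, 9, 2, 33, 4, 18, 6, 250)
  dstar <- clade_dataset(star, data.frame(name = star$tip.label,
                                          richness = rich))
  bm <- pgls_fit(dstar, covariance = "BM")
  id <- pgls_fit(dstar, covariance = "identity")
  expect_equal(bm$beta, id$beta, tolerance = 1e-10)
  expect_equal(bm$t_statistic, id$t_statistic, tolerance = 1e-10)
  # lambda = 0 transform also collapses to OLS
  l0 <- pgls_fit(ds, covariance = "lambda", lambda = 0)
  expect_equal(l0$beta, ols$beta, tolerance = 1e-10)
})

test_that("GLS slope matches explicit matrix arithmetic on a 4-tip tree", {
  tr <- read_timetree("((A:4,B:4):6,(C:7,D:7):3);")
  ds <- clade_dataset(tr, data.frame(name = c("A", "B", "C", "D"),
                                     richness = c(12, 40, 3, 9)))
  fit <- pgls_fit(ds, covariance = "BM")
  V <- ape::vcv.phylo(tr)[ds$records$name, ds$records$name]
  X <- cbind(1, ds$records$stem_age)
  y <- log(ds$records$richness)
  Vi <- solve(V)
  beta_hat <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
  expect_equal(fit$intercept, beta_hat[1, 1], tolerance = 1e-10)
  expect_equal(fit$beta, beta_hat[2, 1], tolerance = 1e-10)
  resid <- y - X %*% beta_hat
  sig2 <- drop(t(resid) %*% Vi %*% resid) / 2
  se <- sqrt(sig2 * solve(t(X) %*% Vi %*% X)[2, 2])
  expect_equal(fit$se_beta, se, tolerance = 1e-10)
  expect_equal(fit$df, 2)
})

test_that("degenerate responses and covariances are handled explicitly", {
  ds <- toy_dataset(seed = 2)
  ds$records$richness <- rep(5, nrow(ds$records))
  fit <- pgls_fit(ds)
  expect_equal(fit$beta, 0, tolerance = 1e-12)
  expect_equal(fit$t_statistic, 0, tolerance = 1e-8)
})

test_that("slope is equivariant under branch rescaling and stable to tip order", {
  ds <- toy_dataset(seed = 3)
  fit <- pgls_fit(ds)
  ds2 <- ds
  ds2$tree$edge.length <- ds2$tree$edge.length * 10
  ds2 <- clade_dataset(ds2$tree, ds2$records[, c("name", "richness")])
  fit2 <- pgls_fit(ds2)
  expect_equal(fit2$beta, fit$beta / 10, tolerance = 1e-9)
  expect_equal(fit2$t_statistic, fit$t_statistic, tolerance = 1e-9)
  expect_equal(fit2$p_value, fit$p_value, tolerance = 1e-9)
  perm <- sample(nrow(ds$records))
  ds3 <- clade_dataset(ds$tree, ds$records[perm, c("name", "richness")])
  expect_equal(pgls_fit(ds3)$beta, fit$beta, tolerance = 1e-10)
})

test_that("Pagel's lambda ML recovers signal and its absence", {
  set.seed(4)
  tr <- generate_timetree(generator_spec(n_tips = 200, seed = 4))
  # Brownian data on the tree: strong signal expected
  y <- simulate_bm_tips(tr, Lambda = 1, root_state = 3, rate = 0.05,
                        n_datasets = 1)[1, ]
  ds <- clade_dataset(tr, data.frame(name = colnames(
    simulate_bm_tips(tr, 1, 0, 1, 1)), richness = pmax(1, round(exp(y)))))
  ds$records$richness <- pmax(1, round(exp(y[ds$records$name])))
  sig <- estimate_lambda(ds)
  expect_gt(sig$Lambda_ml, 0.8)
  expect_gt(sig$delta_aic, 2)
  # i.i.d. tip values: no signal
  ds$records$richness <- pmax(1, round(exp(rnorm(200, 3, 1))))
  sig0 <- estimate_lambda(ds)
  expect_lt(sig0$Lambda_ml, 0.2)
  expect_lt(sig0$delta_aic, 2)
})

test_that("lambda ML agrees with an independent implementation", {
  set.seed(6)
  tr <- generate_timetree(generator_spec(n_tips = 120, seed = 6))
  y <- simulate_bm_tips(tr, Lambda = 0.6, root_state = 2, rate = 0.03,
                        n_datasets = 1)[1, ]
  ds <- clade_dataset(tr, data.frame(name = names(y),
                                     richness = pmax(1, round(exp(y)))))
  sig <- estimate_lambda(ds)
  ref <- phytools::phylosig(tr, stats::setNames(
    log(ds$records$richness), ds$records$name), method = "lambda")
  expect_equal(sig$Lambda_ml, ref$lambda, tolerance = 0.02)
  expect_equal(sig$logL, ref$logL, tolerance = 1e-3)
})

test_that("contrast-variance test detects signal and stays calibrated without it", {
  set.seed(7)
  tr <- generate_timetree(generator_spec(n_tips = 100, seed = 7))
  y <- simulate_bm_tips(tr, Lambda = 1, root_state = 3, rate = 0.05,
                        n_datasets = 1)[1, ]
  ds <- clade_dataset(tr, data.frame(name = names(y),
                                     richness = pmax(1, round(exp(y)))))
  res <- contrasts_signal_test(ds, n_permutations = 199)
  expect_lt(res$p_value, 0.05)
  an <- contrasts_signal_test(ds, n_permutations = 199, mode = "analytic")
  expect_lt(an$p_value, 0.05)
  # identical tip values: zero contrast variance, minimal p
  ds$records$richness <- rep(10, 100)
  res0 <- contrasts_signal_test(ds, n_permutations = 199)
  expect_equal(res0$observed_variance, 0)
  expect_equal(res0$p_value, 1 / 200)
  # i.i.d. values: p not systematically small
  set.seed(8)
  ps <- replicate(20, {
    ds$records$richness <- pmax(1, round(exp(rnorm(100, 3, 1))))
    contrasts_signal_test(ds, n_permutations = 99)$p_value
  })
  expect_gt(mean(ps), 0.25)
})

test_that("subtree scan counts qualifying subtrees and supports exclusions", {
  tr <- balanced16()
  set.seed(9)
  ds <- clade_dataset(tr, data.frame(name = tr$tip.label,
                                     richness = sample(1:100, 16)))
  sc <- scan_subtrees(ds, min_tips = 10)
  expect_equal(sc$n_subtrees, 1)          # children of the root have 8 tips
  expect_equal(sc$table$n_tips, 16)
  # constant-rate growth: positive slopes dominate
  set.seed(10)
  big <- toy_dataset(seed = 10, n_tips = 120, lambda = 0.15, mu = 0.05)
  sc2 <- scan_subtrees(big, min_tips = 10)
  expect_gt(mean(sc2$table$slope > 0), 0.5)
  expect_gte(sc2$n_significant_positive, sc2$n_significant_negative)
  expect_true(all(sc2$table$p_bonferroni >= sc2$table$p))
  # excluding a named subtree removes its tips from the scan
  node <- sc2$table$node[which.max(sc2$table$n_tips < 120)]
  scx <- scan_subtrees(big, min_tips = 10, exclude_node = node)
  expect_lt(scx$n_subtrees, sc2$n_subtrees + 1)
})

test_that("age truncation keeps original stem ages and matches a direct filter", {
  ds <- toy_dataset(seed = 11, n_tips = 60)
  cut <- stats::median(ds$records$stem_age)
  sub <- subset_by_age(ds, cut)
  expect_equal(nrow(sub$records), sum(ds$records$stem_age < cut))
  expect_true(all(sub$records$stem_age < cut))
  orig <- ds$records$stem_age[match(sub$records$name, ds$records$name)]
  expect_equal(sub$records$stem_age, orig)
  # truncation above the root age is the identity
  all_in <- subset_by_age(ds, max(node_heights <- ds$records$stem_age) + 1e3)
  expect_equal(nrow(all_in$records), nrow(ds$records))
  expect_error(subset_by_age(ds, 1e-9), "no clades")
})
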