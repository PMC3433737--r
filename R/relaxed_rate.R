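#' Log-likelihood of clade richness under a net rate and relative extinction
#'
#' Survival-conditioned progeny log-probability of observing \code{n} species
#' after time \code{t} for a clade with net diversification rate \code{r} and
#' relative extinction fraction \code{epsilon}, i.e. speciation
#' \code{lambda = r/(1 - epsilon)} and extinction \code{mu = epsilon*lambda}.
#' Vectorised over clades (recycling scalar \code{r}).
#'
#' @param n Richness values (integers >= 1).
#' @param t Stem ages (> 0), same length as \code{n}.
#' @param r Net diversification rate(s) (> 0), length 1 or \code{length(n)}.
#' @param epsilon Relative extinction in [0, 1).
#' @return Vector of log-probabilities.
#' @export
richness_loglik <- function(n, t, r, epsilon = 0) {
  stopifnot(all(n >= 1), all(n == floor(n)), all(t > 0), all(r > 0),
            epsilon >= 0, epsilon < 1)
  if (length(r) == 1L) r <- rep(r, length(n))
  stopifnot(length(r) == length(n), length(t) == length(n))
  lambda <- r / (1 - epsilon)
  ## b_t per clade; scalar-rate vectorisation of bd_ab over (lambda_i, t_i)
  rt <- r * t
  b <- numeric(length(n))
  bal <- abs(rt) < 1e-8
  if (any(bal)) b[bal] <- lambda[bal] * t[bal] / (1 + lambda[bal] * t[bal])
  if (any(!bal)) {
    em1 <- expm1(rt[!bal])
    b[!bal] <- lambda[!bal] * em1 / (lambda[!bal] * em1 + r[!bal])
  }
  ifelse(b > 0, log1p(-b) + (n - 1) * log(b), ifelse(n == 1, 0, -Inf))
}

ess_acf <- function(x, max_lag = min(200L, length(x) - 1L)) {
  n <- length(x)
  if (stats::sd(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  ## initial positive sequence truncation
  cut <- which(rho < 0)[1]
  if (!is.na(cut)) rho <- rho[seq_len(cut - 1)]
  n / (1 + 2 * sum(rho))
}

split_rhat <- function(chains) {
  ## chains: list of numeric vectors of equal length
  half <- lapply(chains, function(x) {
    m <- floor(length(x) / 2)
    list(x[seq_len(m)], x[m + seq_len(m)])
  })
  segs <- unlist(half, recursive = FALSE)
  mlen <- min(lengths(segs))
  segs <- lapply(segs, function(x) x[seq_len(mlen)])
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, stats::var, numeric(1))
  W <- mean(vars)
  B <- mlen * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((mlen - 1) / mlen * W + B / mlen) / W)
}

#' MCMC for the hierarchical lognormal relaxed-rate model
#'
#' Clade net diversification rates are modelled as draws from an
#' uncorrelated lognormal distribution with hyperparameters \code{m} (mean of
#' log rate) and \code{s} (SD of log rate, > 0); each clade's richness enters
#' through \code{\link{richness_loglik}} at the fixed relative extinction
#' \code{epsilon}. Sampling is Metropolis-within-Gibbs: \code{m} has a
#' conjugate normal update, \code{s} a random-walk update on the log scale
#' under a half-Cauchy prior, and the clade log-rates independent vectorised
#' random-walk updates. Proposal scales adapt during burn-in and are frozen
#' afterward so the retained chain is Markovian.
#'
#' @param dataset A \code{\link{clade_dataset}}.
#' @param epsilon Fixed relative extinction fraction in [0, 1).
#' @param n_iter Iterations per chain (default 50000).
#' @param n_chains Number of chains (default 4).
#' @param burnin Burn-in iterations (default half).
#' @param thin Thinning interval (default 10).
#' @param seed Integer seed.
#' @param priors List with \code{m_mean}, \code{m_sd} (normal prior on
#'   \code{m}) and \code{s_scale} (half-Cauchy scale for \code{s}).
#' @return An object of class \code{"posterior_sample"}: retained draws of
#'   \code{m}, \code{s} and the clade rates per chain, log-posterior values,
#'   acceptance rates, effective sample sizes and split-Rhat for the
#'   hyperparameters, and the \code{epsilon} used.
#' @export
run_mcmc <- function(dataset, epsilon = 0, n_iter = 50000L, n_chains = 4L,
                     burnin = floor(n_iter / 2), thin = 10L, seed = 1L,
                     priors = list(m_mean = 0, m_sd = 10, s_scale = 1)) {
  stopifnot(inherits(dataset, "clade_dataset"), n_iter > burnin)
  n <- dataset$records$richness
  t <- dataset$records$stem_age
  nc <- length(n)
  loglik_x <- function(x) richness_loglik(n, t, exp(x), epsilon)
  log_prior_s <- function(s) stats::dcauchy(s, 0, priors$s_scale, log = TRUE) + log(2)

  chains <- vector("list", n_chains)
  set.seed(seed)
  chain_seeds <- sample.int(2^30, n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    ## data-informed start, jittered per chain
    x <- log(pmax(log(pmax(n, 2)) / t, 1e-6)) + stats::rnorm(nc, 0, 0.1)
    m <- mean(x) + stats::rnorm(1, 0, 0.2)
    s <- max(stats::sd(x), 0.2) * exp(stats::rnorm(1, 0, 0.1))
    ll <- loglik_x(x)
    step_x <- rep(0.5, nc); step_s <- 0.3
    acc_x <- numeric(nc); acc_s <- 0; n_s_prop <- 0
    keep <- seq(burnin + thin, n_iter, by = thin)
    out <- matrix(NA_real_, length(keep), 2 + nc)
    lp_out <- numeric(length(keep))
    ki <- 1L
    for (it in seq_len(n_iter)) {
      ## m | x, s : conjugate normal
      prec <- nc / s^2 + 1 / priors$m_sd^2
      mu <- (sum(x) / s^2 + priors$m_mean / priors$m_sd^2) / prec
      m <- stats::rnorm(1, mu, sqrt(1 / prec))
      ## s : random walk on log s
      s_prop <- s * exp(stats::rnorm(1, 0, step_s))
      lr <- sum(stats::dnorm(x, m, s_prop, log = TRUE)) -
            sum(stats::dnorm(x, m, s, log = TRUE)) +
            log_prior_s(s_prop) - log_prior_s(s) + log(s_prop) - log(s)
      n_s_prop <- n_s_prop + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) { s <- s_prop; acc_s <- acc_s + 1 }
      ## clade log-rates: vectorised componentwise random walk
      x_prop <- x + stats::rnorm(nc, 0, step_x)
      ll_prop <- loglik_x(x_prop)
      lr_x <- ll_prop - ll +
        stats::dnorm(x_prop, m, s, log = TRUE) - stats::dnorm(x, m, s, log = TRUE)
      acc <- is.finite(lr_x) & log(stats::runif(nc)) < lr_x
      x[acc] <- x_prop[acc]; ll[acc] <- ll_prop[acc]
      acc_x <- acc_x + acc
      ## adapt during burn-in only
      if (it <= burnin && it %% 100 == 0) {
        rate_x <- acc_x / 100
        step_x <- step_x * exp(0.3 * (rate_x - 0.35))
        step_s <- step_s * exp(0.3 * (acc_s / n_s_prop - 0.35))
        acc_x[] <- 0; acc_s <- 0; n_s_prop <- 0
      }
      if (ki <= length(keep) && it == keep[ki]) {
        lp <- sum(ll) + sum(stats::dnorm(x, m, s, log = TRUE)) +
          stats::dnorm(m, priors$m_mean, priors$m_sd, log = TRUE) +
          log_prior_s(s)
        if (!is.finite(lp)) stop("divergent chain: non-finite log-posterior; state: m=",
                                 m, " s=", s)
        out[ki, ] <- c(m, s, x)
        lp_out[ki] <- lp
        ki <- ki + 1L
      }
    }
    colnames(out) <- c("m", "s", paste0("log_r_", seq_len(nc)))
    chains[[ch]] <- list(draws = out, log_posterior = lp_out,
                         acc_rate_x = mean(acc_x) / max(n_iter - burnin, 1),
                         acc_rate_s = if (n_s_prop > 0) acc_s / n_s_prop else NA)
  }
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  structure(list(draws = draws, chains = chains, epsilon = epsilon,
                 n_clades = nc,
                 ess = c(m = ess_acf(draws[, "m"]), s = ess_acf(draws[, "s"])),
                 rhat = c(m = split_rhat(lapply(chains, function(c) c$draws[, "m"])),
                          s = split_rhat(lapply(chains, function(c) c$draws[, "s"]))),
                 settings = list(n_iter = n_iter, n_chains = n_chains,
                                 burnin = burnin, thin = thin, seed = seed,
                                 priors = priors)),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  qm <- stats::quantile(x$draws[, "m"], c(0.025, 0.5, 0.975))
  qs <- stats::quantile(x$draws[, "s"], c(0.025, 0.5, 0.975))
  cat(sprintf("relaxed-rate posterior (epsilon = %g, %d retained draws, %d clades)\n",
              x$epsilon, nrow(x$draws), x$n_clades))
  cat(sprintf("  m: %.3f [%.3f, %.3f]  (ESS %.0f, Rhat %.3f)\n",
              qm[2], qm[1], qm[3], x$ess["m"], x$rhat["m"]))
  cat(sprintf("  s: %.3f [%.3f, %.3f]  (ESS %.0f, Rhat %.3f)\n",
              qs[2], qs[1], qs[3], x$ess["s"], x$rhat["s"]))
  invisible(x)
}

#' Posterior-predictive simulation of clade richness
#'
#' For each draw: sample a retained posterior state, draw fresh clade rates
#' from LogNormal(m, s) (the hierarchical variant; set
#' \code{conditional = TRUE} to reuse the fitted clade rates instead), and
#' simulate each clade's richness by a survival-conditioned progeny draw at
#' its observed stem age. The backbone tree is held fixed.
#'
#' @param dataset The observed \code{\link{clade_dataset}}.
#' @param posterior A \code{"posterior_sample"} from \code{\link{run_mcmc}}.
#' @param n_draws Number of simulated richness vectors.
#' @param conditional Reuse fitted clade rates instead of resampling from
#'   the hyperdistribution?
#' @return Matrix (\code{n_draws} x clades) of simulated richness, columns
#'   named by clade.
#' @export
posterior_predictive <- function(dataset, posterior, n_draws = 1000L,
                                 conditional = FALSE) {
  stopifnot(inherits(posterior, "posterior_sample"))
  t <- dataset$records$stem_age
  nc <- length(t)
  eps <- posterior$epsilon
  idx <- sample.int(nrow(posterior$draws), n_draws, replace = TRUE)
  out <- matrix(NA_real_, n_draws, nc,
                dimnames = list(NULL, dataset$records$name))
  for (d in seq_len(n_draws)) {
    st <- posterior$draws[idx[d], ]
    r <- if (conditional) exp(st[-(1:2)])
         else stats::rlnorm(nc, meanlog = st["m"], sdlog = st["s"])
    lambda <- r / (1 - eps)
    for (i in seq_len(nc))
      out[d, i] <- sample_progeny(bd_params(lambda[i], eps * lambda[i]),
                                  t[i], conditioned = TRUE)
  }
  out
}

#' Standardized effect size of the observed age-richness slope
#'
#' Fits the PGLS slope of log-richness on stem age for each simulated
#' richness vector (fixed backbone tree) and scores the observed slope as
#' SES = (beta_obs - mean(beta_sim)) / sd(beta_sim). Negative SES means the
#' observed age-richness coupling is weaker than the model predicts. Both
#' the empirical tail probability (fraction of simulated slopes <= observed)
#' and its normal approximation are reported.
#'
#' @param dataset The observed \code{\link{clade_dataset}}.
#' @param simulated Matrix of simulated richness vectors (rows = datasets,
#'   columns matching the clades), e.g. from
#'   \code{\link{posterior_predictive}}; at least 100 rows.
#' @param beta_obs Observed slope; computed from \code{dataset} by PGLS when
#'   omitted.
#' @param log_base Base of the richness logarithm.
#' @return An object of class \code{"ses_result"} with \code{beta_obs},
#'   \code{beta_sim_mean}, \code{beta_sim_sd}, \code{ses},
#'   \code{tail_probability} (empirical) and \code{tail_probability_normal}.
#' @export
standardized_effect_size <- function(dataset, simulated, beta_obs = NULL,
                                     log_base = exp(1)) {
  stopifnot(inherits(dataset, "clade_dataset"))
  if (nrow(simulated) < 100)
    stop("need at least 100 simulated datasets for a stable SES")
  if (is.null(beta_obs))
    beta_obs <- pgls_fit(dataset, covariance = "BM", log_base = log_base)$beta
  Y <- log(simulated[, dataset$records$name, drop = FALSE], base = log_base)
  colnames(Y) <- dataset$records$name
  fits <- batch_age_regressions(dataset$tree, Y)
  mu <- mean(fits$pgls_slope); sdv <- stats::sd(fits$pgls_slope)
  if (sdv == 0) stop("simulated slopes are degenerate (sd = 0)")
  ses <- (beta_obs - mu) / sdv
  structure(list(beta_obs = beta_obs, beta_sim_mean = mu, beta_sim_sd = sdv,
                 ses = ses,
                 tail_probability = mean(fits$pgls_slope <= beta_obs),
                 tail_probability_normal = stats::pnorm(ses),
                 n_sims = nrow(simulated)),
            class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  cat(sprintf("SES = %.3f (beta_obs = %.4g vs simulated %.4g +- %.3g; empirical tail p = %.3g, normal %.3g)\n",
              x$ses, x$beta_obs, x$beta_sim_mean, x$beta_sim_sd,
              x$tail_probability, x$tail_probability_normal))
  invisible(x)
}
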