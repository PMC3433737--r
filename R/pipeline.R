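#' Pipeline run configuration
#'
#' Bundles all inputs and stage settings of the full analysis: data
#' reconciliation, age-richness regression and signal tests, truncation
#' subsets, subtree scan, stepwise rate-shift fit, higher-taxon simulator
#' null, relaxed-rate posterior SES, and the two robustness studies. A single
#' global seed spawns deterministic per-stage child seeds, which are recorded
#' in every output.
#'
#' @param tree_file Newick timetree path.
#' @param richness_file Richness TSV path.
#' @param missing_file Optional TSV of lineages absent from the richness
#'   table whose species counts must be reassigned during reconciliation
#'   (columns \code{name}, \code{richness}, optional \code{attach_to}).
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @param log_base Base for log-richness.
#' @param covariance PGLS covariance model.
#' @param min_tips,alpha Subtree-scan settings.
#' @param truncation_ages Ages (My) for young-clade subsets.
#' @param medusa_threshold \code{\link{threshold_params}} or a number.
#' @param max_shifts Cap on accepted shifts.
#' @param n_null Accepted simulations for the taxon-model null.
#' @param mcmc List of \code{\link{run_mcmc}} settings
#'   (\code{n_iter}, \code{n_chains}, \code{thin}).
#' @param n_predictive Posterior-predictive draws for the SES.
#' @param epsilons Relative extinction values for the relaxed-rate fits.
#' @param n_signal_sims,n_age_error_sims Robustness-study sizes.
#' @param age_error_deltas Error grid for the age-error study.
#' @param resume Reuse stage outputs already present in \code{out_dir}?
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(tree_file, richness_file, missing_file = NULL,
                       out_dir = "agediv_out", seed = 1L, log_base = exp(1), covariance = "BM",
                       min_tips = 10, alpha = 0.05,
                       truncation_ages = c(50, 100, 150, 200, 250),
                       medusa_threshold = threshold_params(),
                       max_shifts = 10,
                       n_null = 200L,
                       mcmc = list(n_iter = 6000L, n_chains = 2L, thin = 5L),
                       n_predictive = 200L, epsilons = c(0, 0.99),
                       n_signal_sims = 500L, n_age_error_sims = 200L,
                       age_error_deltas = seq(0.1, 0.6, by = 0.1),
                       resume = TRUE) {
  for (f in c(tree_file, richness_file, missing_file))
    if (!file.exists(f)) stop("input file not found: ", f)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are \code{\link{run_config}} arguments.
#' @return A \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$medusa_threshold) && is.list(y$medusa_threshold))
    y$medusa_threshold <- do.call(threshold_params, y$medusa_threshold)
  do.call(run_config, y)
}

stage_path <- function(config, stage) file.path(config$out_dir,
                                                paste0(stage, ".json"))

run_stage <- function(config, stage, fun) {
  path <- stage_path(config, stage)
  if (config$resume && file.exists(path)) {
    message("[", stage, "] cached")
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  t0 <- Sys.time()
  set.seed(spawn_seed(config$seed, stage))
  res <- fun()
  res$seed <- spawn_seed(config$seed, stage)
  write_json(res, path)
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full age-richness analysis pipeline
#'
#' Orchestrates: data reconciliation; PGLS of log-richness on stem age with
#' Pagel's-lambda signal estimation, contrasts test, truncation subsets and
#' subtree scan; the stepwise rate-shift fit; the higher-taxon simulator
#' null distribution of Spearman correlations; the relaxed-rate posterior
#' SES at each relative extinction value; and the signal and age-error
#' robustness studies. Per-stage JSON/TSV outputs land in
#' \code{config$out_dir}; with \code{resume = TRUE} stages found there are
#' not recomputed. Deterministic given the global seed.
#'
#' @param config A \code{\link{run_config}}.
#' @return List of per-stage summaries (also written as
#'   \code{summary.json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tree <- read_timetree(config$tree_file)
  records <- load_richness(config$richness_file)
  missing <- if (!is.null(config$missing_file))
    load_richness(config$missing_file) else NULL
  rec <- reconcile(tree, records, missing = missing, tie_break = "first")
  ds <- rec$dataset
  lb <- config$log_base

  data_stage <- run_stage(config, "data", function() {
    s <- summarize_clades(ds)
    list(n_clades = s$n_clades, total_species = s$total_species,
         age_range = s$age_range, pruned = rec$report$pruned,
         flagged = rec$report$flagged)
  })

  regression <- run_stage(config, "regression", function() {
    fit <- pgls_fit(ds, covariance = config$covariance, log_base = lb)
    sig <- estimate_lambda(ds, log_base = lb)
    ctr <- contrasts_signal_test(ds, mode = "analytic", log_base = lb)
    trunc <- lapply(config$truncation_ages, function(a) {
      sub <- tryCatch(subset_by_age(ds, a), error = function(e) NULL)
      if (is.null(sub) || nrow(sub$records) < 3) return(NULL)
      f <- pgls_fit(sub, covariance = config$covariance, log_base = lb)
      list(max_age = a, n = f$n, beta = f$beta, p = f$p_value)
    })
    list(beta = fit$beta, t = fit$t_statistic, p = fit$p_value, df = fit$df,
         log_base = lb, Lambda_ml = sig$Lambda_ml, delta_aic = sig$delta_aic,
         contrasts_p = ctr$p_value,
         truncation = Filter(Negate(is.null), trunc))
  })

  scan <- run_stage(config, "scan", function() {
    sc <- scan_subtrees(ds, min_tips = config$min_tips, alpha = config$alpha,
                        covariance = config$covariance, log_base = lb)
    write_tsv(sc$table, file.path(config$out_dir, "subtree_scan.tsv"))
    list(n_subtrees = sc$n_subtrees,
         n_significant_positive = sc$n_significant_positive,
         n_significant_negative = sc$n_significant_negative)
  })

  medusa <- stepwise_fit(ds, threshold = config$medusa_threshold,
                         max_shifts = config$max_shifts)
  medusa_stage <- run_stage(config, "medusa", function() {
    write_medusa_result(medusa, ds,
                        json_path = file.path(config$out_dir, "medusa_full.json"),
                        tsv_path = file.path(config$out_dir, "medusa_summary.tsv"))
    list(n_shifts = medusa$n_shifts, np = medusa$np,
         aicc_single = medusa$aicc_single, aicc_best = medusa$aicc_best)
  })

  null_stage <- run_stage(config, "taxon_null", function() {
    cfg <- sim_config_from_medusa(medusa, ds,
                                  n_accepted_target = config$n_null)
    nd <- build_null(cfg, observed = ds)
    utils::write.table(data.frame(rho = nd$rho),
                       file.path(config$out_dir, "null_rho.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(mean_rho = mean(nd$rho), observed_rho = nd$observed_rho,
         p_lower = nd$p_lower, acceptance_rate = nd$acceptance_rate)
  })

  ses_stage <- run_stage(config, "relaxed_rate", function() {
    res <- lapply(config$epsilons, function(eps) {
      post <- run_mcmc(ds, epsilon = eps, n_iter = config$mcmc$n_iter,
                       n_chains = config$mcmc$n_chains,
                       thin = config$mcmc$thin,
                       seed = spawn_seed(config$seed, paste0("mcmc", eps)))
      sims <- posterior_predictive(ds, post, n_draws = config$n_predictive)
      ses <- standardized_effect_size(ds, sims, log_base = lb)
      list(epsilon = eps, m = mean(post$draws[, "m"]),
           s = mean(post$draws[, "s"]), rhat_m = unname(post$rhat["m"]),
           ses = ses$ses, tail_probability = ses$tail_probability)
    })
    list(fits = res)
  })

  robustness <- run_stage(config, "robustness", function() {
    sig <- estimate_lambda(ds, log_base = lb)
    t1 <- type1_error_study(ds$tree, Lambda = sig$Lambda_ml,
                            root_state = sig$bm_root_state,
                            rate = sig$bm_variance_rate,
                            n_datasets = config$n_signal_sims,
                            alpha = config$alpha)
    bd <- fit_constant_rate_ml(ds)
    ae <- age_error_study(ds$records$stem_age, bd$params,
                          delta_grid = config$age_error_deltas,
                          n_sims = config$n_age_error_sims)
    write_tsv(ae$summary, file.path(config$out_dir, "age_error.tsv"))
    list(ols_type1 = t1$ols_rate, pgls_type1 = t1$pgls_rate,
         bd_lambda = bd$params$lambda, bd_mu = bd$params$mu,
         age_error = ae$summary)
  })

  summary <- list(data = data_stage, regression = regression, scan = scan,
                  medusa = medusa_stage, taxon_null = null_stage,
                  relaxed_rate = ses_stage, robustness = robustness,
                  seed = config$seed)
  write_json(summary, file.path(config$out_dir, "summary.json"))
  invisible(summary)
}
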