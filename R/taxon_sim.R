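#' Configuration of the two-state higher-taxon birth-death simulator
#'
#' The simulator evolves two unit types forward in time from a crown start of
#' two lineages: individual lineages, which speciate (rate lambda), go
#' extinct (rate mu), irreversibly convert into higher taxa (rate phi) and
#' undergo diversification rate shifts (rate alpha, new rates resampled with
#' replacement from the pool); and higher taxa, which after formation
#' accumulate species under their inherited (lambda, mu) until the present
#' and may go extinct. By default phi tracks the current speciation rate,
#' which keeps the number of backbone speciation events and taxon formation
#' events roughly balanced; after a rate shift phi follows the new lambda.
#'
#' @param crown_age Crown age T_c in My (> 0); simulations start with two
#'   lineages and run to the present.
#' @param rate_class_pool List of \code{\link{bd_params}} (e.g. the fitted
#'   classes of a stepwise shift model).
#' @param alpha Rate-shift rate per lineage per My.
#' @param phi \code{"speciation"} (default: taxon formation rate equals the
#'   current lambda) or a fixed numeric rate.
#' @param observed_n_terminals Terminal count of the empirical dataset that
#'   the rejection bounds refer to.
#' @param reject_low,reject_high Acceptance bounds on the simulated terminal
#'   count as fractions of \code{observed_n_terminals} (defaults 0.5, 1.5).
#' @param n_accepted_target Accepted simulations per null distribution.
#' @param drop_unconverted Drop lineages that reach the present without
#'   forming a higher taxon? Default keeps them as terminals with richness 1.
#' @param seed Optional integer seed applied by
#'   \code{\link{simulate_higher_taxon_tree}}.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(crown_age, rate_class_pool, alpha = 0,
                       phi = "speciation", observed_n_terminals,
                       reject_low = 0.5, reject_high = 1.5,
                       n_accepted_target = 5000L, drop_unconverted = FALSE,
                       seed = NULL) {
  stopifnot(crown_age > 0, length(rate_class_pool) >= 1,
            all(vapply(rate_class_pool, inherits, logical(1), "bd_params")),
            alpha >= 0, reject_low > 0, reject_low < 1, reject_high > 1,
            observed_n_terminals >= 2)
  structure(list(crown_age = crown_age, rate_class_pool = rate_class_pool,
                 alpha = alpha, phi = phi,
                 observed_n_terminals = as.integer(observed_n_terminals),
                 reject_low = reject_low, reject_high = reject_high,
                 n_accepted_target = as.integer(n_accepted_target),
                 drop_unconverted = drop_unconverted, seed = seed),
            class = "sim_config")
}

#' Derive a simulator configuration from a fitted shift model
#'
#' Sets the rate-class pool to the fitted classes, the shift rate to its
#' Poisson ML estimate on the internal branches, the crown age to the root
#' age of the observed backbone, and the terminal-count bounds to the
#' observed number of clades.
#'
#' @param medusa A \code{"medusa_result"} from \code{\link{stepwise_fit}}.
#' @param dataset The \code{\link{clade_dataset}} the model was fitted to.
#' @param ... Further arguments to \code{\link{sim_config}}.
#' @return A \code{\link{sim_config}}.
#' @export
sim_config_from_medusa <- function(medusa, dataset, ...) {
  sim_config(crown_age = max(node_ages(dataset$tree)),
             rate_class_pool = medusa$classes,
             alpha = shift_rate_mle(dataset$tree, medusa$n_shifts),
             observed_n_terminals = nrow(dataset$records), ...)
}

#' Simulate one higher-taxon dataset under the two-state process
#'
#' Gillespie simulation over the current lineage set: per lineage the waiting
#' time to the next event is exponential with total rate
#' beta = lambda + mu + phi + alpha, and the event identity is sampled
#' proportional to the component rates (e.g. taxon formation with
#' probability phi/beta). A taxon formed at time T1 inherits its parent
#' lineage's rates and its present-day richness is an unconditioned progeny
#' draw over T_c - T1, so taxa can go extinct before the present. Simulations
#' whose terminal count falls outside the rejection bounds (or that exceed
#' ten times the upper bound while running) are rejected.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An object of class \code{"sim_rejection"} (carrying the reason)
#'   on rejection, else a list with \code{dataset} (reconstructed backbone
#'   \code{\link{clade_dataset}} over surviving terminals, stem ages read
#'   from the pruned tree), \code{states} (\code{"higher_taxon"} or
#'   \code{"lineage"} per terminal) and \code{formation_times} (true T1,
#'   hidden from inference).
#' @export
simulate_higher_taxon_tree <- function(config) {
  ## rejection sentinel defined below

  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  Tc <- config$crown_age
  pool_l <- vapply(config$rate_class_pool, `[[`, numeric(1), "lambda")
  pool_m <- vapply(config$rate_class_pool, `[[`, numeric(1), "mu")
  npool <- length(pool_l)
  alpha <- config$alpha
  phi_fixed <- if (is.numeric(config$phi)) config$phi else NULL
  hard_cap <- ceiling(10 * config$reject_high * config$observed_n_terminals)

  cap <- 512L
  parent <- integer(cap); t_birth <- numeric(cap); t_end <- numeric(cap)
  alive <- logical(cap); cls <- integer(cap)
  state <- character(cap)                 # "lineage" | "higher_taxon" | "dead"
  t_form <- rep(NA_real_, cap); rich <- rep(NA_real_, cap)
  grow <- function(n_need) {
    while (n_need > cap) {
      parent <<- c(parent, integer(cap)); t_birth <<- c(t_birth, numeric(cap))
      t_end <<- c(t_end, numeric(cap)); alive <<- c(alive, logical(cap))
      cls <<- c(cls, integer(cap)); state <<- c(state, character(cap))
      t_form <<- c(t_form, rep(NA_real_, cap)); rich <<- c(rich, rep(NA_real_, cap))
      cap <<- 2L * cap
    }
  }
  k0 <- sample.int(npool, 1L)
  n_lin <- 2L
  parent[1:2] <- 0L; t_birth[1:2] <- 0; cls[1:2] <- k0
  state[1:2] <- "lineage"
  active <- c(1L, 2L)
  n_taxa <- 0L
  t <- 0
  repeat {
    if (!length(active)) break
    li <- pool_l[cls[active]]; mi <- pool_m[cls[active]]
    pi <- if (is.null(phi_fixed)) li else rep(phi_fixed, length(active))
    beta <- li + mi + pi + alpha
    R <- sum(beta)
    if (R <= 0) break
    t <- t + stats::rexp(1, R)
    if (t >= Tc) break
    pick <- if (length(active) == 1L) 1L else
      sample.int(length(active), 1L, prob = beta)
    i <- active[pick]
    ev <- sample.int(4L, 1L, prob = c(li[pick], mi[pick], pi[pick], alpha))
    if (ev == 1L) {                       # speciation
      grow(n_lin + 2L)
      id1 <- n_lin + 1L; id2 <- n_lin + 2L
      parent[c(id1, id2)] <- i; t_birth[c(id1, id2)] <- t
      cls[c(id1, id2)] <- cls[i]; state[c(id1, id2)] <- "lineage"
      t_end[i] <- t; state[i] <- "lineage"; alive[i] <- FALSE
      n_lin <- n_lin + 2L
      active <- c(active[-pick], id1, id2)
    } else if (ev == 2L) {                # extinction
      t_end[i] <- t; state[i] <- "dead"; alive[i] <- FALSE
      active <- active[-pick]
    } else if (ev == 3L) {                # higher taxon formation
      t_form[i] <- t
      p <- bd_params(pool_l[cls[i]], pool_m[cls[i]])
      rich[i] <- sample_progeny(p, Tc - t, conditioned = FALSE)
      if (rich[i] >= 1) {
        state[i] <- "higher_taxon"; alive[i] <- TRUE; t_end[i] <- Tc
        n_taxa <- n_taxa + 1L
      } else {
        state[i] <- "dead"; alive[i] <- FALSE; t_end[i] <- t
      }
      active <- active[-pick]
    } else {                              # rate shift
      cls[i] <- sample.int(npool, 1L)
    }
    if (n_taxa + length(active) > hard_cap)
      return(sim_rejection("runaway"))
  }
  ## lineages reaching the present without converting
  if (length(active)) {
    t_end[active] <- Tc; alive[active] <- TRUE
    rich[active] <- 1
  }
  if (config$drop_unconverted && length(active)) {
    alive[active] <- FALSE
    state[active] <- "dead"
  }
  term <- which(alive[seq_len(n_lin)])
  n_term <- length(term)
  lo <- ceiling(config$reject_low * config$observed_n_terminals)
  hi <- floor(config$reject_high * config$observed_n_terminals)
  if (n_term < max(lo, 3L) || n_term > hi)
    return(sim_rejection(sprintf("terminal count %d outside [%d, %d]",
                                 n_term, lo, hi)))
  label <- rep(NA_character_, n_lin)
  label[term] <- paste0("u", seq_len(n_term))
  lin <- data.frame(id = seq_len(n_lin), parent = parent[seq_len(n_lin)],
                    t_birth = t_birth[seq_len(n_lin)],
                    t_end = t_end[seq_len(n_lin)],
                    alive = alive[seq_len(n_lin)],
                    label = label[seq_len(n_lin)], stringsAsFactors = FALSE)
  tree <- lineages_to_phylo(lin, present = Tc)
  if (is.null(tree)) return(sim_rejection("fewer than 2 surviving terminals"))
  ds <- clade_dataset(tree, data.frame(name = label[term],
                                       richness = rich[term],
                                       stringsAsFactors = FALSE))
  ord <- match(ds$records$name, label[term])
  list(dataset = ds,
       states = stats::setNames(state[term][ord], ds$records$name),
       formation_times = stats::setNames(t_form[term][ord], ds$records$name),
       n_terminals = n_term)
}

#' Spearman rank correlation between clade age and richness
#'
#' Rank correlation with average ranks for ties. Constant input yields an
#' undefined correlation, returned as \code{NaN} with a warning.
#'
#' @param ages,richness Equal-length numeric vectors (length >= 3).
#' @return Spearman's rho in [-1, 1], or \code{NaN}.
#' @export
spearman_rho <- function(ages, richness) {
  stopifnot(length(ages) == length(richness), length(ages) >= 3)
  if (stats::sd(ages) == 0 || stats::sd(richness) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NaN)
  }
  stats::cor(ages, richness, method = "spearman")
}

#' Null distribution of age-richness rank correlations under the taxon model
#'
#' Runs the two-state simulator until \code{n_accepted} datasets pass the
#' terminal-count bounds, records the Spearman correlation between
#' reconstructed stem age and richness for each, and scores an observed
#' correlation against the distribution with a one-tailed lower p-value
#' (pseudocount +1): small p means the observed age-richness coupling is
#' weaker than the model predicts.
#'
#' @param config A \code{\link{sim_config}}.
#' @param observed Optional \code{\link{clade_dataset}} (or a single numeric
#'   rho) providing the observed correlation.
#' @param n_accepted Number of accepted simulations (defaults to the
#'   config's target).
#' @param min_acceptance Abort if the running acceptance rate drops below
#'   this after 200 attempts.
#' @return An object of class \code{"null_distribution"}: \code{rho} vector,
#'   \code{acceptance_rate}, \code{observed_rho}, \code{p_lower},
#'   \code{mean_terminals}.
#' @export
build_null <- function(config, observed = NULL, n_accepted = NULL,
                       min_acceptance = 1e-4) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) { set.seed(config$seed); config$seed <- NULL }
  if (is.null(n_accepted)) n_accepted <- config$n_accepted_target
  rho <- numeric(n_accepted); nterm <- integer(n_accepted)
  acc <- 0L; att <- 0L
  while (acc < n_accepted) {
    att <- att + 1L
    if (att > 200 && acc / att < min_acceptance)
      stop(sprintf("acceptance rate %.2g below %g after %d attempts; widen the bounds or revisit the rate pool",
                   acc / att, min_acceptance, att))
    sim <- simulate_higher_taxon_tree(config)
    if (inherits(sim, "sim_rejection")) next
    acc <- acc + 1L
    rho[acc] <- spearman_rho(sim$dataset$records$stem_age,
                             sim$dataset$records$richness)
    nterm[acc] <- sim$n_terminals
  }
  obs_rho <- if (is.null(observed)) NA_real_
             else if (is.numeric(observed)) observed
             else spearman_rho(observed$records$stem_age,
                               observed$records$richness)
  p_lower <- if (is.na(obs_rho)) NA_real_
             else (1 + sum(rho <= obs_rho)) / (1 + n_accepted)
  structure(list(rho = rho, acceptance_rate = acc / att,
                 observed_rho = obs_rho, p_lower = p_lower,
                 mean_terminals = mean(nterm), n_accepted = n_accepted),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null distribution of %d Spearman rho values (mean %.3f, acceptance %.2f)\n",
              x$n_accepted, mean(x$rho), x$acceptance_rate))
  if (!is.na(x$observed_rho))
    cat(sprintf("  observed rho = %.3f, one-tailed lower p = %.4g\n",
                x$observed_rho, x$p_lower))
  invisible(x)
}

## rejection sentinel returned by the simulator
sim_rejection <- function(reason) {
  structure(list(reason = reason), class = "sim_rejection")
}

#' @export
print.sim_rejection <- function(x, ...) {
  cat("rejected simulation:", x$reason, "\n")
  invisible(x)
}
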