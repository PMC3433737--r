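#' Specification for synthetic age-richness datasets
#'
#' Describes how to generate an ultrametric backbone timetree of higher taxa
#' together with tip richness values, with known ground truth, so that every
#' analysis stage can be exercised without an empirical timetree.
#'
#' Richness models:
#' \describe{
#'   \item{constant_rate}{every clade diversifies at the same (lambda, mu);
#'     richness is a survival-conditioned progeny draw at the clade's stem
#'     age, so age predicts richness.}
#'   \item{lognormal_relaxed}{clade net rates are drawn from
#'     LogNormal(m, s) at relative extinction \code{epsilon}, then richness
#'     is a conditioned progeny draw.}
#'   \item{bm_signal_only}{log-richness evolves by Brownian motion on the
#'     Pagel's-lambda transform of the tree: values carry phylogenetic signal
#'     but are independent of clade age by construction.}
#'   \item{higher_taxon_process}{delegated to
#'     \code{\link{simulate_higher_taxon_tree}} with the supplied config.}
#' }
#'
#' Presets: \code{preset = "bm_signal"} sets a signal-only model with
#' Lambda = 0.724, root state 3 and rate 0.02 (a strong-signal regime typical
#' of log-richness across higher taxa); \code{preset = "angiosperm_bd"} sets
#' a constant-rate model with lambda = 0.71, mu = 0.64 (rates of the scale
#' estimated for large angiosperm radiations).
#'
#' @param n_tips Number of terminal clades (>= 4).
#' @param backbone \code{"yule"}, \code{"birth_death"}, or
#'   \code{"yule_shift"} (pure birth with Poisson rate shifts along
#'   lineages, producing the clade-wise branching-rate heterogeneity --
#'   young dense radiations next to old depauperate lineages -- typical of
#'   empirical higher-level timetrees).
#' @param backbone_lambda,backbone_mu Backbone branching rates per My.
#' @param backbone_shift_rate Per-lineage rate of branching-rate shifts
#'   (\code{"yule_shift"} only).
#' @param backbone_multipliers Pool of multipliers applied to
#'   \code{backbone_lambda} at a shift (\code{"yule_shift"} only).
#' @param crown_age Optional: rescale the backbone so the root has this age
#'   (My). Default keeps the simulated depth.
#' @param richness_model One of \code{"constant_rate"},
#'   \code{"lognormal_relaxed"}, \code{"bm_signal_only"},
#'   \code{"higher_taxon_process"}.
#' @param model_params Named list of parameters for the richness model
#'   (\code{lambda}, \code{mu}; or \code{m}, \code{s}, \code{epsilon}; or
#'   \code{Lambda}, \code{root_state}, \code{rate}; or \code{config}).
#' @param preset Optional preset name (see Details).
#' @param seed Integer seed; every generated artefact is reproducible from it.
#' @return An object of class \code{"generator_spec"}.
#' @export
generator_spec <- function(n_tips = 100,
                           backbone = c("yule", "birth_death", "yule_shift"),
                           backbone_lambda = 0.1, backbone_mu = 0,
                           backbone_shift_rate = 0.002,
                           backbone_multipliers = c(0.2, 1, 5, 10),
                           crown_age = NULL,
                           richness_model = c("constant_rate",
                                              "lognormal_relaxed",
                                              "bm_signal_only",
                                              "higher_taxon_process"),
                           model_params = list(lambda = 0.1, mu = 0.05),
                           preset = NULL, seed = 1L) {
  backbone <- match.arg(backbone)
  richness_model <- match.arg(richness_model)
  if (!is.null(preset)) {
    if (preset == "bm_signal") {
      richness_model <- "bm_signal_only"
      model_params <- list(Lambda = 0.724, root_state = 3, rate = 0.02)
    } else if (preset == "angiosperm_bd") {
      richness_model <- "constant_rate"
      model_params <- list(lambda = 0.71, mu = 0.64)
    } else stop("unknown preset: ", preset)
  }
  stopifnot(n_tips >= 4, backbone_lambda > 0, backbone_mu >= 0)
  structure(list(n_tips = as.integer(n_tips), backbone = backbone,
                 backbone_lambda = backbone_lambda, backbone_mu = backbone_mu,
                 backbone_shift_rate = backbone_shift_rate,
                 backbone_multipliers = backbone_multipliers,
                 crown_age = crown_age, richness_model = richness_model,
                 model_params = model_params, preset = preset,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

## forward pure-birth simulation stopped after the (n-1)-th split plus a final
## Exp(n*lambda) segment; waiting time with k lineages is Exp(k*lambda)
simulate_yule_tree <- function(n_tips, lambda) {
  waits <- stats::rexp(n_tips, rate = lambda * seq_len(n_tips))
  total <- sum(waits)
  split_times <- cumsum(waits)[seq_len(n_tips - 1)]
  k_max <- 2L * n_tips - 1L
  parent <- integer(k_max); t_birth <- numeric(k_max); t_end <- numeric(k_max)
  alive <- logical(k_max)
  parent[1] <- 0L; t_birth[1] <- 0; alive[1] <- TRUE
  n_lin <- 1L
  active <- c(1L, integer(n_tips - 1L)); n_active <- 1L
  for (k in seq_len(n_tips - 1)) {
    tk <- split_times[k]
    pick <- sample.int(n_active, 1L)
    j <- active[pick]
    t_end[j] <- tk; alive[j] <- FALSE
    id1 <- n_lin + 1L; id2 <- n_lin + 2L
    parent[id1] <- j; parent[id2] <- j
    t_birth[id1] <- tk; t_birth[id2] <- tk
    alive[id1] <- TRUE; alive[id2] <- TRUE
    n_lin <- n_lin + 2L
    active[pick] <- id1
    n_active <- n_active + 1L
    active[n_active] <- id2
  }
  t_end[alive] <- total
  label <- rep(NA_character_, k_max)
  label[alive] <- paste0("t", seq_len(sum(alive)))
  lin <- data.frame(id = seq_len(n_lin), parent = parent[seq_len(n_lin)],
                    t_birth = t_birth[seq_len(n_lin)],
                    t_end = t_end[seq_len(n_lin)],
                    alive = alive[seq_len(n_lin)],
                    label = label[seq_len(n_lin)], stringsAsFactors = FALSE)
  lineages_to_phylo(lin, present = total)
}

## forward pure-birth simulation with per-lineage Poisson rate shifts,
## stopped after the (n-1)-th split; produces clades that radiated at
## different tempos, so stem age aligns with clade membership
simulate_yule_shift_tree <- function(n_tips, lambda, shift_rate,
                                     multipliers) {
  k_max <- 2L * n_tips - 1L
  parent <- integer(k_max); t_birth <- numeric(k_max); t_end <- numeric(k_max)
  alive <- logical(k_max)
  rate <- numeric(k_max)
  parent[1] <- 0L; t_birth[1] <- 0; alive[1] <- TRUE; rate[1] <- lambda
  n_lin <- 1L; n_active <- 1L
  active <- c(1L, integer(n_tips - 1L))
  t <- 0
  repeat {
    rl <- rate[active[seq_len(n_active)]]
    tot <- sum(rl) + shift_rate * n_active
    t <- t + stats::rexp(1, tot)
    if (stats::runif(1) < shift_rate * n_active / tot) {  # rate shift
      pick <- sample.int(n_active, 1L)
      j <- active[pick]
      rate[j] <- lambda * sample(multipliers, 1L)
      next
    }
    pick <- sample.int(n_active, 1L, prob = rl)           # birth
    j <- active[pick]
    t_end[j] <- t; alive[j] <- FALSE
    id1 <- n_lin + 1L; id2 <- n_lin + 2L
    parent[c(id1, id2)] <- j; t_birth[c(id1, id2)] <- t
    alive[c(id1, id2)] <- TRUE; rate[c(id1, id2)] <- rate[j]
    n_lin <- n_lin + 2L
    active[pick] <- id1
    n_active <- n_active + 1L
    active[n_active] <- id2
    if (n_active == n_tips) break
  }
  ## final segment: time to the next event among n_tips lineages
  t <- t + stats::rexp(1, sum(rate[active]) + shift_rate * n_tips)
  t_end[alive] <- t
  label <- rep(NA_character_, k_max)
  label[alive] <- paste0("t", seq_len(sum(alive)))
  lin <- data.frame(id = seq_len(n_lin), parent = parent[seq_len(n_lin)],
                    t_birth = t_birth[seq_len(n_lin)],
                    t_end = t_end[seq_len(n_lin)],
                    alive = alive[seq_len(n_lin)],
                    label = label[seq_len(n_lin)], stringsAsFactors = FALSE)
  lineages_to_phylo(lin, present = t)
}

#' Generate a synthetic ultrametric backbone timetree
#'
#' Yule backbones are simulated forward in time (waiting times are
#' exponential order statistics, giving an exact analytic reference for the
#' internode distribution); birth-death backbones use the reconstructed
#' constant-rate simulator \code{ape::rphylo} conditioned on the tip count;
#' \code{"yule_shift"} backbones add Poisson branching-rate shifts along
#' lineages, yielding the among-clade tempo heterogeneity of empirical
#' higher-level timetrees.
#'
#' @param spec A \code{\link{generator_spec}}.
#' @return An ultrametric \code{phylo} with exactly \code{spec$n_tips} tips.
#' @export
generate_timetree <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spawn_seed(spec$seed, "timetree"))
  tree <- if (spec$backbone == "yule") {
    simulate_yule_tree(spec$n_tips, spec$backbone_lambda)
  } else if (spec$backbone == "yule_shift") {
    simulate_yule_shift_tree(spec$n_tips, spec$backbone_lambda,
                             spec$backbone_shift_rate,
                             spec$backbone_multipliers)
  } else {
    tr <- NULL
    for (try in 1:50) {
      tr <- tryCatch(ape::rphylo(spec$n_tips, birth = spec$backbone_lambda,
                                 death = spec$backbone_mu, fossils = FALSE),
                     error = function(e) NULL)
      if (!is.null(tr)) break
    }
    if (is.null(tr)) stop("backbone simulation failed repeatedly; extinction too high?")
    tr
  }
  if (!is.null(spec$crown_age)) {
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * spec$crown_age / h
  }
  validate_timetree(tree)
  tree
}

#' Generate a synthetic clade dataset with ground truth
#'
#' Draws a backbone timetree and tip richness values under the richness model
#' of the spec, returning the dataset together with a ground-truth record
#' (true rates, signal parameters, seeds) sufficient to replay every value.
#'
#' @param spec A \code{\link{generator_spec}}.
#' @return List with \code{dataset} (a \code{\link{clade_dataset}}) and
#'   \code{truth}.
#' @export
generate_clade_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  mp <- spec$model_params
  if (spec$richness_model == "higher_taxon_process") {
    sim <- NULL
    set.seed(spawn_seed(spec$seed, "higher_taxon"))
    for (i in 1:1000) {
      sim <- simulate_higher_taxon_tree(mp$config)
      if (!is.null(sim)) break
    }
    if (is.null(sim)) stop("higher-taxon simulation rejected 1000 times")
    recs <- data.frame(name = sim$dataset$records$name,
                       richness = sim$dataset$records$richness,
                       stringsAsFactors = FALSE)
    return(list(dataset = sim$dataset,
                truth = list(model = "higher_taxon_process",
                             formation_times = sim$formation_times,
                             states = sim$states, seed = spec$seed)))
  }
  tree <- generate_timetree(spec)
  ages <- stem_ages(tree)
  set.seed(spawn_seed(spec$seed, "richness"))
  truth <- list(model = spec$richness_model, params = mp, seed = spec$seed)
  richness <- switch(spec$richness_model,
    constant_rate = {
      p <- bd_params(mp$lambda, mp$mu)
      sample_progeny(p, unname(ages), size = length(ages), conditioned = TRUE)
    },
    lognormal_relaxed = {
      r <- stats::rlnorm(length(ages), meanlog = mp$m, sdlog = mp$s)
      truth$clade_rates <- r
      eps <- if (is.null(mp$epsilon)) 0 else mp$epsilon
      vapply(seq_along(ages), function(i) {
        lam <- r[i] / (1 - eps)
        sample_progeny(bd_params(lam, eps * lam), unname(ages[i]),
                       conditioned = TRUE)
      }, numeric(1))
    },
    bm_signal_only = {
      y <- simulate_bm_tips(tree, Lambda = mp$Lambda,
                            root_state = mp$root_state, rate = mp$rate,
                            n_datasets = 1L)[1, ]
      truth$log_richness <- y
      pmax(1, round(exp(y)))
    })
  ds <- clade_dataset(tree, data.frame(name = names(ages),
                                       richness = as.numeric(richness),
                                       stringsAsFactors = FALSE))
  list(dataset = ds, truth = truth)
}

#' Write a versioned synthetic fixture set
#'
#' Emits Newick + richness-TSV + ground-truth-JSON triplets for a list of
#' generator specs, the plain-text fixture format consumed by the test suite
#' and the pipeline examples.
#'
#' @param specs List of \code{\link{generator_spec}} objects.
#' @param dir Output directory.
#' @return Paths of the files written, invisibly.
#' @export
make_fixtures <- function(specs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(specs)) {
    g <- generate_clade_dataset(specs[[i]])
    base <- file.path(dir, sprintf("fixture_%02d", i))
    write_timetree(g$dataset$tree, paste0(base, ".nwk"))
    write_tsv(g$dataset$records[, c("name", "richness")],
              paste0(base, ".tsv"))
    write_json(g$truth, paste0(base, ".json"))
    paths <- c(paths, paste0(base, c(".nwk", ".tsv", ".json")))
  }
  invisible(paths)
}
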