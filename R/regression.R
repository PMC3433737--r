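## phylogenetic covariance under a Pagel's-lambda transform: off-diagonal
## shared path lengths scaled by lambda, tip variances untouched
lambda_vcv <- function(V, lambda) {
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

gls_solve <- function(V, X, y) {
  L <- tryCatch(t(chol(V)), error = function(e) {
    idx <- which(upper.tri(V) & abs(outer(diag(V), diag(V), pmin) - V) < 1e-12,
                 arr.ind = TRUE)
    stop("singular phylogenetic covariance (zero-length cherries between tip pairs: ",
         paste(apply(idx, 1, paste, collapse = "/"), collapse = ", "), ")")
  })
  Xs <- forwardsolve(L, X)
  ys <- forwardsolve(L, y)
  fit <- stats::lm.fit(Xs, ys)
  n <- length(y); p <- ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(fit$qr))
  list(coef = fit$coefficients, vcov = sigma2 * XtX_inv, sigma2 = sigma2,
       rss = rss, logdetV = 2 * sum(log(diag(L))), n = n)
}

#' Phylogenetic generalized least-squares regression of log-richness on stem age
#'
#' Fits log(richness) ~ stem_age by generalized least squares with residual
#' covariance proportional to shared phylogenetic branch lengths (Brownian
#' motion on the timetree), a Pagel's-lambda transform thereof, or the
#' identity matrix (ordinary least squares). The slope is tested with a
#' two-tailed t test on \code{n - 2} degrees of freedom.
#'
#' @param dataset A \code{\link{clade_dataset}}.
#' @param covariance \code{"BM"} (default), \code{"lambda"} or
#'   \code{"identity"}.
#' @param lambda Pagel's lambda for \code{covariance = "lambda"}.
#' @param log_base Base of the richness logarithm; natural log by default.
#'   Slopes are base-dependent, so results record the base used.
#' @return An object of class \code{"regression_result"}: slope \code{beta}
#'   (change in log-richness per My), \code{intercept}, standard errors,
#'   \code{t_statistic}, two-tailed \code{p_value}, \code{df},
#'   \code{covariance_model} and \code{log_base}.
#' @export
pgls_fit <- function(dataset, covariance = c("BM", "lambda", "identity"),
                     lambda = 1, log_base = exp(1)) {
  covariance <- match.arg(covariance)
  stopifnot(inherits(dataset, "clade_dataset"))
  rec <- dataset$records
  n <- nrow(rec)
  if (n < 3) stop("need at least 3 clades for regression")
  y <- log(rec$richness, base = log_base)
  X <- cbind(intercept = 1, age = rec$stem_age)
  V <- switch(covariance,
              identity = diag(n),
              BM = ape::vcv.phylo(dataset$tree)[rec$name, rec$name],
              lambda = lambda_vcv(ape::vcv.phylo(dataset$tree)[rec$name, rec$name],
                                  lambda))
  g <- gls_solve(V, X, y)
  se <- sqrt(diag(g$vcov))
  ## a numerically perfect fit (e.g. constant response) has slope 0 by
  ## construction; the 0/0 t ratio is defined as 0
  perfect <- g$rss <= 1e-20 * (sum(y^2) + 1)
  tstat <- if (!perfect && se[2] > 0) unname(g$coef[2] / se[2]) else 0
  structure(list(beta = unname(g$coef[2]), intercept = unname(g$coef[1]),
                 se_beta = unname(se[2]), se_intercept = unname(se[1]),
                 t_statistic = unname(tstat),
                 p_value = 2 * stats::pt(-abs(tstat), df = n - 2),
                 df = n - 2, n = n, sigma2 = g$sigma2,
                 covariance_model = covariance, log_base = log_base),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s regression of log(richness) on stem age (log base %.4g)\n",
              if (x$covariance_model == "identity") "OLS" else
                paste0("PGLS[", x$covariance_model, "]"), x$log_base))
  cat(sprintf("  beta = %.6g (SE %.3g), t = %.4g, df = %d, p = %.4g\n",
              x$beta, x$se_beta, x$t_statistic, x$df, x$p_value))
  invisible(x)
}

## profiled Brownian-motion log-likelihood of tip values under covariance V
bm_profile_loglik <- function(V, y) {
  n <- length(y)
  L <- t(chol(V))
  ys <- forwardsolve(L, y)
  ones <- forwardsolve(L, rep(1, n))
  mu <- sum(ones * ys) / sum(ones^2)
  res <- ys - mu * ones
  sigma2 <- sum(res^2) / n
  list(logL = -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(L))) + n),
       root_state = mu, rate = sigma2)
}

#' Maximum-likelihood estimate of Pagel's lambda for log-richness
#'
#' Estimates phylogenetic signal in log-transformed species richness by
#' maximising the Brownian-motion likelihood over the Pagel's-lambda transform
#' of the timetree covariance, jointly (by profiling) with the root state and
#' variance rate. Reports the AIC difference against the non-phylogenetic
#' model (lambda = 0); positive values favour phylogenetic signal.
#'
#' @param dataset A \code{\link{clade_dataset}}.
#' @param log_base Base of the richness logarithm.
#' @return An object of class \code{"signal_result"}: \code{Lambda_ml},
#'   \code{delta_aic} (AIC(lambda = 0) - AIC(lambda = ML)),
#'   \code{bm_root_state}, \code{bm_variance_rate}, \code{logL}, and a
#'   \code{boundary} flag when the optimum sits at 0 or 1.
#' @export
estimate_lambda <- function(dataset, log_base = exp(1)) {
  stopifnot(inherits(dataset, "clade_dataset"))
  rec <- dataset$records
  if (nrow(rec) < 4) stop("need at least 4 clades to estimate lambda")
  y <- log(rec$richness, base = log_base)
  V <- ape::vcv.phylo(dataset$tree)[rec$name, rec$name]
  f <- function(lam) -bm_profile_loglik(lambda_vcv(V, lam), y)$logL
  opt <- stats::optimize(f, interval = c(0, 1), tol = 1e-8)
  ## optimize() never lands exactly on the interval ends: compare explicitly
  cand <- c(opt$minimum, 0, 1)
  vals <- c(opt$objective, f(0), f(1))
  lam_ml <- cand[which.min(vals)]
  fit_ml <- bm_profile_loglik(lambda_vcv(V, lam_ml), y)
  fit_0 <- bm_profile_loglik(diag(diag(V)), y)
  delta_aic <- (2 * 2 - 2 * fit_0$logL) - (2 * 3 - 2 * fit_ml$logL)
  structure(list(Lambda_ml = lam_ml, delta_aic = delta_aic,
                 bm_root_state = fit_ml$root_state,
                 bm_variance_rate = fit_ml$rate, logL = fit_ml$logL,
                 logL_lambda0 = fit_0$logL,
                 boundary = lam_ml %in% c(0, 1)),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Pagel's lambda ML = %.4g (delta AIC vs lambda = 0: %.4g)%s\n",
              x$Lambda_ml, x$delta_aic,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Variance-of-independent-contrasts test of phylogenetic signal
#'
#' Tests phylogenetic signal in log-richness by comparing the variance of
#' standardized independent contrasts to its null distribution under random
#' reassignment of values to tips. Signal makes neighbouring tips similar and
#' the contrast variance low, so the test is one-tailed (low variance =
#' signal). \code{mode = "permutation"} gives an exact Monte-Carlo p bounded
#' below by \code{1/(n_permutations + 1)}; \code{mode = "analytic"} fits a
#' normal approximation to the permuted log-variances and can report extreme
#' p-values.
#'
#' @param dataset A \code{\link{clade_dataset}} with a binary ultrametric tree.
#' @param n_permutations Number of tip-label permutations.
#' @param mode \code{"permutation"} or \code{"analytic"}.
#' @param log_base Base of the richness logarithm.
#' @return List with \code{p_value}, \code{observed_variance}, \code{mode}
#'   and the permutation variances.
#' @export
contrasts_signal_test <- function(dataset, n_permutations = 999,
                                  mode = c("permutation", "analytic"),
                                  log_base = exp(1)) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "clade_dataset"))
  tree <- dataset$tree
  y <- stats::setNames(log(dataset$records$richness, base = log_base),
                       dataset$records$name)
  pic_var <- function(vals) {
    contr <- tryCatch(ape::pic(vals, tree),
                      error = function(e)
                        stop("contrast standardization failed (zero-length ",
                             "branches? consider collapsing or jittering them): ",
                             conditionMessage(e)))
    stats::var(contr)
  }
  obs <- pic_var(y[tree$tip.label])
  perm <- vapply(seq_len(n_permutations), function(i)
    pic_var(stats::setNames(sample(unname(y)), tree$tip.label)), numeric(1))
  p <- if (mode == "permutation") {
    ## strict inequality so the degenerate all-equal case (zero variance
    ## everywhere, i.e. perfect similarity) reports the minimal p
    (1 + sum(perm < obs)) / (1 + n_permutations)
  } else {
    lp <- log(perm)
    stats::pnorm((log(obs) - mean(lp)) / stats::sd(lp))
  }
  list(p_value = p, observed_variance = obs, mode = mode,
       permutation_variances = perm)
}

#' Age-richness regression across all qualifying subtrees
#'
#' Repeats the PGLS fit within every subtree of the timetree containing at
#' least \code{min_tips} terminal clades, counting significantly positive and
#' negative slopes at level \code{alpha}. No multiple-testing correction is
#' applied to the significance counts; a Bonferroni-adjusted p column is
#' emitted for information. Supplying \code{exclude_node} removes that
#' subtree's tips before scanning, which exposes "trickle-down" effects where
#' one nested subtree drives significance at more inclusive nodes.
#'
#' @param dataset A reconciled \code{\link{clade_dataset}}.
#' @param min_tips Minimum number of terminal clades per qualifying subtree.
#' @param alpha Significance level for the counts.
#' @param exclude_node Optional node id whose subtree's tips are removed
#'   before the scan.
#' @param covariance,log_base Passed to \code{\link{pgls_fit}}.
#' @return An object of class \code{"subtree_scan"}: data frame \code{table}
#'   (node id in postorder numbering, n_tips, slope, p, p_bonferroni) plus
#'   counts \code{n_significant_positive} / \code{n_significant_negative}.
#' @export
scan_subtrees <- function(dataset, min_tips = 10, alpha = 0.05,
                          exclude_node = NULL, covariance = "BM",
                          log_base = exp(1)) {
  stopifnot(inherits(dataset, "clade_dataset"))
  tree <- dataset$tree
  if (!is.null(exclude_node)) {
    drop <- ape::extract.clade(tree, exclude_node)$tip.label
    keep <- setdiff(tree$tip.label, drop)
    if (length(keep) < min_tips) stop("exclusion removes nearly all tips")
    tree2 <- ape::keep.tip(tree, keep)
    dataset <- clade_dataset(tree2, dataset$records[
      dataset$records$name %in% keep, , drop = FALSE])
    tree <- dataset$tree
  }
  ntip <- ape::Ntip(tree)
  post <- rev(ape::postorder(tree))
  clades <- ape::prop.part(tree)   # tip sets per internal node, root first
  rows <- list()
  for (k in seq_along(clades)) {
    node <- ntip + k
    tipset <- tree$tip.label[clades[[k]]]
    if (length(tipset) < min_tips) next
    sub_tree <- if (node == ntip + 1) tree else ape::extract.clade(tree, node)
    sub <- clade_dataset(sub_tree, dataset$records[
      dataset$records$name %in% tipset, , drop = FALSE])
    ## subtree clades keep their stem ages from the full timetree
    sub$records$stem_age <- dataset$records$stem_age[
      match(sub$records$name, dataset$records$name)]
    fit <- pgls_fit(sub, covariance = covariance, log_base = log_base)
    rows[[length(rows) + 1L]] <-
      data.frame(node = node, n_tips = length(tipset), slope = fit$beta,
                 t = fit$t_statistic, p = fit$p_value)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(node = integer(0), n_tips = integer(0),
                                      slope = numeric(0), t = numeric(0),
                                      p = numeric(0))
  ## deterministic ordering: postorder position of each node
  post_nodes <- unique(tree$edge[post, 2])
  rank <- match(tab$node, c(post_nodes, ntip + 1L))
  tab <- tab[order(rank), , drop = FALSE]
  tab$p_bonferroni <- pmin(1, tab$p * nrow(tab))
  structure(list(table = tab,
                 n_subtrees = nrow(tab),
                 n_significant_positive = sum(tab$p < alpha & tab$slope > 0),
                 n_significant_negative = sum(tab$p < alpha & tab$slope < 0),
                 alpha = alpha, min_tips = min_tips),
            class = "subtree_scan")
}

#' @export
print.subtree_scan <- function(x, ...) {
  cat(sprintf("subtree scan: %d qualifying subtrees (>= %d tips); %d significant positive, %d significant negative at alpha = %g\n",
              x$n_subtrees, x$min_tips, x$n_significant_positive,
              x$n_significant_negative, x$alpha))
  invisible(x)
}

#' Restrict a dataset to clades younger than a truncation age
#'
#' Keeps only clades with stem age strictly below \code{max_age}, pruning the
#' tree accordingly. Retained clades keep their original stem ages (pruning
#' can lengthen pendant branches, but the age of a clade is a property of the
#' full timetree, not of the pruned one).
#'
#' @param dataset A \code{\link{clade_dataset}}.
#' @param max_age Truncation age in My (> 0).
#' @return A \code{\link{clade_dataset}} of the retained clades.
#' @export
subset_by_age <- function(dataset, max_age) {
  stopifnot(inherits(dataset, "clade_dataset"), max_age > 0)
  keep <- dataset$records$name[dataset$records$stem_age < max_age]
  if (!length(keep)) stop("no clades younger than ", max_age, " My")
  tree <- ape::keep.tip(dataset$tree, keep)
  out <- clade_dataset(tree, dataset$records[dataset$records$name %in% keep, ,
                                             drop = FALSE])
  out$records$stem_age <- dataset$records$stem_age[
    match(out$records$name, dataset$records$name)]
  out
}
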