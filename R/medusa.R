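#' AICc improvement threshold coefficients
#'
#' Coefficients of the sample-size-dependent AICc improvement threshold used
#' by the stepwise shift-selection procedure,
#' \eqn{\Delta AICc = A (N - B)^C + D}. Defaults are the GEIGER threshold
#' selection values A = -35.94105, B = 6.73726, C = -0.10062, D = 27.51668.
#'
#' @param A,B,C,D Real coefficients.
#' @return An object of class \code{"threshold_params"}.
#' @export
threshold_params <- function(A = -35.94105, B = 6.73726, C = -0.10062,
                             D = 27.51668) {
  structure(list(A = A, B = B, C = C, D = D), class = "threshold_params")
}

#' Evaluate the AICc improvement threshold
#'
#' @param N Taxon count (must exceed \code{params$B}).
#' @param params A \code{\link{threshold_params}} object.
#' @return The required AICc improvement for accepting one more rate shift.
#' @export
aicc_threshold <- function(N, params = threshold_params()) {
  stopifnot(inherits(params, "threshold_params"))
  if (any(N <= params$B)) stop("taxon count must exceed B = ", params$B)
  params$A * (N - params$B)^params$C + params$D
}

## Per-dataset edge table for the backbone likelihood: durations, child ages,
## pendant flags and tip richness aligned to edges.
medusa_prep <- function(dataset) {
  tree <- dataset$tree
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  pendant <- child <= ntip
  n <- rep(NA_real_, nrow(tree$edge))
  n[pendant] <- dataset$records$richness[
    match(tree$tip.label[child[pendant]], dataset$records$name)]
  list(tree = tree, ntip = ntip, parent = parent, child = child,
       s = ages[parent] - ages[child], t2 = ages[child], pendant = pendant,
       n = n, root = ntip + 1L)
}

## Log-likelihood contributions of a set of edges under one rate class,
## assembled as a proper pruning density of the observed backbone tree plus
## tip richness. A pendant edge carries the survival-conditioned progeny
## probability of the tip's richness times the clade-survival probability
## over its stem branch, i.e. the unconditioned progeny probability
##   (1 - a_s)(1 - b_s) b_s^(n-1).
## An internal edge from age t1 down to t2 carries the probability that the
## lineage leaves exactly one descendant at t2 whose progeny is observed
## while all its other descendants at t2 die out before the present, times
## the speciation density at the child node:
##   (1 - a_s)(1 - b_s) / (1 - b_s * ext(t2))^2 * lambda
## with (a_s, b_s) the progeny parameters over the edge duration s and
## ext(t2) the extinction-by-present probability from age t2 (evaluated under
## the same class; descendants governed by later shifts keep their own terms).
medusa_edge_loglik <- function(params, prep, idx) {
  s <- prep$s[idx]; t2 <- prep$t2[idx]
  pend <- prep$pendant[idx]; n <- prep$n[idx]
  ab <- bd_ab_vec(params, s)
  a <- ab[, "a"]; b <- ab[, "b"]
  out <- numeric(length(idx))
  if (any(pend)) {
    ap <- a[pend]; bp <- b[pend]; np <- n[pend]
    out[pend] <- ifelse(bp > 0,
                        log1p(-ap) + log1p(-bp) + (np - 1) * log(bp),
                        ifelse(np == 1, log1p(-ap), -Inf))
  }
  if (any(!pend)) {
    ext2 <- bd_ab_vec(params, t2[!pend])[, "a"]
    out[!pend] <- log1p(-a[!pend]) + log1p(-b[!pend]) -
      2 * log1p(-b[!pend] * ext2) +
      log(max(params$lambda, 1e-300))
  }
  out
}

## edge class assignment induced by painting shift subtrees downstream;
## shift i (at node shift_nodes[i]) paints its stem edge and subtree with
## class i + 1 until a nested shift overrides
paint_edges <- function(prep, shift_nodes) {
  nn <- prep$ntip + prep$tree$Nnode
  node_class <- integer(nn); node_class[prep$root] <- 1L
  shift_of <- integer(nn)
  shift_of[shift_nodes] <- seq_along(shift_nodes) + 1L
  cls <- integer(length(prep$s))
  for (e in seq_along(prep$s)) {   # cladewise order: parents precede children
    ch <- prep$child[e]
    cls[e] <- if (shift_of[ch] > 0L) shift_of[ch] else node_class[prep$parent[e]]
    node_class[ch] <- cls[e]
  }
  cls
}

fit_class_ml <- function(prep, idx, start = NULL) {
  nll <- function(p) {
    v <- -sum(medusa_edge_loglik(bd_params(exp(p[1]), exp(p[2])), prep, idx))
    if (!is.finite(v)) 1e10 else v   # bounded penalty keeps L-BFGS-B in range
  }
  s0 <- if (is.null(start)) c(log(0.1), log(0.05))
        else c(log(max(start$lambda, 1e-8)), log(max(start$mu, 1e-8)))
  o <- try(stats::optim(s0, nll, method = "L-BFGS-B",
                        lower = c(log(1e-8), log(1e-8)),
                        upper = c(log(1e3), log(1e3))), silent = TRUE)
  if (inherits(o, "try-error")) return(NULL)
  list(params = bd_params(exp(o$par[1]), exp(o$par[2])), nll = o$value,
       convergence = o$convergence == 0)
}

#' Backbone likelihood of a shift configuration
#'
#' Log-likelihood of a reconciled dataset under a mixture of constant-rate
#' birth-death processes: every tree edge is governed by exactly one rate
#' class, shifts painting their subtree downstream until overridden. Tip
#' richness enters through survival-conditioned progeny probabilities over
#' stem branches; internal branches carry the reconstructed-process terms of
#' the governing class (see source for the exact per-edge factors).
#'
#' @param dataset A \code{\link{clade_dataset}} with a binary tree.
#' @param shifts Integer vector of shift node ids (may be empty).
#' @param classes List of \code{\link{bd_params}}, one per class: base class
#'   first, then one per shift in order.
#' @return Total log-likelihood (scalar).
#' @export
model_likelihood <- function(dataset, shifts = integer(0), classes) {
  stopifnot(inherits(dataset, "clade_dataset"),
            length(classes) == length(shifts) + 1L)
  prep <- medusa_prep(dataset)
  if (any(shifts == prep$root))
    stop("a shift at the root duplicates the base rate class")
  cls <- paint_edges(prep, shifts)
  sum(vapply(seq_along(classes), function(k) {
    idx <- which(cls == k)
    if (!length(idx)) 0 else sum(medusa_edge_loglik(classes[[k]], prep, idx))
  }, numeric(1)))
}

medusa_aicc <- function(logL, n_shifts, N) {
  k <- 3 * n_shifts + 2   # 2 rates per class + 1 location per shift
  if (N - k - 1 <= 0) return(Inf)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (N - k - 1)
}

#' Stepwise AICc selection of diversification rate shifts
#'
#' Forward stepwise search over rate-shift placements on a backbone timetree
#' with tip richness. Each round evaluates every candidate node (the shift
#' painting that node's stem branch and subtree), fits the prospective new
#' class by maximum likelihood with extinction permitted to exceed
#' speciation, and accepts the single best shift if the AICc improvement
#' exceeds the sample-size-dependent threshold; accepted configurations are
#' then fully refit class by class. Ties in AICc are broken toward the
#' lowest postorder node index, so reruns are deterministic.
#'
#' @param dataset A reconciled \code{\link{clade_dataset}} with binary tree.
#' @param threshold A \code{\link{threshold_params}} object, or a single
#'   number used as a fixed AICc improvement threshold (0 gives ordinary
#'   forward AICc selection).
#' @param N AICc sample size; defaults to the number of tips.
#' @param max_shifts Cap on the number of accepted shifts.
#' @return An object of class \code{"medusa_result"}: \code{shifts} (node
#'   ids), \code{classes} (list of \code{\link{bd_params}}), \code{logL},
#'   \code{aicc_single}, \code{aicc_best}, \code{n_shifts}, \code{np} and the
#'   stepwise \code{trajectory}.
#' @export
stepwise_fit <- function(dataset, threshold = threshold_params(), N = NULL,
                         max_shifts = Inf) {
  stopifnot(inherits(dataset, "clade_dataset"))
  prep <- medusa_prep(dataset)
  if (is.null(N)) N <- prep$ntip
  thr <- if (inherits(threshold, "threshold_params"))
    aicc_threshold(N, threshold) else as.numeric(threshold)

  base <- fit_class_ml(prep, seq_along(prep$s))
  if (is.null(base)) stop("single-rate model failed to converge")
  classes <- list(base$params)
  shifts <- integer(0)
  cur_logL <- -base$nll
  aicc_single <- medusa_aicc(cur_logL, 0, N)
  cur_aicc <- aicc_single
  trajectory <- data.frame(step = 0L, shift_node = NA_integer_,
                           logL = cur_logL, aicc = cur_aicc)

  ## deterministic candidate order: postorder position of each node
  post_nodes <- unique(as.vector(t(prep$tree$edge[ape::postorder(prep$tree),
                                                  c(2, 1)])))
  candidates <- setdiff(post_nodes, prep$root)

  ## per-node edge sets (stem edge first, then subtree edges), computed once
  subtree_edges <- vector("list", prep$ntip + prep$tree$Nnode)
  for (e in rev(seq_along(prep$s))) {   # reverse cladewise = children first
    ch <- prep$child[e]
    subtree_edges[[ch]] <- c(e, if (ch > prep$ntip)
      unlist(subtree_edges[prep$child[prep$parent == ch]]))
  }

  repeat {
    if (length(shifts) >= max_shifts) break
    cls <- paint_edges(prep, shifts)
    class_edges <- lapply(seq_along(classes), function(k) which(cls == k))
    class_ll <- vapply(seq_along(classes), function(k) {
      if (!length(class_edges[[k]])) 0
      else sum(medusa_edge_loglik(classes[[k]], prep, class_edges[[k]]))
    }, numeric(1))
    best <- NULL
    for (v in setdiff(candidates, shifts)) {
      ## edges the new shift repaints: the part of v's subtree still governed
      ## by the class at v's stem (nested existing shifts keep their edges)
      idx <- subtree_edges[[v]]
      painted <- idx[cls[idx] == cls[idx[1]]]
      if (!length(painted)) next
      fit_new <- fit_class_ml(prep, painted, start = classes[[cls[painted[1]]]])
      if (is.null(fit_new)) { warning("optimizer failed at node ", v); next }
      logL_v <- -fit_new$nll
      ok <- TRUE
      for (k in seq_along(classes)) {
        rest <- setdiff(class_edges[[k]], painted)
        if (length(rest) == length(class_edges[[k]])) {
          logL_v <- logL_v + class_ll[k]        # class untouched
        } else {
          rf <- fit_class_ml(prep, rest, start = classes[[k]])
          if (is.null(rf)) { ok <- FALSE; break }
          logL_v <- logL_v - rf$nll
        }
      }
      if (!ok) { warning("optimizer failed refitting around node ", v); next }
      aicc_v <- medusa_aicc(logL_v, length(shifts) + 1L, N)
      if (is.null(best) || aicc_v < best$aicc - 1e-12) {
        best <- list(node = v, aicc = aicc_v, logL = logL_v,
                     params = fit_new$params)
      }
    }
    if (is.null(best) || (cur_aicc - best$aicc) < thr) break
    shifts <- c(shifts, best$node)
    classes <- c(classes, list(best$params))
    ## full refit: classes partition the edges, so refit each independently
    cls <- paint_edges(prep, shifts)
    for (k in seq_along(classes)) {
      idx <- which(cls == k)
      if (!length(idx)) next
      rf <- fit_class_ml(prep, idx, start = classes[[k]])
      if (!is.null(rf)) classes[[k]] <- rf$params
    }
    cur_logL <- model_likelihood(dataset, shifts, classes)
    cur_aicc <- medusa_aicc(cur_logL, length(shifts), N)
    trajectory <- rbind(trajectory,
                        data.frame(step = length(shifts),
                                   shift_node = best$node, logL = cur_logL,
                                   aicc = cur_aicc))
  }
  structure(list(shifts = shifts, classes = classes, logL = cur_logL,
                 aicc_single = aicc_single, aicc_best = cur_aicc,
                 n_shifts = length(shifts), np = 3 * length(shifts) + 2,
                 N = N, threshold = thr, trajectory = trajectory),
            class = "medusa_result")
}

#' @export
print.medusa_result <- function(x, ...) {
  cat(sprintf("stepwise rate-shift model: %d shift(s), np = %d\n",
              x$n_shifts, x$np))
  cat(sprintf("  AICc single-rate = %.2f, AICc best = %.2f (threshold %.3f)\n",
              x$aicc_single, x$aicc_best, x$threshold))
  for (k in seq_along(x$classes)) {
    p <- x$classes[[k]]
    cat(sprintf("  class %d%s: lambda = %.4g, mu = %.4g\n", k,
                if (k == 1) " (root)" else paste0(" (node ", x$shifts[k - 1], ")"),
                p$lambda, p$mu))
  }
  invisible(x)
}

#' Poisson maximum-likelihood estimate of the rate-shift rate
#'
#' Treats inferred rate shifts as a Poisson process on the internal branches
#' of the phylogeny: the ML event rate is the number of inferred shifts
#' divided by the summed internal branch lengths.
#'
#' @param tree A \code{phylo} object.
#' @param n_shifts Number of inferred shifts (>= 0).
#' @return Shift rate alpha, per lineage per My.
#' @export
shift_rate_mle <- function(tree, n_shifts) {
  stopifnot(n_shifts >= 0)
  internal <- tree$edge[, 2] > ape::Ntip(tree)
  L <- sum(tree$edge.length[internal])
  if (L <= 0) stop("tree has zero total internal branch length")
  n_shifts / L
}

#' Serialize a stepwise shift-selection result
#'
#' Writes the shift nodes, per-class rates and AICc trajectory as JSON, and a
#' one-row TSV with the summary columns Clades, N, AICc-1, AICc-MEDUSA,
#' Shifts, np.
#'
#' @param result A \code{"medusa_result"}.
#' @param dataset The fitted \code{\link{clade_dataset}}.
#' @param json_path,tsv_path Output paths (either may be \code{NULL}).
#' @return The summary row, invisibly.
#' @export
write_medusa_result <- function(result, dataset, json_path = NULL,
                                tsv_path = NULL) {
  row <- data.frame(Clades = nrow(dataset$records),
                    N = sum(dataset$records$richness),
                    AICc_1 = result$aicc_single,
                    AICc_MEDUSA = result$aicc_best,
                    Shifts = result$n_shifts, np = result$np)
  if (!is.null(json_path))
    write_json(list(shifts = result$shifts,
                    classes = lapply(result$classes, function(p)
                      list(lambda = p$lambda, mu = p$mu)),
                    logL = result$logL, aicc_single = result$aicc_single,
                    aicc_best = result$aicc_best,
                    trajectory = result$trajectory), json_path)
  if (!is.null(tsv_path)) write_tsv(row, tsv_path)
  invisible(row)
}
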