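#' Constant-rate birth-death parameters
#'
#' Container for a speciation/extinction rate pair. Rates are per lineage per
#' million years. The net diversification rate \code{r = lambda - mu} may be
#' negative (declining diversity) and the relative extinction fraction
#' \code{epsilon = mu/lambda} may exceed 1.
#'
#' @param lambda Speciation rate (>= 0, finite).
#' @param mu Extinction rate (>= 0, finite).
#' @return An object of class \code{"bd_params"} with elements \code{lambda},
#'   \code{mu}, \code{r} and \code{epsilon} (\code{NA} when \code{lambda = 0}).
#' @export
#' @examples
#' bd_params(0.2, 0.1)
bd_params <- function(lambda, mu) {
  stopifnot(is.numeric(lambda), is.numeric(mu), length(lambda) == 1L,
            length(mu) == 1L)
  if (!is.finite(lambda) || !is.finite(mu) || lambda < 0 || mu < 0)
    stop("birth-death rates must be finite and non-negative")
  structure(list(lambda = lambda, mu = mu, r = lambda - mu,
                 epsilon = if (lambda > 0) mu / lambda else NA_real_),
            class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf("birth-death rates: lambda = %g, mu = %g (r = %g, epsilon = %s)\n",
              x$lambda, x$mu, x$r,
              if (is.na(x$epsilon)) "NA" else format(x$epsilon)))
  invisible(x)
}

## Kendall geometric-tail parameters (a_t, b_t) of the progeny distribution:
## P(N = 0) = a, P(N = n) = (1 - a)(1 - b) b^(n-1).  Written via expm1 so the
## expressions stay stable as r -> 0; the exact balanced limit a = b =
## lambda*t/(1 + lambda*t) engages when |r|*t < 1e-8.
bd_ab <- function(params, t) {
  lambda <- params$lambda; mu <- params$mu; r <- params$r
  if (abs(r) * t < 1e-8) {
    a <- b <- lambda * t / (1 + lambda * t)
    return(list(a = a, b = b))
  }
  em1 <- expm1(r * t)               # e^{rt} - 1
  if (!is.finite(em1))              # e^{rt} overflow: asymptotic forms
    return(list(a = mu / lambda,
                b = 1 - max((r / lambda) * exp(-r * t), 5e-324)))
  denom <- lambda * em1 + r         # lambda e^{rt} - mu, cancellation-free
  list(a = mu * em1 / denom, b = lambda * em1 / denom)
}

## vectorised over t, returns two-column matrix (a, b)
bd_ab_vec <- function(params, t) {
  lambda <- params$lambda; mu <- params$mu; r <- params$r
  a <- b <- numeric(length(t))
  bal <- abs(r) * t < 1e-8
  if (any(bal)) a[bal] <- b[bal] <- lambda * t[bal] / (1 + lambda * t[bal])
  if (any(!bal)) {
    em1 <- expm1(r * t[!bal])
    denom <- lambda * em1 + r
    aa <- mu * em1 / denom
    bb <- lambda * em1 / denom
    over <- !is.finite(em1)        # e^{rt} overflow: use asymptotic forms
    if (any(over)) {
      aa[over] <- mu / lambda
      bb[over] <- 1 - pmax((r / lambda) * exp(-r * t[!bal][over]), 5e-324)
    }
    a[!bal] <- aa
    b[!bal] <- bb
  }
  cbind(a = a, b = b)
}

#' Probability a single lineage has extant descendants after time t
#'
#' Survival probability of the constant-rate birth-death process started from
#' one lineage, i.e. \eqn{1 - P(N(t) = 0)}. Equals 1 for a pure-birth process
#' and \eqn{1/(1 + \lambda t)} for the balanced process (\eqn{\mu = \lambda}).
#'
#' @param params A \code{\link{bd_params}} object.
#' @param t Elapsed time in My (vectorised, all >= 0).
#' @return Survival probabilities in [0, 1].
#' @export
survival_probability <- function(params, t) {
  stopifnot(inherits(params, "bd_params"))
  if (any(t < 0)) stop("elapsed time must be non-negative")
  unname(1 - bd_ab_vec(params, t)[, "a"])
}

#' Expected species richness under constant-rate birth-death
#'
#' Unconditioned expectation \eqn{n_0 e^{rt}}, or the expectation conditioned
#' on survival of the clade to the present, \eqn{e^{rt} / P(survival)}
#' (defined for a single ancestral lineage). Under the balanced process the
#' conditioned expectation reduces to \eqn{N(t) = 1 + \lambda t}.
#'
#' @param params A \code{\link{bd_params}} object.
#' @param t Elapsed time in My (vectorised).
#' @param conditioned Condition on >= 1 extant descendant? Default \code{TRUE}.
#' @param n0 Number of starting lineages (unconditioned case only).
#' @return Expected number of extant species.
#' @export
expected_richness <- function(params, t, conditioned = TRUE, n0 = 1L) {
  stopifnot(inherits(params, "bd_params"), n0 >= 1)
  if (any(t < 0)) stop("elapsed time must be non-negative")
  if (!conditioned) return(n0 * exp(params$r * t))
  if (n0 != 1L) stop("conditioned expectation is defined for n0 = 1")
  surv <- survival_probability(params, t)
  if (any(surv <= 0)) stop("survival probability is zero; conditioned expectation undefined")
  exp(params$r * t) / surv
}

#' Progeny-count distribution of the birth-death process
#'
#' Probability mass \eqn{P(N(t) = n)} for the number of extant descendants of
#' a single lineage after time \code{t}: \eqn{P(0) = a_t} and
#' \eqn{P(n) = (1 - a_t)(1 - b_t) b_t^{n-1}} for \eqn{n \ge 1}, with the
#' standard constant-rate parameters \eqn{a_t, b_t}. The survival-conditioned
#' variant divides by \eqn{1 - a_t}, giving a geometric distribution on
#' \eqn{n \ge 1}. Computed in log space so counts up to 1e7 do not underflow.
#'
#' @param params A \code{\link{bd_params}} object.
#' @param t Elapsed time in My.
#' @param n Integer count(s), >= 0 (>= 1 when conditioned).
#' @param conditioned Condition on survival? Default \code{FALSE}.
#' @param log Return log-probabilities?
#' @return Probabilities (or log-probabilities) of the same length as \code{n}.
#' @export
progeny_pmf <- function(params, t, n, conditioned = FALSE, log = FALSE) {
  stopifnot(inherits(params, "bd_params"), t >= 0)
  if (any(n < 0) || any(n != floor(n))) stop("n must be non-negative integers")
  if (conditioned && any(n < 1)) stop("conditioned progeny counts start at n = 1")
  ab <- bd_ab(params, t)
  a <- ab$a; b <- ab$b
  lp <- numeric(length(n))
  pos <- n >= 1
  if (any(pos)) {
    core <- if (b > 0) log1p(-b) + (n[pos] - 1) * log(b)
            else ifelse(n[pos] == 1, 0, -Inf)
    lp[pos] <- if (conditioned) core else core + log1p(-a)
  }
  if (any(!pos)) lp[!pos] <- if (a > 0) log(a) else -Inf
  if (log) lp else exp(lp)
}

#' Sample progeny counts from the birth-death process
#'
#' Exact O(1) inverse-CDF draws from \code{\link{progeny_pmf}}, using the
#' geometric structure of the distribution. Reproducible under
#' \code{set.seed}. Draws are capped at 1e15: beyond that the geometric
#' parameter is no longer representable in double precision, and any
#' downstream use is on the log scale where the cap is inconsequential.
#'
#' @param params A \code{\link{bd_params}} object.
#' @param t Elapsed time in My (scalar, or vector of length \code{size}).
#' @param size Number of draws.
#' @param conditioned Condition on survival (counts >= 1)?
#' @return Integer-valued numeric vector of extant descendant counts.
#' @export
sample_progeny <- function(params, t, size = 1L, conditioned = FALSE) {
  stopifnot(inherits(params, "bd_params"), all(t >= 0), size >= 1)
  if (length(t) == 1L) t <- rep(t, size)
  stopifnot(length(t) == size)
  ab <- bd_ab_vec(params, t)
  a <- ab[, "a"]; b <- ab[, "b"]
  out <- numeric(size)
  u <- stats::runif(size)
  alive <- if (conditioned) rep(TRUE, size) else u >= a
  ## conditional on survival, N - 1 is geometric with failure prob b
  ug <- stats::runif(size)
  nb <- ifelse(b >= 1, Inf,
               ifelse(b > 0, 1 + floor(log(ug) / log(b)), 1))
  out[alive] <- pmin(nb[alive], 1e15)
  out
}

#' Maximum-likelihood constant-rate fit to stem ages and richness
#'
#' Fits a single (lambda, mu) pair to a set of clades by maximising the sum of
#' survival-conditioned progeny log-probabilities of each clade's richness
#' given its stem age. Optimisation is over (log lambda, log mu), which lets
#' extinction exceed speciation smoothly; with \code{epsilon} fixed the
#' problem is one-dimensional in the net rate.
#'
#' @param ages Stem ages (My) or a \code{clade_dataset} (then \code{richness}
#'   is ignored).
#' @param richness Extant species counts aligned with \code{ages}.
#' @param epsilon Optional fixed relative extinction fraction in [0, 1).
#' @return A list with \code{params} (\code{\link{bd_params}}), \code{logL},
#'   \code{convergence} flag and \code{boundary} flag (set when the data carry
#'   no growth signal and the net rate runs to its lower search bound).
#' @export
fit_constant_rate_ml <- function(ages, richness = NULL, epsilon = NULL) {
  if (inherits(ages, "clade_dataset")) {
    richness <- ages$records$richness
    ages <- ages$records$stem_age
  }
  stopifnot(length(ages) == length(richness), length(ages) >= 1,
            all(ages > 0), all(richness >= 1))
  nll <- function(lambda, mu) {
    p <- bd_params(lambda, mu)
    ab <- bd_ab_vec(p, ages)
    b <- ab[, "b"]
    lp <- ifelse(b > 0, log1p(-b) + (richness - 1) * log(b),
                 ifelse(richness == 1, 0, -Inf))
    v <- -sum(lp)
    if (!is.finite(v)) 1e10 else v
  }
  if (!is.null(epsilon)) {
    stopifnot(epsilon >= 0, epsilon < 1)
    f <- function(logr) {
      r <- exp(logr)
      nll(r / (1 - epsilon), epsilon * r / (1 - epsilon))
    }
    opt <- stats::optimize(f, interval = c(log(1e-9), log(100)), tol = 1e-10)
    r <- exp(opt$minimum)
    lam <- r / (1 - epsilon)
    boundary <- opt$minimum < log(1e-9) + 1e-3
    return(list(params = bd_params(lam, epsilon * lam), logL = -opt$objective,
                convergence = TRUE, boundary = boundary))
  }
  ## two-parameter fit, multi-start on crude growth-rate guesses
  r0 <- max(mean(log(pmax(richness, 1)) / ages), 1e-4)
  starts <- list(c(log(r0), log(r0 / 2)), c(log(2 * r0), log(1.5 * r0)),
                 c(log(r0), log(1e-4)))
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(s, function(p) nll(exp(p[1]), exp(p[2])),
                          method = "L-BFGS-B",
                          lower = c(log(1e-9), log(1e-9)),
                          upper = c(log(1e3), log(1e3))), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("constant-rate ML fit failed to converge from all starts")
  lam <- exp(best$par[1]); mu <- exp(best$par[2])
  list(params = bd_params(lam, mu), logL = -best$value,
       convergence = best$convergence == 0,
       boundary = (lam - mu) < 2e-9 || best$par[1] < log(1e-9) + 1e-3)
}
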