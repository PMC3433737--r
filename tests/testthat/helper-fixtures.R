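# small trees and datasets built in code, shared across test files

newick3 <- "((A:10,B:10):5,C:15);"

tree3 <- function() read_timetree(newick3)

# star tree: all tips attach directly to the root (the basal polytomy is
# resolved with zero-length edges, leaving the covariance diagonal)
star_tree <- function(n = 8, height = 10) {
  read_timetree(paste0("(", paste0("t", seq_len(n), ":", height,
                                   collapse = ","), ");"),
                resolve_polytomies = TRUE)
}

# balanced 16-tip tree of depth 4 with unit edges
balanced16 <- function() {
  lab <- paste0("t", 1:16)
  nw <- lab
  for (lev in 1:4) {
    nw <- vapply(seq_len(length(nw) / 2), function(i)
      paste0("(", nw[2 * i - 1], ":1,", nw[2 * i], ":1)"), character(1))
  }
  read_timetree(paste0(nw, ";"))
}

toy_dataset <- function(seed = 1, n_tips = 40, lambda = 0.1, mu = 0.05) {
  set.seed(seed)
  tr <- generate_timetree(generator_spec(n_tips = n_tips,
                                         backbone_lambda = 0.08, seed = seed))
  ages <- stem_ages(tr)
  rich <- sample_progeny(bd_params(lambda, mu), unname(ages),
                         size = length(ages), conditioned = TRUE)
  clade_dataset(tr, data.frame(name = names(ages), richness = rich,
                               stringsAsFactors = FALSE))
}

# brute-force truncated-CTMC progeny distribution: matrix exponential of the
# linear birth-death generator on states 0..n_max (state 0 absorbing)
ctmc_progeny <- function(lambda, mu, t, n_max = 500) {
  Q <- matrix(0, n_max + 1, n_max + 1)
  for (n in 1:(n_max - 1)) {
    i <- n + 1
    Q[i, i + 1] <- n * lambda
    Q[i, i - 1] <- n * mu
    Q[i, i] <- -n * (lambda + mu)
  }
  Q[n_max + 1, n_max] <- n_max * mu   # reflecting truncation at the top
  Q[n_max + 1, n_max + 1] <- -n_max * mu
  P <- as.matrix(Matrix::expm(Q * t))
  P[2, ]                              # started from one lineage
}
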