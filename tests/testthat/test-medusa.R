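test_that("AICc improvement threshold follows the printed formula", {
  # A = 0 collapses to the constant D
  expect_equal(aicc_threshold(100, threshold_params(A = 0, D = 3)), 3)
  # default coefficients at N = 100, against direct evaluation
  p <- threshold_params()
  expect_equal(aicc_threshold(100),
               p$A * (100 - p$B)^p$C + p$D, tolerance = 1e-12)
  expect_equal(aicc_threshold(100), 4.745, tolerance = 1e-3)
  expect_error(aicc_threshold(5), "exceed")
})

test_that("backbone likelihood assembles per-edge closed-form terms", {
  tr <- read_timetree("(((A:2,B:2):3,C:5):5,(D:6,E:6):4);")
  ds <- clade_dataset(tr, data.frame(name = LETTERS[1:5],
                                     richness = c(4, 1, 10, 2, 7)))
  cls <- bd_params(0.3, 0.1)
  got <- model_likelihood(ds, classes = list(cls))
  # independent per-term assembly from the progeny parameters
  ages <- agediv:::node_ages(tr)
  term <- 0
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    s <- ages[par] - ages[ch]
    ab <- agediv:::bd_ab(cls, s)
    if (ch <= 5) {
      n <- ds$records$richness[ds$records$name == tr$tip.label[ch]]
      term <- term + log(1 - ab$a) + log(1 - ab$b) + (n - 1) * log(ab$b)
    } else {
      ext <- agediv:::bd_ab(cls, ages[ch])$a
      term <- term + log(1 - ab$a) + log(1 - ab$b) -
        2 * log(1 - ab$b * ext) + log(cls$lambda)
    }
  }
  expect_equal(got, term, tolerance = 1e-10)
  # degenerate lambda = mu class evaluates without NaN
  expect_true(is.finite(model_likelihood(ds,
                                         classes = list(bd_params(0.2, 0.2)))))
  # likelihood responds to the data
  ds2 <- ds
  ds2$records$richness <- ds2$records$richness * 2
  expect_false(isTRUE(all.equal(model_likelihood(ds2, classes = list(cls)),
                                got)))
  expect_error(model_likelihood(ds, shifts = 6, classes = list(cls, cls)),
               "root")
})

test_that("stepwise selection respects its threshold and bookkeeping", {
  set.seed(21)
  ds <- toy_dataset(seed = 21, n_tips = 40, lambda = 0.1, mu = 0.03)
  # an infinite threshold always returns the single-rate model
  m_inf <- stepwise_fit(ds, threshold = Inf)
  expect_equal(m_inf$n_shifts, 0)
  expect_equal(m_inf$np, 2)
  expect_equal(m_inf$aicc_best, m_inf$aicc_single)
  # AICc improves monotonically along the accepted trajectory
  m0 <- suppressWarnings(stepwise_fit(ds, threshold = 0, max_shifts = 3))
  expect_true(all(diff(m0$trajectory$aicc) < 0))
  expect_equal(m0$np, 3 * m0$n_shifts + 2)
  expect_lte(m0$aicc_best, m0$aicc_single)
  # reruns are deterministic
  m1 <- suppressWarnings(stepwise_fit(ds, threshold = 0, max_shifts = 3))
  expect_identical(m0$shifts, m1$shifts)
})

test_that("stepwise selection finds a planted rate shift and rejects none on homogeneous data", {
  set.seed(22)
  hits <- 0; clean <- 0
  for (rep in 1:3) {
    sp <- generator_spec(n_tips = 80, backbone_lambda = 0.08,
                         seed = 300 + rep)
    tr <- generate_timetree(sp)
    ages <- stem_ages(tr)
    cl <- ape::prop.part(tr)
    sizes <- lengths(cl)
    k <- which(sizes >= 15 & sizes <= 30)[1]
    fast <- tr$tip.label[cl[[k]]]
    rich <- vapply(seq_along(ages), function(i) {
      lam <- if (names(ages)[i] %in% fast) 0.5 else 0.05
      sample_progeny(bd_params(lam, 0.2 * lam), unname(ages[i]),
                     conditioned = TRUE)
    }, numeric(1))
    ds <- clade_dataset(tr, data.frame(name = names(ages), richness = rich))
    m <- suppressWarnings(stepwise_fit(ds, max_shifts = 4))
    if (m$n_shifts >= 1) {
      first <- m$shifts[1]
      ft <- if (first <= 80) tr$tip.label[first]
            else ape::extract.clade(tr, first)$tip.label
      if (all(ft %in% fast)) hits <- hits + 1
    }
    rich0 <- sample_progeny(bd_params(0.08, 0.02), unname(ages),
                            size = length(ages), conditioned = TRUE)
    ds0 <- clade_dataset(tr, data.frame(name = names(ages),
                                        richness = rich0))
    m0 <- suppressWarnings(stepwise_fit(ds0, max_shifts = 2))
    if (m0$n_shifts == 0) clean <- clean + 1
  }
  expect_gte(hits, 2)
  expect_gte(clean, 2)
})

test_that("shift rate ML is events over summed internal branch length", {
  expect_equal(shift_rate_mle(tree3(), 0), 0)
  # toy tree with known internal length
  tr <- read_timetree("(((A:2,B:2):3,C:5):5,(D:6,E:6):4);")
  internal_len <- 3 + 5 + 4   # edges ending at internal nodes
  expect_equal(shift_rate_mle(tr, 3), 3 / internal_len)
  # a star tree has zero internal branch length: the estimate is undefined
  expect_error(shift_rate_mle(star_tree(4), 2), "zero")
})

test_that("results serialize to summary tables", {
  ds <- toy_dataset(seed = 23, n_tips = 30)
  m <- stepwise_fit(ds, threshold = Inf)
  jj <- tempfile(fileext = ".json"); tt <- tempfile(fileext = ".tsv")
  row <- write_medusa_result(m, ds, json_path = jj, tsv_path = tt)
  expect_true(file.exists(jj) && file.exists(tt))
  back <- utils::read.delim(tt)
  expect_equal(back$Shifts, 0)
  expect_equal(back$Clades, 30)
  expect_equal(back$N, sum(ds$records$richness))
})
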