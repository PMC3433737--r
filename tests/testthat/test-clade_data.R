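test_that("Newick reading validates timetree invariants", {
  tr <- tree3()
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(max(ape::node.depth.edgelength(tr)), 15)
  expect_error(read_timetree("((A:10,B:-2):5,C:15);"), "negative")
  expect_error(read_timetree("((A:10,B:10):5,C:9);"), "ultrametric")
  expect_silent(read_timetree("((A:10,B:10):5,C:9);",
                              allow_nonultrametric = TRUE))
  expect_error(read_timetree("((A:5,B:5,C:5):10,D:15);"), "polytom")
  poly <- read_timetree("((A:5,B:5,C:5):10,D:15);", resolve_polytomies = TRUE)
  expect_true(ape::is.binary(poly))
  expect_warning(read_timetree("((A:10,B:10)[&&NHX:x=1]:5,C:15);"),
                 "comments")
})

test_that("write-then-read round trip preserves topology and lengths", {
  set.seed(3)
  tr <- generate_timetree(generator_spec(n_tips = 50, seed = 3))
  path <- tempfile(fileext = ".nwk")
  write_timetree(tr, path)
  tr2 <- read_timetree(path)
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = FALSE))
  rel <- abs(sort(tr$edge.length) - sort(tr2$edge.length)) /
    max(tr$edge.length)
  expect_lt(max(rel), 1e-9)
})

test_that("stem age of a tip is the age of its parent node", {
  sa <- stem_ages(tree3())
  expect_equal(sa, c(A = 10, B = 10, C = 15))
  # equals the pendant branch length on an ultrametric tree, and matches an
  # independent node-depth traversal; invariant under tip reordering
  set.seed(5)
  tr <- generate_timetree(generator_spec(n_tips = 50, seed = 5))
  sa <- stem_ages(tr)
  depth <- ape::node.depth.edgelength(tr)
  h <- max(depth[seq_len(50)])
  oracle <- vapply(seq_len(50), function(i) {
    par <- tr$edge[tr$edge[, 2] == i, 1]
    h - depth[par]
  }, numeric(1))
  expect_equal(unname(sa[tr$tip.label]), oracle, tolerance = 1e-12)
  pend <- tr$edge.length[match(seq_len(50), tr$edge[, 2])]
  expect_equal(unname(sa[tr$tip.label]), pend, tolerance = 1e-9)
  rot <- read_timetree(ape::write.tree(ape::rotate(tr, 52)))
  expect_equal(stem_ages(rot)[names(sa)], sa, tolerance = 1e-9)
})

test_that("richness tables are validated row by row", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("name\trichness", "A\t10", "B\t3"), path)
  rec <- load_richness(path)
  expect_equal(nrow(rec), 2)
  expect_equal(sum(rec$richness), 13)
  writeLines(c("name\trichness", "A\t0"), path)
  expect_error(load_richness(path), "rows: 1")
  writeLines(c("name\trichness", "A\t2.5"), path)
  expect_error(load_richness(path), "integer")
  writeLines(c("name\trichness", "A\t2", "A\t3"), path)
  expect_error(load_richness(path), "duplicate")
})

test_that("reconciliation reassigns missing richness to the closest sister", {
  tr <- tree3()
  rec <- data.frame(name = c("A", "C"), richness = c(10, 4))
  out <- reconcile(tr, rec,
                   missing = data.frame(name = "B", richness = 5))
  expect_equal(out$dataset$records$richness[
    out$dataset$records$name == "A"], 15)
  expect_false("B" %in% out$dataset$records$name)
  expect_equal(out$report$merges$to, "A")
  # pruning a cherry member: merged tip keeps the cherry's stem age
  expect_equal(out$dataset$records$stem_age[
    out$dataset$records$name == "A"], 15)
  # total species conserved
  expect_equal(sum(out$dataset$records$richness), 10 + 4 + 5)
})

test_that("reconciliation is the identity on complete records and conserves totals", {
  set.seed(8)
  tr <- generate_timetree(generator_spec(n_tips = 8, seed = 8))
  rec <- data.frame(name = tr$tip.label, richness = 1:8)
  out <- reconcile(tr, rec)
  expect_equal(nrow(out$report$merges), 0)
  expect_equal(out$dataset$records$richness[
    match(tr$tip.label, out$dataset$records$name)], 1:8)
  # nested missing tips: totals conserved
  keepn <- tr$tip.label[1:5]
  rec2 <- data.frame(name = keepn, richness = 1:5)
  miss <- data.frame(name = tr$tip.label[6:8], richness = c(10, 20, 30))
  out2 <- reconcile(tr, rec2, miss, tie_break = "first")
  expect_equal(sum(out2$dataset$records$richness), sum(1:5) + 60)
  # unplaceable names are flagged, not guessed
  out3 <- reconcile(tr, rec2,
                    missing = data.frame(name = "nowhere", richness = 7))
  expect_equal(out3$report$flagged, "nowhere")
  expect_error(reconcile(tr, data.frame(name = "zzz", richness = 1)),
               "no overlap")
})

test_that("dataset summaries report exact totals", {
  ds <- clade_dataset(tree3(),
                      data.frame(name = c("A", "B", "C"),
                                 richness = c(7, 2, 11)))
  s <- summarize_clades(ds)
  expect_identical(s$n_clades, 3L)
  expect_equal(s$total_species, 20)
  expect_equal(s$age_range, c(10, 15))
  ds1 <- clade_dataset(star_tree(3),
                       data.frame(name = paste0("t", 1:3),
                                  richness = c(7, 1, 1)))
  expect_equal(summarize_clades(ds1)$total_species, 9)
  expect_error(clade_dataset(tree3(), data.frame(name = c("A", "B"),
                                                 richness = c(1, 2))),
               "bijection")
})
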