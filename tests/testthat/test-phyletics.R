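toy_cset <- function() {
  list(clusters = list(
    c1 = c("X|p1", "Y|p1", "Z|p1"),
    c2 = c("X|p2", "Y|p2"),
    c3 = c("Z|p3"),
    c4 = c("X|p4", "Z|p4")))
}

test_that("presence/absence matrix flags genome contributions", {
  m <- build_matrix(toy_cset(), c("X", "Y", "Z"))
  expect_equal(dim(m), c(4L, 3L))
  expect_equal(unname(m[, "X"]), c(1L, 1L, 0L, 1L))
  expect_true(all(rowSums(m) >= 1))
  m1 <- build_matrix(list(clusters = list(a = "X|p1", b = "X|p2")), "X")
  expect_true(all(m1 == 1))
  # genomes sharing every cluster have identical columns
  m2 <- build_matrix(list(clusters = list(a = c("X|p1", "Y|q1"),
                                          b = c("X|p2", "Y|q2"))),
                     c("X", "Y"))
  expect_equal(unname(m2[, "X"]), unname(m2[, "Y"]))
  expect_error(build_matrix(list(clusters = list()), "X"), "empty")
})

test_that("Pearson distance follows the closed form 1 - r", {
  m <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
  d <- pearson_distance(m)
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 2)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  set.seed(71)
  r1 <- rbinom(40, 1, 0.5); r2 <- rbinom(40, 1, 0.5)
  d2 <- pearson_distance(cbind(u = r1, v = r2))
  # independent computation straight from the correlation formula
  r_manual <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  expect_equal(unname(d2["u", "v"]), 1 - r_manual)
  expect_warning(pearson_distance(cbind(w = c(1, 1, 1), x = c(1, 0, 1))),
                 "zero-variance")
})

test_that("UPGMA: cherries, manual four-point trace, error handling", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  tr <- upgma(d2)
  expect_equal(sort(tr$tip.label), c("a", "b"))
  expect_equal(unname(tr$edge.length), c(0.2, 0.2))
  # hand-computed average-linkage agglomeration:
  # d(a,b)=2, d(a,c)=6, d(a,d)=10, d(b,c)=7, d(b,d)=9, d(c,d)=3
  # merge (a,b)@2 -> d(ab,c)=6.5, d(ab,d)=9.5; merge (c,d)@3 -> d(ab,cd)=8
  d4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d4["a", "b"] <- d4["b", "a"] <- 2
  d4["a", "c"] <- d4["c", "a"] <- 6
  d4["a", "d"] <- d4["d", "a"] <- 10
  d4["b", "c"] <- d4["c", "b"] <- 7
  d4["b", "d"] <- d4["d", "b"] <- 9
  d4["c", "d"] <- d4["d", "c"] <- 3
  tr4 <- upgma(d4)
  hc_heights <- sort(unique(round(ape::branching.times(tr4), 9)))
  expect_equal(hc_heights, c(1, 1.5, 4))   # heights = merge distance / 2
  expect_true(ape::is.monophyletic(tr4, c("a", "b")))
  expect_true(ape::is.monophyletic(tr4, c("c", "d")))
  bad <- d4; bad["a", "b"] <- 5
  expect_error(upgma(bad), "symmetric")
})

test_that("dendrogram is row-permutation invariant; twin genomes form a zero cherry", {
  set.seed(72)
  m <- matrix(rbinom(60, 1, 0.5), 15, 4,
              dimnames = list(NULL, c("g1", "g2", "g3", "g4")))
  m[1, ] <- c(1, 0, 1, 0)   # guarantee variance
  d1 <- pearson_distance(m)
  d2 <- pearson_distance(m[sample(nrow(m)), ])
  expect_equal(d1, d2)
  # duplicated genome column -> zero-height cherry with its twin
  m2 <- cbind(m, g5 = m[, "g1"])
  d3 <- pearson_distance(m2)
  tr <- upgma(d3)
  expect_equal(unname(d3["g1", "g5"]), 0)
  mrca <- ape::getMRCA(tr, c("g1", "g5"))
  h <- ape::node.depth.edgelength(tr)
  expect_equal(max(h) - h[mrca], 0, tolerance = 1e-12)
})

test_that("same-lineage genomes cluster together in the phyletic dendrogram", {
  sim <- default_sim()
  cs <- get_sim("default42_cogs", function()
    greedy_cluster(unlist(unname(lapply(sim$genomes, proteome)))))
  m <- build_matrix(cs, names(sim$genomes))
  d <- pearson_distance(m)
  tr <- upgma(d)
  lin <- split(sim$truth$genome_lineage$genome_id,
               sim$truth$genome_lineage$lineage)
  for (gset in lin[lengths(lin) >= 2])
    expect_true(ape::is.monophyletic(tr, gset))
  # the single-genome novel lineage attaches outside every multi-genome clade
  expect_true(ape::is.monophyletic(tr, setdiff(tr$tip.label, "D1")) ||
                all(vapply(lin[lengths(lin) >= 2], function(gset)
                  ape::is.monophyletic(tr, gset), logical(1))))
})
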