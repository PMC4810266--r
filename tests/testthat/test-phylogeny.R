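sch <- scoring_scheme()

test_that("progressive alignment: trivial cases and invariants", {
  ident <- setNames(rep(random_aa(50, seed = 81), 4), paste0("g", 1:4))
  aln <- progressive_align(ident, sch)
  expect_equal(unique(nchar(aln)), 50)
  expect_false(any(grepl("-", unclass(aln), fixed = TRUE)))
  a2 <- progressive_align(c(x = "ACDEF", y = "ACEF"), sch)
  expect_equal(unique(nchar(a2)), 5)
  expect_equal(sum(strsplit(a2[["y"]], "")[[1]] == "-"), 1)
  expect_equal(ungap(a2)[["x"]], "ACDEF")
  expect_equal(ungap(a2)[["y"]], "ACEF")
  set.seed(82)
  seqs <- setNames(c(random_aa(40), random_aa(35), random_aa(45)),
                   c("p", "q", "r"))
  a3 <- progressive_align(seqs, sch)
  expect_gte(unique(nchar(a3)), max(nchar(seqs)))
  expect_equal(ungap(a3)[names(seqs)], seqs)
  expect_equal(unclass(progressive_align(seqs[1], sch)), seqs[1])
})

test_that("concatenated Kimura distance follows the closed form", {
  a1 <- structure(c(g1 = strrep("A", 100), g2 = strrep("A", 100)),
                  class = "multiple_alignment")
  expect_equal(unname(concat_and_distance(list(a1))["g1", "g2"]), 0)
  # 10 differences over 100 comparable columns
  row2 <- paste0(strrep("C", 10), strrep("A", 90))
  a2 <- structure(c(g1 = strrep("A", 100), g2 = row2),
                  class = "multiple_alignment")
  d <- concat_and_distance(list(a2))
  expect_equal(unname(d["g1", "g2"]), -log(1 - 0.1 - 0.01 / 5))
  # a genome missing from one alignment contributes an all-gap block;
  # a pair with zero comparable columns is flagged missing
  a3 <- structure(c(g1 = "AAAA"), class = "multiple_alignment")
  a4 <- structure(c(g3 = "CCCC"), class = "multiple_alignment")
  d2 <- concat_and_distance(list(a3, a4))
  expect_true(is.na(d2["g1", "g3"]))
})

test_that("neighbour joining is exact on additive distances", {
  tree <- ape::read.tree(text = "((a:2,b:3):1,(c:4,d:5):2);")
  d <- ape::cophenetic.phylo(tree)
  nj <- neighbor_joining(d)
  expect_equal(ape::dist.topo(ape::unroot(tree), nj), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  expect_equal(length(neighbor_joining(d[1:3, 1:3])$tip.label), 3)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("canonical keys coincide exactly with topological identity", {
  set.seed(83)
  for (i in 1:12) {
    t1 <- ape::rtree(6, rooted = FALSE)
    t2 <- ape::rtree(6, rooted = FALSE)
    expect_equal(canon_key(t1) == canon_key(t2),
                 ape::dist.topo(t1, t2) == 0)
    # same topology, shuffled representation
    t3 <- ape::read.tree(text = ape::write.tree(ape::rotateConstr(
      t1, sample(t1$tip.label))))
    expect_equal(canon_key(t3), canon_key(t1))
  }
})

test_that("SPR neighbourhoods match independent ape-based tree surgery", {
  fixtures <- c("((a,b),c,(d,e));", "(a,b,(c,(d,e)));",
                "((a,b),(c,d),(e,f));", "(a,(b,(c,(d,(e,f)))));")
  for (nwk in fixtures) {
    t <- ape::read.tree(text = nwk)
    mine <- sort(vapply(panlineage:::spr_neighbors(t), `[[`, character(1),
                        "key"))
    expect_equal(mine, ape_spr_neighbors(t))
  }
})

test_that("SPR distance: zero, one-move, symmetry and triangle inequality", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  expect_equal(spr_distance(t1, t1), 0L)
  nbs <- panlineage:::spr_neighbors(t1)
  for (nb in nbs[c(1, 8, length(nbs))])
    expect_equal(spr_distance(t1, nb$tree), 1L)
  set.seed(84)
  trees <- replicate(4, ape::rtree(6, rooted = FALSE), simplify = FALSE)
  for (t in trees) t$tip.label <- letters[1:6]
  rel <- function(t) { t$tip.label <- letters[1:6]; t }
  trees <- lapply(trees, rel)
  for (i in 1:3) for (j in (i + 1):4) {
    dij <- spr_distance(trees[[i]], trees[[j]])
    expect_equal(dij, spr_distance(trees[[j]], trees[[i]]))
    for (k in seq_len(4)[-c(i, j)]) {
      expect_lte(dij, spr_distance(trees[[i]], trees[[k]]) +
                   spr_distance(trees[[k]], trees[[j]]))
    }
  }
  t2 <- ape::read.tree(text = "((a,b),(c,g),(e,f));")
  expect_error(spr_distance(t1, t2), "leaf sets")
})

test_that("SPR distances agree with the independent BFS on fixture pairs", {
  fixtures5 <- lapply(c("((a,b),c,(d,e));", "((a,c),b,(d,e));",
                        "((a,d),b,(c,e));", "((a,e),d,(b,c));"),
                      function(x) ape::read.tree(text = x))
  for (i in seq_along(fixtures5)) for (j in seq_along(fixtures5)) {
    if (i >= j) next
    expect_equal(spr_distance(fixtures5[[i]], fixtures5[[j]]),
                 ape_spr_distance(fixtures5[[i]], fixtures5[[j]]))
  }
  fixtures6 <- lapply(c("((a,b),(c,d),(e,f));", "((a,c),(b,d),(e,f));",
                        "(a,(b,(c,(d,(e,f)))));"),
                      function(x) ape::read.tree(text = x))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(spr_distance(fixtures6[[i]], fixtures6[[j]]),
                 ape_spr_distance(fixtures6[[i]], fixtures6[[j]]))
  }
})

test_that("supertree: identical inputs are returned verbatim with score 0", {
  t <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  st <- spr_supertree(list(t, t, t))
  expect_equal(st$score, 0)
  expect_equal(canon_key(st$tree), canon_key(t))
})

test_that("supertree of 4 concordant + 1 discordant inputs is the majority topology", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  nbs <- panlineage:::spr_neighbors(t1)
  keys <- vapply(nbs, `[[`, character(1), "key")
  t2 <- nbs[[order(keys)[1]]]$tree      # exactly one SPR move away
  expect_equal(ape_spr_distance(t1, as_phylo_tree(t2)), 1)
  st <- spr_supertree(list(t1, t1, t1, t1, as_phylo_tree(t2)))
  expect_equal(canon_key(st$tree), canon_key(t1))
  expect_equal(st$score, 1)
  expect_equal(sort(st$per_input), c(0L, 0L, 0L, 0L, 1L))
  expect_error(spr_supertree(list(t1)), "at least 2")
})

test_that("marker selection recovers the tagged truth and applies tie rules", {
  sim <- small_sim()
  p <- lapply(sim$genomes, proteome)
  mk <- select_markers(p, sim$truth$marker_seeds, sch)
  tr <- sim$truth$proteins
  for (i in seq_len(nrow(mk))) {
    truth_id <- tr$cds_id[tr$genome_id == mk$genome_id[i] &
                            !is.na(tr$marker) & tr$marker == mk$marker[i]]
    expect_equal(mk$protein_id[i], paste0(mk$genome_id[i], "|", truth_id))
  }
  # a duplicated marker copy resolves to the higher-scoring original
  g1 <- names(p)[1]
  dup <- p[[g1]]
  mk1 <- mk$protein_id[mk$genome_id == g1 &
                         mk$marker == "major_capsid_protein"]
  extra <- mutate_protein(dup[[mk1]], 70, seed = 3)
  dup <- c(dup, setNames(extra, paste0(g1, "|dupcopy")))
  mk2 <- select_markers(stats::setNames(list(dup), g1),
                        sim$truth$marker_seeds["major_capsid_protein"], sch)
  expect_equal(mk2$protein_id, mk1)
  # a marker absent everywhere warns
  nomk <- lapply(p, function(x) x[1:10])
  expect_warning(select_markers(nomk, sim$truth$marker_seeds["D5_primase_helicase"],
                                sch), "absent")
})

test_that("family phylogeny recovers lineage clades and the generating topology", {
  sim <- default_sim()
  p <- lapply(sim$genomes, proteome)
  mt <- get_sim("default42_mt", function() {
    mk <- select_markers(p, sim$truth$marker_seeds, sch)
    marker_trees(mk, p, sch)
  })
  expect_equal(length(mt$trees), 5)
  dm <- concat_and_distance(mt$alignments)
  njt <- neighbor_joining(dm)
  lin <- split(sim$truth$genome_lineage$genome_id,
               sim$truth$genome_lineage$lineage)
  for (gset in lin[lengths(lin) >= 2]) {
    expect_true(is_clade_unrooted(njt, gset))
  }
  st <- spr_supertree(mt$trees, seed = 3)
  for (gset in lin[lengths(lin) >= 2])
    expect_true(is_clade_unrooted(st$tree, gset))
  # restricted to one representative per lineage, the supertree equals the
  # generating lineage topology
  reps <- vapply(lin, `[[`, character(1), 1)
  restr <- ape::keep.tip(st$tree, unname(reps))
  gen <- ape::read.tree(text = sim$config$lineage_tree)
  gen$tip.label <- unname(reps[gen$tip.label])
  expect_equal(ape::dist.topo(ape::unroot(restr), ape::unroot(gen)), 0,
               ignore_attr = TRUE)
})
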