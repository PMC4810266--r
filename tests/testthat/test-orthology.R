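sch <- scoring_scheme()

make_hits <- function(q, s, pident, bitscore,
                      evalue = 1e-20, cov = 100) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = 100,
             mismatch = 0, gapopen = 0, qstart = 1, qend = 100, sstart = 1,
             send = 100, evalue = evalue, bitscore = bitscore, qcov = cov,
             scov = cov, stringsAsFactors = FALSE)
}

test_that("identical proteomes give a full RBH set at 100% identity", {
  set.seed(21)
  pa <- setNames(replicate(8, random_aa(80)), paste0("X|p", 1:8))
  pb <- setNames(unname(pa), paste0("Y|p", 1:8))
  ab <- all_vs_all(pa, pb, sch)
  ba <- all_vs_all(pb, pa, sch)
  rbh <- reciprocal_best_hits(ab, ba)
  expect_equal(nrow(rbh), 8)
  expect_true(all(rbh$identity_pct == 100))
  expect_equal(sub("X\\|", "", rbh$protein_a), sub("Y\\|", "", rbh$protein_b))
})

test_that("toy hit tables reproduce the brute-force RBH enumeration", {
  # 5 proteins each side; engineered bests with a sub-threshold distractor
  ab <- rbind(
    make_hits("A|1", "B|1", 80, 200), make_hits("A|1", "B|2", 60, 150),
    make_hits("A|2", "B|2", 70, 180), make_hits("A|3", "B|3", 25, 90),
    make_hits("A|4", "B|4", 55, 120, evalue = 1),    # fails e-value
    make_hits("A|5", "B|5", 90, 300, cov = 30))      # fails coverage
  ba <- rbind(
    make_hits("B|1", "A|1", 80, 200), make_hits("B|2", "A|2", 70, 180),
    make_hits("B|2", "A|1", 60, 150), make_hits("B|3", "A|3", 25, 90),
    make_hits("B|4", "A|4", 55, 120, evalue = 1),
    make_hits("B|5", "A|5", 90, 300, cov = 30))
  rbh <- reciprocal_best_hits(ab, ba)
  # brute force: filter thresholds, per-query argmax, mutual intersection
  th <- orthology_thresholds()
  bf <- function(h) {
    h <- h[h$evalue <= th$evalue & h$pident >= th$identity &
             h$qcov >= th$coverage & h$scov >= th$coverage, ]
    vapply(split(h, h$qseqid), function(x)
      x$sseqid[which.max(x$bitscore)], character(1))
  }
  fa <- bf(ab); fb <- bf(ba)
  expected <- sort(names(fa)[fb[fa] == names(fa)])
  expect_equal(sort(rbh$protein_a), expected)
  expect_equal(nrow(rbh), 2)   # A|1-B|1 and A|2-B|2 survive
})

test_that("RBH is symmetric and bounded by the smaller proteome", {
  sim <- small_sim()
  pa <- proteome(sim$genomes$A1); pb <- proteome(sim$genomes$B1)
  ab <- all_vs_all(pa, pb, sch); ba <- all_vs_all(pb, pa, sch)
  r1 <- reciprocal_best_hits(ab, ba)
  r2 <- reciprocal_best_hits(ba, ab)
  expect_equal(sort(paste(r1$protein_a, r1$protein_b)),
               sort(paste(r2$protein_b, r2$protein_a)))
  expect_lte(nrow(r1), min(length(pa), length(pb)))
  expect_error(reciprocal_best_hits(ab, ab), "same proteome pair")
})

test_that("RBH recovers nearly all true ortholog pairs in the family regime", {
  sim <- default_sim()
  p <- lapply(sim$genomes, proteome)
  for (pair in list(c("A1", "D1"), c("A1", "B1"))) {
    ab <- all_vs_all(p[[pair[1]]], p[[pair[2]]], sch)
    ba <- panlineage:::swap_hits(ab, sum(nchar(p[[pair[1]]])),
                                 setNames(nchar(p[[pair[2]]]),
                                          names(p[[pair[2]]])))
    rbh <- reciprocal_best_hits(ab, ba)
    tp <- true_ortholog_pairs(sim, pair[1], pair[2])
    got <- paste(rbh$protein_a, rbh$protein_b)
    truth <- paste(tp$protein_a, tp$protein_b)
    expect_gte(mean(truth %in% got), 0.95)
  }
})

test_that("paralog families equal graph components on toy graphs", {
  expect_equal(paralog_families(panlineage:::empty_hits()), list())
  # two triangles: {p1,p2,p3} and {p4,p5,p6}
  tri <- function(a, b) rbind(make_hits(a, b, 90, 200),
                              make_hits(b, a, 90, 200))
  h <- rbind(tri("G|p1", "G|p2"), tri("G|p2", "G|p3"), tri("G|p1", "G|p3"),
             tri("G|p4", "G|p5"), tri("G|p5", "G|p6"), tri("G|p4", "G|p6"))
  fams <- paralog_families(h)
  expect_equal(length(fams), 2)
  expect_equal(lapply(fams, `[[`, "members"),
               list(c("G|p1", "G|p2", "G|p3"), c("G|p4", "G|p5", "G|p6")))
  # every member shares a qualifying hit with another member
  for (f in fams) expect_true(all(f$members %in% c(h$qseqid, h$sseqid)))
})

test_that("the largest simulated paralog family is recovered intact", {
  sim <- default_sim()
  g <- "A1"
  p <- proteome(sim$genomes[[g]])
  self <- all_vs_all(p, p, sch)
  fams <- paralog_families(self)
  tr <- sim$truth$proteins
  tr_g <- tr[tr$genome_id == g & !tr$is_orfan, ]
  fam_sizes <- table(tr_g$family)
  largest_true <- max(fam_sizes)
  expect_gte(largest_true, 10)   # the 14-copy family minus possible losses
  detected <- max(lengths(lapply(fams, `[[`, "members")))
  expect_equal(detected, as.integer(largest_true))
})

test_that("ortholog clusters merge RBH and paralog edges with presence flags", {
  rbh <- data.frame(genome_a = c("X", "X"), protein_a = c("X|u", "X|u"),
                    genome_b = c("Y", "Z"), protein_b = c("Y|u", "Z|u"),
                    identity_pct = 90, bitscore = 100,
                    stringsAsFactors = FALSE)
  fam <- list(structure(list(genome_id = "X",
                             members = c("X|u", "X|u2")),
                        class = "paralog_family"))
  allp <- c("X|u", "Y|u", "Z|u", "X|u2", "Y|solo")
  lmap <- data.frame(genome_id = c("X", "Y", "Z"),
                     lineage = c("L1", "L1", "L2"), stringsAsFactors = FALSE)
  ocs <- ortholog_clusters(list(rbh), fam, allp, lineage_map = lmap)
  expect_equal(length(ocs$clusters), 2)   # {X|u,Y|u,Z|u,X|u2} and {Y|solo}
  expect_true(all(ocs$presence[1, ]))
  # zero RBH -> all singletons
  ocs2 <- ortholog_clusters(list(), list(), allp)
  expect_equal(length(ocs2$clusters), length(allp))
  expect_error(
    ortholog_clusters(list(rbh), list(), allp,
                      lineage_map = lmap[1:2, ]), "missing")
})

toy_gene_genome <- function(id, order, strands) {
  n <- length(order)
  feats <- data.frame(cds_id = order, start = seq(1, by = 100,
                                                  length.out = n),
                      end = seq(60, by = 100, length.out = n),
                      strand = strands, wraps_origin = FALSE, protein = "M",
                      stringsAsFactors = FALSE)
  annotated_genome(id, strrep("ACGT", 100 * n / 4 + 25), feats,
                   topology = "circular")
}

toy_rbh <- function(a, b, genes) {
  data.frame(genome_a = a, protein_a = paste0(a, "|", genes),
             genome_b = b, protein_b = paste0(b, "|", genes),
             identity_pct = 99, bitscore = 100, stringsAsFactors = FALSE)
}

test_that("synteny index: identity and full reversal both score 1", {
  genes <- paste0("g", 1:8)
  ga <- toy_gene_genome("a", genes, rep(c("+", "-"), 4))
  gb <- toy_gene_genome("b", genes, rep(c("+", "-"), 4))
  rbh <- toy_rbh("a", "b", genes)
  expect_equal(synteny_index(ga, gb, rbh), 1)
  grev <- toy_gene_genome("b", rev(genes),
                          rev(ifelse(rep(c("+", "-"), 4) == "+", "-", "+")))
  expect_equal(synteny_index(ga, grev, rbh), 1)
  expect_error(synteny_index(ga, gb, rbh[1, , drop = FALSE]), "fewer than 2")
})

test_that("synteny index decreases with accumulated inversions on average", {
  apply_inversions <- function(order, strands, r, seed) {
    set.seed(seed)
    n <- length(order)
    for (k in seq_len(r)) {
      s <- sample.int(n, 1); l <- sample(2:(n %/% 3), 1)
      idx <- ((s - 1 + 0:(l - 1)) %% n) + 1
      order[idx] <- rev(order[idx])
      strands[idx] <- rev(ifelse(strands[idx] == "+", "-", "+"))
    }
    list(order = order, strands = strands)
  }
  genes <- paste0("g", 1:30)
  str0 <- rep(c("+", "-"), 15)
  ga <- toy_gene_genome("a", genes, str0)
  rbh <- toy_rbh("a", "b", genes)
  mean_syn <- function(r) {
    mean(vapply(1:12, function(sd) {
      iv <- apply_inversions(genes, str0, r, seed = 1000 + 37 * sd + r)
      synteny_index(ga, toy_gene_genome("b", iv$order, iv$strands), rbh)
    }, numeric(1)))
  }
  s1 <- mean_syn(1); s4 <- mean_syn(4); s10 <- mean_syn(10)
  expect_gt(s1, s4)
  expect_gt(s4, s10)
})
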