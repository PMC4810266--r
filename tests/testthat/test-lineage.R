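block_matrix <- function(lins, within = 97, between = 65, noise = 0,
                         seed = 1) {
  set.seed(seed)
  ids <- unlist(mapply(function(l, n) paste0(l, seq_len(n)), names(lins),
                       lins, SIMPLIFY = FALSE))
  lab <- rep(names(lins), unlist(lins))
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in 1:n) for (j in 1:n) {
    m[i, j] <- if (i == j) 100
    else if (lab[i] == lab[j]) within + rnorm(1, 0, noise)
    else between + rnorm(1, 0, noise)
  }
  (m + t(m)) / 2
}

test_that("single-linkage AAI grouping: one lineage, outlier, monotonicity", {
  m <- block_matrix(list(L = 4), within = 99, between = 99)
  p1 <- assign_lineages(m)
  expect_equal(p1$n_lineages, 1)

  # the founding-member pattern: one genome below threshold against all
  m2 <- block_matrix(list(A = 3, B = 1), within = 97, between = 66)
  p2 <- assign_lineages(m2)
  expect_equal(p2$n_lineages, 2)
  expect_equal(sum(table(p2$assignment$lineage) == 1), 1)
  expect_true(p2$within_aai_min > p2$between_aai_max)

  # partition count is non-decreasing in the threshold
  m3 <- block_matrix(list(A = 3, B = 2, C = 2), within = 96.5,
                     between = 64, noise = 1, seed = 5)
  counts <- vapply(seq(90, 99, by = 1), function(th)
    assign_lineages(m3, within_threshold = th)$n_lineages, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("lineage assignment is invariant to genome order and handles NA", {
  m <- block_matrix(list(A = 2, B = 2), within = 97, between = 60)
  p1 <- assign_lineages(m)
  perm <- c(3, 1, 4, 2)
  p2 <- assign_lineages(m[perm, perm])
  expect_equal(p1$assignment, p2$assignment)
  m2 <- m; m2["A1", "B1"] <- m2["B1", "A1"] <- NA
  expect_error(assign_lineages(m2), "missing")
  p3 <- assign_lineages(m2, allow_missing = TRUE)
  expect_equal(p3$n_lineages, 2)
})

test_that("lineage recovery is exact across seeds in the calibrated regime", {
  skip_if_not_installed("mclust")
  for (seed in c(101, 202)) {
    sim <- get_sim(paste0("small", seed),
                   function() simulate_family(small_config(seed)))
    p <- lapply(sim$genomes, proteome)
    m <- aai_matrix(p)
    part <- assign_lineages(m)
    truth <- sim$truth$genome_lineage
    ari <- mclust::adjustedRandIndex(
      part$assignment$lineage,
      truth$lineage[match(part$assignment$genome_id, truth$genome_id)])
    expect_equal(ari, 1)
  }
})

test_that("evidence report scores concordance and flags discordance", {
  m <- block_matrix(list(A = 2, B = 2), within = 97, between = 62)
  part <- assign_lineages(m)
  syn_good <- block_matrix(list(A = 2, B = 2), within = 0.9, between = 0.4)
  rep1 <- evidence_report(part, m, synteny = syn_good)
  expect_true(rep1$lines$aai$concordant)
  expect_true(rep1$lines$synteny$concordant)
  expect_true(rep1$verdict)
  expect_true(rep1$novel_lineage)

  # engineered conflict: synteny pattern contradicts the AAI partition
  syn_bad <- block_matrix(list(A = 2, B = 2), within = 0.3, between = 0.9)
  rep2 <- evidence_report(part, m, synteny = syn_bad)
  expect_false(rep2$lines$synteny$concordant)
  # the conflict is reported, not silently overridden
  expect_true(rep2$lines$aai$concordant)

  single <- assign_lineages(block_matrix(list(A = 3), within = 99,
                                         between = 99))
  rep3 <- evidence_report(single, block_matrix(list(A = 3), 99, 99))
  expect_false(rep3$novel_lineage)
})

test_that("a clean simulated family yields a fully concordant report", {
  sim <- default_sim()
  acc <- get_sim("default42_aai", function() {
    p <- lapply(sim$genomes, proteome)
    hits <- family_hits(p)
    list(p = p, hits = hits, m = aai_matrix(p, hits = hits))
  })
  cs <- get_sim("default42_cogs", function()
    greedy_cluster(unlist(unname(lapply(sim$genomes, proteome)))))
  part <- assign_lineages(acc$m)
  truth <- sim$truth$genome_lineage
  expect_equal(part$n_lineages, length(unique(truth$lineage)))

  ids <- names(sim$genomes)
  syn <- matrix(NA_real_, 8, 8, dimnames = list(ids, ids))
  th <- orthology_thresholds()
  rbh_list <- list()
  for (i in 1:7) for (j in (i + 1):8) {
    hp <- pair_hits(acc$hits, ids[i], ids[j])
    r <- reciprocal_best_hits(hp$ab, hp$ba, th)
    rbh_list[[panlineage:::pair_key(ids[i], ids[j])]] <- r
    syn[i, j] <- syn[j, i] <-
      synteny_index(sim$genomes[[ids[i]]], sim$genomes[[ids[j]]], r)
  }
  usage <- lapply(sim$genomes, usage_profile)
  allp <- unlist(lapply(acc$p, names), use.names = FALSE)
  ocs <- ortholog_clusters(rbh_list, list(), allp,
                           lineage_map = part$assignment)
  sharing <- lineage_sharing(ocs, part$assignment)
  curve <- accumulation(cs, ids)
  rep <- evidence_report(part, acc$m, synteny = syn, usage = usage,
                         sharing = sharing, curve = curve)
  expect_equal(rep$n_evaluable, 5)
  expect_equal(rep$n_concordant, 5)
  expect_true(rep$verdict)
})
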