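# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: naive O(mn) dynamic programming in plain R,
# ape-based tree surgery, direct counting.

# Naive affine-gap local alignment, score only. A gap of length L costs
# open + L * extend.
naive_sw_score <- function(a, b, scheme = scoring_scheme()) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  sub <- scheme$matrix
  open <- scheme$gap_open; ext <- scheme$gap_extend
  NEG <- -1e9
  M <- matrix(0, m + 1, n + 1)
  Ix <- matrix(NEG, m + 1, n + 1)
  Iy <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      s <- sub[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + s)
      best <- max(best, M[i, j])
    }
  }
  best
}

random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

# Independent SPR neighbourhood via ape tree surgery: prune every possible
# subtree (leaf set C), regraft on every edge of the remainder. Topology-only;
# all branch lengths set to 1. Returns the set of canonical Newick keys.
ape_spr_neighbors <- function(tree) {
  tree <- ape::unroot(tree)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tips <- tree$tip.label
  n <- length(tips)
  keys <- character(0)
  self <- canon_key(tree)
  subsets <- list()
  for (sz in 1:(n - 3)) {
    cmb <- utils::combn(tips, sz, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  for (C in subsets) {
    # C must form a subtree (clade in some rooting): check it is a split
    rest <- setdiff(tips, C)
    pruned <- tryCatch(ape::keep.tip(tree, rest), error = function(e) NULL)
    if (is.null(pruned)) next
    if (!is_split(tree, C)) next
    # the regrafted subtree keeps its rooting at the original cut point:
    # root the full tree on the remainder side, then extract the clade
    if (length(C) == 1) {
      sub <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                            tip.label = C, edge.length = 1, Nnode = 1L),
                       class = "phylo")
    } else {
      rt <- ape::root(tree, outgroup = rest[1], resolve.root = TRUE)
      sub <- ape::extract.clade(rt, ape::getMRCA(rt, C))
    }
    sub$root.edge <- 1
    pr <- ape::unroot(pruned)
    pr$edge.length <- rep(1, nrow(pr$edge))
    # attach along every edge of the pruned tree
    for (node in pr$edge[, 2]) {
      cand <- tryCatch(
        ape::bind.tree(pr, sub, where = node, position = 0.5),
        error = function(e) NULL)
      if (is.null(cand)) next
      cand <- ape::collapse.singles(ape::unroot(cand))
      if (length(cand$tip.label) != n) next
      k <- canon_key(cand)
      if (k != self) keys <- c(keys, k)
    }
  }
  sort(unique(keys))
}

# is the leaf set C one side of an edge-induced bipartition of `tree`?
is_split <- function(tree, C) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  bp <- ape::prop.part(tree)   # clades w.r.t. internal rooting
  labs <- attr(bp, "labels")
  sets <- lapply(bp, function(i) labs[i])
  all_splits <- c(sets, lapply(sets, function(s) setdiff(labs, s)),
                  as.list(labs), lapply(labs, function(l) setdiff(labs, l)))
  any(vapply(all_splits, setequal, logical(1), y = C))
}

# Independent BFS SPR distance using the ape-based neighbourhood.
ape_spr_distance <- function(t1, t2, max_depth = 4) {
  k1 <- canon_key(t1); k2 <- canon_key(t2)
  if (k1 == k2) return(0L)
  frontier <- list(t1)
  seen <- k1
  for (d in seq_len(max_depth)) {
    nxt <- list()
    for (tr in frontier) {
      for (k in ape_spr_neighbors(tr)) {
        if (k == k2) return(d)
        if (!(k %in% seen)) {
          seen <- c(seen, k)
          nxt[[length(nxt) + 1L]] <- ape::read.tree(text = k)
        }
      }
    }
    frontier <- nxt
  }
  NA_integer_
}

# unrooted monophyly: does the tree contain the split gset | rest?
is_clade_unrooted <- function(tree, gset) {
  out <- setdiff(tree$tip.label, gset)[1]
  rooted <- ape::root(ape::unroot(tree), outgroup = out,
                      resolve.root = TRUE)
  ape::is.monophyletic(rooted, gset)
}

# memoised simulations shared across test files
.sim_cache <- new.env(parent = emptyenv())

small_config <- function(seed, ...) {
  simulation_config(
    seed = seed,
    lineage_tree = "(A:0.18,B:0.22);",
    n_genomes_per_lineage = c(A = 2L, B = 1L),
    ancestral_gene_count = 60L,
    paralog_expansion = list(n_families = 3L, max_copies = 5L),
    orfan_count = 5L,
    ...)
}

get_sim <- function(name, cfg_fun) {
  if (is.null(.sim_cache[[name]])) .sim_cache[[name]] <- cfg_fun()
  .sim_cache[[name]]
}

small_sim <- function(seed = 101) {
  get_sim(paste0("small", seed),
          function() simulate_family(small_config(seed)))
}

default_sim <- function(seed = 42) {
  get_sim(paste0("default", seed),
          function() simulate_family(simulation_config(seed = seed)))
}

# independent greedy oracle: no k-mer index, direct pairwise alignment
oracle_greedy <- function(proteins, identity = 30, coverage = 50,
                          scheme = scoring_scheme()) {
  ord <- order(-nchar(proteins), names(proteins))
  seqs <- proteins[ord]
  reps <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      h <- smith_waterman(seqs[[i]], seqs[[reps[ci]]], scheme)
      if (h$identity_pct >= identity && h$q_cov >= coverage &&
          h$s_cov >= coverage) {
        assign[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, i); assign[i] <- length(reps) }
  }
  unname(split(names(seqs), assign))
}

toy_proteins <- function(seed = 61) {
  set.seed(seed)
  base1 <- random_aa(120); base2 <- random_aa(90)
  c(`X|a1` = base1,
    `X|a2` = mutate_protein(base1, 70, seed = 1),
    `Y|a3` = mutate_protein(base1, 55, seed = 2),
    `Y|b1` = base2,
    `Z|b2` = mutate_protein(base2, 60, seed = 3),
    `Z|c1` = random_aa(100),
    `X|c2` = random_aa(40))
}

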