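# Synthetic genome-family generator.
#
# Emulates a family of ~8 circular dsDNA virus genomes (346-387 kb, ~480
# protein-coding genes) organised in lineages with ~97% within-lineage and
# ~56-73% between-lineage protein identity, lineage-specific gene birth and
# death, ancestral paralogous families (largest 14 copies), per-genome ORFans
# and gene-order inversions. Full truth tables (lineages, gene families,
# ortholog pairs, marker tags, rearrangement log, per-branch substitution
# counts) make every pipeline stage testable without downloads.

# Amino-acid background frequencies (Robinson-Robinson-like).
aa_background <- c(
  A = 0.078, C = 0.019, D = 0.052, E = 0.063, F = 0.039, G = 0.074,
  H = 0.022, I = 0.052, K = 0.057, L = 0.090, M = 0.022, N = 0.041,
  P = 0.052, Q = 0.043, R = 0.051, S = 0.071, T = 0.058, V = 0.064,
  W = 0.013, Y = 0.032)

# Replacement kernel: P(a -> b) proportional to exp(BLOSUM62[a,b]/2), b != a.
# A fixed Dayhoff-like exchangeability table: conservative replacements are
# favoured, as in real protein evolution.
replacement_kernel <- function() {
  if (!is.null(.pkg_cache$repl_kernel)) return(.pkg_cache$repl_kernel)
  sch <- scoring_scheme("BLOSUM62")
  aas <- names(aa_background)
  B <- sch$matrix[aas, aas]
  k <- lapply(aas, function(a) {
    w <- exp(B[a, ] / 2)
    w[a] <- 0
    w / sum(w)
  })
  names(k) <- aas
  .pkg_cache$repl_kernel <- k
  k
}

# mutate a flat character vector of residues: each site changes with
# probability p, replacements drawn from the exchangeability kernel
mutate_chars <- function(chars, p, kernel = replacement_kernel()) {
  if (p <= 0 || length(chars) == 0) return(list(chars = chars, n_sub = 0L))
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit) == 0) return(list(chars = chars, n_sub = 0L))
  cur <- chars[hit]
  for (a in unique(cur)) {
    sel <- hit[cur == a]
    kk <- kernel[[a]]
    chars[sel] <- sample(names(kk), length(sel), replace = TRUE, prob = kk)
  }
  list(chars = chars, n_sub = length(hit))
}

#' Mutate a protein toward a target identity
#'
#' Each site is substituted independently with probability
#' `1 - target_identity/100`; replacements are drawn from a fixed
#' BLOSUM62-derived exchangeability kernel, so the expected fraction of
#' unchanged sites equals the target. No indels are introduced.
#'
#' @param seq A protein string.
#' @param target_identity Percent in `(0, 100]`.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @return The mutated protein string.
#' @export
mutate_protein <- function(seq, target_identity, seed = NULL) {
  stopifnot(target_identity > 0, target_identity <= 100)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  ch <- strsplit(seq, "")[[1]]
  paste(mutate_chars(ch, 1 - target_identity / 100)$chars, collapse = "")
}

random_protein <- function(len) {
  paste(sample(names(aa_background), len, replace = TRUE,
               prob = aa_background), collapse = "")
}

draw_gene_length <- function(n) {
  pmin(pmax(round(stats::rlnorm(n, meanlog = log(195), sdlog = 0.5)),
            34L), 1553L)
}

marker_defaults <- data.frame(
  name = c("DNA_polymerase_B", "D6_D11_helicase", "VV_A18_helicase",
           "D5_primase_helicase", "major_capsid_protein"),
  product = c("DNA polymerase family B", "D6/D11-type helicase",
              "VV A18-type helicase", "D5 primase-helicase",
              "major capsid protein"),
  len = c(1000L, 600L, 550L, 800L, 460L),
  stringsAsFactors = FALSE)

#' Configuration for the genome-family simulator
#'
#' Defaults encode the statistical regime of the Marseilleviridae family:
#' eight genomes in four lineages (A x4, B x1, C x2, D x1), ~480 gene copies
#' per ancestral genome of which ~94 sit in 30 paralogous families (largest
#' 14 copies), 29 ORFans per genome, ~97% within-lineage and ~56-73%
#' between-lineage protein identity, G+C ~43-45%, and a slight excess of
#' minus-strand genes.
#'
#' @param seed Mandatory integer seed.
#' @param lineage_tree Newick over lineage labels; branch lengths are expected
#'   amino-acid substitutions per site between lineage ancestors.
#' @param n_genomes_per_lineage Named integer vector (names = lineage labels).
#' @param ancestral_gene_count Total ancestral gene copies (incl. paralogs).
#' @param gene_birth_rate,gene_death_rate Expected gene gains/losses per unit
#'   branch length.
#' @param within_lineage_target_identity Percent pairwise identity between
#'   genomes of one lineage.
#' @param between_lineage_target_identity_range Two percentages; the implied
#'   between-lineage identities of `lineage_tree` must fall inside this band
#'   (checked at construction).
#' @param paralog_expansion List with `n_families` and `max_copies`.
#' @param orfan_count ORFans (random-composition proteins >= 100 aa with no
#'   homologs) added to every genome.
#' @param inversion_rate Gene-order inversions per unit branch length.
#' @param genome_length_range,gc_target Informative targets used to shape
#'   gene lengths, spacers and codon choice.
#' @param minus_strand_frac Probability a gene lies on the minus strand.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(
    seed,
    lineage_tree = "((A:0.16,B:0.17):0.05,(C:0.15,D:0.21):0.04);",
    n_genomes_per_lineage = c(A = 4L, B = 1L, C = 2L, D = 1L),
    ancestral_gene_count = 480L,
    gene_birth_rate = 60,
    gene_death_rate = 80,
    within_lineage_target_identity = 97,
    between_lineage_target_identity_range = c(56, 73),
    paralog_expansion = list(n_families = 30L, max_copies = 14L),
    orfan_count = 29L,
    inversion_rate = 12,
    genome_length_range = c(346000, 387000),
    gc_target = c(43, 45),
    minus_strand_frac = 0.53) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(gene_birth_rate >= 0, gene_death_rate >= 0, inversion_rate >= 0,
            orfan_count >= 0,
            within_lineage_target_identity > 0,
            within_lineage_target_identity <= 100)
  tr <- ape::read.tree(text = lineage_tree)
  lineages <- tr$tip.label
  if (!all(names(n_genomes_per_lineage) %in% lineages))
    stop("n_genomes_per_lineage names must match lineage_tree tips")
  n_genomes_per_lineage <-
    n_genomes_per_lineage[lineages[lineages %in% names(n_genomes_per_lineage)]]
  # implied between-lineage identities must be reachable / inside the band
  if (length(lineages) > 1) {
    d <- stats::cophenetic(tr)
    w <- within_lineage_target_identity / 100
    implied <- 100 * exp(-d[upper.tri(d)]) * w
    band <- between_lineage_target_identity_range
    if (any(implied < band[1] - 3 | implied > band[2] + 3))
      stop("lineage_tree branch lengths imply between-lineage identities (",
           paste(sprintf("%.1f", range(implied)), collapse = "-"),
           ") outside the configured band")
    if (min(100 * w) <= max(implied))
      stop("within-lineage identity target does not exceed implied ",
           "between-lineage identities")
  }
  depth <- max(ape::node.depth.edgelength(tr))
  if (gene_death_rate * depth > 0.5 * ancestral_gene_count)
    stop("gene_death_rate too high: gene content would collapse before ",
         "identity targets are reached")
  structure(list(
    seed = as.integer(seed), lineage_tree = lineage_tree,
    n_genomes_per_lineage = n_genomes_per_lineage,
    ancestral_gene_count = as.integer(ancestral_gene_count),
    gene_birth_rate = gene_birth_rate, gene_death_rate = gene_death_rate,
    within_lineage_target_identity = within_lineage_target_identity,
    between_lineage_target_identity_range =
      between_lineage_target_identity_range,
    paralog_expansion = paralog_expansion, orfan_count = as.integer(orfan_count),
    inversion_rate = inversion_rate,
    genome_length_range = genome_length_range, gc_target = gc_target,
    minus_strand_frac = minus_strand_frac), class = "simulation_config")
}

# ---- content evolution -----------------------------------------------------

mutate_content <- function(content, p, kernel) {
  if (nrow(content) == 0 || p <= 0) return(list(content = content, n_sub = 0L))
  ch <- strsplit(content$seq, "")
  lens <- lengths(ch)
  flat <- unlist(ch, use.names = FALSE)
  m <- mutate_chars(flat, p, kernel)
  grp <- rep.int(seq_len(nrow(content)), lens)
  content$seq <- vapply(split(m$chars, grp), paste, character(1),
                        collapse = "")
  list(content = content, n_sub = m$n_sub)
}

invert_segment <- function(content, minus_strand_frac) {
  n <- nrow(content)
  if (n < 3) return(list(content = content, start = NA, len = NA))
  s <- sample.int(n, 1)
  l <- sample(2:max(2L, n %/% 3L), 1)
  idx <- ((s - 1L + 0:(l - 1L)) %% n) + 1L
  seg <- content[idx, , drop = FALSE]
  seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  seg$strand <- ifelse(seg$strand == "+", "-", "+")
  content[idx, ] <- seg
  list(content = content, start = s, len = l)
}

evolve_branch <- function(content, t, branch_id, cfg, kernel, log_env) {
  if (t > 0) {
    m <- mutate_content(content, 1 - exp(-t), kernel)
    content <- m$content
    log_env$subs <- rbind(log_env$subs,
                          data.frame(branch = branch_id, length = t,
                                     n_sub = m$n_sub))
  }
  nd <- if (t > 0) stats::rpois(1, cfg$gene_death_rate * t) else 0L
  if (nd > 0) {
    killable <- which(is.na(content$marker))
    kill <- killable[sample.int(length(killable), min(nd, length(killable)))]
    if (length(kill)) {
      log_env$events <- rbind(log_env$events,
                              data.frame(branch = branch_id, event = "death",
                                         detail = content$uid[kill]))
      content <- content[-kill, , drop = FALSE]
    }
  }
  nb <- if (t > 0) stats::rpois(1, cfg$gene_birth_rate * t) else 0L
  if (nb > 0) {
    lens <- draw_gene_length(nb)
    born <- data.frame(
      uid = sprintf("%s.b%02d", branch_id, seq_len(nb)),
      family = sprintf("%s.b%02d", branch_id, seq_len(nb)),
      copy = 1L,
      seq = vapply(lens, random_protein, character(1)),
      strand = ifelse(stats::runif(nb) < cfg$minus_strand_frac, "-", "+"),
      marker = NA_character_, product = "hypothetical protein",
      stringsAsFactors = FALSE)
    for (i in seq_len(nb)) {
      pos <- sample.int(nrow(content) + 1L, 1)
      content <- rbind(content[seq_len(pos - 1L), , drop = FALSE],
                       born[i, , drop = FALSE],
                       content[seq(pos, length.out = nrow(content) - pos + 1L),
                               , drop = FALSE])
    }
    log_env$events <- rbind(log_env$events,
                            data.frame(branch = branch_id, event = "birth",
                                       detail = born$uid))
  }
  ni <- if (t > 0) stats::rpois(1, cfg$inversion_rate * t) else 0L
  for (i in seq_len(ni)) {
    iv <- invert_segment(content, cfg$minus_strand_frac)
    content <- iv$content
    log_env$events <- rbind(log_env$events,
                            data.frame(branch = branch_id,
                                       event = "inversion",
                                       detail = sprintf("start=%s;len=%s",
                                                        iv$start, iv$len)))
  }
  rownames(content) <- NULL
  content
}

# ---- nucleotide emission ---------------------------------------------------

codon_tables <- function() {
  if (!is.null(.pkg_cache$codon_tables)) return(.pkg_cache$codon_tables)
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), code)
  by_aa[["*"]] <- NULL
  gc_count <- vapply(names(code), function(c)
    sum(strsplit(c, "")[[1]] %in% c("G", "C")), numeric(1))
  .pkg_cache$codon_tables <- list(by_aa = by_aa, gc_count = gc_count)
  .pkg_cache$codon_tables
}

# codon weights per aa so that expected coding G+C hits the target
codon_weights_for_gc <- function(gc_frac) {
  ct <- codon_tables()
  exp_gc <- function(beta) {
    per_aa <- vapply(names(aa_background), function(a) {
      cods <- ct$by_aa[[a]]
      w <- exp(-beta * ct$gc_count[cods])
      sum(w / sum(w) * ct$gc_count[cods]) / 3
    }, numeric(1))
    sum(aa_background * per_aa)
  }
  beta <- stats::uniroot(function(b) exp_gc(b) - gc_frac,
                         c(-4, 4), tol = 1e-6)$root
  lapply(ct$by_aa, function(cods) {
    w <- exp(-beta * ct$gc_count[cods])
    stats::setNames(w / sum(w), cods)
  })
}

reverse_translate <- function(aa_chars, weights) {
  out <- character(length(aa_chars))
  for (a in unique(aa_chars)) {
    sel <- which(aa_chars == a)
    w <- weights[[a]]
    out[sel] <- sample(names(w), length(sel), replace = TRUE, prob = w)
  }
  out
}

# base-R reverse complement (hot path: called once per minus-strand gene)
revcomp_str <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
}

content_hash <- function(content) {
  x <- paste(content$uid, substr(content$seq, 1, 8), content$strand,
             collapse = ";")
  sum(utf8ToInt(x) * (seq_along(utf8ToInt(x)) %% 97 + 1)) %% 2000000011
}

emit_genome <- function(genome_id, content, cfg, weights) {
  # emission RNG is a pure function of seed + content: identical gene content
  # always yields an identical GenBank record
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((cfg$seed * 131071 + content_hash(content)) %% .Machine$integer.max)
  n <- nrow(content)
  gc <- mean(cfg$gc_target) / 100
  # batch the reverse translation over the whole proteome, then re-split
  aa_lists <- strsplit(content$seq, "")
  lens <- lengths(aa_lists)
  cods <- reverse_translate(unlist(aa_lists, use.names = FALSE), weights)
  genes_nt <- paste0(
    vapply(split(cods, rep.int(seq_len(n), lens)), paste, character(1),
           collapse = ""), "TAA")
  spacer_len <- stats::rgeom(n, 1 / 21) + 1L
  # intergenic DNA slightly AT-richer than coding, as in real genomes
  gc_nc <- max(gc - 0.011, 0.01)
  sp_flat <- sample(c("G", "C", "A", "T"), sum(spacer_len), replace = TRUE,
                    prob = c(gc_nc / 2, gc_nc / 2,
                             (1 - gc_nc) / 2, (1 - gc_nc) / 2))
  spacers <- vapply(split(sp_flat, rep.int(seq_len(n), spacer_len)), paste,
                    character(1), collapse = "")
  placed_nt <- ifelse(content$strand == "-",
                      vapply(genes_nt, revcomp_str, character(1)), genes_nt)
  pieces <- as.vector(rbind(spacers, placed_nt))
  sequence <- paste(pieces, collapse = "")
  L <- nchar(sequence)
  glen <- nchar(placed_nt)
  # layout: spacer1 gene1 spacer2 gene2 ...
  starts <- as.integer(cumsum(spacer_len) + c(0L, cumsum(glen)[-n]) + 1L)
  ends <- starts + glen - 1L
  # rotate so the origin falls inside the last gene: exercises wrap handling
  rot <- starts[n] + glen[n] %/% 2L
  sequence <- paste0(substr(sequence, rot, L), substr(sequence, 1L, rot - 1L))
  new_start <- ((starts - rot) %% L) + 1L
  new_end <- ((ends - rot) %% L) + 1L
  wraps <- new_start > new_end
  feats <- data.frame(
    cds_id = sprintf("%s_%03d", genome_id, seq_len(n)),
    start = new_start, end = new_end, strand = content$strand,
    wraps_origin = wraps, protein = content$seq, product = content$product,
    stringsAsFactors = FALSE)
  ord <- order(ifelse(wraps, 0L, new_start))  # wrapped gene sorts first
  feats <- feats[ord, , drop = FALSE]
  feats$cds_id <- sprintf("%s_%03d", genome_id, seq_len(n))
  rownames(feats) <- NULL
  list(genome = annotated_genome(genome_id, sequence, feats,
                                 topology = "circular"),
       content_order = content$uid[ord])
}

# ---- main entry ------------------------------------------------------------

#' Simulate a genome family with truth tables
#'
#' Evolves gene content and protein sequences along the configured lineage
#' tree (birth/death of gene families, BLOSUM-kernel substitutions calibrated
#' to the identity targets, gene-order inversions), expands ancestral
#' paralogous families, adds per-genome ORFans, and emits each genome as an
#' [annotated_genome()] (circular, with one origin-spanning CDS and genes on
#' both strands). The same configuration and seed always produce byte-identical
#' genomes.
#'
#' @param cfg A [simulation_config()].
#' @return Object of class `sim_family`: `genomes` (named list of
#'   [annotated_genome()]), `truth` (lineage map, protein/family table, marker
#'   tags and seeds, event log, per-branch substitution counts, per-genome
#'   gene order), `config`.
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  kernel <- replacement_kernel()
  tr <- ape::read.tree(text = cfg$lineage_tree)
  lineages <- tr$tip.label

  # ancestral gene copies: paralogous families first, then singletons
  pe <- cfg$paralog_expansion
  sizes <- integer(0)
  if (pe$n_families > 0) {
    sizes <- c(pe$max_copies, 6L, 5L, 4L,
               rep(3L, 13L), rep(2L, 13L))[seq_len(pe$n_families)]
  }
  n_paralog_copies <- sum(sizes)
  n_singletons <- cfg$ancestral_gene_count - n_paralog_copies
  stopifnot(n_singletons >= 5)
  fam_products <- c("MORN repeat-containing protein",
                    "F-box-containing protein", "restriction endonuclease",
                    "Vsr/MutH/archaeal HJR family endonuclease")
  rows <- list()
  for (j in seq_along(sizes)) {
    fam <- sprintf("P%03d", j)
    len <- draw_gene_length(1)
    seed_seq <- random_protein(len)
    prod <- if (j <= length(fam_products)) fam_products[j]
            else "hypothetical protein"
    for (cp in seq_len(sizes[j])) {
      # copies diverge from the family seed so orthologs outscore paralogs
      rows[[length(rows) + 1L]] <- data.frame(
        uid = sprintf("%s.c%02d", fam, cp), family = fam, copy = cp,
        seq = mutate_protein(seed_seq, 85), strand = NA_character_,
        marker = NA_character_, product = prod, stringsAsFactors = FALSE)
    }
  }
  mk <- marker_defaults
  for (j in seq_len(nrow(mk))) {
    rows[[length(rows) + 1L]] <- data.frame(
      uid = sprintf("M%d.c01", j), family = sprintf("M%d", j), copy = 1L,
      seq = random_protein(mk$len[j]), strand = NA_character_,
      marker = mk$name[j], product = mk$product[j], stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_singletons - nrow(mk))) {
    len <- draw_gene_length(1)
    rows[[length(rows) + 1L]] <- data.frame(
      uid = sprintf("F%04d.c01", j), family = sprintf("F%04d", j), copy = 1L,
      seq = random_protein(len), strand = NA_character_,
      marker = NA_character_, product = "hypothetical protein",
      stringsAsFactors = FALSE)
  }
  ancestor <- do.call(rbind, rows)
  ancestor <- ancestor[sample.int(nrow(ancestor)), , drop = FALSE]
  ancestor$strand <- ifelse(stats::runif(nrow(ancestor)) <
                              cfg$minus_strand_frac, "-", "+")
  rownames(ancestor) <- NULL
  marker_seeds <- stats::setNames(
    ancestor$seq[match(mk$name, ancestor$marker)], mk$name)

  log_env <- new.env()
  log_env$events <- data.frame(branch = character(0), event = character(0),
                               detail = character(0))
  log_env$subs <- data.frame(branch = character(0), length = numeric(0),
                             n_sub = integer(0))

  # evolve lineage ancestors along the tree (preorder)
  nodes <- vector("list", ape::Ntip(tr) + tr$Nnode)
  root <- ape::Ntip(tr) + 1L
  nodes[[root]] <- ancestor
  eo <- ape::reorder.phylo(tr, "cladewise")
  for (e in seq_len(nrow(eo$edge))) {
    par <- eo$edge[e, 1]; child <- eo$edge[e, 2]
    t <- eo$edge.length[e]
    lab <- if (child <= ape::Ntip(tr)) tr$tip.label[child]
           else sprintf("node%d", child)
    nodes[[child]] <- evolve_branch(nodes[[par]], t, lab, cfg, kernel,
                                    log_env)
  }
  if (length(lineages) == 1 && nrow(eo$edge) == 0) nodes[[1L]] <- ancestor

  t_tip <- -log(sqrt(cfg$within_lineage_target_identity / 100))
  base_weights <- codon_weights_for_gc(mean(cfg$gc_target) / 100)
  # lineage-specific codon usage: synonymous-codon preferences drift between
  # lineages (codon signatures), while amino-acid usage stays put
  lineage_weights <- lapply(names(cfg$n_genomes_per_lineage), function(ln) {
    lapply(base_weights, function(w) {
      w2 <- w * exp(stats::rnorm(length(w), sd = 0.25))
      w2 / sum(w2)
    })
  })
  names(lineage_weights) <- names(cfg$n_genomes_per_lineage)

  genomes <- list(); orders <- list()
  prot_truth <- list()
  for (ln in names(cfg$n_genomes_per_lineage)) {
    weights <- lineage_weights[[ln]]
    anc <- nodes[[match(ln, tr$tip.label)]]
    for (gi in seq_len(cfg$n_genomes_per_lineage[[ln]])) {
      gid <- paste0(ln, gi)
      content <- evolve_branch(anc, t_tip, paste0("tip_", gid), cfg, kernel,
                               log_env)
      if (cfg$orfan_count > 0) {
        lens <- pmax(round(stats::runif(cfg$orfan_count, 101, 400)), 101L)
        orf <- data.frame(
          uid = sprintf("%s.o%02d", gid, seq_len(cfg$orfan_count)),
          family = sprintf("%s.o%02d", gid, seq_len(cfg$orfan_count)),
          copy = 1L, seq = vapply(lens, random_protein, character(1)),
          strand = ifelse(stats::runif(cfg$orfan_count) <
                            cfg$minus_strand_frac, "-", "+"),
          marker = NA_character_, product = "ORFan hypothetical protein",
          stringsAsFactors = FALSE)
        pos <- sort(sample.int(nrow(content) + 1L, cfg$orfan_count,
                               replace = TRUE))
        content <- insert_rows(content, orf, pos)
      }
      em <- emit_genome(gid, content, cfg, weights)
      genomes[[gid]] <- em$genome
      orders[[gid]] <- em$content_order
      ord <- match(em$content_order, content$uid)
      prot_truth[[gid]] <- data.frame(
        genome_id = gid, cds_id = em$genome$features$cds_id,
        gene_uid = content$uid[ord], family = content$family[ord],
        copy = content$copy[ord],
        is_orfan = grepl("\\.o\\d+$", content$uid[ord]),
        marker = content$marker[ord], stringsAsFactors = FALSE)
    }
  }

  truth <- list(
    genome_lineage = data.frame(
      genome_id = names(genomes),
      lineage = sub("[0-9]+$", "", names(genomes)),
      stringsAsFactors = FALSE),
    proteins = do.call(rbind, prot_truth),
    marker_seeds = marker_seeds,
    events = log_env$events,
    branch_substitutions = log_env$subs,
    gene_orders = orders)
  structure(list(genomes = genomes, truth = truth, config = cfg),
            class = "sim_family")
}

insert_rows <- function(df, new, pos) {
  # insert new[i,] before original row pos[i]; pos non-decreasing
  out <- df
  for (i in rev(seq_len(nrow(new)))) {
    p <- pos[i]
    out <- rbind(out[seq_len(p - 1L), , drop = FALSE],
                 new[i, , drop = FALSE],
                 out[seq(p, length.out = nrow(out) - p + 1L), ,
                     drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' @export
print.sim_family <- function(x, ...) {
  cat("sim_family:", length(x$genomes), "genomes,",
      length(unique(x$truth$genome_lineage$lineage)), "lineages, seed",
      x$config$seed, "\n")
  invisible(x)
}

#' True ortholog pairs between two simulated genomes
#'
#' Two proteins are true orthologs when they descend from the same ancestral
#' gene copy (identical `gene_uid` in the truth table).
#' @param sim A `sim_family`.
#' @param a,b Genome ids.
#' @return data.frame with `protein_a`, `protein_b` (genome-qualified ids).
#' @export
true_ortholog_pairs <- function(sim, a, b) {
  p <- sim$truth$proteins
  pa <- p[p$genome_id == a & !p$is_orfan, ]
  pb <- p[p$genome_id == b & !p$is_orfan, ]
  m <- merge(pa, pb, by = "gene_uid")
  data.frame(protein_a = paste0(a, "|", m$cds_id.x),
             protein_b = paste0(b, "|", m$cds_id.y),
             stringsAsFactors = FALSE)
}
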