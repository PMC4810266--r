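# Ortholog detection by reciprocal best hits, within-genome paralogous
# families, cross-genome ortholog clusters and an ortholog-adjacency synteny
# index.

#' Default similarity thresholds for orthology
#'
#' E-value at most 1e-5, identity at least 30%, and coverage of both the
#' query and the subject at least 50% (the strict reading: both sequences
#' must be covered).
#' @param evalue,identity,coverage Threshold values.
#' @return Named list.
#' @export
orthology_thresholds <- function(evalue = 1e-5, identity = 30,
                                 coverage = 50) {
  list(evalue = evalue, identity = identity, coverage = coverage)
}

filter_hits <- function(hits, th) {
  hits[hits$evalue <= th$evalue & hits$pident >= th$identity &
         hits$qcov >= th$coverage & hits$scov >= th$coverage, , drop = FALSE]
}

# best hit per query: highest bitscore, ties by higher identity then
# lexicographic subject id
best_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  h <- hits[order(hits$qseqid, -hits$bitscore, -hits$pident, hits$sseqid), ,
            drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

split_pid <- function(ids) {
  pos <- regexpr("|", ids, fixed = TRUE)
  data.frame(genome = substr(ids, 1, pos - 1),
             cds = substr(ids, pos + 1, nchar(ids)),
             stringsAsFactors = FALSE)
}

#' Reciprocal best hits between two proteomes
#'
#' Filters both directed hit tables at the thresholds (filtering precedes
#' best-hit selection), selects each protein's best hit, and keeps the pairs
#' that are mutual. This is the operational definition of bona fide orthologs
#' used throughout: each protein is the other's best-scoring qualifying hit.
#'
#' @param hits_ab,hits_ba Hit tables from [all_vs_all()] for A vs B and
#'   B vs A of the same proteome pair.
#' @param thresholds See [orthology_thresholds()].
#' @return data.frame of class `ortholog_pairs`: `genome_a`, `protein_a`,
#'   `genome_b`, `protein_b`, `identity_pct`, `bitscore`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba,
                                 thresholds = orthology_thresholds()) {
  ga <- unique(split_pid(hits_ab$qseqid)$genome)
  gb <- unique(split_pid(hits_ab$sseqid)$genome)
  ga2 <- unique(split_pid(hits_ba$sseqid)$genome)
  gb2 <- unique(split_pid(hits_ba$qseqid)$genome)
  if (nrow(hits_ab) > 0 && nrow(hits_ba) > 0 &&
      (!setequal(ga, ga2) || !setequal(gb, gb2)))
    stop("hit tables are not from the same proteome pair")
  fa <- best_per_query(filter_hits(hits_ab, thresholds))
  fb <- best_per_query(filter_hits(hits_ba, thresholds))
  key_ab <- paste(fa$qseqid, fa$sseqid)
  key_ba <- paste(fb$sseqid, fb$qseqid)
  keep <- fa[key_ab %in% key_ba, , drop = FALSE]
  pa <- split_pid(keep$qseqid); pb <- split_pid(keep$sseqid)
  out <- data.frame(genome_a = pa$genome, protein_a = keep$qseqid,
                    genome_b = pb$genome, protein_b = keep$sseqid,
                    identity_pct = keep$pident, bitscore = keep$bitscore,
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_a), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_pairs", class(out))
  out
}

# Markov clustering on a weighted adjacency matrix; returns integer cluster
# labels. Plain MCL: add self loops, column-normalise, iterate expansion
# (squaring) and inflation until the matrix is (near) idempotent.
mcl_cluster <- function(adj, inflation = 1.5, max_iter = 100L,
                        tol = 1e-8) {
  n <- nrow(adj)
  if (n == 1) return(1L)
  M <- adj + diag(n)
  M <- sweep(M, 2, colSums(M), "/")
  for (i in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < 1e-12] <- 0
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  # each column is assigned to its dominant attractor row; attractors linked
  # through shared columns merge into one cluster
  owner <- apply(M, 2, which.max)
  comp_g <- igraph::graph_from_edgelist(
    cbind(owner, seq_len(n)), directed = FALSE)
  comp <- igraph::components(comp_g)$membership
  as.integer(factor(comp[seq_len(n)]))
}

#' Within-genome paralogous families
#'
#' Families are connected components of the within-genome qualifying-hit
#' graph, refined by Markov-style clustering (configurable inflation).
#' Singletons are not families.
#'
#' @param self_hits Self-comparison hit table (self-hits already excluded, as
#'   produced by `all_vs_all(p, p)`).
#' @param thresholds See [orthology_thresholds()].
#' @param inflation MCL inflation; higher splits more aggressively.
#' @return List of `paralog_family` objects (`genome_id`, `members`).
#' @export
paralog_families <- function(self_hits,
                             thresholds = orthology_thresholds(),
                             inflation = 1.5) {
  h <- filter_hits(self_hits, thresholds)
  if (nrow(h) == 0) return(list())
  gnm <- unique(split_pid(c(h$qseqid, h$sseqid))$genome)
  if (length(gnm) > 1) stop("self_hits spans more than one genome")
  ids <- sort(unique(c(h$qseqid, h$sseqid)))
  g <- igraph::graph_from_data_frame(h[, c("qseqid", "sseqid")],
                                     directed = FALSE,
                                     vertices = ids)
  comp <- igraph::components(g)$membership
  fams <- list()
  for (cmp in unique(comp)) {
    mem <- names(comp)[comp == cmp]
    if (length(mem) < 2) next
    adj <- matrix(0, length(mem), length(mem),
                  dimnames = list(mem, mem))
    sub <- h[h$qseqid %in% mem & h$sseqid %in% mem, ]
    for (r in seq_len(nrow(sub))) {
      w <- sub$bitscore[r]
      adj[sub$qseqid[r], sub$sseqid[r]] <-
        max(adj[sub$qseqid[r], sub$sseqid[r]], w)
      adj[sub$sseqid[r], sub$qseqid[r]] <- adj[sub$qseqid[r], sub$sseqid[r]]
    }
    lab <- mcl_cluster(adj, inflation = inflation)
    for (l in unique(lab)) {
      m2 <- mem[lab == l]
      if (length(m2) >= 2) {
        fams[[length(fams) + 1L]] <- structure(
          list(genome_id = gnm, members = sort(m2)), class = "paralog_family")
      }
    }
  }
  fams[order(vapply(fams, function(f) f$members[1], character(1)))]
}

#' Cross-genome ortholog clusters
#'
#' Connected components of the union graph whose edges are all pairwise RBH
#' pairs plus within-genome paralog-family co-membership. Unclustered proteins
#' become singleton clusters, so the cluster set partitions the protein
#' universe. When a genome-to-lineage map is supplied, per-lineage presence
#' flags are attached (a cluster is present in a lineage when at least one of
#' that lineage's genomes contributes a protein).
#'
#' @param rbh_list List of [reciprocal_best_hits()] results over all genome
#'   pairs.
#' @param paralog_list List of [paralog_families()] results (possibly empty).
#' @param all_proteins Character vector of every genome-qualified protein id.
#' @param lineage_map Optional data.frame `genome_id`, `lineage`.
#' @return List of class `ortholog_cluster_set`: `clusters` (list of protein
#'   id vectors), `presence` (clusters x lineages logical matrix or NULL).
#' @export
ortholog_clusters <- function(rbh_list, paralog_list = list(),
                              all_proteins, lineage_map = NULL) {
  fams <- if (length(paralog_list) &&
              !inherits(paralog_list[[1]], "paralog_family"))
    unlist(paralog_list, recursive = FALSE) else paralog_list
  edges <- do.call(rbind, c(
    lapply(rbh_list, function(r)
      if (nrow(r)) cbind(r$protein_a, r$protein_b) else NULL),
    lapply(fams, function(f)
      cbind(f$members[-length(f$members)], f$members[-1]))))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_proteins), name = all_proteins)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(matrix(match(edges, all_proteins),
                                       ncol = 2)))
  comp <- igraph::components(g)$membership
  clusters <- split(all_proteins, comp)
  # stable ordering: by size desc, then first member id
  ord <- order(-lengths(clusters),
               vapply(clusters, function(x) sort(x)[1], character(1)))
  clusters <- lapply(clusters[ord], sort)
  names(clusters) <- sprintf("cluster_%04d", seq_along(clusters))
  presence <- NULL
  if (!is.null(lineage_map)) {
    gmap <- stats::setNames(lineage_map$lineage, lineage_map$genome_id)
    lins <- sort(unique(lineage_map$lineage))
    cg <- lapply(clusters, function(x) unique(split_pid(x)$genome))
    if (!all(unlist(cg) %in% names(gmap)))
      stop("genome missing from lineage map")
    presence <- t(vapply(cg, function(gs) lins %in% unique(gmap[gs]),
                         logical(length(lins))))
    colnames(presence) <- lins
  }
  structure(list(clusters = clusters, presence = presence),
            class = "ortholog_cluster_set")
}

#' @export
print.ortholog_cluster_set <- function(x, ...) {
  cat("ortholog_cluster_set:", length(x$clusters), "clusters,",
      sum(lengths(x$clusters)), "proteins\n")
  invisible(x)
}

#' Shared-cluster proportions between and within lineages
#'
#' For each pair of lineages, the fraction of clusters present in either that
#' is present in both (Jaccard on presence flags); the diagonal is defined for
#' lineages with at least two genomes as the fraction of the lineage's
#' clusters shared by all its genomes.
#' @param ocs An [ortholog_clusters()] result with presence flags.
#' @param lineage_map data.frame `genome_id`, `lineage`.
#' @return Symmetric matrix of proportions (diagonal NA for singleton
#'   lineages).
#' @export
lineage_sharing <- function(ocs, lineage_map) {
  if (is.null(ocs$presence)) stop("cluster set has no lineage presence flags")
  lins <- colnames(ocs$presence)
  m <- matrix(NA_real_, length(lins), length(lins),
              dimnames = list(lins, lins))
  for (i in seq_along(lins)) for (j in seq_along(lins)) {
    if (i == j) {
      gs <- lineage_map$genome_id[lineage_map$lineage == lins[i]]
      if (length(gs) < 2) next
      inall <- vapply(ocs$clusters, function(x)
        all(gs %in% unique(split_pid(x)$genome)), logical(1))
      inany <- vapply(ocs$clusters, function(x)
        any(gs %in% unique(split_pid(x)$genome)), logical(1))
      m[i, j] <- sum(inall) / sum(inany)
    } else {
      pi <- ocs$presence[, lins[i]]; pj <- ocs$presence[, lins[j]]
      m[i, j] <- sum(pi & pj) / sum(pi | pj)
    }
  }
  m
}

#' Ortholog-adjacency synteny index
#'
#' A lightweight stand-in for whole-genome alignment synteny: the fraction of
#' adjacent ortholog pairs in genome `a` (circular gene order by forward-
#' strand CDS start, restricted to genes with an RBH partner) that are also
#' adjacent in genome `b` with consistent relative orientation. 1.0 for
#' identical gene orders and for a full reversal (adjacency and relative
#' orientation are both preserved); decreases with accumulated inversions.
#'
#' @param genome_a,genome_b [annotated_genome()] objects.
#' @param rbh [reciprocal_best_hits()] pairs for the two genomes.
#' @return A value in `[0, 1]`.
#' @export
synteny_index <- function(genome_a, genome_b, rbh) {
  if (nrow(rbh) < 2) stop("synteny index undefined for fewer than 2 RBH pairs")
  ord_a <- genome_a$features$cds_id[order(genome_a$features$start)]
  ord_b <- genome_b$features$cds_id[order(genome_b$features$start)]
  str_a <- stats::setNames(genome_a$features$strand, genome_a$features$cds_id)
  str_b <- stats::setNames(genome_b$features$strand, genome_b$features$cds_id)
  pa <- split_pid(rbh$protein_a)$cds
  pb <- split_pid(rbh$protein_b)$cds
  map <- stats::setNames(pb, pa)
  a_genes <- ord_a[ord_a %in% pa]
  b_genes <- ord_b[ord_b %in% pb]
  n <- length(a_genes)
  if (n < 2) stop("synteny index undefined for fewer than 2 shared orthologs")
  b_pos <- stats::setNames(seq_along(b_genes), b_genes)
  nb <- length(b_genes)
  conserved <- 0L
  for (i in seq_len(n)) {
    g1 <- a_genes[i]; g2 <- a_genes[if (i == n) 1L else i + 1L]
    p1 <- map[[g1]]; p2 <- map[[g2]]
    d <- (b_pos[[p2]] - b_pos[[p1]]) %% nb
    adjacent <- d == 1L || d == nb - 1L
    if (!adjacent) next
    same_a <- str_a[[g1]] == str_a[[g2]]
    same_b <- str_b[[p1]] == str_b[[p2]]
    if (same_a == same_b) conserved <- conserved + 1L
  }
  conserved / n
}

#' Write ortholog clusters as OrthoMCL-style groups text
#' @param ocs An [ortholog_clusters()] result.
#' @param path Output path; one line per cluster,
#'   `cluster_0001: gA|p12 gB|p7 ...`.
#' @export
write_cluster_groups <- function(ocs, path) {
  lines <- vapply(seq_along(ocs$clusters), function(i)
    paste0(names(ocs$clusters)[i], ": ",
           paste(ocs$clusters[[i]], collapse = " ")), character(1))
  writeLines(lines, path)
  invisible(path)
}
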