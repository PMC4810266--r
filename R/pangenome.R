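# Greedy protein clustering into clusters of orthologous groups (COGs) and
# pan-/core-genome accumulation under stepwise genome inclusion.

#' Greedy centroid clustering of proteins into COGs
#'
#' BLASTclust-style clustering: proteins are sorted by decreasing length
#' (ties by id), and each protein joins the first existing cluster whose
#' representative (its founding, longest member) it matches at the identity
#' and coverage thresholds, otherwise it founds a new cluster. Deterministic
#' by construction. The k-mer prefilter restricts which representatives are
#' aligned; disable it (`prefilter = FALSE`) for exhaustive comparison.
#'
#' @param proteins Named character vector of genome-qualified proteins
#'   (`"genome|cds"`), possibly from several genomes.
#' @param identity,coverage Thresholds in percent; coverage applies to both
#'   the member and the representative.
#' @param scheme A [scoring_scheme()].
#' @param prefilter,k,min_shared See [kmer_prefilter()].
#' @return List of class `gene_cluster_set`: `clusters` (named list of member
#'   id vectors), `representative` (named character), `n_genomes` per cluster.
#' @export
greedy_cluster <- function(proteins, identity = 30, coverage = 50,
                           scheme = scoring_scheme(), prefilter = TRUE,
                           k = 5L, min_shared = 2L) {
  if (length(proteins) == 0) stop("no proteins to cluster")
  ord <- order(-nchar(proteins), names(proteins))
  seqs <- proteins[ord]
  ids <- names(seqs)
  n <- length(seqs)
  rep_idx <- integer(0)           # indices (into seqs) of representatives
  assign_to <- integer(n)         # cluster id per protein
  is_rep <- logical(n)
  cluster_of <- integer(n)        # cluster id of each representative index
  neighbors <- NULL
  if (prefilter) {
    # one-shot candidate graph: pairs sharing enough k-mers, in length order
    pf <- kmer_prefilter(seqs, seqs, k = k, min_shared = min_shared)
    pf <- pf[pf$q != pf$s, , drop = FALSE]
    neighbors <- split(pf$s, factor(pf$q, levels = seq_len(n)))
  }
  for (i in seq_len(n)) {
    cand <- if (prefilter) {
      nb <- neighbors[[i]]
      nb[is_rep[nb]]
    } else {
      rep_idx
    }
    placed <- FALSE
    if (length(cand)) {
      # try candidate representatives in founding order, stopping at the
      # first qualifying match ("joins the first cluster that matches")
      cand <- cand[order(cluster_of[cand])]
      for (cc in cand) {
        r <- sw_raw(unname(seqs[i]), unname(seqs[cc]), scheme)
        pid <- if (r$aln_len > 0) 100 * r$matches / r$aln_len else 0
        qc <- 100 * (r$qend - r$qstart + 1) / nchar(seqs[i])
        sc <- 100 * (r$send - r$sstart + 1) / nchar(seqs[cc])
        if (pid >= identity && qc >= coverage && sc >= coverage) {
          assign_to[i] <- cluster_of[cc]
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      is_rep[i] <- TRUE
      cluster_of[i] <- length(rep_idx)
      assign_to[i] <- cluster_of[i]
    }
  }
  clusters <- split(ids, assign_to)
  names(clusters) <- sprintf("COG_%04d", seq_along(clusters))
  reps <- stats::setNames(ids[rep_idx], names(clusters))
  n_genomes <- vapply(clusters, function(x)
    length(unique(split_pid(x)$genome)), integer(1))
  structure(list(clusters = clusters, representative = reps,
                 n_genomes = n_genomes), class = "gene_cluster_set")
}

#' @export
print.gene_cluster_set <- function(x, ...) {
  cat("gene_cluster_set:", length(x$clusters), "COGs over",
      sum(lengths(x$clusters)), "proteins\n")
  invisible(x)
}

cluster_genomes <- function(clusters) {
  lapply(clusters, function(x) unique(split_pid(x)$genome))
}

#' Pan-/core-genome accumulation curve
#'
#' Stepwise genome inclusion: at step k the pan-genome is the number of
#' clusters with at least one protein from genomes 1..k, the core genome the
#' number of clusters with a protein from every one of genomes 1..k.
#' Increments and decrements are first differences.
#'
#' @param cset A [greedy_cluster()] result (or any object with `clusters`).
#' @param inclusion_order Character vector of genome ids, each of which must
#'   have contributed proteins to the clustering.
#' @return data.frame of class `pan_core_curve`: `step`, `genome`, `pan`,
#'   `core`, `d_pan`, `d_core`.
#' @export
accumulation <- function(cset, inclusion_order) {
  cg <- cluster_genomes(cset$clusters)
  all_gen <- unique(unlist(cg))
  unknown <- setdiff(inclusion_order, all_gen)
  if (length(unknown))
    stop("genomes absent from clustering: ", paste(unknown, collapse = ", "))
  K <- length(inclusion_order)
  pan <- core <- integer(K)
  for (s in seq_len(K)) {
    gs <- inclusion_order[seq_len(s)]
    inak <- vapply(cg, function(x) any(gs %in% x), logical(1))
    inall <- vapply(cg, function(x) all(gs %in% x), logical(1))
    pan[s] <- sum(inak); core[s] <- sum(inall)
  }
  out <- data.frame(step = seq_len(K), genome = inclusion_order,
                    pan = pan, core = core,
                    d_pan = c(pan[1], diff(pan)),
                    d_core = c(0L, diff(core)))
  class(out) <- c("pan_core_curve", class(out))
  out
}

#' Core-gene ratio per genome
#'
#' For each genome, the number of clusters shared by every genome of the set
#' (and containing that genome's proteins) divided by the genome's own number
#' of distinct clusters — the intra/inter-group core-to-content ratio.
#' @param cset A cluster set.
#' @param genome_set Genome ids defining the core.
#' @return Named numeric vector over `genome_set`.
#' @export
core_ratio <- function(cset, genome_set) {
  cg <- cluster_genomes(cset$clusters)
  core <- vapply(cg, function(x) all(genome_set %in% x), logical(1))
  vapply(genome_set, function(g) {
    own <- vapply(cg, function(x) g %in% x, logical(1))
    if (!any(own)) return(NA_real_)
    sum(core & own) / sum(own)
  }, numeric(1))
}

#' Write clusters in BLASTclust-style line format and the curve as TSV
#' @param cset A [greedy_cluster()] result.
#' @param path Output path (one cluster per line, space-separated ids).
#' @export
write_blastclust <- function(cset, path) {
  writeLines(vapply(cset$clusters, paste, character(1), collapse = " "),
             path)
  invisible(path)
}

#' @rdname write_blastclust
#' @param curve An [accumulation()] result.
#' @export
write_curve_tsv <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
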