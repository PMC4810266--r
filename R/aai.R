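# Average amino-acid identity (AAI) between genome pairs: the central
# lineage-delineation statistic. Two-way AAI averages the alignment
# identities of reciprocal best hits; one-way AAI averages per-query best
# hits and is generally asymmetric.

aai_result <- function(genome_a, genome_b, mode, identities) {
  structure(list(genome_a = genome_a, genome_b = genome_b, mode = mode,
                 n_pairs = length(identities),
                 mean_identity = mean(identities),
                 median_identity = stats::median(identities),
                 sd_identity = stats::sd(identities)),
            class = "aai_result")
}

#' @export
print.aai_result <- function(x, ...) {
  cat(sprintf("AAI %s ~ %s [%s]: mean %.1f%%, median %.1f%% over %d pairs\n",
              x$genome_a, x$genome_b, x$mode, x$mean_identity,
              x$median_identity, x$n_pairs))
  invisible(x)
}

#' Two-way AAI from reciprocal best hits
#'
#' Unweighted mean and median of the alignment-level identities of the RBH
#' pairs. Exactly symmetric in the two genomes. A pair with zero qualifying
#' orthologs is an error, never a silent 0.
#' @param rbh A [reciprocal_best_hits()] result with at least one pair.
#' @return An `aai_result` (`mode = "two_way"`).
#' @export
two_way_aai <- function(rbh) {
  if (nrow(rbh) == 0)
    stop("no ortholog pairs: two-way AAI is undefined for this genome pair")
  aai_result(rbh$genome_a[1], rbh$genome_b[1], "two_way", rbh$identity_pct)
}

#' One-way AAI from best hits
#'
#' Mean identity over each query's best qualifying hit (no reciprocity
#' requirement). Directional: `one_way_aai(hits_ab)` and
#' `one_way_aai(hits_ba)` generally differ.
#' @param hits A directed hit table from [all_vs_all()].
#' @param thresholds See [orthology_thresholds()]; the same thresholds as RBH
#'   by default.
#' @return An `aai_result` (`mode = "one_way"`).
#' @export
one_way_aai <- function(hits, thresholds = orthology_thresholds()) {
  h <- best_per_query(filter_hits(hits, thresholds))
  if (nrow(h) == 0)
    stop("no qualifying best hits: one-way AAI is undefined")
  pa <- split_pid(h$qseqid); pb <- split_pid(h$sseqid)
  aai_result(pa$genome[1], pb$genome[1], "one_way", h$pident)
}

#' Two-way AAI matrix over a genome set
#'
#' Computes all pairwise two-way AAIs. The diagonal is 100; pairs with zero
#' qualifying RBH are reported as `NA` (missing), never as 0. The companion
#' `n_pairs` matrix is attached as an attribute.
#'
#' @param proteomes Named list of genome-qualified proteomes (see
#'   [proteome()]).
#' @param scheme A [scoring_scheme()].
#' @param thresholds See [orthology_thresholds()].
#' @param hits Optional precomputed pair hits from [family_hits()] to avoid
#'   realignment.
#' @return Symmetric numeric matrix with `n_pairs` attribute.
#' @export
aai_matrix <- function(proteomes, scheme = scoring_scheme(),
                       thresholds = orthology_thresholds(), hits = NULL) {
  ids <- names(proteomes)
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  np <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  diag(np) <- vapply(proteomes, length, integer(1))
  if (n < 2) return(structure(m, n_pairs = np))
  if (is.null(hits)) hits <- family_hits(proteomes, scheme)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    hp <- hits$cross[[pair_key(ids[i], ids[j])]]
    rbh <- reciprocal_best_hits(hp$ab, hp$ba, thresholds)
    if (nrow(rbh) == 0) next
    a <- two_way_aai(rbh)
    m[i, j] <- m[j, i] <- a$mean_identity
    np[i, j] <- np[j, i] <- a$n_pairs
  }
  structure(m, n_pairs = np)
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "||")

#' All-vs-all hits for every genome pair of a family
#'
#' Runs [all_vs_all()] once per unordered genome pair (emitting both
#' directions; the alignment is computed once and the roles swapped) and per
#' genome against itself (for paralog detection).
#' @param proteomes Named list of proteomes.
#' @param scheme A [scoring_scheme()].
#' @param ... Passed to [all_vs_all()].
#' @return List with `cross` (keyed `"A||B"`, each `list(ab, ba)`) and `self`
#'   (keyed by genome).
#' @export
family_hits <- function(proteomes, scheme = scoring_scheme(), ...) {
  ids <- names(proteomes)
  cross <- list()
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      a <- proteomes[[i]]; b <- proteomes[[j]]
      ab <- all_vs_all(a, b, scheme, ...)
      ba <- swap_hits(ab, sum(nchar(a)), stats::setNames(nchar(b), names(b)))
      cross[[pair_key(ids[i], ids[j])]] <-
        if (ids[i] <= ids[j]) list(ab = ab, ba = ba)
        else list(ab = ba, ba = ab)
    }
  }
  self <- lapply(proteomes, function(p) all_vs_all(p, p, scheme, ...))
  list(cross = cross, self = self)
}

#' Fetch the directed hit tables for a genome pair
#'
#' Convenience accessor into a [family_hits()] result: returns the tables
#' oriented as `a` vs `b` regardless of key order.
#' @param hits A [family_hits()] result.
#' @param a,b Genome ids.
#' @return `list(ab, ba)` of directed hit tables.
#' @export
pair_hits <- function(hits, a, b) {
  hp <- hits$cross[[pair_key(a, b)]]
  if (is.null(hp)) stop("no hits stored for pair ", a, " / ", b)
  if (a <= b) list(ab = hp$ab, ba = hp$ba) else list(ab = hp$ba, ba = hp$ab)
}

#' Write an AAI matrix (and long-format per-pair table) as TSV
#' @param m Matrix from [aai_matrix()].
#' @param path Matrix output path.
#' @param long_path Optional long-format path (`genome_a`, `genome_b`,
#'   `n_pairs`, `mean`).
#' @export
write_aai_tsv <- function(m, path, long_path = NULL) {
  utils::write.table(round(m, 3), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  if (!is.null(long_path)) {
    np <- attr(m, "n_pairs")
    idx <- which(upper.tri(m), arr.ind = TRUE)
    df <- data.frame(genome_a = rownames(m)[idx[, 1]],
                     genome_b = colnames(m)[idx[, 2]],
                     n_pairs = np[idx], mean = m[idx])
    utils::write.table(df, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
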