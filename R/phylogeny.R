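# Core-gene phylogeny: marker selection, progressive multiple alignment,
# concatenated Kimura-corrected protein distances, neighbour-joining, and
# per-gene trees feeding the SPR supertree.

#' Select single-copy marker genes across genomes
#'
#' For each marker seed sequence (e.g. the five Megavirales core genes:
#' family B DNA polymerase, D6/D11 helicase, VV A18 helicase, D5
#' primase-helicase, major capsid protein), finds each genome's best
#' qualifying hit. Duplicate copies resolve to the higher bit score, ties to
#' the longer protein. Absences are recorded; a marker missing from more than
#' half the genomes raises a warning.
#'
#' @param proteomes Named list of genome-qualified proteomes.
#' @param marker_seeds Named character vector of reference marker proteins.
#' @param scheme A [scoring_scheme()].
#' @param thresholds See [orthology_thresholds()].
#' @return data.frame `marker`, `genome_id`, `protein_id` (NA when absent),
#'   `bitscore`.
#' @export
select_markers <- function(proteomes, marker_seeds,
                           scheme = scoring_scheme(),
                           thresholds = orthology_thresholds()) {
  out <- list()
  for (g in names(proteomes)) {
    p <- proteomes[[g]]
    hits <- all_vs_all(marker_seeds, p, scheme)
    hits <- filter_hits(hits, thresholds)
    for (mk in names(marker_seeds)) {
      h <- hits[hits$qseqid == mk, , drop = FALSE]
      if (nrow(h)) {
        h <- h[order(-h$bitscore, -nchar(p[h$sseqid]), h$sseqid), ,
               drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          marker = mk, genome_id = g, protein_id = h$sseqid[1],
          bitscore = h$bitscore[1], stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          marker = mk, genome_id = g, protein_id = NA_character_,
          bitscore = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  absent <- tapply(is.na(res$protein_id), res$marker, mean)
  for (mk in names(absent)[absent > 0.5])
    warning("marker ", mk, " absent from more than half the genomes")
  res
}

aln_profile <- function(rows, alphabet) {
  # columns x residues frequency matrix; gaps contribute nothing
  L <- nchar(rows[1])
  m <- matrix(0, nrow = L, ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  for (r in rows) {
    ch <- strsplit(r, "")[[1]]
    ok <- ch != "-"
    idx <- match(ch[ok], alphabet)
    keep <- !is.na(idx)
    w <- which(ok)[keep]
    for (i in seq_along(w)) m[w[i], idx[i]] <- m[w[i], idx[i]] + 1
  }
  m / length(rows)
}

merge_alignments <- function(rows_a, rows_b, scheme) {
  alpha <- scheme$alphabet
  pa <- aln_profile(rows_a, alpha)
  pb <- aln_profile(rows_b, alpha)
  S <- pa %*% scheme$matrix %*% t(pb)
  path <- .nw_profile_cpp(S, scheme$gap_open, scheme$gap_extend)
  expand <- function(rows, idx) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      paste(ifelse(idx == 0L, "-", ch[pmax(idx, 1L)]), collapse = "")
    }, character(1), USE.NAMES = TRUE)
  }
  c(expand(rows_a, path$a), expand(rows_b, path$b))
}

#' Progressive multiple alignment (MSA-lite)
#'
#' A deterministic progressive aligner: a k-mer-distance guide tree (UPGMA)
#' orders profile-profile merges; each merge is a global affine-gap dynamic
#' programme over average-of-pairs BLOSUM62 column scores. Adequate for the
#' highly similar core-gene sets this package aligns; it makes no claim to
#' match dedicated MSA tools on deep alignments.
#'
#' @param seqs Named character vector of proteins (>= 1).
#' @param scheme A [scoring_scheme()].
#' @param k Word size for guide-tree distances.
#' @return Object of class `multiple_alignment`: named character vector of
#'   equal-length aligned rows (`-` gaps), in input order.
#' @export
progressive_align <- function(seqs, scheme = scoring_scheme(), k = 3L) {
  if (length(seqs) == 0) stop("no sequences")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  if (length(seqs) == 1)
    return(structure(seqs, class = "multiple_alignment"))
  if (length(seqs) == 2) {
    rows <- merge_alignments(seqs[1], seqs[2], scheme)
    return(structure(rows[names(seqs)], class = "multiple_alignment"))
  }
  kt <- kmer_table(seqs, k)
  sets <- split(kt$kmer, kt$id)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sets[[as.character(i)]]; b <- sets[[as.character(j)]]
    jac <- length(intersect(a, b)) / length(union(a, b))
    d[i, j] <- d[j, i] <- 1 - jac
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  groups <- as.list(names(seqs))
  aligned <- lapply(seqs, identity)
  names(aligned) <- names(seqs)
  merged <- vector("list", nrow(hc$merge))
  get_rows <- function(ref) {
    if (ref < 0) stats::setNames(seqs[-ref], names(seqs)[-ref])
    else merged[[ref]]
  }
  for (s in seq_len(nrow(hc$merge))) {
    ra <- get_rows(hc$merge[s, 1])
    rb <- get_rows(hc$merge[s, 2])
    merged[[s]] <- merge_alignments(ra, rb, scheme)
  }
  rows <- merged[[nrow(hc$merge)]]
  structure(rows[names(seqs)], class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("multiple_alignment:", length(x), "sequences x", nchar(x[1]),
      "columns\n")
  invisible(x)
}

#' Ungap an aligned row
#' @param x A `multiple_alignment` or character vector of aligned rows.
#' @return Character vector without gap characters.
#' @export
ungap <- function(x) gsub("-", "", unclass(x), fixed = TRUE)

#' Concatenated Kimura-corrected distance matrix from gene alignments
#'
#' Alignments are concatenated column-wise over the union genome set (a
#' genome missing from an alignment contributes an all-gap block). For each
#' genome pair, `p` is the fraction of differing positions among columns
#' where both rows are ungapped, corrected as `d = -ln(1 - p - p^2/5)`
#' (Kimura's protein-distance approximation). Pairs with no comparable
#' columns, or with `p` beyond the correction's domain, are `NA` (flagged
#' missing).
#'
#' @param alignments List of `multiple_alignment` objects whose names are
#'   genome ids.
#' @return Symmetric distance matrix over the union genome set.
#' @export
concat_and_distance <- function(alignments) {
  stopifnot(length(alignments) >= 1)
  genomes <- sort(unique(unlist(lapply(alignments, names))))
  blocks <- lapply(alignments, function(a) {
    L <- nchar(a[[1]])
    full <- stats::setNames(rep(strrep("-", L), length(genomes)), genomes)
    full[names(a)] <- unclass(a)
    full
  })
  concat <- vapply(genomes, function(g)
    paste(vapply(blocks, `[[`, character(1), g), collapse = ""),
    character(1))
  chars <- lapply(concat, function(s) strsplit(s, "")[[1]])
  n <- length(genomes)
  d <- matrix(0, n, n, dimnames = list(genomes, genomes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- chars[[i]]; b <- chars[[j]]
    comp <- a != "-" & b != "-"
    nc <- sum(comp)
    if (nc == 0) { d[i, j] <- d[j, i] <- NA_real_; next }
    p <- sum(a[comp] != b[comp]) / nc
    arg <- 1 - p - p^2 / 5
    d[i, j] <- d[j, i] <- if (arg <= 0) NA_real_ else -log(arg)
  }
  d
}

#' Neighbour-joining tree with deterministic conventions
#'
#' Canonical NJ (via ape) on a symmetric distance matrix, with taxa ordered
#' by label beforehand and negative branch lengths clamped to zero. Exact on
#' additive matrices.
#' @param d Symmetric distance matrix, >= 3 taxa, no missing entries.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbour joining needs at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (anyNA(d)) stop("distance matrix has missing entries")
  ord <- order(rownames(d))
  tr <- ape::nj(stats::as.dist(d[ord, ord]))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Per-marker gene trees and helpers for the core-gene phylogeny
#'
#' Builds, for each marker, the alignment of its selected proteins and the
#' NJ tree of Kimura distances. Genomes lacking a marker are pruned from
#' that marker's tree (default) or retained as all-gap rows.
#'
#' @param markers [select_markers()] result.
#' @param proteomes Named list of proteomes.
#' @param scheme A [scoring_scheme()].
#' @param prune_missing Drop genomes lacking the marker (default TRUE).
#' @return List with `alignments` (per marker) and `trees` (per marker,
#'   NULL when fewer than 3 genomes carry the marker).
#' @export
marker_trees <- function(markers, proteomes, scheme = scoring_scheme(),
                         prune_missing = TRUE) {
  alns <- list(); trees <- list()
  for (mk in unique(markers$marker)) {
    sel <- markers[markers$marker == mk & !is.na(markers$protein_id), ,
                   drop = FALSE]
    if (nrow(sel) == 0) next
    seqs <- stats::setNames(
      vapply(seq_len(nrow(sel)), function(i)
        proteomes[[sel$genome_id[i]]][[sel$protein_id[i]]], character(1)),
      sel$genome_id)
    aln <- progressive_align(seqs, scheme)
    alns[[mk]] <- aln
    if (length(seqs) >= 3) {
      dm <- concat_and_distance(list(aln))
      if (!anyNA(dm)) trees[[mk]] <- neighbor_joining(dm)
    }
  }
  list(alignments = alns, trees = trees)
}

#' Write a multiple alignment as aligned FASTA
#' @param aln A `multiple_alignment`.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(unclass(aln)), path)
  invisible(path)
}
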