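# Phyletic presence/absence profiles over gene clusters and
# Pearson-distance hierarchical clustering.

#' Presence/absence matrix of gene clusters across genomes
#'
#' Cell is 1 iff the genome contributes at least one protein to the cluster.
#' Any cluster membership can be supplied (in-package COGs by default, or an
#' external catalogue such as NCVOG assignments read from TSV).
#'
#' @param cset A cluster set (e.g. [greedy_cluster()] or
#'   [ortholog_clusters()]).
#' @param genomes Character vector of genome ids (matrix columns).
#' @return Binary matrix, rows = clusters, columns = genomes; every row has
#'   at least one 1.
#' @export
build_matrix <- function(cset, genomes) {
  if (length(cset$clusters) == 0) stop("empty cluster set")
  cg <- cluster_genomes(cset$clusters)
  m <- vapply(genomes, function(g)
    as.integer(vapply(cg, function(x) g %in% x, logical(1))),
    integer(length(cg)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(cg))
  dimnames(m) <- list(names(cset$clusters), genomes)
  m[rowSums(m) > 0, , drop = FALSE]
}

#' Pearson-correlation distance between phyletic profiles
#'
#' `d(i, j) = 1 - r(profile_i, profile_j)`, in `[0, 2]`, zero on the
#' diagonal. A zero-variance profile (a genome present in every cluster or
#' none) has undefined correlation: its distances are `NA` and a warning is
#' raised.
#' @param m Presence/absence matrix from [build_matrix()].
#' @return Symmetric genome-by-genome distance matrix.
#' @export
pearson_distance <- function(m) {
  if (ncol(m) < 2) stop("need at least 2 genomes")
  v <- apply(m, 2, stats::var)
  if (any(v == 0))
    warning("zero-variance profile(s): ",
            paste(colnames(m)[v == 0], collapse = ", "),
            "; their distances are undefined")
  d <- 1 - suppressWarnings(stats::cor(m))
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) dendrogram from a distance matrix
#'
#' Labels are sorted before agglomeration so the result is invariant to the
#' input ordering of the matrix. The returned tree is ultrametric; a merge at
#' distance h places the two children at height h/2.
#' @param d Symmetric, zero-diagonal distance matrix.
#' @return An [ape::phylo] dendrogram.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  if (anyNA(d)) stop("distance matrix contains undefined entries")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Write a presence/absence matrix as TSV or MatrixMarket
#' @param m Matrix from [build_matrix()].
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
write_matrix_mtx <- function(m, path) {
  idx <- which(m != 0, arr.ind = TRUE)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), nrow(idx))), con)
  writeLines(sprintf("%d %d %d", idx[, 1], idx[, 2], m[idx]), con)
  invisible(path)
}
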