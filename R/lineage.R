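# Lineage assignment from the AAI matrix, and the multi-line evidence report
# combining synteny, AAI, codon/amino-acid usage, cluster sharing and
# pan-genome increments.

#' Assign genomes to lineages by single-linkage AAI grouping
#'
#' Genomes whose two-way AAI is at or above the threshold are linked;
#' connected components are lineages. Singleton components are new lineages
#' (the founding-member pattern). The default threshold of 95% sits inside
#' the empirical gap between within-lineage identity (~97%) and
#' between-lineage identity (<73%) observed in marseillevirus families.
#'
#' @param aai Symmetric AAI matrix from [aai_matrix()].
#' @param within_threshold Percent AAI linking two genomes into one lineage.
#' @param allow_missing Treat `NA` cells as below-threshold instead of
#'   erroring.
#' @return List of class `lineage_partition`: `assignment` (data.frame
#'   `genome_id`, `lineage`), `n_lineages`, `within_aai_min`,
#'   `between_aai_max`.
#' @export
assign_lineages <- function(aai, within_threshold = 95,
                            allow_missing = FALSE) {
  m <- as.matrix(aai)
  if (anyNA(m[upper.tri(m)])) {
    if (!allow_missing) stop("AAI matrix has missing cells; ",
                             "set allow_missing = TRUE to treat them as ",
                             "below threshold")
    m[is.na(m)] <- -Inf
  }
  ids <- sort(rownames(m))
  m <- m[ids, ids]
  g <- igraph::graph_from_adjacency_matrix(1 * (m >= within_threshold),
                                           mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  # stable lineage labels: L1, L2, ... in order of each component's first
  # (alphabetical) genome
  first <- tapply(ids, comp, function(x) sort(x)[1])
  relabel <- stats::setNames(sprintf("L%d", rank(first)), names(first))
  assignment <- data.frame(genome_id = ids,
                           lineage = unname(relabel[as.character(comp)]),
                           stringsAsFactors = FALSE)
  rownames(assignment) <- NULL
  within <- c(); between <- c()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    v <- m[i, j]
    if (!is.finite(v)) next
    if (assignment$lineage[i] == assignment$lineage[j]) within <- c(within, v)
    else between <- c(between, v)
  }
  structure(list(assignment = assignment,
                 n_lineages = length(unique(assignment$lineage)),
                 within_aai_min = if (length(within)) min(within) else NA_real_,
                 between_aai_max = if (length(between)) max(between)
                                   else NA_real_),
            class = "lineage_partition")
}

#' @export
print.lineage_partition <- function(x, ...) {
  cat("lineage_partition:", x$n_lineages, "lineages\n")
  for (l in unique(x$assignment$lineage)) {
    cat(" ", l, ":",
        paste(x$assignment$genome_id[x$assignment$lineage == l],
              collapse = " "), "\n")
  }
  cat("  within-lineage AAI min:", round(x$within_aai_min, 1),
      "| between-lineage AAI max:", round(x$between_aai_max, 1), "\n")
  invisible(x)
}

# Spearman rank correlation of codon usage (codon signatures discriminate
# lineages even when amino-acid usage is near-identical)
usage_rank_correlation <- function(usage_a, usage_b) {
  fa <- usage_a$codon_counts / sum(usage_a$codon_counts)
  fb <- usage_b$codon_counts / sum(usage_b$codon_counts)
  common <- intersect(names(fa), names(fb))
  stats::cor(rank(fa[common]), rank(fb[common]))
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

#' Evidence report for a lineage partition
#'
#' Scores five independent lines of evidence for the partition, each
#' concordant when the within-lineage signal exceeds the between-lineage
#' signal: (1) ortholog-adjacency synteny, (2) AAI separation, (3) rank
#' correlation of amino-acid usage (reported only, never used for the
#' partition itself), (4) shared ortholog-cluster proportions, (5) pan-genome
#' increments at new-lineage versus same-lineage inclusion steps. The overall
#' verdict is the majority of the evaluable lines; disagreement is flagged,
#' never silently overridden.
#'
#' @param partition [assign_lineages()] result.
#' @param aai AAI matrix.
#' @param synteny Optional symmetric matrix of [synteny_index()] values.
#' @param usage Optional named list of [usage_profile()] tables.
#' @param sharing Optional [lineage_sharing()] matrix (lineages of the
#'   partition).
#' @param curve Optional [accumulation()] curve whose inclusion order covers
#'   the partition's genomes.
#' @return List of class `evidence_report`: per-line verdicts with the
#'   numbers behind them, `n_concordant`, `n_evaluable`, `verdict`,
#'   `novel_lineage`.
#' @export
evidence_report <- function(partition, aai, synteny = NULL, usage = NULL,
                            sharing = NULL, curve = NULL) {
  asg <- partition$assignment
  lin <- stats::setNames(asg$lineage, asg$genome_id)
  ids <- asg$genome_id
  same <- outer(lin[ids], lin[ids], "==")
  ut <- upper.tri(same)
  lines <- list()
  pairmeans <- function(m) {
    m <- as.matrix(m)[ids, ids]
    list(within = mean_or_na(m[ut & same][is.finite(m[ut & same])]),
         between = mean_or_na(m[ut & !same][is.finite(m[ut & !same])]))
  }
  add_line <- function(name, within, between, detail = NULL) {
    ok <- if (is.na(within) || is.na(between)) NA else within > between
    lines[[name]] <<- list(within = within, between = between,
                           concordant = ok, detail = detail)
  }
  if (!is.null(synteny)) {
    s <- pairmeans(synteny)
    add_line("synteny", s$within, s$between)
  }
  a <- pairmeans(aai)
  add_line("aai", a$within, a$between,
           detail = list(within_min = partition$within_aai_min,
                         between_max = partition$between_aai_max))
  if (!is.null(usage)) {
    w <- c(); b <- c()
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      r <- usage_rank_correlation(usage[[ids[i]]], usage[[ids[j]]])
      if (lin[ids[i]] == lin[ids[j]]) w <- c(w, r) else b <- c(b, r)
    }
    add_line("usage", mean_or_na(w), mean_or_na(b))
  }
  if (!is.null(sharing)) {
    dg <- diag(sharing)
    off <- sharing[upper.tri(sharing)]
    add_line("cluster_sharing", mean_or_na(dg[is.finite(dg)]),
             mean_or_na(off[is.finite(off)]))
  }
  if (!is.null(curve)) {
    seen <- character(0)
    new_lin <- logical(nrow(curve))
    for (s in seq_len(nrow(curve))) {
      l <- lin[curve$genome[s]]
      new_lin[s] <- !(l %in% seen)
      seen <- union(seen, l)
    }
    # first step is trivially a "new lineage"; exclude it
    new_steps <- which(new_lin)[-1]
    old_steps <- which(!new_lin)
    add_line("pan_increment",
             within = mean_or_na(curve$d_pan[new_steps]),
             between = mean_or_na(curve$d_pan[old_steps]))
    # for this line "within" holds the new-lineage increments; concordance
    # means new-lineage steps add more clusters than same-lineage steps
  }
  conc <- vapply(lines, function(l) l$concordant, logical(1))
  n_eval <- sum(!is.na(conc))
  n_conc <- sum(conc, na.rm = TRUE)
  structure(list(lines = lines, n_concordant = n_conc,
                 n_evaluable = n_eval,
                 verdict = if (n_eval == 0) NA else n_conc > n_eval / 2,
                 novel_lineage = partition$n_lineages > 1),
            class = "evidence_report")
}

#' @export
print.evidence_report <- function(x, ...) {
  if (!x$novel_lineage)
    cat("evidence_report: no novel lineage (single-lineage family)\n")
  for (nm in names(x$lines)) {
    l <- x$lines[[nm]]
    cat(sprintf("  %-16s within %8.3f  between %8.3f  %s\n", nm,
                l$within, l$between,
                if (is.na(l$concordant)) "n/a"
                else if (l$concordant) "concordant" else "DISCORDANT"))
  }
  cat(sprintf("  verdict: %d/%d lines concordant -> %s\n", x$n_concordant,
              x$n_evaluable,
              if (isTRUE(x$verdict)) "supported"
              else if (isFALSE(x$verdict)) "not supported" else "n/a"))
  invisible(x)
}

#' Write a lineage partition as TSV and the evidence report as JSON
#' @param partition [assign_lineages()] result.
#' @param path Output TSV path.
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(partition$assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @param report [evidence_report()] result.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
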