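# Pairwise local protein alignment: the substrate for orthology, AAI and
# clustering. The engine is an affine-gap Smith-Waterman in C++ with the
# conventions of gapped BLASTp: BLOSUM62, gap open 11 / extend 1 (a gap of
# length L costs 11 + L), identity over aligned columns including gaps,
# Karlin-Altschul e-values with lambda = 0.267, K = 0.041.

#' Scoring scheme for protein alignment
#'
#' Bundles the substitution matrix, affine gap costs and Karlin-Altschul
#' statistical parameters used by every alignment-based operation in the
#' package. Defaults reproduce gapped BLASTp conventions (BLOSUM62,
#' open 11 / extend 1, lambda 0.267, K 0.041). `X` is treated as an ambiguity
#' character and scored 0 against everything.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`), or a symmetric numeric matrix with residue dimnames.
#' @param gap_open,gap_extend Non-negative gap costs; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters for bit scores and e-values.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    key <- paste0("submat_", matrix)
    if (is.null(.pkg_cache[[key]])) {
      e <- new.env()
      utils::data(list = matrix, package = "Biostrings", envir = e)
      .pkg_cache[[key]] <- get(matrix, envir = e)
    }
    m <- .pkg_cache[[key]]
  } else {
    m <- matrix
  }
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix must be symmetric")
  if (gap_open < gap_extend) stop("gap_open must be >= gap_extend")
  if (gap_extend < 0) stop("gap costs must be non-negative")
  if (lambda <= 0 || K <= 0) stop("Karlin-Altschul parameters must be positive")
  m <- apply(m, 2, as.integer)
  rownames(m) <- colnames(m)
  if ("X" %in% rownames(m)) {      # ambiguity residue scores 0
    m["X", ] <- 0L
    m[, "X"] <- 0L
  }
  structure(list(matrix = m, alphabet = rownames(m),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring_scheme: gap open", x$gap_open, "extend", x$gap_extend,
      "| lambda", x$lambda, "K", x$K, "\n")
  invisible(x)
}

bit_score <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

#' Karlin-Altschul e-value
#'
#' `E = m * n * 2^(-bitscore)`: the expected number of chance local alignments
#' of at least this bit score between a query of length `m` and a database of
#' `n` residues. Monotone decreasing in the bit score, linear in `m` and `n`.
#'
#' @param bitscore Numeric bit score(s).
#' @param m Query length in residues.
#' @param n Total subject letters searched.
#' @return Numeric e-value(s), `>= 0`.
#' @export
evalue <- function(bitscore, m, n) {
  stopifnot(all(is.finite(bitscore)))
  as.numeric(m) * as.numeric(n) * 2^(-bitscore)
}

# Batched SW over index pairs; returns a list of result vectors.
sw_raw <- function(a, b, scheme) {
  m <- .sw_batch_cpp(a, b, scheme$matrix, scheme$alphabet,
                     scheme$gap_open, scheme$gap_extend)
  list(score = m[, 1L], matches = m[, 2L], aln_len = m[, 3L],
       qstart = m[, 4L], qend = m[, 5L], sstart = m[, 6L], send = m[, 7L],
       gapopen = m[, 8L], mismatch = m[, 9L])
}

#' Optimal local alignment of two proteins
#'
#' Affine-gap Smith-Waterman under a [scoring_scheme()]. Identity is
#' matches / aligned columns with gap columns counted in the denominator
#' (BLAST convention); query and subject coverage are the fractions of each
#' sequence inside the local alignment. Traceback is deterministic
#' (diagonal preferred over up over left; ties in the best cell resolved
#' row-major).
#'
#' @param a,b Non-empty protein strings (standard alphabet, `X` allowed).
#' @param scheme A [scoring_scheme()].
#' @param db_len Total subject letters for the e-value (defaults to
#'   `nchar(b)`).
#' @return One-row data.frame: `score`, `bitscore`, `evalue`, `identity_pct`,
#'   `aln_len`, `qstart`, `qend`, `sstart`, `send`, `q_cov`, `s_cov`.
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme(),
                           db_len = nchar(b)) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 ||
      length(b) != 1 || !nzchar(a) || !nzchar(b))
    stop("'a' and 'b' must be single non-empty protein strings")
  r <- sw_raw(a, b, scheme)
  bs <- bit_score(r$score, scheme)
  data.frame(
    score = r$score, bitscore = bs,
    evalue = evalue(bs, nchar(a), db_len),
    identity_pct = ifelse(r$aln_len > 0, 100 * r$matches / r$aln_len, 0),
    aln_len = r$aln_len, qstart = r$qstart, qend = r$qend,
    sstart = r$sstart, send = r$send,
    q_cov = 100 * (r$qend - r$qstart + 1) / nchar(a),
    s_cov = 100 * (r$send - r$sstart + 1) / nchar(b)
  )
}

# distinct k-mers per sequence, as a data.table(id, kmer)
kmer_table <- function(seqs, k) {
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  data.table::data.table(
    id = rep.int(seq_along(seqs), lengths(sets)),
    kmer = unlist(sets, use.names = FALSE))
}

#' Candidate pair prefilter by shared k-mers
#'
#' Returns all query/subject index pairs sharing at least a minimum number of
#' distinct k-mers. Short sequences get a relaxed per-pair threshold
#' (`max(1, min(min_shared, floor(min_kmers / 50)))`) so that genuine but short
#' homologs are not dropped. The prefilter is a speed device: in the identity
#' regime this package targets (>= ~50% between orthologs) it retains every
#' pair that determines reciprocal best hits and AAI, leaving those results
#' unchanged relative to exhaustive alignment — a property the test-suite
#' validates empirically. Weak sub-best-hit pairs near the detection floor
#' may be skipped.
#'
#' @param queries,subjects Character vectors of proteins.
#' @param k Word size, in `[3, 6]`.
#' @param min_shared Baseline number of shared distinct k-mers.
#' @return data.frame with integer columns `q`, `s` (indices) and `shared`.
#' @export
kmer_prefilter <- function(queries, subjects, k = 5L, min_shared = 2L) {
  stopifnot(k >= 3, k <= 6)
  kq <- kmer_table(queries, k)
  ks <- kmer_table(subjects, k)
  nq <- kq[, .N, by = "id"]
  ns <- ks[, .N, by = "id"]
  m <- merge(kq, ks, by = "kmer", allow.cartesian = TRUE,
             suffixes = c(".q", ".s"))
  if (nrow(m) == 0)
    return(data.frame(q = integer(0), s = integer(0), shared = integer(0)))
  cnt <- m[, .(shared = .N), by = c("id.q", "id.s")]
  data.table::setnames(cnt, c("id.q", "id.s"), c("q", "s"))
  nkq <- integer(length(queries)); nkq[nq$id] <- nq$N
  nks <- integer(length(subjects)); nks[ns$id] <- ns$N
  thr <- pmax(1L, pmin(min_shared,
                       pmin(nkq[cnt$q], nks[cnt$s]) %/% 50L))
  out <- cnt[cnt$shared >= thr, ]
  data.table::setorderv(out, c("q", "s"))
  as.data.frame(out)
}

hit_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore", "qcov", "scov")

#' All-vs-all local alignment of two proteomes
#'
#' Aligns every candidate query/subject pair (after the k-mer prefilter, or
#' exhaustively with `prefilter = FALSE`) and reports hits up to `max_evalue`
#' in a BLAST outfmt-6-style table extended with query and subject coverage.
#' Hits are sorted per query by bit score, then identity, then subject id, so
#' downstream best-hit selection is reproducible. Self-comparisons
#' (`identical(names(a), names(b))`) exclude each protein's hit to itself.
#'
#' @param a,b Named character vectors of proteins; names are genome-qualified
#'   ids (`"genome|cds"`).
#' @param scheme A [scoring_scheme()].
#' @param max_evalue Report threshold.
#' @param prefilter,k,min_shared See [kmer_prefilter()].
#' @return data.frame with the 12 outfmt-6 columns plus `qcov`, `scov`.
#' @export
all_vs_all <- function(a, b, scheme = scoring_scheme(), max_evalue = 1e-3,
                       prefilter = TRUE, k = 5L, min_shared = 2L) {
  if (length(a) == 0 || length(b) == 0) stop("proteomes must be non-empty")
  if (is.null(names(a)) || is.null(names(b))) stop("proteomes must be named")
  self <- identical(names(a), names(b)) && identical(unname(a), unname(b))
  if (prefilter) {
    cand <- kmer_prefilter(a, b, k = k, min_shared = min_shared)
  } else {
    cand <- expand.grid(q = seq_along(a), s = seq_along(b),
                        KEEP.OUT.ATTRS = FALSE)
  }
  if (self) cand <- cand[cand$q != cand$s, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_hits())
  r <- sw_raw(unname(a[cand$q]), unname(b[cand$s]), scheme)
  bs <- bit_score(r$score, scheme)
  qlen <- nchar(a[cand$q]); slen <- nchar(b[cand$s])
  ev <- evalue(bs, qlen, sum(nchar(b)))
  h <- data.frame(
    qseqid = names(a)[cand$q], sseqid = names(b)[cand$s],
    pident = ifelse(r$aln_len > 0, 100 * r$matches / r$aln_len, 0),
    length = r$aln_len, mismatch = r$mismatch, gapopen = r$gapopen,
    qstart = r$qstart, qend = r$qend, sstart = r$sstart, send = r$send,
    evalue = ev, bitscore = bs,
    qcov = 100 * (r$qend - r$qstart + 1) / qlen,
    scov = 100 * (r$send - r$sstart + 1) / slen,
    stringsAsFactors = FALSE
  )
  h <- h[h$evalue <= max_evalue, , drop = FALSE]
  h <- h[order(h$qseqid, -h$bitscore, -h$pident, h$sseqid), , drop = FALSE]
  rownames(h) <- NULL
  h
}

empty_hits <- function() {
  h <- data.frame(qseqid = character(0), sseqid = character(0),
                  pident = numeric(0), length = integer(0),
                  mismatch = integer(0), gapopen = integer(0),
                  qstart = integer(0), qend = integer(0),
                  sstart = integer(0), send = integer(0),
                  evalue = numeric(0), bitscore = numeric(0),
                  qcov = numeric(0), scov = numeric(0),
                  stringsAsFactors = FALSE)
  h
}

# swap query/subject roles in a hit table, recomputing e-values for the new
# subject database size
swap_hits <- function(h, new_db_letters, qlen) {
  if (nrow(h) == 0) return(empty_hits())
  s <- data.frame(qseqid = h$sseqid, sseqid = h$qseqid, pident = h$pident,
                  length = h$length, mismatch = h$mismatch,
                  gapopen = h$gapopen, qstart = h$sstart, qend = h$send,
                  sstart = h$qstart, send = h$qend,
                  evalue = evalue(h$bitscore, qlen[h$sseqid], new_db_letters),
                  bitscore = h$bitscore, qcov = h$scov, scov = h$qcov,
                  stringsAsFactors = FALSE)
  s <- s[order(s$qseqid, -s$bitscore, -s$pident, s$sseqid), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Write / read hit tables as BLAST outfmt-6-style TSV
#'
#' Column order is the classic 12-column outfmt 6 plus `qcov` and `scov`; no
#' header line, so files interoperate with BLAST tooling.
#' @param hits A hit table from [all_vs_all()].
#' @param path File path.
#' @export
write_hits <- function(hits, path) {
  data.table::fwrite(hits[, hit_columns], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  h <- data.table::fread(path, sep = "\t", header = FALSE,
                         col.names = hit_columns, data.table = FALSE)
  h
}
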