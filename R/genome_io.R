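# Annotated-genome container and GenBank flat-file I/O.
#
# Coordinates are 1-based inclusive (GenBank convention). A CDS that spans
# the origin of a circular genome is stored with start > end and
# wraps_origin = TRUE; its nucleotides are the concatenation
# [start..length] + [1..end] on the forward strand.

#' Construct an annotated genome
#'
#' The unit of comparison throughout the package: a (usually circular) dsDNA
#' genome sequence plus its ordered protein-coding features.
#'
#' @param genome_id Short unique identifier.
#' @param sequence DNA string over `A,C,G,T,N`.
#' @param features data.frame with columns `cds_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `wraps_origin` (logical), `protein`, and optionally
#'   `product`.
#' @param topology `"circular"` or `"linear"`.
#' @param source_accession Optional accession string.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, sequence, features,
                             topology = c("circular", "linear"),
                             source_accession = NA_character_) {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be over {A,C,G,T,N}")
  req <- c("cds_id", "start", "end", "strand", "wraps_origin", "protein")
  if (!all(req %in% names(features))) {
    stop("features must have columns: ", paste(req, collapse = ", "))
  }
  if (!"product" %in% names(features)) features$product <- NA_character_
  if (anyDuplicated(features$cds_id)) stop("cds_id must be unique")
  L <- nchar(sequence)
  bad <- features$start < 1 | features$start > L |
    features$end < 1 | features$end > L
  if (any(bad)) stop("feature coordinates outside [1, genome length]")
  if (topology == "linear" && any(features$wraps_origin))
    stop("linear genomes cannot have origin-spanning features")
  if (any(nchar(features$protein) < 1)) stop("proteins must be non-empty")
  structure(list(genome_id = genome_id, sequence = sequence,
                 topology = topology, features = features,
                 source_accession = source_accession),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome", x$genome_id, ":", nchar(x$sequence), "bp",
      x$topology, "|", nrow(x$features), "CDS\n")
  invisible(x)
}

cds_length_nt <- function(g, i) {
  f <- g$features[i, ]
  if (f$wraps_origin) nchar(g$sequence) - f$start + 1L + f$end
  else f$end - f$start + 1L
}

# forward-strand nucleotides of feature i (before strand correction)
cds_forward_nt <- function(g, i) {
  f <- g$features[i, ]
  if (f$wraps_origin) {
    paste0(substr(g$sequence, f$start, nchar(g$sequence)),
           substr(g$sequence, 1L, f$end))
  } else {
    substr(g$sequence, f$start, f$end)
  }
}

#' Coding nucleotide sequence of a CDS
#'
#' Strand-corrected (reverse-complemented for `-` features), with
#' origin-spanning features unwrapped.
#' @param g An [annotated_genome()].
#' @param i Feature row index.
#' @return A single DNA string.
#' @export
cds_nt <- function(g, i) {
  nt <- cds_forward_nt(g, i)
  if (g$features$strand[i] == "-") {
    nt <- intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", nt))))
  }
  nt
}

translate_nt <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)), if.fuzzy.codon = "solve")))
  sub("\\*$", "", aa)
}

parse_location <- function(loc) {
  strand <- "+"
  s <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", s)) {
    strand <- "-"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  wraps <- FALSE
  if (grepl("^join\\(", s)) {
    s <- sub("^join\\((.*)\\)$", "\\1", s)
    parts <- strsplit(s, ",")[[1]]
    rng <- do.call(rbind, lapply(parts, function(p)
      as.integer(strsplit(p, "\\.\\.")[[1]])))
    if (nrow(rng) != 2) stop("only 2-segment join() locations are supported")
    wraps <- TRUE
    start <- rng[1, 1]; end <- rng[2, 2]
  } else {
    rng <- as.integer(strsplit(s, "\\.\\.")[[1]])
    if (length(rng) == 1) rng <- c(rng, rng)
    start <- rng[1]; end <- rng[2]
  }
  list(start = start, end = end, strand = strand, wraps = wraps)
}

#' Read a GenBank flat file
#'
#' Parses LOCUS (length, topology), ACCESSION/VERSION, CDS features (including
#' `complement()` and two-segment `join()` locations for origin-spanning genes
#' on circular genomes) with `/locus_tag`, `/product` and `/translation`
#' qualifiers, and the ORIGIN sequence. When a CDS carries no `/translation`,
#' the protein is derived with the standard genetic code. A provided
#' translation containing an internal stop triggers a warning but the feature
#' is kept.
#'
#' @param path Path to a GenBank flat file with at least one CDS.
#' @param genome_id Identifier; defaults to the LOCUS name.
#' @return An [annotated_genome()].
#' @export
read_genbank <- function(path, genome_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("not a GenBank flat file (no LOCUS): ", path)
  locus_name <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  topology <- if (grepl("circular", locus[1], ignore.case = TRUE))
    "circular" else "linear"
  acc <- NA_character_
  vline <- grep("^VERSION", lines, value = TRUE)
  if (length(vline)) acc <- strsplit(trimws(sub("^VERSION", "", vline[1])),
                                     "\\s+")[[1]][1]
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) stop("GenBank record has no ORIGIN sequence: ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(endrec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank record has an empty sequence: ", path)

  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) == 0) stop("GenBank record has no FEATURES: ", path)
  flines <- lines[(feat_start[1] + 1L):(ori[1] - 1L)]
  # split the feature table into entries: a new entry starts at column 6
  is_key <- grepl("^ {5}\\S", flines)
  entry_id <- cumsum(is_key)
  keys <- sub("^ {5}(\\S+).*", "\\1", flines[is_key])
  cds_entries <- which(keys == "CDS")
  if (length(cds_entries) == 0) stop("GenBank record has no CDS features")

  feats <- lapply(cds_entries, function(e) {
    block <- flines[entry_id == e]
    hdr <- block[1]
    body <- block[-1]
    # location may continue over lines until the first qualifier
    qual_starts <- grep("^ {21}/", body)
    loc_extra <- if (length(qual_starts) && qual_starts[1] > 1)
      body[seq_len(qual_starts[1] - 1)] else character(0)
    loc <- paste0(trimws(sub("^ {5}CDS", "", hdr)),
                  paste(trimws(loc_extra), collapse = ""))
    qbody <- if (length(qual_starts)) body[qual_starts[1]:length(body)]
             else character(0)
    # stitch multi-line qualifiers
    quals <- list()
    cur <- NULL
    for (ln in qbody) {
      t <- trimws(ln)
      if (startsWith(t, "/")) {
        if (!is.null(cur)) quals[[cur$name]] <- cur$val
        eq <- regexpr("=", t, fixed = TRUE)
        if (eq > 0) {
          cur <- list(name = substr(t, 2, eq - 1),
                      val = substr(t, eq + 1, nchar(t)))
        } else {
          cur <- list(name = substring(t, 2), val = "")
        }
      } else if (!is.null(cur)) {
        sep <- if (cur$name == "translation") "" else " "
        cur$val <- paste(cur$val, t, sep = sep)
      }
    }
    if (!is.null(cur)) quals[[cur$name]] <- cur$val
    quals <- lapply(quals, function(v) gsub("\"", "", v))
    l <- parse_location(loc)
    list(loc = l, quals = quals)
  })

  L <- nchar(sequence)
  ids <- vapply(seq_along(feats), function(i) {
    q <- feats[[i]]$quals
    q$locus_tag %||% q$protein_id %||% sprintf("cds_%04d", i)
  }, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  df <- data.frame(
    cds_id = ids,
    start = vapply(feats, function(f) f$loc$start, numeric(1)),
    end = vapply(feats, function(f) f$loc$end, numeric(1)),
    strand = vapply(feats, function(f) f$loc$strand, character(1)),
    wraps_origin = vapply(feats, function(f) f$loc$wraps, logical(1)),
    protein = "X",  # placeholder until translations are resolved below
    product = vapply(feats, function(f) f$quals$product %||% NA_character_,
                     character(1)),
    stringsAsFactors = FALSE
  )
  g <- annotated_genome(genome_id %||% locus_name, sequence, df,
                        topology = topology, source_accession = acc)
  prov <- vapply(feats, function(f) f$quals$translation %||% NA_character_,
                 character(1))
  prot <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!is.na(prov[i])) {
      p <- gsub("\\s", "", prov[i])
      if (grepl("\\*", sub("\\*$", "", p))) {
        warning("CDS ", ids[i], ": provided translation has an internal stop")
      }
      prot[i] <- sub("\\*$", "", p)
    } else {
      prot[i] <- translate_nt(cds_nt(g, i))
    }
  }
  g$features$protein <- prot
  g
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

format_location <- function(f, L) {
  loc <- if (f$wraps_origin) {
    sprintf("join(%d..%d,1..%d)", f$start, L, f$end)
  } else {
    sprintf("%d..%d", f$start, f$end)
  }
  if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

wrap_qualifier <- function(name, value, width = 58L) {
  txt <- sprintf("/%s=\"%s\"", name, value)
  out <- character(0)
  while (nchar(txt) > width) {
    out <- c(out, substr(txt, 1, width))
    txt <- substr(txt, width + 1L, nchar(txt))
  }
  c(out, txt)
}

#' Write a GenBank flat file
#'
#' Inverse of [read_genbank()]: emits LOCUS, VERSION, a FEATURES table with
#' one CDS per feature (`/locus_tag`, `/product`, `/translation`) and the
#' ORIGIN sequence. Round-trips sequence, coordinates, strands and
#' translations.
#' @param g An [annotated_genome()].
#' @param path Output path.
#' @export
write_genbank <- function(g, path) {
  L <- nchar(g$sequence)
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl(sprintf("LOCUS       %-16s %d bp    DNA     %-8s VRL 01-JAN-2026",
             g$genome_id, L, g$topology))
  wl(sprintf("DEFINITION  %s annotated genome.", g$genome_id))
  if (!is.na(g$source_accession))
    wl(sprintf("VERSION     %s", g$source_accession))
  wl("FEATURES             Location/Qualifiers")
  wl(sprintf("     source          1..%d", L))
  for (i in seq_len(nrow(g$features))) {
    f <- g$features[i, ]
    wl(sprintf("     CDS             %s", format_location(f, L)))
    pad <- strrep(" ", 21)
    wl(paste0(pad, sprintf("/locus_tag=\"%s\"", f$cds_id)))
    if (!is.na(f$product))
      wl(paste0(pad, wrap_qualifier("product", f$product)))
    wl(paste0(pad, wrap_qualifier("translation", f$protein)))
  }
  wl("ORIGIN")
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(g$sequence, p, min(p + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    wl(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))))
  }
  wl("//")
  invisible(path)
}

#' Read a genome from FASTA + GFF3 (+ optional protein FASTA)
#'
#' Alternative input route: genome sequence from FASTA, CDS coordinates from
#' GFF3 (1-based inclusive, `type == "CDS"`), translations taken from a
#' protein FASTA keyed by the GFF3 `ID` attribute when supplied, otherwise
#' derived with the standard code.
#' @param fasta,gff Paths; `proteins` optional protein FASTA path.
#' @param genome_id Identifier; defaults to the FASTA record name.
#' @return An [annotated_genome()].
#' @export
read_fasta_gff <- function(fasta, gff, proteins = NULL, genome_id = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_fasta_gff() requires the rtracklayer package")
  dna <- Biostrings::readDNAStringSet(fasta)
  sequence <- as.character(dna[[1]])
  gr <- rtracklayer::import(gff)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) stop("GFF3 has no CDS features: ", gff)
  grd <- as.data.frame(gr)
  ids <- if (!is.null(grd$ID)) as.character(grd$ID)
         else sprintf("cds_%04d", seq_len(nrow(grd)))
  df <- data.frame(cds_id = ids,
                   start = grd$start,
                   end = grd$end,
                   strand = as.character(grd$strand),
                   wraps_origin = FALSE,
                   protein = "X",
                   stringsAsFactors = FALSE)
  g <- annotated_genome(genome_id %||% names(dna)[1], sequence, df,
                        topology = "linear")
  prot <- NULL
  if (!is.null(proteins)) {
    aa <- Biostrings::readAAStringSet(proteins)
    prot <- setNames(as.character(aa), sub("\\s.*", "", names(aa)))
  }
  g$features$protein <- vapply(seq_len(nrow(df)), function(i) {
    if (!is.null(prot) && df$cds_id[i] %in% names(prot))
      sub("\\*$", "", prot[[df$cds_id[i]]])
    else translate_nt(cds_nt(g, i))
  }, character(1))
  g
}

coding_ranges <- function(g) {
  L <- nchar(g$sequence)
  f <- g$features
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nrow(f))) {
    if (f$wraps_origin[i]) {
      starts <- c(starts, f$start[i], 1L)
      ends <- c(ends, L, f$end[i])
    } else {
      starts <- c(starts, f$start[i])
      ends <- c(ends, f$end[i])
    }
  }
  IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
}

gc_percent <- function(s) {
  if (!nzchar(s)) return(NA_real_)
  x <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                   letters = c("G", "C", "A", "T"))
  denom <- sum(x)
  if (denom == 0) return(NA_real_)
  100 * (x[["G"]] + x[["C"]]) / denom
}

#' Descriptive genome statistics
#'
#' Length, overall / coding / non-coding G+C (forward strand; ambiguous bases
#' excluded from denominators), CDS counts per strand, gene density per kbp,
#' coding density over the union of CDS spans on both strands (overlapping
#' CDS count each base once; origin-spanning CDS unwrapped), and ORF length
#' summaries in amino acids.
#'
#' @param g An [annotated_genome()] with at least one CDS.
#' @return A list of class `genome_stats`.
#' @export
compute_stats <- function(g) {
  if (nrow(g$features) == 0) stop("genome has no CDS features")
  L <- nchar(g$sequence)
  cr <- coding_ranges(g)
  coding_bases <- sum(IRanges::width(cr))
  coding_seq <- paste(substring(g$sequence, IRanges::start(cr),
                                IRanges::end(cr)), collapse = "")
  nc <- IRanges::gaps(cr, start = 1L, end = L)
  noncoding_seq <- if (length(nc) == 0) "" else
    paste(substring(g$sequence, IRanges::start(nc), IRanges::end(nc)),
          collapse = "")
  plen <- nchar(g$features$protein)
  out <- list(
    genome_id = g$genome_id,
    length_bp = L,
    gc_overall = gc_percent(g$sequence),
    gc_coding = gc_percent(coding_seq),
    gc_noncoding = gc_percent(noncoding_seq),
    n_cds = nrow(g$features),
    n_plus = sum(g$features$strand == "+"),
    n_minus = sum(g$features$strand == "-"),
    gene_density = nrow(g$features) / (L / 1000),
    coding_density = 100 * coding_bases / L,
    orf_len_min = min(plen), orf_len_max = max(plen),
    orf_len_mean = mean(plen)
  )
  class(out) <- "genome_stats"
  out
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "%s: %d bp | G+C %.1f%% (coding %.1f%%, non-coding %.1f%%)\n",
    "  %d CDS (+%d/-%d) | %.1f genes/kbp | coding density %.1f%%\n",
    "  ORF length (aa): min %d, max %d, mean %.0f\n"),
    x$genome_id, x$length_bp, x$gc_overall, x$gc_coding, x$gc_noncoding,
    x$n_cds, x$n_plus, x$n_minus, x$gene_density, x$coding_density,
    x$orf_len_min, x$orf_len_max, x$orf_len_mean))
  invisible(x)
}

#' Codon and amino-acid usage profile
#'
#' Codon counts over all CDS (strand-corrected reading frames), relative codon
#' frequencies within each amino acid, and overall amino-acid frequencies.
#' Stop codons are excluded from amino-acid frequencies; codons containing `N`
#' are excluded from all counts and tallied separately.
#'
#' @param g An [annotated_genome()].
#' @return List of class `usage_table` with `codon_counts` (named 64-vector),
#'   `codon_freq` (relative within amino acid), `aa_freq` (20-vector summing
#'   to 1), `n_ambiguous`.
#' @export
usage_profile <- function(g) {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  counts <- setNames(integer(64), codons)
  n_amb <- 0L
  for (i in seq_len(nrow(g$features))) {
    nt <- cds_nt(g, i)
    n <- nchar(nt) - nchar(nt) %% 3L
    cod <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
    amb <- grepl("N", cod, fixed = TRUE)
    n_amb <- n_amb + sum(amb)
    tab <- table(cod[!amb])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  aa_of <- code[codons]
  nonstop <- aa_of != "*"
  aa_counts <- tapply(counts[nonstop], aa_of[nonstop], sum)
  aa_freq <- aa_counts / sum(aa_counts)
  codon_freq <- counts
  for (a in unique(aa_of)) {
    sel <- aa_of == a
    tot <- sum(counts[sel])
    codon_freq[sel] <- if (tot > 0) counts[sel] / tot else NA_real_
  }
  structure(list(genome_id = g$genome_id, codon_counts = counts,
                 codon_freq = codon_freq,
                 aa_freq = aa_freq[sort(names(aa_freq))],
                 n_ambiguous = n_amb),
            class = "usage_table")
}

#' Genome-qualified proteome of a genome
#'
#' @param g An [annotated_genome()].
#' @return Named character vector; names are `"genomeID|cdsID"`.
#' @export
proteome <- function(g) {
  setNames(g$features$protein, paste0(g$genome_id, "|", g$features$cds_id))
}

#' Write proteomes as FASTA with `genomeID|cdsID` headers
#' @param genomes A list of [annotated_genome()] objects (or one).
#' @param path Output FASTA path.
#' @export
write_protein_fasta <- function(genomes, path) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  aa <- unlist(lapply(genomes, proteome))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aa), path)
  invisible(path)
}

#' Write genome statistics / usage tables as TSV
#' @param x A list of `genome_stats` or `usage_table` objects.
#' @param path Output path.
#' @export
write_stats_tsv <- function(x, path) {
  if (inherits(x, "genome_stats")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(s) as.data.frame(unclass(s))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stats_tsv
#' @export
write_usage_tsv <- function(x, path) {
  if (inherits(x, "usage_table")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(u) {
    data.frame(genome_id = u$genome_id, codon = names(u$codon_counts),
               count = as.integer(u$codon_counts),
               codon_freq = as.numeric(u$codon_freq),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
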