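make_toy_genome <- function(seed = 2) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  feats <- data.frame(
    cds_id = c("g1", "g2"), start = c(10, 100), end = c(39, 21),
    strand = c("+", "-"), wraps_origin = c(FALSE, TRUE),
    protein = c("MKVLAWCDE", "MHHHHHHHHH"),
    product = c("test protein", NA), stringsAsFactors = FALSE)
  annotated_genome("toy", seq, feats, topology = "circular")
}

test_that("GenBank write/read round-trips coordinates, strands, proteins", {
  g <- make_toy_genome()
  f <- tempfile(fileext = ".gbk")
  write_genbank(g, f)
  g2 <- read_genbank(f)
  expect_equal(g2$sequence, g$sequence)
  expect_equal(as.integer(g2$features$start), as.integer(g$features$start))
  expect_equal(as.integer(g2$features$end), as.integer(g$features$end))
  expect_equal(g2$features$strand, g$features$strand)
  expect_equal(g2$features$wraps_origin, g$features$wraps_origin)
  expect_equal(g2$features$protein, g$features$protein)
  expect_equal(g2$topology, "circular")
})

test_that("an origin-spanning CDS translates from the concatenated span", {
  # forward-strand gene wrapping the origin of a 60 bp circular genome:
  # last 9 bases + first 12 bases spell a known 6-codon peptide + stop
  gene_nt <- "ATGAAATTTGGGCCCTAA"           # M K F G P *
  pre <- strrep("C", 42)
  seq <- paste0(substr(gene_nt, 10, 18), pre, substr(gene_nt, 1, 9))
  feats <- data.frame(cds_id = "w1", start = 52, end = 9, strand = "+",
                      wraps_origin = TRUE, protein = "X",
                      stringsAsFactors = FALSE)
  g <- annotated_genome("wrap", seq, feats, topology = "circular")
  nt <- cds_nt(g, 1)
  expect_equal(nt, gene_nt)
  # independent translation of the unwrapped span
  expect_equal(
    panlineage:::translate_nt(nt),
    as.character(Biostrings::translate(Biostrings::DNAString("ATGAAATTTGGGCCC"))))
  f <- tempfile(fileext = ".gbk")
  g$features$protein <- panlineage:::translate_nt(nt)
  write_genbank(g, f)
  g2 <- read_genbank(f)
  expect_true(g2$features$wraps_origin[1])
  expect_equal(g2$features$protein[1], "MKFGP")
})

test_that("genome statistics: trivial densities and union arithmetic", {
  s <- strrep("ATGC", 25)
  f1 <- data.frame(cds_id = "a", start = 1, end = 100, strand = "+",
                   wraps_origin = FALSE, protein = strrep("M", 33),
                   stringsAsFactors = FALSE)
  st <- compute_stats(annotated_genome("g", s, f1, topology = "linear"))
  expect_equal(st$coding_density, 100)
  expect_equal(st$gc_overall, 50)
  expect_equal(st$gene_density, 10)

  f2 <- data.frame(cds_id = c("a", "b"), start = c(1, 31), end = c(60, 90),
                   strand = c("+", "-"), wraps_origin = FALSE,
                   protein = c(strrep("M", 20), strrep("M", 20)),
                   stringsAsFactors = FALSE)
  st2 <- compute_stats(annotated_genome("g", strrep("ATGC", 25), f2,
                                        topology = "linear"))
  expect_equal(st2$coding_density, 90)     # union of 1-60 and 31-90
  expect_equal(st2$n_plus + st2$n_minus, st2$n_cds)
})

test_that("overall G+C is the length-weighted blend of coding/non-coding", {
  g <- make_toy_genome(seed = 9)
  st <- compute_stats(g)
  cr <- panlineage:::coding_ranges(g)
  w_cod <- sum(IRanges::width(cr))
  w_all <- nchar(g$sequence)
  blended <- (st$gc_coding * w_cod + st$gc_noncoding * (w_all - w_cod)) / w_all
  expect_equal(st$gc_overall, blended, tolerance = 1e-10)
})

test_that("reverse-complementing the genome with flipped strands preserves CDS content", {
  set.seed(4)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  feats <- data.frame(cds_id = c("a", "b"), start = c(10, 150),
                      end = c(69, 239), strand = c("+", "-"),
                      wraps_origin = FALSE, protein = "X",
                      stringsAsFactors = FALSE)
  g <- annotated_genome("fwd", seq, feats, topology = "linear")
  g$features$protein <- vapply(1:2, function(i)
    panlineage:::translate_nt(cds_nt(g, i)), character(1))
  L <- nchar(seq)
  rc <- intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", seq))))
  rfe <- data.frame(cds_id = c("a", "b"),
                    start = L - feats$end + 1, end = L - feats$start + 1,
                    strand = c("-", "+"), wraps_origin = FALSE,
                    protein = g$features$protein,
                    stringsAsFactors = FALSE)
  g2 <- annotated_genome("rev", rc, rfe, topology = "linear")
  expect_equal(vapply(1:2, function(i) cds_nt(g2, i), character(1)),
               vapply(1:2, function(i) cds_nt(g, i), character(1)))
  s1 <- compute_stats(g); s2 <- compute_stats(g2)
  expect_equal(s2$n_cds, s1$n_cds)
  expect_equal(sort(g2$features$protein), sort(g$features$protein))
  expect_equal(usage_profile(g2)$aa_freq, usage_profile(g)$aa_freq)
})

test_that("usage profile counts codons and normalises per amino acid", {
  feats <- data.frame(cds_id = "c1", start = 1, end = 9, strand = "+",
                      wraps_origin = FALSE, protein = "MFF",
                      stringsAsFactors = FALSE)
  g <- annotated_genome("u", "ATGTTTTTC", feats, topology = "linear")
  u <- usage_profile(g)
  expect_equal(unname(u$codon_counts[c("ATG", "TTT", "TTC")]), c(1L, 1L, 1L))
  expect_equal(unname(u$codon_freq[c("TTT", "TTC")]), c(0.5, 0.5))
  expect_equal(sum(u$aa_freq), 1, tolerance = 1e-9)
  expect_identical(usage_profile(g), u)   # deterministic
})

test_that("usage profile equals a brute-force recount on a random CDS", {
  set.seed(77)
  n_codons <- 999
  nt <- paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
              collapse = "")
  feats <- data.frame(cds_id = "r", start = 1, end = 3 * n_codons,
                      strand = "+", wraps_origin = FALSE, protein = "X",
                      stringsAsFactors = FALSE)
  g <- annotated_genome("r", nt, feats, topology = "linear")
  u <- usage_profile(g)
  # independent counter: simple loop over codon windows
  counts <- integer(0)
  for (i in seq(1, 3 * n_codons, by = 3)) {
    cod <- substr(nt, i, i + 2)
    counts[cod] <- (if (is.na(counts[cod])) 0L else counts[cod]) + 1L
  }
  for (cod in names(counts))
    expect_equal(unname(u$codon_counts[cod]), unname(counts[cod]))
  expect_equal(sum(u$codon_counts), n_codons)
})

test_that("parse failures and translation warnings are signalled", {
  f <- tempfile()
  writeLines(c("LOCUS       x 10 bp DNA linear", "FEATURES",
               "     CDS             1..9"), f)
  expect_error(read_genbank(f), "ORIGIN")
  g <- make_toy_genome()
  g$features$protein[1] <- "MK*LA"   # internal stop in provided translation
  f2 <- tempfile(fileext = ".gbk")
  write_genbank(g, f2)
  expect_warning(gg <- read_genbank(f2), "internal stop")
  expect_equal(nrow(gg$features), 2)
})

test_that("FASTA + GFF3 input route matches the GenBank route", {
  skip_if_not_installed("rtracklayer")
  set.seed(12)
  seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", seq), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "test", "CDS", "10", "69", ".", "+", "0",
                     "ID=x1", sep = "\t"),
               paste("chr1", "test", "CDS", "100", "159", ".", "-", "0",
                     "ID=x2", sep = "\t")), gff)
  g <- read_fasta_gff(fa, gff, genome_id = "gg")
  expect_equal(nrow(g$features), 2)
  expect_equal(g$features$strand, c("+", "-"))
  expect_equal(g$features$protein[1],
               panlineage:::translate_nt(substr(seq, 10, 69)))
})
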