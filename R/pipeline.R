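# End-to-end orchestration: io -> align -> orthology -> aai / pangenome /
# phyletics / phylogeny -> lineage, with a manifest of every artifact and
# checksum-based skipping of completed stages on re-runs.

#' Pipeline configuration
#'
#' @param inputs Character vector of GenBank paths, a named list of
#'   [annotated_genome()] objects, or a `sim_family`.
#' @param outdir Output directory (created if missing).
#' @param evalue,min_identity,min_coverage RBH thresholds.
#' @param cluster_identity,cluster_coverage Greedy-clustering thresholds.
#' @param aai_threshold Lineage-assignment AAI threshold (percent).
#' @param inclusion_order Genome ids for the accumulation curve (default:
#'   input order).
#' @param marker_seeds Named character vector of marker proteins (taken from
#'   the simulation truth when `inputs` is a `sim_family`).
#' @param seed Seed for the supertree restarts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, outdir,
                            evalue = 1e-5, min_identity = 30,
                            min_coverage = 50,
                            cluster_identity = 30, cluster_coverage = 50,
                            aai_threshold = 95,
                            inclusion_order = NULL, marker_seeds = NULL,
                            seed = 1L) {
  stopifnot(evalue > 0, min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 100,
            cluster_identity >= 0, cluster_identity <= 100,
            aai_threshold > 0, aai_threshold <= 100)
  structure(list(inputs = inputs, outdir = outdir, evalue = evalue,
                 min_identity = min_identity, min_coverage = min_coverage,
                 cluster_identity = cluster_identity,
                 cluster_coverage = cluster_coverage,
                 aai_threshold = aai_threshold,
                 inclusion_order = inclusion_order,
                 marker_seeds = marker_seeds, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_inputs <- function(cfg) {
  x <- cfg$inputs
  if (inherits(x, "sim_family")) {
    return(list(genomes = x$genomes,
                marker_seeds = cfg$marker_seeds %||% x$truth$marker_seeds))
  }
  if (is.character(x)) {
    genomes <- list()
    for (p in x) {
      g <- tryCatch(read_genbank(p), error = function(e)
        stop("failed to read GenBank input '", p, "': ", conditionMessage(e),
             call. = FALSE))
      genomes[[g$genome_id]] <- g
    }
    return(list(genomes = genomes, marker_seeds = cfg$marker_seeds))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "annotated_genome"))) {
    nm <- vapply(x, function(g) g$genome_id, character(1))
    return(list(genomes = stats::setNames(x, nm),
                marker_seeds = cfg$marker_seeds))
  }
  stop("inputs must be GenBank paths, annotated genomes, or a sim_family")
}

params_digest <- function(cfg, genomes) {
  sig <- paste(cfg$evalue, cfg$min_identity, cfg$min_coverage,
               cfg$cluster_identity, cfg$cluster_coverage,
               cfg$aai_threshold, cfg$seed,
               paste(cfg$inclusion_order, collapse = ","),
               paste(vapply(genomes, function(g)
                 paste0(g$genome_id, ":", nchar(g$sequence), ":",
                        nrow(g$features)), character(1)), collapse = ";"))
  x <- utf8ToInt(sig)
  sprintf("%08x", sum(x * (seq_along(x) %% 101 + 1)) %% 4294967291)
}

#' Run the full comparative pipeline
#'
#' Stages run in dependency order: genome I/O and statistics; all-vs-all
#' alignment; RBH orthology, paralog families, ortholog clusters and synteny;
#' AAI matrix; greedy clustering with pan/core accumulation; phyletic
#' profiles and UPGMA dendrogram; marker selection, per-gene trees,
#' concatenated NJ tree and SPR supertree (when marker seeds are available);
#' lineage assignment and the evidence report. Every written artifact is
#' listed with an md5 checksum in `manifest.json`; a re-run with identical
#' inputs and parameters skips completed stages.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return A result bundle (list) with every intermediate object, invisibly
#'   written under `cfg$outdir`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[panlineage] ", ...)
  t0 <- Sys.time()
  res <- resolve_inputs(cfg)
  genomes <- res$genomes
  digest <- params_digest(cfg, genomes)
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  prev <- NULL
  if (file.exists(manifest_path)) {
    prev <- tryCatch(jsonlite::read_json(manifest_path),
                     error = function(e) NULL)
    if (!is.null(prev) && !identical(prev$params_digest, digest)) prev <- NULL
  }
  manifest <- list(params_digest = digest,
                   parameters = cfg[setdiff(names(cfg), c("inputs",
                                                          "marker_seeds"))],
                   genomes = names(genomes), files = list(), stages = list())
  cache_path <- file.path(cfg$outdir, "stage_cache.rds")
  cache <- if (!is.null(prev) && file.exists(cache_path))
    readRDS(cache_path) else list()
  fresh <- list()
  stage <- function(name, files_expected, compute) {
    if (!is.null(prev) && !is.null(cache[[name]]) &&
        all(file.exists(file.path(cfg$outdir, files_expected)))) {
      say("stage ", name, ": skipped (up to date)")
      manifest$stages[[name]] <<- "skipped"
      return(cache[[name]])
    }
    say("stage ", name, " ...")
    val <- compute()
    cache[[name]] <<- val
    fresh[[name]] <<- TRUE
    manifest$stages[[name]] <<- "run"
    val
  }
  out <- function(f) file.path(cfg$outdir, f)
  th <- orthology_thresholds(cfg$evalue, cfg$min_identity, cfg$min_coverage)
  scheme <- scoring_scheme()

  stats <- stage("io", c("genome_stats.tsv", "proteins.faa"), function() {
    st <- lapply(genomes, compute_stats)
    write_stats_tsv(st, out("genome_stats.tsv"))
    write_protein_fasta(genomes, out("proteins.faa"))
    st
  })
  usage <- stage("usage", "usage.tsv", function() {
    u <- lapply(genomes, usage_profile)
    write_usage_tsv(u, out("usage.tsv"))
    u
  })
  proteomes <- lapply(genomes, proteome)
  hits <- stage("align", "hits", function() {
    h <- family_hits(proteomes, scheme)
    dir.create(out("hits"), showWarnings = FALSE)
    for (kk in names(h$cross))
      write_hits(h$cross[[kk]]$ab,
                 out(file.path("hits", paste0(gsub("\\|\\|", "__", kk),
                                              ".tsv"))))
    h
  })
  orth <- stage("orthology", c("rbh.tsv", "clusters_groups.txt"), function() {
    ids <- names(genomes)
    rbh_list <- list()
    syn <- matrix(NA_real_, length(ids), length(ids),
                  dimnames = list(ids, ids))
    diag(syn) <- 1
    if (length(ids) > 1) {
      for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
        hp <- pair_hits(hits, ids[i], ids[j])
        r <- reciprocal_best_hits(hp$ab, hp$ba, th)
        rbh_list[[pair_key(ids[i], ids[j])]] <- r
        if (nrow(r) >= 2) {
          syn[i, j] <- syn[j, i] <-
            synteny_index(genomes[[ids[i]]], genomes[[ids[j]]], r)
        }
      }
    }
    paralogs <- lapply(hits$self, paralog_families, thresholds = th)
    all_prot <- unlist(lapply(proteomes, names), use.names = FALSE)
    ocs <- ortholog_clusters(rbh_list, paralogs, all_prot)
    rbh_all <- do.call(rbind, rbh_list)
    utils::write.table(rbh_all, out("rbh.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_cluster_groups(ocs, out("clusters_groups.txt"))
    list(rbh = rbh_list, paralogs = paralogs, clusters = ocs, synteny = syn)
  })
  aai <- stage("aai", "aai_matrix.tsv", function() {
    m <- aai_matrix(proteomes, scheme, th, hits = hits)
    write_aai_tsv(m, out("aai_matrix.tsv"), out("aai_pairs.tsv"))
    m
  })
  pang <- stage("pangenome", c("cogs.txt", "pan_core_curve.tsv"), function() {
    cs <- greedy_cluster(unlist(unname(proteomes)),
                         identity = cfg$cluster_identity,
                         coverage = cfg$cluster_coverage, scheme = scheme)
    ord <- cfg$inclusion_order %||% names(genomes)
    curve <- accumulation(cs, ord)
    write_blastclust(cs, out("cogs.txt"))
    write_curve_tsv(curve, out("pan_core_curve.tsv"))
    list(clusters = cs, curve = curve)
  })
  phyl <- stage("phyletics", "phyletic_dendrogram.nwk", function() {
    m <- build_matrix(pang$clusters, names(genomes))
    pm <- write_matrix_tsv(m, out("phyletic_matrix.tsv"))
    if (length(genomes) < 2) return(list(matrix = m))
    d <- pearson_distance(m)
    dend <- NULL
    if (!anyNA(d)) {
      dend <- upgma(d)
      ape::write.tree(dend, out("phyletic_dendrogram.nwk"))
    } else {
      writeLines(";", out("phyletic_dendrogram.nwk"))
    }
    list(matrix = m, dist = d, dendrogram = dend)
  })
  tre <- stage("phylogeny", "concat_nj.nwk", function() {
    if (is.null(res$marker_seeds) || length(genomes) < 3) {
      writeLines(";", out("concat_nj.nwk"))
      return(NULL)
    }
    mk <- select_markers(proteomes, res$marker_seeds, scheme, th)
    mt <- marker_trees(mk, proteomes, scheme)
    dm <- concat_and_distance(mt$alignments)
    nj_tree <- if (!anyNA(dm) && nrow(dm) >= 3) neighbor_joining(dm)
               else NULL
    if (!is.null(nj_tree)) ape::write.tree(nj_tree, out("concat_nj.nwk"))
    else writeLines(";", out("concat_nj.nwk"))
    st <- NULL
    if (length(mt$trees) >= 2) {
      st <- spr_supertree(mt$trees, seed = cfg$seed)
      ape::write.tree(st$tree, out("supertree.nwk"))
      jsonlite::write_json(list(score = st$score,
                                per_input = st$per_input,
                                inputs = names(mt$trees), seed = st$seed),
                           out("supertree.json"), auto_unbox = TRUE,
                           digits = NA)
    }
    list(markers = mk, marker_trees = mt, concat_dist = dm,
         concat_tree = nj_tree, supertree = st)
  })
  lin <- stage("lineage", c("lineages.tsv", "evidence.json"), function() {
    part <- assign_lineages(aai, within_threshold = cfg$aai_threshold,
                            allow_missing = TRUE)
    sharing <- NULL
    ocs2 <- tryCatch(
      ortholog_clusters(orth$rbh, orth$paralogs,
                        unlist(lapply(proteomes, names), use.names = FALSE),
                        lineage_map = part$assignment),
      error = function(e) NULL)
    if (!is.null(ocs2) && !is.null(ocs2$presence))
      sharing <- lineage_sharing(ocs2, part$assignment)
    rep <- evidence_report(part, aai, synteny = orth$synteny,
                           usage = usage, sharing = sharing,
                           curve = pang$curve)
    write_partition_tsv(part, out("lineages.tsv"))
    write_report_json(rep, out("evidence.json"))
    list(partition = part, report = rep)
  })

  saveRDS(cache, cache_path)
  files <- setdiff(list.files(cfg$outdir, recursive = TRUE),
                   c("manifest.json", "stage_cache.rds"))
  manifest$files <- lapply(stats::setNames(files, files), function(f)
    unname(tools::md5sum(file.path(cfg$outdir, f))))
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(genomes = genomes, stats = stats, usage = usage,
                 hits = hits, orthology = orth, aai = aai,
                 pangenome = pang, phyletics = phyl, phylogeny = tre,
                 lineage = lin, manifest = manifest))
}

#' Fetch a GenBank record from NCBI (network required)
#'
#' Optional convenience downloader for the deposited genome accessions; it is
#' never used by the test-suite, which runs entirely on simulated data.
#' @param accession Accession string (e.g. `"KT752522"`).
#' @param dest Destination path.
#' @return `dest`, invisibly.
#' @export
fetch_genbank <- function(accession, dest) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", accession,
                "&rettype=gbwithparts&retmode=text")
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  invisible(dest)
}
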