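## ---------------------------------------------------------------------------
## End-to-end pipeline: parse -> threshold -> catalog -> dedupe -> classify
## -> map/cluster -> duplicate/families -> summaries -> optional phylogeny,
## with TSV outputs, a machine-readable manifest, and a markdown report.
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Either the three input paths (`proteins`, `coords`, `domtbl`) or a
#' `simulate` block must be given, not both.
#'
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed (mandatory when any stochastic stage runs:
#'   simulation or bootstrap).
#' @param proteins,coords,domtbl input paths (protein FASTA, GFF3/TSV
#'   coordinates, HMMER3 domtblout).
#' @param simulate a [simulation_config()] to generate the inputs instead.
#' @param filter a [filter_config()].
#' @param coils a [coils_config()].
#' @param cluster a [cluster_config()].
#' @param align an [align_params()].
#' @param criteria a [dup_criteria()].
#' @param strict_nterm drop NL genes (no TIR, no CC) from the NBS-LRR
#'   catalog.
#' @param prefilter pair enumeration mode for [all_pair_stats()].
#' @param bootstrap_replicates NJ bootstrap replicates (default 1000).
#' @param phylo_genes gene ids for the phylogeny stage; `NULL` picks the
#'   largest LRR-RLK family with >= 4 members (skipping the stage if none).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = NULL,
                            proteins = NULL, coords = NULL, domtbl = NULL,
                            simulate = NULL,
                            filter = filter_config(),
                            coils = coils_config(),
                            cluster = cluster_config(),
                            align = align_params(),
                            criteria = dup_criteria(),
                            strict_nterm = FALSE,
                            prefilter = c("kmer", "none"),
                            bootstrap_replicates = 1000,
                            phylo_genes = NULL) {
  have_files <- !is.null(proteins) || !is.null(coords) || !is.null(domtbl)
  if (have_files && !is.null(simulate))
    stop("give either input paths or a simulate block, not both",
         call. = FALSE)
  if (!have_files && is.null(simulate))
    stop("either input paths or a simulate block is required", call. = FALSE)
  if (have_files && (is.null(proteins) || is.null(coords) || is.null(domtbl)))
    stop("all three inputs (proteins, coords, domtbl) are required",
         call. = FALSE)
  if (is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 proteins = proteins, coords = coords, domtbl = domtbl,
                 simulate = simulate, filter = filter, coils = coils,
                 cluster = cluster, align = align, criteria = criteria,
                 strict_nterm = isTRUE(strict_nterm),
                 prefilter = match.arg(prefilter),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 phylo_genes = phylo_genes),
            class = "pipeline_config")
}

#' @noRd
stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return a `report_bundle`: list of result data.frames, output paths and
#'   the manifest. All outputs are deterministic under a fixed seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)

  ## ---- inputs -----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    stage_log("simulate", "generating synthetic genome")
    sim <- simulate_genome(config$simulate)
    genes <- sim$genes
    hits <- annotate_roles(sim$hits)
    truth <- sim$truth
  } else {
    for (p in c(config$proteins, config$coords, config$domtbl))
      if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    stage_log("parse", "reading inputs")
    genes <- read_gene_records(config$proteins, config$coords)
    hits <- parse_domtbl(config$domtbl)
  }
  offenders <- setdiff(unique(hits$gene_id), genes$gene_id)
  if (length(offenders))
    stop("hit table references unknown gene id(s): ",
         paste(utils::head(offenders, 10), collapse = ", "), call. = FALSE)
  stage_log("parse", sprintf("%d genes, %d domain hits",
                             nrow(genes), nrow(hits)))

  ## ---- threshold + catalog + dedupe -------------------------------------
  kept <- threshold_hits(hits, config$filter)
  stage_log("threshold", sprintf("%d hits at E <= %g", nrow(kept),
                                 config$filter$evalue_max))
  catalog <- build_catalog(kept)
  if (nrow(genes)) {
    dd <- remove_redundant(catalog, genes, config$filter)
    catalog <- dd$catalog
    removal_log <- dd$removed
  } else {
    removal_log <- data.frame(removed = character(), kept = character(),
                              set = character(), identity_pct = numeric())
  }
  stage_log("catalog", sprintf("NBS %d | NBS-LRR %d | RLK %d | LRR-RLK %d",
                               length(catalog$nbs_genes),
                               length(catalog$nbs_lrr_genes),
                               length(catalog$rlk_genes),
                               length(catalog$lrr_rlk_genes)))

  ## ---- N-terminal classification ----------------------------------------
  nbslrr_genes <- genes[genes$gene_id %in% catalog$nbs_lrr_genes, ,
                        drop = FALSE]
  profiles <- coil_profiles(nbslrr_genes, config$coils)
  cls <- classify_nterm(catalog, kept, profiles,
                        strict = config$strict_nterm, config$coils)
  catalog <- cls$catalog
  stage_log("classify", sprintf("CNL %d | TNL %d | NL %d%s",
                                cls$counts[["CNL"]], cls$counts[["TNL"]],
                                cls$counts[["NL"]],
                                if (length(cls$dropped))
                                  sprintf(" (%d dropped, strict mode)",
                                          length(cls$dropped)) else ""))

  ## ---- mapping and clustering -------------------------------------------
  chrom_order <- unique(genes$chromosome)
  set_genes <- function(ids) genes[genes$gene_id %in% ids, , drop = FALSE]
  nbs_set <- set_genes(catalog$nbs_lrr_genes)
  rlk_set <- set_genes(catalog$lrr_rlk_genes)
  dist_nbs <- per_chromosome_counts(nbs_set, chrom_order)
  dist_rlk <- per_chromosome_counts(rlk_set, chrom_order)
  clus_nbs <- call_clusters_genome(nbs_set, config$cluster, chrom_order)
  clus_rlk <- call_clusters_genome(rlk_set, config$cluster, chrom_order)
  stage_log("map", sprintf("NBS-LRR clusters %d | LRR-RLK clusters %d",
                           nrow(clus_nbs), nrow(clus_rlk)))

  ## ---- duplication families ---------------------------------------------
  empty_stats <- data.frame(gene_a = character(), gene_b = character(),
                            score = numeric(), coverage_pct = numeric(),
                            identity_pct = numeric(),
                            is_duplicate = logical(),
                            stringsAsFactors = FALSE)
  fam_of <- function(set) {
    if (nrow(set) < 2)
      return(list(stats = empty_stats,
                  families = build_families(empty_stats)))
    seqs <- setNames(set$protein, set$gene_id)
    stats <- all_pair_stats(seqs, config$align, config$criteria,
                            prefilter = config$prefilter)
    list(stats = stats, families = build_families(stats))
  }
  dup_nbs <- fam_of(nbs_set)
  dup_rlk <- fam_of(rlk_set)
  summary_nbs <- summarize_families(dup_nbs$families, nrow(nbs_set))
  summary_rlk <- summarize_families(dup_rlk$families, nrow(rlk_set))
  stage_log("dupfind", sprintf(
    "NBS-LRR: %d families / %d genes | LRR-RLK: %d families / %d genes",
    summary_nbs$n_multigene_families, summary_nbs$n_multigenes,
    summary_rlk$n_multigene_families, summary_rlk$n_multigenes))

  ## ---- phylogeny (optional) ---------------------------------------------
  phylo <- NULL
  phylo_ids <- config$phylo_genes
  if (is.null(phylo_ids) && nrow(dup_rlk$families)) {
    big <- dup_rlk$families[which.max(dup_rlk$families$n), ]
    if (big$n >= 4)
      phylo_ids <- strsplit(big$members, ",", fixed = TRUE)[[1]]
  }
  if (!is.null(phylo_ids) && length(phylo_ids) >= 4) {
    pg <- set_genes(phylo_ids)
    seqs <- setNames(pg$protein, pg$gene_id)
    msa <- progressive_align(seqs, config$align)
    identsim <- identity_similarity_matrix(seqs, config$align)
    tree <- bootstrap_support(msa, config$bootstrap_replicates,
                              seed = config$seed)
    phylo <- list(msa = msa, identsim = identsim, tree = tree)
    stage_log("phylo", sprintf("%d taxa, %d bootstrap replicates",
                               length(msa), config$bootstrap_replicates))
  } else {
    stage_log("phylo", "skipped (no gene set with >= 4 members)")
  }

  ## ---- write bundle -------------------------------------------------------
  paths <- c(
    catalog = file.path(out_dir, "catalog.tsv"),
    removal_log = file.path(out_dir, "removal_log.tsv"),
    classification = file.path(out_dir, "classification.tsv"),
    distribution = file.path(out_dir, "distribution.tsv"),
    clusters = file.path(out_dir, "clusters.tsv"),
    clusters_bed = file.path(out_dir, "clusters.bed"),
    families = file.path(out_dir, "families.tsv"),
    family_summary = file.path(out_dir, "family_summary.tsv"),
    identsim = file.path(out_dir, "identity_similarity.tsv"),
    newick = file.path(out_dir, "tree.nwk"),
    manifest = file.path(out_dir, "manifest.json"))

  catalog_df <- data.frame(
    gene_id = unique(c(catalog$nbs_genes, catalog$rlk_genes)),
    stringsAsFactors = FALSE)
  catalog_df$nbs <- catalog_df$gene_id %in% catalog$nbs_genes
  catalog_df$nbs_lrr <- catalog_df$gene_id %in% catalog$nbs_lrr_genes
  catalog_df$rlk <- catalog_df$gene_id %in% catalog$rlk_genes
  catalog_df$lrr_rlk <- catalog_df$gene_id %in% catalog$lrr_rlk_genes
  write_tsv(catalog_df, paths[["catalog"]])
  write_tsv(removal_log, paths[["removal_log"]])
  write_tsv(cls$classes, paths[["classification"]])

  dist <- merge(dist_nbs, dist_rlk, by = "chromosome", sort = FALSE)
  names(dist) <- c("chromosome", "nbs_lrr", "lrr_rlk")
  write_tsv(dist, paths[["distribution"]])

  clus_nbs$set <- if (nrow(clus_nbs)) "NBS_LRR" else character(0)
  clus_rlk$set <- if (nrow(clus_rlk)) "LRR_RLK" else character(0)
  clusters <- rbind(clus_nbs, clus_rlk)
  write_tsv(clusters, paths[["clusters"]])
  write_cluster_bed(clusters, paths[["clusters_bed"]])

  dup_nbs$families$set <- if (nrow(dup_nbs$families)) "NBS_LRR"
    else character(0)
  dup_rlk$families$set <- if (nrow(dup_rlk$families)) "LRR_RLK"
    else character(0)
  families <- rbind(dup_nbs$families, dup_rlk$families)
  write_tsv(families, paths[["families"]])
  fam_summary <- rbind(cbind(set = "NBS_LRR", summary_nbs),
                       cbind(set = "LRR_RLK", summary_rlk))
  write_tsv(fam_summary, paths[["family_summary"]])

  if (!is.null(phylo)) {
    write_tsv(phylo$identsim, paths[["identsim"]])
    ape::write.tree(phylo$tree, paths[["newick"]])
  } else {
    paths <- paths[setdiff(names(paths), c("identsim", "newick"))]
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lrrminer")),
    seed = config$seed,
    inputs = if (is.null(config$simulate))
      list(proteins = config$proteins, coords = config$coords,
           domtbl = config$domtbl)
      else list(simulate = list(seed = config$simulate$seed,
                                n_genes = nrow(genes))),
    parameters = list(
      evalue_max = config$filter$evalue_max,
      coils_window = config$coils$window,
      coils_matrix = config$coils$matrix,
      coils_threshold = config$coils$probability_threshold,
      cluster_gap_bp = config$cluster$max_gap_bp,
      min_coverage_pct = config$criteria$min_coverage_pct,
      min_identity_pct = config$criteria$min_identity_pct,
      strict_nterm = config$strict_nterm,
      prefilter = config$prefilter,
      bootstrap_replicates = config$bootstrap_replicates),
    counts = list(
      genes = nrow(genes),
      hits_total = nrow(hits),
      hits_kept = nrow(kept),
      nbs = length(catalog$nbs_genes),
      nbs_lrr = length(catalog$nbs_lrr_genes),
      rlk = length(catalog$rlk_genes),
      lrr_rlk = length(catalog$lrr_rlk_genes),
      cnl = unname(cls$counts[["CNL"]]),
      tnl = unname(cls$counts[["TNL"]]),
      nl = unname(cls$counts[["NL"]]),
      nbs_lrr_clusters = nrow(clus_nbs),
      lrr_rlk_clusters = nrow(clus_rlk),
      nbs_lrr_families = summary_nbs$n_multigene_families,
      nbs_lrr_multigenes = summary_nbs$n_multigenes,
      lrr_rlk_families = summary_rlk$n_multigene_families,
      lrr_rlk_multigenes = summary_rlk$n_multigenes))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(list(genes = genes, hits = hits, catalog = catalog,
                 removal_log = removal_log, classification = cls$classes,
                 class_counts = cls$counts, distribution = dist,
                 clusters = clusters, families = families,
                 family_summary = fam_summary, phylo = phylo,
                 truth = truth, manifest = manifest, paths = paths),
            class = "report_bundle")
}

#' Render a report bundle as markdown
#'
#' One section per summary table; counts printed as integers, means at one
#' decimal and percentages at two decimals.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @return a single markdown string (invisibly returns it too when
#'   printed).
#' @export
render_tables <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  need <- c("manifest", "distribution", "clusters", "families",
            "family_summary", "classification")
  for (m in need)
    if (is.null(bundle[[m]]))
      stop("bundle is missing member: ", m, call. = FALSE)
  fmt_tbl <- function(df) {
    if (!nrow(df)) return("*(empty)*")
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r)
      paste0("| ", paste(trimws(r), collapse = " | "), " |"))
    paste(c(hdr, sep, rows), collapse = "\n")
  }
  cm <- bundle$manifest$counts
  sec <- c(
    "# LRR-receptor mining report",
    "",
    "## Candidate catalogs",
    "",
    sprintf("- NBS genes: %d", cm$nbs),
    sprintf("- NBS-LRR genes: %d", cm$nbs_lrr),
    sprintf("- RLK genes: %d", cm$rlk),
    sprintf("- LRR-RLK genes: %d", cm$lrr_rlk),
    "",
    "## N-terminal classes",
    "",
    sprintf("- CNL: %d, TNL: %d, NL: %d genes", cm$cnl, cm$tnl, cm$nl),
    "",
    "## Chromosomal distribution",
    "",
    fmt_tbl(bundle$distribution),
    "",
    "## Gene clusters",
    "",
    if (nrow(bundle$clusters)) fmt_tbl(
      bundle$clusters[, c("cluster_id", "chromosome", "n", "designation",
                          "members")])
    else "0 genes in clusters",
    "",
    "## Multigene families",
    "",
    if (nrow(bundle$families)) fmt_tbl(bundle$families)
    else "0 genes in multigene families",
    "",
    "## Duplication summary",
    "",
    fmt_tbl(within(bundle$family_summary, {
      mean_family_size <- sprintf("%.1f", mean_family_size)
      pct_multigenes <- sprintf("%.2f", pct_multigenes)
    })),
    "")
  if (!is.null(bundle$phylo)) {
    sec <- c(sec,
             "## Identity / similarity",
             "",
             fmt_tbl(within(bundle$phylo$identsim, {
               identity_pct <- sprintf("%.2f", identity_pct)
               similarity_pct <- sprintf("%.2f", similarity_pct)
             })),
             "",
             "## Phylogeny (Newick)",
             "",
             paste0("    ", ape::write.tree(bundle$phylo$tree)),
             "")
  }
  paste(sec, collapse = "\n")
}
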