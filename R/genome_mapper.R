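## ---------------------------------------------------------------------------
## Chromosomal distribution tables and 200-kb gene-cluster calling.
## ---------------------------------------------------------------------------

#' Cluster-calling configuration
#'
#' @param max_gap_bp two sorted genes belong to the same cluster when their
#'   gap is at most this many bp (inclusive boundary). Default 200000, the
#'   classical 200-kb cluster window.
#' @param min_cluster_size minimum members for a reported cluster (>= 2).
#' @param gap_mode `"start_to_start"` (default; insensitive to annotated
#'   gene-length noise) or `"end_to_start"` to measure the intergenic gap.
#' @return a `cluster_config` list.
#' @export
cluster_config <- function(max_gap_bp = 200000, min_cluster_size = 2,
                           gap_mode = c("start_to_start", "end_to_start")) {
  if (max_gap_bp <= 0) stop("max_gap_bp must be > 0", call. = FALSE)
  if (min_cluster_size < 2)
    stop("min_cluster_size must be >= 2", call. = FALSE)
  structure(list(max_gap_bp = as.numeric(max_gap_bp),
                 min_cluster_size = as.integer(min_cluster_size),
                 gap_mode = match.arg(gap_mode)),
            class = "cluster_config")
}

#' Per-chromosome gene counts
#'
#' @param genes gene-record data.frame (`chromosome` column).
#' @param chromosome_order chromosomes in report order; genes on
#'   chromosomes not listed are collected under `OTHER`.
#' @return data.frame `chromosome, count` with a final `Total` row; the
#'   counts partition the gene list.
#' @export
per_chromosome_counts <- function(genes, chromosome_order = NULL) {
  if (is.null(chromosome_order))
    chromosome_order <- unique(genes$chromosome)
  chr <- ifelse(genes$chromosome %in% chromosome_order,
                genes$chromosome, "OTHER")
  counts <- vapply(chromosome_order, function(cc) sum(chr == cc), 0L)
  other <- sum(chr == "OTHER")
  df <- data.frame(chromosome = chromosome_order, count = unname(counts),
                   stringsAsFactors = FALSE)
  if (other > 0)
    df <- rbind(df, data.frame(chromosome = "OTHER", count = other))
  rbind(df, data.frame(chromosome = "Total", count = nrow(genes)))
}

#' Call gene clusters on one chromosome
#'
#' Genes are sorted by start (ties broken by gene id); a gene joins the open
#' cluster when its gap to the previous gene is at most `max_gap_bp`
#' (inclusive). Maximal chains with at least `min_cluster_size` members are
#' reported; two-member clusters are designated `PAIR`, larger ones
#' `MULTIGENE`.
#'
#' @param genes gene records, all on one chromosome.
#' @param config a [cluster_config()].
#' @return data.frame: `cluster_id, chromosome, members` (comma-joined in
#'   genomic order), `n, span_start, span_end, designation`.
#' @export
call_clusters <- function(genes, config = cluster_config()) {
  stopifnot(inherits(config, "cluster_config"))
  if (!nrow(genes)) return(empty_clusters())
  if (length(unique(genes$chromosome)) > 1L)
    stop("call_clusters expects genes from a single chromosome",
         call. = FALSE)
  g <- genes[order(genes$start, genes$gene_id), , drop = FALSE]
  n <- nrow(g)
  gap <- if (config$gap_mode == "start_to_start")
    g$start[-1L] - g$start[-n] else g$start[-1L] - g$end[-n]
  new_chain <- c(TRUE, gap > config$max_gap_bp)
  chain <- cumsum(new_chain)
  out <- lapply(split(seq_len(n), chain), function(idx) {
    if (length(idx) < config$min_cluster_size) return(NULL)
    data.frame(cluster_id = NA_character_,
               chromosome = g$chromosome[1],
               members = paste(g$gene_id[idx], collapse = ","),
               n = length(idx),
               span_start = min(g$start[idx]),
               span_end = max(g$end[idx]),
               designation = if (length(idx) == 2L) "PAIR" else "MULTIGENE",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(empty_clusters())
  out$cluster_id <- sprintf("%s_c%d", out$chromosome, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' @noRd
empty_clusters <- function() {
  data.frame(cluster_id = character(), chromosome = character(),
             members = character(), n = integer(),
             span_start = numeric(), span_end = numeric(),
             designation = character(), stringsAsFactors = FALSE)
}

#' Call gene clusters genome-wide
#'
#' Applies [call_clusters()] per chromosome and concatenates the results in
#' chromosome order.
#'
#' @inheritParams call_clusters
#' @param chromosome_order optional ordering for the output.
#' @return combined cluster data.frame.
#' @export
call_clusters_genome <- function(genes, config = cluster_config(),
                                 chromosome_order = NULL) {
  if (!nrow(genes)) return(empty_clusters())
  chrs <- chromosome_order %||% unique(genes$chromosome)
  out <- do.call(rbind, lapply(chrs, function(cc) {
    call_clusters(genes[genes$chromosome == cc, , drop = FALSE], config)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of catalog genes located in clusters
#'
#' @param clusters cluster data.frame from [call_clusters()].
#' @param catalog_size number of genes in the catalog (> 0).
#' @param digits decimal places of the reported percentage (half-up
#'   rounding; default 2).
#' @return percentage of distinct clustered genes.
#' @export
clustered_fraction <- function(clusters, catalog_size, digits = 2) {
  if (!is.numeric(catalog_size) || catalog_size <= 0)
    stop("catalog_size must be > 0", call. = FALSE)
  n_clustered <- length(unique(unlist(
    strsplit(clusters$members, ",", fixed = TRUE))))
  round_half_up(100 * n_clustered / catalog_size, digits)
}

#' Write cluster spans as BED
#'
#' Converts the 1-based inclusive spans to BED's 0-based half-open
#' convention at write time.
#'
#' @param clusters cluster data.frame.
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
write_cluster_bed <- function(clusters, path) {
  bed <- data.frame(chrom = clusters$chromosome,
                    chromStart = as.integer(clusters$span_start) - 1L,
                    chromEnd = as.integer(clusters$span_end),
                    name = clusters$cluster_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
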