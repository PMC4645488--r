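## ---------------------------------------------------------------------------
## Curated maize B73 (RefGen_v3) LRR-receptor catalog tables shipped with
## the package: per-chromosome counts of the 151 NBS-LRR / 226 LRR-RLK
## genes, and the duplicated-gene listings with genomic coordinates.
## ---------------------------------------------------------------------------

#' Curated maize LRR-receptor catalog tables
#'
#' Returns the packaged reference tables for the maize B73 catalog:
#' `counts` (per-chromosome numbers of NBS-LRR and LRR-RLK genes),
#' `nbs_lrr_families` and `lrr_rlk_families` (duplicated genes with family
#' assignment, chromosome and 1-based inclusive coordinates).
#'
#' @return list of three data.frames.
#' @export
maize_catalog_tables <- function() {
  rd <- function(f) utils::read.delim(
    system.file("extdata", f, package = "lrrminer", mustWork = TRUE),
    stringsAsFactors = FALSE, colClasses = c(chromosome = "character"))
  list(counts = rd("maize_chromosome_counts.tsv"),
       nbs_lrr_families = rd("maize_nbs_lrr_families.tsv"),
       lrr_rlk_families = rd("maize_lrr_rlk_families.tsv"))
}

#' Expand a count table into stub gene records
#'
#' Builds placeholder gene records (ids `chr<k>_g<i>`) matching a
#' per-chromosome count table, for distribution-table arithmetic that does
#' not need sequences or exact coordinates.
#'
#' @param counts data.frame with `chromosome` and a count column.
#' @param column name of the count column.
#' @return gene-record style data.frame (`gene_id`, `chromosome`).
#' @export
expand_counts_to_genes <- function(counts, column) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts[[column]][i]
    if (!n) return(NULL)
    data.frame(gene_id = sprintf("chr%s_g%d", counts$chromosome[i],
                                 seq_len(n)),
               chromosome = as.character(counts$chromosome[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Convert a curated family listing into the family table shape
#'
#' Groups a `family, gene_id, ...` listing into the `family_id, n, members`
#' shape produced by [build_families()], so the same summaries apply.
#'
#' @param listing data.frame with `family` and `gene_id` columns.
#' @return data.frame `family_id, n, members`.
#' @export
families_from_listing <- function(listing) {
  rows <- lapply(split(listing$gene_id, listing$family), function(mem) {
    mem <- sort(mem)
    data.frame(family_id = mem[1], n = length(mem),
               members = paste(mem, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
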