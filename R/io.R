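## ---------------------------------------------------------------------------
## File formats: protein FASTA, GFF3 gene features, HMMER3 --domtblout
## dialect, plain TSV. Coordinates are 1-based inclusive throughout (GFF3
## convention); BED output converts to 0-based half-open at write time.
## ---------------------------------------------------------------------------

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of protein sequences (names = record ids,
#'   truncated at the first whitespace).
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

## Deterministic GFF3 writer for gene features. Annotation columns
## (signal_end, tm_start, tm_end, kinase_type) become GFF3 attributes.
#' @noRd
write_gff3_genes <- function(genes, path) {
  ann_cols <- intersect(c("signal_end", "tm_start", "tm_end", "kinase_type"),
                        names(genes))
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    attrs <- sprintf("ID=%s", genes$gene_id[i])
    for (a in ann_cols) {
      v <- genes[[a]][i]
      if (!is.na(v)) attrs <- paste0(attrs, ";", a, "=", format(v,
                                                scientific = FALSE))
    }
    paste(genes$chromosome[i], "lrrminer", "gene",
          format(genes$start[i], scientific = FALSE),
          format(genes$end[i], scientific = FALSE),
          ".", "+", ".", attrs, sep = "\t")
  }, character(1))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read gene coordinates
#'
#' Accepts either GFF3 (only `gene` features are used; parsed with
#' \pkg{rtracklayer}) or a headered 4+ column TSV
#' (`gene_id, chromosome, start, end`). Coordinates are 1-based inclusive.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or TSV file.
#' @return data.frame with columns `gene_id, chromosome, start, end` plus
#'   any annotation attributes found (`signal_end, tm_start, tm_end,
#'   kinase_type`).
#' @export
read_coords <- function(path) {
  is_gff <- grepl("\\.gff3?$", tolower(path))
  if (is_gff) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    df <- data.frame(gene_id = gr$ID,
                     chromosome = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
    for (a in c("signal_end", "tm_start", "tm_end")) {
      df[[a]] <- if (a %in% names(S4Vectors::mcols(gr)))
        as.numeric(S4Vectors::mcols(gr)[[a]]) else NA_real_
    }
    df$kinase_type <- if ("kinase_type" %in% names(S4Vectors::mcols(gr)))
      as.character(S4Vectors::mcols(gr)[["kinase_type"]]) else NA_character_
    df
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chromosome", "start", "end")
    if (!all(need %in% names(df)))
      stop("coordinate TSV must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    df
  }
}

#' Assemble gene records from fixture files
#'
#' Joins proteins (FASTA) with coordinates (GFF3/TSV) on gene id.
#'
#' @param proteins_path protein FASTA.
#' @param coords_path GFF3 or TSV coordinates.
#' @return gene-record data.frame (one row per gene).
#' @export
read_gene_records <- function(proteins_path, coords_path) {
  prot <- read_proteins(proteins_path)
  coords <- read_coords(coords_path)
  missing <- setdiff(coords$gene_id, names(prot))
  if (length(missing))
    stop("genes without protein sequence: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  coords$protein <- unname(prot[coords$gene_id])
  for (a in c("signal_end", "tm_start", "tm_end"))
    if (is.null(coords[[a]])) coords[[a]] <- NA_real_
  if (is.null(coords$kinase_type)) coords$kinase_type <- NA_character_
  coords[, c("gene_id", "chromosome", "start", "end", "protein",
             "signal_end", "tm_start", "tm_end", "kinase_type")]
}

## Model names used when writing the HMMER3 dialect (cosmetic only; parsing
## keys on the accession column).
#' @noRd
PFAM_MODEL_NAMES <- c(PF00931 = "NB-ARC", PF00560 = "LRR_1",
                      PF08263 = "LRRNT_2", PF12799 = "LRR_4",
                      PF00069 = "Pkinase", PF01582 = "TIR")

#' Write a domain-hit table in HMMER3 `--domtblout` dialect
#'
#' One whitespace-delimited data row per hit, `#` comment header/footer,
#' hmmscan column order (target = domain model, query = protein). The
#' independent-domain E-value column carries the hit E-value.
#'
#' @param hits data.frame with `gene_id, accession, ali_start, ali_end,
#'   evalue`.
#' @param path output path.
#' @param qlen optional named vector of protein lengths (else inferred from
#'   `ali_end`).
#' @return the path, invisibly.
#' @export
write_domtbl <- function(hits, path, qlen = NULL) {
  hdr <- c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ----------  ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    acc <- hits$accession[i]
    model <- PFAM_MODEL_NAMES[sub("\\..*$", "", acc)]
    if (is.na(model)) model <- "unknown"
    ql <- if (!is.null(qlen) && hits$gene_id[i] %in% names(qlen))
      qlen[[hits$gene_id[i]]] else hits$ali_end[i]
    sprintf(paste("%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f",
                  "%3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d",
                  "%4.2f %s"),
            model, paste0(acc, ".1"), 120L, hits$gene_id[i], "-",
            as.integer(ql), hits$evalue[i], 100, 0.1, 1L, 1L,
            hits$evalue[i], hits$evalue[i], 95, 0.1, 1L, 120L,
            hits$ali_start[i], hits$ali_end[i],
            hits$ali_start[i], hits$ali_end[i], 0.9, "-")
  }, character(1))
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
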