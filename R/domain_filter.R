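## ---------------------------------------------------------------------------
## Domain-based candidate identification: threshold Pfam-style hits, assign
## roles, intersect role sets into NBS / NBS-LRR / RLK / LRR-RLK catalogs,
## and remove redundant entries.
## ---------------------------------------------------------------------------

#' Default Pfam accession-to-role map
#'
#' PF00931 (NB-ARC) -> NBS; PF00560, PF08263 and PF12799 -> LRR; PF00069
#' (protein kinase catalytic domain) -> KINASE; PF01582 (TIR) -> TIR.
#' Version suffixes (".N") are stripped before lookup; unknown accessions
#' map to OTHER.
#'
#' @return named character vector, accession -> role.
#' @export
default_role_map <- function() {
  c(PF00931 = "NBS",
    PF00560 = "LRR", PF08263 = "LRR", PF12799 = "LRR",
    PF00069 = "KINASE",
    PF01582 = "TIR")
}

#' Filtering configuration
#'
#' @param evalue_max E-value cutoff (inclusive: hits with E-value `<=`
#'   `evalue_max` are kept). Default `1e-4`.
#' @param redundancy_identity_pct sequence identity (percent) above which two
#'   genes at overlapping loci are treated as redundant annotations of the
#'   same locus. Default 100 (exact duplicates only).
#' @return a `filter_config` list.
#' @export
filter_config <- function(evalue_max = 1e-4, redundancy_identity_pct = 100) {
  if (!is.numeric(evalue_max) || evalue_max <= 0)
    stop("evalue_max must be > 0", call. = FALSE)
  structure(list(evalue_max = evalue_max,
                 redundancy_identity_pct = redundancy_identity_pct),
            class = "filter_config")
}

#' Assign roles to accessions
#' @noRd
accession_role <- function(accession, role_map = default_role_map()) {
  base <- sub("\\..*$", "", accession)
  role <- unname(role_map[base])
  role[is.na(role)] <- "OTHER"
  role
}

#' Parse an HMMER3 `--domtblout` table
#'
#' Skips `#` comment lines; reads one domain hit per data row using the
#' hmmscan column convention (query = protein, target = domain model). The
#' thresholded E-value is the independent-domain (i-Evalue) column.
#'
#' @param path domtblout file.
#' @param role_map accession-to-role map (see [default_role_map()]).
#' @return data.frame of hits: `gene_id, accession` (version stripped),
#'   `role, ali_start, ali_end, evalue`.
#' @export
parse_domtbl <- function(path, role_map = default_role_map()) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) return(cbind(empty_hits(), role = character()))
  idx <- which(keep)
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  parse_row <- function(f, lineno) {
    if (length(f) < 22)
      stop(sprintf("malformed domtbl row at line %d: %d fields (>=22 needed)",
                   lineno, length(f)), call. = FALSE)
    ev <- suppressWarnings(as.numeric(f[13]))
    a1 <- suppressWarnings(as.integer(f[18]))
    a2 <- suppressWarnings(as.integer(f[19]))
    if (is.na(ev) || ev < 0)
      stop(sprintf("malformed domtbl row at line %d: bad E-value '%s'",
                   lineno, f[13]), call. = FALSE)
    if (is.na(a1) || is.na(a2) || a1 > a2)
      stop(sprintf("malformed domtbl row at line %d: bad alignment coords",
                   lineno), call. = FALSE)
    data.frame(gene_id = f[4], accession = sub("\\..*$", "", f[2]),
               ali_start = a1, ali_end = a2, evalue = ev,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Map(parse_row, fields, idx))
  out$role <- accession_role(out$accession, role_map)
  rownames(out) <- NULL
  out[, c("gene_id", "accession", "role", "ali_start", "ali_end", "evalue")]
}

#' Threshold domain hits at an E-value cutoff
#'
#' Keeps exactly the hits with `evalue <= evalue_max` (inclusive boundary),
#' preserving input order.
#'
#' @param hits hit data.frame (needs an `evalue` column).
#' @param config a [filter_config()].
#' @return the filtered hit data.frame.
#' @export
threshold_hits <- function(hits, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  hits[hits$evalue <= config$evalue_max, , drop = FALSE]
}

#' Build the candidate catalogs from thresholded hits
#'
#' Role-presence intersection: a gene is an NBS candidate if it has at least
#' one NBS-role hit, an NBS-LRR candidate if it additionally has an LRR-role
#' hit; RLK and LRR-RLK analogously from KINASE/LRR roles. Gene order within
#' each set is first appearance in the hit table.
#'
#' @param hits thresholded hit data.frame with a `role` column (add one via
#'   [parse_domtbl()] or [annotate_roles()]).
#' @param role_map used only if `hits` lacks a `role` column.
#' @return a `candidate_catalog`: list with `nbs_genes, nbs_lrr_genes,
#'   rlk_genes, lrr_rlk_genes` (character vectors) and `evidence` (the hits
#'   of cataloged genes).
#' @export
build_catalog <- function(hits, role_map = default_role_map()) {
  if (is.null(hits$role)) hits$role <- accession_role(hits$accession, role_map)
  genes_with <- function(role) unique(hits$gene_id[hits$role == role])
  nbs <- genes_with("NBS")
  lrr <- genes_with("LRR")
  kin <- genes_with("KINASE")
  cat_genes <- union(nbs, kin)
  structure(list(
    nbs_genes = nbs,
    nbs_lrr_genes = nbs[nbs %in% lrr],
    rlk_genes = kin,
    lrr_rlk_genes = kin[kin %in% lrr],
    evidence = hits[hits$gene_id %in% cat_genes, , drop = FALSE]),
    class = "candidate_catalog")
}

#' @export
print.candidate_catalog <- function(x, ...) {
  cat("Candidate catalog:\n")
  cat(sprintf("  NBS genes:     %d\n", length(x$nbs_genes)))
  cat(sprintf("  NBS-LRR genes: %d\n", length(x$nbs_lrr_genes)))
  cat(sprintf("  RLK genes:     %d\n", length(x$rlk_genes)))
  cat(sprintf("  LRR-RLK genes: %d\n", length(x$lrr_rlk_genes)))
  invisible(x)
}

#' Add a role column to a hit table
#' @param hits hit data.frame with an `accession` column.
#' @param role_map accession-to-role map.
#' @return `hits` with a `role` column.
#' @export
annotate_roles <- function(hits, role_map = default_role_map()) {
  hits$role <- accession_role(hits$accession, role_map)
  hits
}

## Percent identity between two equal-or-unequal proteins, used only for the
## redundancy rule; exact string comparison short-circuits the common case.
#' @noRd
redundancy_identity <- function(a, b) {
  if (identical(a, b)) return(100)
  aln <- global_align(a, b)
  ps <- alignment_columns(aln)
  100 * sum(ps$a == ps$b & ps$a != "-") / max(nchar(a), nchar(b))
}

#' Remove redundant catalog entries
#'
#' Two catalog genes are redundant annotations of one locus when their
#' sequences are identical at or above `redundancy_identity_pct` *and* their
#' coordinates overlap on the same chromosome. Each redundancy group is
#' collapsed to the lexicographically smallest gene id. Identical sequences
#' at non-overlapping loci are kept (paralogs, not redundancy).
#'
#' @param catalog a `candidate_catalog`.
#' @param genes gene-record data.frame covering every cataloged gene.
#' @param config a [filter_config()].
#' @return list with `catalog` (pruned) and `removed` (removal log:
#'   `removed, kept, set, identity_pct`).
#' @export
remove_redundant <- function(catalog, genes, config = filter_config()) {
  stopifnot(inherits(catalog, "candidate_catalog"))
  sets <- c("nbs_genes", "nbs_lrr_genes", "rlk_genes", "lrr_rlk_genes")
  all_ids <- unique(unlist(catalog[sets]))
  missing <- setdiff(all_ids, genes$gene_id)
  if (length(missing))
    stop("catalog gene(s) missing from gene list: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  g <- genes[match(all_ids, genes$gene_id), , drop = FALSE]
  log_rows <- list()
  drop_of <- list()
  for (set in sets) {
    ids <- catalog[[set]]
    if (length(ids) < 2) next
    d <- g[match(ids, g$gene_id), , drop = FALSE]
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    pair_identity <- matrix(NA_real_, length(ids), length(ids))
    for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
      same_chr <- d$chromosome[i] == d$chromosome[j]
      overlap <- same_chr && d$start[i] <= d$end[j] && d$start[j] <= d$end[i]
      if (!overlap) next
      idpct <- redundancy_identity(d$protein[i], d$protein[j])
      if (idpct >= config$redundancy_identity_pct) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        pair_identity[i, j] <- pair_identity[j, i] <- idpct
      }
    }
    root <- vapply(seq_along(ids), find, 1L)
    survivor_of <- vapply(seq_along(ids), function(i) {
      min(ids[root == root[i]])
    }, "")
    removed_idx <- which(ids != survivor_of)
    for (i in removed_idx) {
      idpct <- suppressWarnings(max(pair_identity[i, ], na.rm = TRUE))
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        removed = ids[i], kept = survivor_of[i], set = set,
        identity_pct = if (is.finite(idpct)) idpct else NA_real_,
        stringsAsFactors = FALSE)
    }
    catalog[[set]] <- ids[ids == survivor_of]
    drop_of[[set]] <- ids[removed_idx]
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(removed = character(), kept = character(),
               set = character(), identity_pct = numeric(),
               stringsAsFactors = FALSE)
  dropped <- unique(unlist(drop_of))
  if (length(dropped))
    catalog$evidence <- catalog$evidence[
      !catalog$evidence$gene_id %in% dropped, , drop = FALSE]
  rownames(log) <- NULL
  list(catalog = catalog, removed = log)
}
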