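## ---------------------------------------------------------------------------
## TNL / CNL / NL classification of NBS-LRR candidates.
## A TIR-role domain hit takes precedence; otherwise a qualifying
## coiled-coil segment N-terminal of the NBS domain makes the gene a CNL;
## genes with neither are NL (dropped from the catalog in strict mode).
## ---------------------------------------------------------------------------

#' Compute coil profiles for a set of genes
#'
#' @param genes gene-record data.frame (`gene_id`, `protein`).
#' @param config a [coils_config()].
#' @return named list of `coil_profile` objects.
#' @export
coil_profiles <- function(genes, config = coils_config()) {
  setNames(lapply(genes$protein, coils_scan, config = config),
           genes$gene_id)
}

#' Classify N-termini of NBS-LRR candidates
#'
#' @param catalog a `candidate_catalog` (its `nbs_lrr_genes` set is
#'   classified).
#' @param hits thresholded, role-annotated hit table (TIR hits and the NBS
#'   hit start that bounds the coiled-coil search region are read from it).
#' @param profiles named list of `coil_profile`s covering the catalog genes
#'   (see [coil_profiles()]).
#' @param strict if `TRUE`, NL genes (no TIR, no CC) are dropped from the
#'   returned catalog and logged.
#' @param config a [coils_config()].
#' @return list with `classes` (data.frame: gene_id, class, cc_start,
#'   cc_end, max_probability, tir_hit), `counts` (named TNL/CNL/NL vector),
#'   `catalog` (input catalog, NL-pruned when strict), and `dropped`
#'   (character vector of NL genes removed in strict mode).
#' @export
classify_nterm <- function(catalog, hits, profiles, strict = FALSE,
                           config = coils_config()) {
  stopifnot(inherits(catalog, "candidate_catalog"))
  ids <- catalog$nbs_lrr_genes
  rows <- lapply(ids, function(id) {
    gh <- hits[hits$gene_id == id, , drop = FALSE]
    tir <- any(gh$role == "TIR")
    nbs_start <- if (any(gh$role == "NBS"))
      min(gh$ali_start[gh$role == "NBS"]) else NA_integer_
    prof <- profiles[[id]]
    if (is.null(prof))
      stop("no coil profile for gene ", id, call. = FALSE)
    cc <- has_cc(prof, config, nbs_start = nbs_start)
    cls <- if (tir) "TNL" else if (cc$has_cc) "CNL" else "NL"
    data.frame(gene_id = id, class = cls,
               cc_start = cc$start, cc_end = cc$end,
               max_probability = cc$max_probability,
               tir_hit = tir, stringsAsFactors = FALSE)
  })
  classes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), class = character(),
               cc_start = integer(), cc_end = integer(),
               max_probability = numeric(), tir_hit = logical(),
               stringsAsFactors = FALSE)
  counts <- c(TNL = sum(classes$class == "TNL"),
              CNL = sum(classes$class == "CNL"),
              NL = sum(classes$class == "NL"))
  dropped <- character()
  if (strict) {
    dropped <- classes$gene_id[classes$class == "NL"]
    catalog$nbs_lrr_genes <- setdiff(catalog$nbs_lrr_genes, dropped)
  }
  list(classes = classes, counts = counts, catalog = catalog,
       dropped = dropped)
}
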