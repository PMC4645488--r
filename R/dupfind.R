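## ---------------------------------------------------------------------------
## Duplication detection: all-vs-all global affine-gap alignment (BLOSUM62,
## gap open 11 / extend 1), coverage/identity duplicate criteria, and
## single-linkage multigene families.
## ---------------------------------------------------------------------------

#' Alignment parameters
#'
#' @param matrix substitution matrix id (only `"BLOSUM62"` is shipped).
#' @param gap_open gap existence cost (default 11).
#' @param gap_extend gap extension cost per residue (default 1). A gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @return an `align_params` list.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (gap_open < gap_extend || gap_extend < 0)
    stop("need gap_open >= gap_extend >= 0", call. = FALSE)
  if (!identical(matrix, "BLOSUM62"))
    stop("only BLOSUM62 is available", call. = FALSE)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

#' Duplicate-pair criteria
#'
#' A pair is a duplicate when the alignment covers *more than*
#' `min_coverage_pct` of the longer sequence (strict boundary) and the
#' aligned region is at least `min_identity_pct` identical (inclusive
#' boundary).
#'
#' @param min_coverage_pct coverage threshold in percent (default 70).
#' @param min_identity_pct identity threshold in percent (default 70).
#' @return a `dup_criteria` list.
#' @export
dup_criteria <- function(min_coverage_pct = 70, min_identity_pct = 70) {
  for (v in c(min_coverage_pct, min_identity_pct))
    if (v <= 0 || v > 100)
      stop("criteria must be in (0, 100]", call. = FALSE)
  structure(list(min_coverage_pct = min_coverage_pct,
                 min_identity_pct = min_identity_pct),
            class = "dup_criteria")
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal Needleman-Wunsch alignment under BLOSUM62 with affine gap costs
#' (existence 11, extension 1 by default), computed by
#' [Biostrings::pairwiseAlignment()]. Traceback is deterministic.
#'
#' @param a,b non-empty protein sequences.
#' @param params an [align_params()].
#' @return a `global_alignment` list: `aligned_a`, `aligned_b` (gapped
#'   strings of equal length), `score`.
#' @export
global_align <- function(a, b, params = align_params()) {
  stopifnot(is_protein_string(a), is_protein_string(b))
  if (!nchar(a) || !nchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  structure(list(aligned_a = as.character(Biostrings::pattern(pa)),
                 aligned_b = as.character(Biostrings::subject(pa)),
                 score = BiocGenerics::score(pa)),
            class = "global_alignment")
}

#' @noRd
alignment_columns <- function(aln) {
  list(a = seq_chars(aln$aligned_a), b = seq_chars(aln$aligned_b))
}

#' Coverage/identity statistics for an aligned pair
#'
#' Coverage is measured over the matched core: the columns between the
#' first and the last column where both sequences carry a residue. The
#' numerator counts the longer sequence's residues inside that region and
#' the denominator is the longer sequence's full length. Identity is the
#' fraction of identical columns over all columns of the core region (gap
#' columns included, the BLAST convention).
#'
#' @param aln a `global_alignment` from [global_align()].
#' @param len_a,len_b unaligned sequence lengths.
#' @param criteria a [dup_criteria()].
#' @return one-row data.frame: `score, coverage_pct, identity_pct,
#'   is_duplicate`.
#' @export
pair_stats <- function(aln, len_a, len_b, criteria = dup_criteria()) {
  cols <- alignment_columns(aln)
  both <- which(cols$a != "-" & cols$b != "-")
  longer <- if (len_a >= len_b) "a" else "b"
  if (!length(both)) {
    return(data.frame(score = aln$score, coverage_pct = 0,
                      identity_pct = 0, is_duplicate = FALSE))
  }
  region <- both[1]:both[length(both)]
  longer_res <- sum(cols[[longer]][region] != "-")
  coverage <- 100 * longer_res / max(len_a, len_b)
  identity <- 100 * sum(cols$a[region] == cols$b[region] &
                          cols$a[region] != "-") / length(region)
  data.frame(score = aln$score,
             coverage_pct = coverage,
             identity_pct = identity,
             is_duplicate = coverage > criteria$min_coverage_pct &
               identity >= criteria$min_identity_pct)
}

## Shared k-mer prefilter: pairs of sequences with no shared k-mer cannot
## reach a 70% identity over 70% coverage, so they are skipped in "kmer"
## mode. Exhaustive mode aligns every pair.
#' @noRd
kmer_sets <- function(seqs, k = 5L) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

#' All-vs-all pair statistics
#'
#' Aligns every unordered pair of sequences (optionally skipping pairs that
#' share no k-mer) and computes [pair_stats()] for each.
#'
#' @param seqs named character vector of protein sequences.
#' @param params an [align_params()].
#' @param criteria a [dup_criteria()].
#' @param prefilter `"none"` (exhaustive) or `"kmer"` (skip pairs sharing no
#'   k-mer; skipped pairs are reported with zero coverage/identity and
#'   `is_duplicate = FALSE`).
#' @param k k-mer length for the prefilter.
#' @return data.frame: `gene_a, gene_b, score, coverage_pct, identity_pct,
#'   is_duplicate`, one row per unordered pair.
#' @export
all_pair_stats <- function(seqs, params = align_params(),
                           criteria = dup_criteria(),
                           prefilter = c("none", "kmer"), k = 5L) {
  prefilter <- match.arg(prefilter)
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(seqs)
  if (n < 2)
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), coverage_pct = numeric(),
                      identity_pct = numeric(), is_duplicate = logical(),
                      stringsAsFactors = FALSE))
  km <- if (prefilter == "kmer") kmer_sets(seqs, k) else NULL
  lens <- nchar(seqs)
  out <- vector("list", n - 1L)
  for (j in 2:n) {
    is <- seq_len(j - 1L)
    if (!is.null(km)) {
      shared <- vapply(is, function(i) any(km[[i]] %in% km[[j]]), TRUE)
    } else {
      shared <- rep(TRUE, length(is))
    }
    rows <- data.frame(gene_a = ids[is], gene_b = ids[j],
                       score = NA_real_, coverage_pct = 0,
                       identity_pct = 0, is_duplicate = FALSE,
                       stringsAsFactors = FALSE)
    hit <- is[shared]
    if (length(hit)) {
      pa <- Biostrings::pairwiseAlignment(
        unname(seqs[hit]), unname(seqs[j]), type = "global",
        substitutionMatrix = blosum62(),
        gapOpening = params$gap_open, gapExtension = params$gap_extend)
    pat <- as.character(Biostrings::pattern(pa))
      sub <- as.character(Biostrings::subject(pa))
      sc <- BiocGenerics::score(pa)
      for (q in seq_along(hit)) {
        aln <- structure(list(aligned_a = pat[q], aligned_b = sub[q],
                              score = sc[q]), class = "global_alignment")
        st <- pair_stats(aln, lens[hit[q]], lens[j], criteria)
        r <- match(hit[q], is)
        rows[r, c("score", "coverage_pct", "identity_pct")] <-
          st[, c("score", "coverage_pct", "identity_pct")]
        rows$is_duplicate[r] <- st$is_duplicate
      }
    }
    out[[j - 1L]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group duplicate pairs into multigene families
#'
#' Families are the connected components (single linkage) of the duplicate
#' relation with at least two members. The family id is the
#' lexicographically smallest member id; members are sorted.
#'
#' @param stats pair-stats data.frame (from [all_pair_stats()]); only rows
#'   with `is_duplicate = TRUE` contribute edges.
#' @return data.frame: `family_id, n, members` (comma-joined sorted ids).
#' @export
build_families <- function(stats) {
  edges <- stats[stats$is_duplicate, c("gene_a", "gene_b"), drop = FALSE]
  if (!nrow(edges))
    return(data.frame(family_id = character(), n = integer(),
                      members = character(), stringsAsFactors = FALSE))
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(gr)
  ids <- names(comp$membership)
  fams <- split(ids, comp$membership)
  rows <- lapply(fams, function(mem) {
    mem <- sort(mem)
    data.frame(family_id = mem[1], n = length(mem),
               members = paste(mem, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize multigene families
#'
#' The classic duplication summary: number of multigene families, genes in
#' them, largest family, mean family size (1 decimal, half-up) and the
#' percentage of catalog genes that are duplicated (2 decimals, half-up).
#'
#' @param families family data.frame (`family_id, n, members`).
#' @param total_genes catalog size (>= genes in families).
#' @return one-row data.frame: `total_genes, n_multigene_families,
#'   n_multigenes, max_family_size, mean_family_size, pct_multigenes,
#'   n_single_genes`.
#' @export
summarize_families <- function(families, total_genes) {
  members <- unlist(strsplit(families$members, ",", fixed = TRUE))
  if (anyDuplicated(members))
    stop("families are not a partition: duplicated member(s)",
         call. = FALSE)
  n_multi <- length(members)
  if (total_genes < n_multi)
    stop("total_genes is smaller than the number of family members",
         call. = FALSE)
  n_fam <- nrow(families)
  data.frame(
    total_genes = total_genes,
    n_multigene_families = n_fam,
    n_multigenes = n_multi,
    max_family_size = if (n_fam) max(families$n) else 0L,
    mean_family_size = if (n_fam) round_half_up(n_multi / n_fam, 1) else 0,
    pct_multigenes = round_half_up(100 * n_multi / total_genes, 2),
    n_single_genes = total_genes - n_multi)
}
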