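## ---------------------------------------------------------------------------
## Homology characterization: pairwise identity/similarity, progressive
## multiple alignment, p-distances, Saitou-Nei neighbor joining with
## bootstrap support, and domain-architecture tables.
## ---------------------------------------------------------------------------

#' Pairwise identity and similarity
#'
#' Globally aligns the pair (affine gaps, BLOSUM62), trims terminal gap
#' columns (the overhang before the first and after the last column where
#' both sequences carry a residue), and reports identity = identical
#' columns / core columns and similarity = columns whose residue pair has a
#' positive BLOSUM62 score (identities included) / core columns. Interior
#' gap columns count in the denominator only.
#'
#' @param a,b non-empty protein sequences.
#' @param params an [align_params()].
#' @return one-row data.frame: `identity_pct, similarity_pct`.
#' @export
identity_similarity <- function(a, b, params = align_params()) {
  aln <- global_align(a, b, params)
  cols <- alignment_columns(aln)
  both <- which(cols$a != "-" & cols$b != "-")
  if (!length(both))
    return(data.frame(identity_pct = 0, similarity_pct = 0))
  region <- both[1]:both[length(both)]
  ca <- cols$a[region]; cb <- cols$b[region]
  res <- ca != "-" & cb != "-"
  ident <- sum(res & ca == cb)
  simil <- sum(blosum62()[cbind(ca[res], cb[res])] > 0)
  data.frame(identity_pct = 100 * ident / length(region),
             similarity_pct = 100 * simil / length(region))
}

#' Pairwise identity/similarity matrix
#'
#' @param seqs named character vector (>= 2 sequences).
#' @param params an [align_params()].
#' @return data.frame with one row per unordered pair: `seq_a, seq_b,
#'   identity_pct, similarity_pct`.
#' @export
identity_similarity_matrix <- function(seqs, params = align_params()) {
  ids <- names(seqs)
  n <- length(seqs)
  rows <- list()
  for (j in 2:n) for (i in seq_len(j - 1L)) {
    st <- identity_similarity(seqs[[i]], seqs[[j]], params)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(seq_a = ids[i], seq_b = ids[j], stringsAsFactors = FALSE),
      st)
  }
  do.call(rbind, rows)
}

## ---- progressive multiple alignment ---------------------------------------

## Fractional shared k-mer distance used for the guide tree.
#' @noRd
kmer_distance_matrix <- function(seqs, k = 3L) {
  km <- kmer_sets(seqs, k)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (j in 2:n) for (i in seq_len(j - 1L)) {
    denom <- min(length(km[[i]]), length(km[[j]]))
    sh <- if (denom) length(intersect(km[[i]], km[[j]])) / denom else 0
    d[i, j] <- d[j, i] <- 1 - sh
  }
  d
}

## Profile-profile global affine alignment. Profiles are character matrices
## (rows = sequences, columns = alignment columns, "-" = gap). Column-pair
## score is the mean BLOSUM62 score over residue pairs (gaps score 0).
#' @noRd
align_profiles <- function(A, B, params) {
  B62 <- blosum62()
  alpha <- rownames(B62)
  count_mat <- function(P) {
    ## alphabet x ncol residue counts (gaps dropped)
    out <- matrix(0, length(alpha), ncol(P))
    rownames(out) <- alpha
    for (r in seq_len(nrow(P))) {
      res <- P[r, ] != "-"
      idx <- match(P[r, res], alpha)
      cols <- which(res)
      for (q in seq_along(cols)) out[idx[q], cols[q]] <-
          out[idx[q], cols[q]] + 1
    }
    out
  }
  CA <- count_mat(A); CB <- count_mat(B)
  S <- t(CA) %*% B62 %*% CB / (nrow(A) * nrow(B))
  la <- ncol(A); lb <- ncol(B)
  go <- params$gap_open; ge <- params$gap_extend
  NEG <- -1e18
  M <- matrix(NEG, la + 1L, lb + 1L)
  X <- matrix(NEG, la + 1L, lb + 1L)  # gap in B (consume A column)
  Y <- matrix(NEG, la + 1L, lb + 1L)  # gap in A (consume B column)
  M[1, 1] <- 0
  if (la >= 1) X[2:(la + 1), 1] <- -go - ge * (1:la)
  if (lb >= 1) Y[1, 2:(lb + 1)] <- -go - ge * (1:lb)
  for (i in 2:(la + 1L)) {
    Mi1 <- M[i - 1L, ]; Xi1 <- X[i - 1L, ]; Yi1 <- Y[i - 1L, ]
    Mi <- M[i, ]; Xi <- X[i, ]; Yi <- Y[i, ]
    Xi[] <- pmax(Mi1 - go - ge, Xi1 - ge, Yi1 - go - ge)
    Xi[1] <- X[i, 1]
    for (j in 2:(lb + 1L)) {
      Mi[j] <- max(Mi1[j - 1L], Xi1[j - 1L], Yi1[j - 1L]) + S[i - 1L, j - 1L]
      Yi[j] <- max(Mi[j - 1L] - go - ge, Yi[j - 1L] - ge,
                   Xi[j - 1L] - go - ge)
    }
    M[i, ] <- Mi; X[i, ] <- Xi; Y[i, ] <- Yi
  }
  ## traceback, tie order: diagonal (M) > up (X) > left (Y)
  i <- la + 1L; j <- lb + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  ops <- character(0)
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      ops <- c("D", ops)
      sc <- M[i, j] - S[i - 1L, j - 1L]
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      state <- which.max(abs(prev - sc) < 1e-6)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ops <- c("U", ops)
      cand <- c(M[i - 1L, j] - go - ge, X[i - 1L, j] - ge,
                Y[i - 1L, j] - go - ge)
      state <- which.max(abs(cand - X[i, j]) < 1e-6)
      i <- i - 1L
    } else {
      ops <- c("L", ops)
      cand <- c(M[i, j - 1L] - go - ge, X[i, j - 1L] - go - ge,
                Y[i, j - 1L] - ge)
      state <- c(1L, 2L, 3L)[which.max(abs(cand - Y[i, j]) < 1e-6)]
      j <- j - 1L
    }
    if (i == 1L && j == 1L) break
  }
  ncols <- length(ops)
  out <- matrix("-", nrow(A) + nrow(B), ncols)
  rownames(out) <- c(rownames(A), rownames(B))
  ai <- 0L; bj <- 0L
  for (q in seq_len(ncols)) {
    op <- ops[q]
    if (op != "L") { ai <- ai + 1L; out[seq_len(nrow(A)), q] <- A[, ai] }
    if (op != "U") { bj <- bj + 1L
      out[nrow(A) + seq_len(nrow(B)), q] <- B[, bj] }
  }
  out
}

#' Progressive multiple sequence alignment
#'
#' ClustalW-style progressive scheme: a UPGMA guide tree on fractional
#' shared k-mer distances, then profile-profile global affine alignment
#' (BLOSUM62, mean-of-pairs column scores) following the guide tree's merge
#' order. Deleting the gaps of any output row recovers the corresponding
#' input sequence exactly.
#'
#' @param seqs named character vector of sequences (>= 1).
#' @param params an [align_params()].
#' @param k k-mer length for the guide-tree distance.
#' @return named character vector of aligned (gapped) sequences of equal
#'   length, in the input order.
#' @export
progressive_align <- function(seqs, params = align_params(), k = 3L) {
  n <- length(seqs)
  stopifnot(n >= 1L, !is.null(names(seqs)))
  if (n == 1L) return(seqs)
  if (n == 2L) {
    aln <- global_align(seqs[[1]], seqs[[2]], params)
    return(setNames(c(aln$aligned_a, aln$aligned_b), names(seqs)))
  }
  d <- kmer_distance_matrix(seqs, k)
  guide <- stats::hclust(stats::as.dist(d), method = "average")
  profiles <- list()
  leaf_profile <- function(i) {
    m <- matrix(seq_chars(seqs[[i]]), nrow = 1)
    rownames(m) <- names(seqs)[i]
    m
  }
  for (s in seq_len(nrow(guide$merge))) {
    a <- guide$merge[s, 1]; b <- guide$merge[s, 2]
    A <- if (a < 0) leaf_profile(-a) else profiles[[a]]
    B <- if (b < 0) leaf_profile(-b) else profiles[[b]]
    profiles[[s]] <- align_profiles(A, B, params)
  }
  final <- profiles[[nrow(guide$merge)]]
  final <- final[match(names(seqs), rownames(final)), , drop = FALSE]
  setNames(apply(final, 1, paste, collapse = ""), names(seqs))
}

## ---- distances and trees ---------------------------------------------------

#' p-distance matrix from a multiple alignment
#'
#' d(i, j) = mismatched columns / columns where both rows carry a residue.
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pdistance_matrix <- function(msa) {
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: rows differ in length", call. = FALSE)
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (j in seq_len(n)) for (i in seq_len(j - 1L)) {
    comp <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(comp))
      stop(sprintf("no comparable columns between %s and %s",
                   names(msa)[i], names(msa)[j]), call. = FALSE)
    d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined (ties broken by the smallest row then column
#' index) with branch lengths from the standard formulas. A negative
#' branch length is clamped to zero and the difference transferred to its
#' sibling so the joined pair's path length is preserved. On additive
#' matrices the generating tree (topology and branch lengths) is recovered
#' exactly.
#'
#' @param d symmetric distance matrix with >= 3 labelled taxa.
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  labs <- rownames(d) %||% paste0("t", seq_len(n))
  frag <- labs                       # newick fragments per active node
  D <- d
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(D2) <- colnames(D2) <- seq_len(m - 1L)
    D <- D2
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(ls[1]), frag[2], fmt(ls[2]),
                 frag[3], fmt(ls[3]))
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, recomputes the
#' p-distance + NJ tree per replicate, and reports for each internal
#' branch of the full-data tree the percentage of replicate trees
#' containing the same bipartition. Deterministic per seed.
#'
#' @param msa named character vector of aligned sequences (>= 4 rows).
#' @param n_replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return the full-data `phylo` tree with `node.label` set to the rounded
#'   percentage supports (and a `bootstrap` attribute carrying the numeric
#'   values).
#' @export
bootstrap_support <- function(msa, n_replicates = 1000, seed) {
  stopifnot(length(msa) >= 4L, n_replicates >= 1L)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  base <- neighbor_joining(pdistance_matrix(msa))
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  L <- ncol(m)
  reps <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      rs <- setNames(apply(m[, cols, drop = FALSE], 1, paste,
                           collapse = ""), names(msa))
      tryCatch(neighbor_joining(pdistance_matrix(rs)),
               error = function(e) NULL)
    })
  })
  reps <- reps[!vapply(reps, is.null, TRUE)]
  counts <- if (length(reps)) {
    cl <- reps
    class(cl) <- "multiPhylo"
    ape::prop.clades(base, cl, rooted = FALSE)
  } else rep(0L, base$Nnode)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_replicates
  base$node.label <- as.character(round_half_up(support))
  attr(base, "bootstrap") <- support
  base
}

## ---- domain architecture ----------------------------------------------------

ARCH_ROLES <- c("SIGNAL", "LRRNT", "LRR", "TM", "KINASE_STK",
                "KINASE_STYK", "LOW_COMPLEXITY")

#' Domain-architecture table
#'
#' Orders each protein's domain segments, merges overlapping segments of
#' the same role, and classifies the protein: `RLK` for LRR + TM + kinase,
#' `RLP` for LRR + TM without a kinase (the transmembrane
#' receptor-like-protein pattern), `OTHER` otherwise.
#'
#' @param segments data.frame `protein, role, start, end` with roles from
#'   `SIGNAL, LRRNT, LRR, TM, KINASE_STK, KINASE_STYK, LOW_COMPLEXITY`.
#' @param protein_lengths named vector of protein lengths.
#' @return data.frame `protein, role, start, end` sorted by protein then
#'   start, with attribute `classes` (data.frame `protein, class`).
#' @export
architecture_table <- function(segments, protein_lengths) {
  bad <- setdiff(unique(segments$role), ARCH_ROLES)
  if (length(bad))
    stop("unknown architecture role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  over <- segments$end > protein_lengths[segments$protein]
  if (any(over))
    stop("segment exceeds protein length for: ",
         paste(unique(segments$protein[over]), collapse = ", "),
         call. = FALSE)
  merged <- do.call(rbind, lapply(split(segments,
                                        segments[c("protein", "role")],
                                        drop = TRUE), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    out <- d[1, , drop = FALSE]
    for (i in seq_len(nrow(d))[-1]) {
      last <- nrow(out)
      if (d$start[i] <= out$end[last]) {
        out$end[last] <- max(out$end[last], d$end[i])
      } else {
        out <- rbind(out, d[i, , drop = FALSE])
      }
    }
    out
  }))
  merged <- merged[order(merged$protein, merged$start, merged$role), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  classes <- do.call(rbind, lapply(split(merged, merged$protein),
                                   function(d) {
    has <- function(r) any(d$role %in% r)
    cls <- if (has("LRR") && has("TM") &&
               has(c("KINASE_STK", "KINASE_STYK"))) "RLK"
      else if (has("LRR") && has("TM")) "RLP"
      else "OTHER"
    data.frame(protein = d$protein[1], class = cls,
               stringsAsFactors = FALSE)
  }))
  rownames(classes) <- NULL
  attr(merged, "classes") <- classes
  merged
}

#' Build architecture segments from gene records and hits
#'
#' Converts role-mapped domain hits plus the annotation columns
#' (`signal_end`, `tm_start`/`tm_end`, `kinase_type`) into the segment
#' table consumed by [architecture_table()].
#'
#' @param genes gene-record data.frame.
#' @param hits role-annotated hit table.
#' @return segment data.frame `protein, role, start, end`.
#' @export
gene_segments <- function(genes, hits) {
  rows <- list()
  add <- function(p, role, s, e) {
    rows[[length(rows) + 1L]] <<- data.frame(
      protein = p, role = role, start = as.integer(s), end = as.integer(e),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(genes))) {
    id <- genes$gene_id[i]
    if (!is.na(genes$signal_end[i])) add(id, "SIGNAL", 1, genes$signal_end[i])
    if (!is.na(genes$tm_start[i]))
      add(id, "TM", genes$tm_start[i], genes$tm_end[i])
    gh <- hits[hits$gene_id == id, , drop = FALSE]
    for (q in seq_len(nrow(gh))) {
      role <- switch(gh$role[q],
                     LRR = "LRR",
                     KINASE = if (identical(genes$kinase_type[i], "STYK"))
                       "KINASE_STYK" else "KINASE_STK",
                     NULL)
      if (!is.null(role)) add(id, role, gh$ali_start[q], gh$ali_end[q])
    }
  }
  if (!length(rows))
    return(data.frame(protein = character(), role = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
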