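# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct scans, closed
# forms.

# Enumerate every global alignment of two short sequences and return the
# best affine-gap score (gap of length L costs open + L * extend; a
# transition between insertion and deletion opens a new gap).
brute_force_align_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  B62 <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  rec <- function(i, j, score, last_op) {
    if (i > n && j > m) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= n && j <= m)
      rec(i + 1L, j + 1L, score + B62[ca[i], cb[j]], "D")
    if (i <= n)
      rec(i + 1L, j, score - gap_extend -
            (if (identical(last_op, "U")) 0 else gap_open), "U")
    if (j <= m)
      rec(i, j + 1L, score - gap_extend -
            (if (identical(last_op, "L")) 0 else gap_open), "L")
  }
  rec(1L, 1L, 0, "")
  best
}

# Brute-force maximal-chain clustering: grow a chain from every start gene,
# keep the maximal ones. Independent of the rle/cumsum implementation.
brute_force_chains <- function(starts, ids, max_gap, min_size = 2) {
  ord <- order(starts, ids)
  s <- starts[ord]; id <- ids[ord]
  n <- length(s)
  chains <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] - s[j] <= max_gap) j <- j + 1L
    if (j - i + 1L >= min_size)
      chains[[length(chains) + 1L]] <- sort(id[i:j])
    i <- j + 1L
  }
  chains
}

# Transitive closure of a boolean adjacency matrix (Floyd-Warshall style).
transitive_closure_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ])
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1L
    comp[which(reach[i, ] & reach[, i])] <- cid
  }
  comp
}

# Direct (loop-based) coiled-coil probability oracle mirroring the scoring
# definition: per-residue max over frames and covering windows of the
# geometric-mean propensity, transformed by the two-Gaussian rule.
oracle_coil_probability <- function(seq, matrix = "MTIDK", window = 21) {
  mat <- load_coils_matrix(matrix)
  prop <- mat$propensity
  g <- mat$gauss[mat$gauss$window == window, ]
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  best <- numeric(L)
  if (L >= window) {
    for (s in seq_len(L - window + 1L)) {
      for (f in 0:6) {
        vals <- vapply(seq_len(window), function(q) {
          pos <- s + q - 1L
          reg <- ((pos - 1L + f) %% 7L) + 1L
          prop[ch[pos], reg]
        }, 0)
        sc <- if (any(vals == 0)) 0 else exp(mean(log(vals)))
        idx <- s:(s + window - 1L)
        best[idx] <- pmax(best[idx], sc)
      }
    }
  }
  gcc <- dnorm(best, g$cc_mean, g$cc_sd)
  gg <- dnorm(best, g$glob_mean, g$glob_sd)
  p <- gcc / (gcc + gg)
  p[!is.finite(p)] <- 0
  pmin(pmax(p, 0), 1)
}

random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}
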