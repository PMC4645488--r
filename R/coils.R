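## ---------------------------------------------------------------------------
## Sliding-window heptad-propensity coiled-coil scorer (Lupas-style).
## For every window placement and each of the 7 heptad frames, the window
## score is the geometric mean of per-residue propensities at their assigned
## registers; a per-residue score is the max over covering windows/frames,
## converted to a probability by a two-Gaussian (coiled-coil vs globular)
## decision rule whose parameters ship with the propensity tables.
## ---------------------------------------------------------------------------

COIL_REGISTERS <- c("a", "b", "c", "d", "e", "f", "g")

#' Coiled-coil scan configuration
#'
#' @param window scan window length; one of 14, 21, 28 (default 21).
#' @param matrix propensity table id, `"MTK"` or `"MTIDK"` (default MTIDK).
#' @param probability_threshold per-residue probability needed for a residue
#'   to count toward a coiled-coil segment (default 0.9, the conventional
#'   cutoff).
#' @param min_run minimum number of consecutive above-threshold residues for
#'   a qualifying segment (default 7, one heptad).
#' @param search_region `"N_TERMINAL_OF_NBS"` restricts the coiled-coil
#'   search to positions before the first NBS-role hit (falling back to the
#'   whole protein when no NBS hit is available); `"WHOLE_PROTEIN"` scans
#'   everything.
#' @return a `coils_config` list.
#' @export
coils_config <- function(window = 21, matrix = c("MTIDK", "MTK"),
                         probability_threshold = 0.9, min_run = 7,
                         search_region = c("N_TERMINAL_OF_NBS",
                                           "WHOLE_PROTEIN")) {
  if (!window %in% c(14, 21, 28))
    stop("window must be one of 14, 21, 28", call. = FALSE)
  if (probability_threshold < 0 || probability_threshold > 1)
    stop("probability_threshold must be in [0, 1]", call. = FALSE)
  structure(list(window = as.integer(window),
                 matrix = match.arg(matrix),
                 probability_threshold = probability_threshold,
                 min_run = as.integer(min_run),
                 search_region = match.arg(search_region)),
            class = "coils_config")
}

## Loader for the packaged propensity tables. Format: '# gauss <window>
## <cc_mean> <cc_sd> <glob_mean> <glob_sd>' comment lines, then a TSV of 20
## amino-acid rows x 7 register columns. Cached per matrix id.
.coils_cache <- new.env(parent = emptyenv())

#' Load a packaged coiled-coil propensity table
#'
#' @param matrix `"MTK"` or `"MTIDK"`.
#' @return list with `propensity` (matrix 21 x 7; row "X" is all 1) and
#'   `gauss` (data.frame: window, cc_mean, cc_sd, glob_mean, glob_sd).
#' @export
load_coils_matrix <- function(matrix = c("MTIDK", "MTK")) {
  matrix <- match.arg(matrix)
  if (!is.null(.coils_cache[[matrix]])) return(.coils_cache[[matrix]])
  path <- system.file("extdata", paste0("coils_", matrix, ".tsv"),
                      package = "lrrminer", mustWork = TRUE)
  lines <- readLines(path)
  gl <- grep("^# gauss ", lines, value = TRUE)
  gauss <- do.call(rbind, lapply(gl, function(x) {
    v <- as.numeric(strsplit(sub("^# gauss ", "", x), "\\s+")[[1]])
    data.frame(window = v[1], cc_mean = v[2], cc_sd = v[3],
               glob_mean = v[4], glob_sd = v[5])
  }))
  tab <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                           stringsAsFactors = FALSE)
  prop <- as.matrix(tab[, COIL_REGISTERS])
  rownames(prop) <- tab$aa
  prop <- rbind(prop, X = rep(1, 7))
  out <- list(propensity = prop, gauss = gauss)
  assign(matrix, out, envir = .coils_cache)
  out
}

#' Scan a protein for coiled-coil propensity
#'
#' @param seq protein sequence over the 20-letter alphabet (X allowed,
#'   scored with propensity 1).
#' @param config a [coils_config()].
#' @return a `coil_profile`: list with per-residue `probability` (in
#'   \[0, 1\]; 0 where no window covers the residue), `score` (best
#'   geometric-mean window score), `register` (heptad register a-g of the
#'   best-scoring frame), and the scan settings.
#' @export
coils_scan <- function(seq, config = coils_config()) {
  stopifnot(inherits(config, "coils_config"), is_protein_string(seq))
  ch <- seq_chars(seq)
  L <- length(ch)
  mat <- load_coils_matrix(config$matrix)
  bad <- setdiff(unique(ch), rownames(mat$propensity))
  if (length(bad))
    stop("illegal residue character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  w <- config$window
  out <- list(probability = numeric(L), score = numeric(L),
              register = rep(NA_character_, L),
              window = w, matrix = config$matrix)
  class(out) <- "coil_profile"
  if (L < w) return(out)

  best_score <- numeric(L)               # max over frames and windows
  best_reg <- rep(NA_character_, L)
  for (f in 0:6) {
    reg <- ((seq_len(L) - 1L + f) %% 7L) + 1L
    p <- mat$propensity[cbind(match(ch, rownames(mat$propensity)), reg)]
    lg <- ifelse(p > 0, log(p), 0)
    zero <- as.integer(p == 0)
    cs_lg <- c(0, cumsum(lg))
    cs_z <- c(0, cumsum(zero))
    starts <- seq_len(L - w + 1L)
    wsum <- cs_lg[starts + w] - cs_lg[starts]
    wzero <- cs_z[starts + w] - cs_z[starts]
    wscore <- ifelse(wzero > 0, 0, exp(wsum / w))
    ## propagate each window's score to the residues it covers
    frame_best <- numeric(L)
    for (s in starts) {
      idx <- s:(s + w - 1L)
      upd <- wscore[s] > frame_best[idx]
      if (any(upd)) frame_best[idx[upd]] <- wscore[s]
    }
    better <- frame_best > best_score
    if (any(better)) {
      best_score[better] <- frame_best[better]
      best_reg[better] <- COIL_REGISTERS[reg[better]]
    }
  }
  g <- mat$gauss[mat$gauss$window == w, ]
  if (!nrow(g)) stop("no Gaussian parameters for window ", w, call. = FALSE)
  gcc <- stats::dnorm(best_score, g$cc_mean, g$cc_sd)
  gg <- stats::dnorm(best_score, g$glob_mean, g$glob_sd)
  prob <- gcc / (gcc + gg)
  prob[!is.finite(prob)] <- 0
  out$probability <- pmin(pmax(prob, 0), 1)
  out$score <- best_score
  out$register <- best_reg
  out
}

#' Decide whether a profile contains a coiled-coil segment
#'
#' `TRUE` iff at least `min_run` consecutive residues reach the probability
#' threshold (both boundaries inclusive) within the search region. When the
#' configured region is N-terminal of the NBS domain but no NBS hit start is
#' supplied, the whole protein is searched and the fallback is flagged.
#'
#' @param profile a `coil_profile` from [coils_scan()].
#' @param config a [coils_config()].
#' @param nbs_start 1-based start of the first NBS-role hit, or `NULL`.
#' @return list with `has_cc` (flag), `start`, `end` (maximal qualifying
#'   segment, longest then leftmost; `NA` if none), `max_probability`, and
#'   `fallback_whole_protein` (flag).
#' @export
has_cc <- function(profile, config = coils_config(), nbs_start = NULL) {
  stopifnot(inherits(profile, "coil_profile"))
  L <- length(profile$probability)
  fallback <- FALSE
  region_end <- L
  if (config$search_region == "N_TERMINAL_OF_NBS") {
    if (is.null(nbs_start) || is.na(nbs_start)) {
      fallback <- TRUE
    } else {
      region_end <- min(L, max(0L, as.integer(nbs_start) - 1L))
    }
  }
  p <- profile$probability[seq_len(region_end)]
  res <- list(has_cc = FALSE, start = NA_integer_, end = NA_integer_,
              max_probability = if (length(p)) max(p) else 0,
              fallback_whole_protein = fallback)
  if (!length(p)) return(res)
  r <- rle(p >= config$probability_threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= config$min_run)
  if (!length(ok)) return(res)
  pick <- ok[which.max(r$lengths[ok])]
  res$has_cc <- TRUE
  res$start <- starts[pick]
  res$end <- ends[pick]
  res
}
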