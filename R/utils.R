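#' Round half away from zero
#'
#' Fixed-precision rounding with the half-up convention used throughout the
#' report tables (base `round()` rounds half to even, which would print 2.45
#' as 2.4 rather than 2.5).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up at `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG state, restoring the caller's state.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Split protein strings into character matrices / vectors.
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' @noRd
is_protein_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

## The 20 standard amino acids, in a fixed order used by all scoring tables.
#' @noRd
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Background amino-acid frequencies (Robinson-Robinson composition), used by
## the simulator and by the coiled-coil calibration. Kept in code so the
## simulator has no file dependency.
#' @noRd
AA_BACKGROUND <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
  Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
  L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
  S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.064
)

## BLOSUM62 accessor (lazy, cached) from Biostrings.
#' @noRd
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' @noRd
stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single non-negative integer", name),
         call. = FALSE)
  }
}
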