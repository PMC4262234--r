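# Shared internal helpers: amino-acid tables, seeded evaluation, small checks.

# Standard 20-letter alphabet, fixed ordering used for all frequency vectors.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA_123 <- setNames(names(AA_321), unname(AA_321))

# Bondi van der Waals radii (Angstrom) for the heavy elements that occur in
# protein ATOM records. Unknown elements are a hard error at the call site.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)

#' BLOSUM62-derived background amino-acid frequencies
#'
#' The marginal amino-acid frequencies underlying the BLOSUM62 substitution
#' matrix, normalized to sum to exactly 1. Used as the default background
#' distribution for Jensen-Shannon conservation scoring and for the synthetic
#' alignment generator.
#'
#' @return Named numeric vector of length 20 (one entry per standard amino
#'   acid) summing to 1.
#' @export
#' @examples
#' sum(blosum62Background())
blosum62Background <- function() {
  bg <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
          Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
          L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
          S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)
  bg / sum(bg)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Validate that `x` is a probability vector over the 20-letter alphabet.
checkBackground <- function(x) {
  if (!is.numeric(x) || length(x) != 20L)
    stop("background must be a numeric vector of length 20", call. = FALSE)
  if (is.null(names(x)) || !setequal(names(x), AA_ALPHABET))
    stop("background must be named by the 20 standard amino acids",
         call. = FALSE)
  if (abs(sum(x) - 1) > 1e-9)
    stop("background frequencies must sum to 1 (within 1e-9)", call. = FALSE)
  x[AA_ALPHABET]
}

checkSpan <- function(span, n, what = "span") {
  if (length(span) != 2L || !is.numeric(span) || any(is.na(span)))
    stop(sprintf("%s must be a numeric (start, end) pair", what),
         call. = FALSE)
  if (span[1] < 1 || span[2] > n || span[1] > span[2])
    stop(sprintf("%s [%d, %d] out of bounds for length %d",
                 what, span[1], span[2], n), call. = FALSE)
  as.integer(span)
}

# Euclidean distances between one point and rows of a matrix.
distToPoint <- function(xyz, p) {
  sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2)
}

# All pairwise distances between rows of two xyz matrices (small inputs).
crossDist <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 +
       outer(a[, 2], b[, 2], "-")^2 +
       outer(a[, 3], b[, 3], "-")^2)
}

splitSeq <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
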