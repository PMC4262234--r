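# Shared fixture builders and independent oracles. Everything here is kept
# deliberately naive (brute-force scans, exhaustive enumeration) so it can
# serve as an oracle for the package's optimized implementations.

# Hand-build a ProteinStructure from (chain, resno, resid, elety, x, y, z).
makeStructure <- function(df, id = "test") {
  df$elesy <- vapply(df$elety, function(e) {
    if (e == "SG") "S" else substr(gsub("[0-9]", "", e), 1, 1)
  }, character(1))
  new("ProteinStructure", id = id,
      atoms = df[c("chain", "resno", "resid", "elety", "elesy",
                   "x", "y", "z")])
}

# Minimal residue: a single CA atom (plus optional SG for cysteines).
simpleChain <- function(chain, n, y = 0, cys = integer(0),
                        sgOffset = 1.5) {
  rows <- data.frame(chain = chain, resno = seq_len(n),
                     resid = ifelse(seq_len(n) %in% cys, "CYS", "ALA"),
                     elety = "CA", x = 3.8 * (seq_len(n) - 1), y = y,
                     z = 0, stringsAsFactors = FALSE)
  if (length(cys) > 0) {
    sg <- data.frame(chain = chain, resno = cys, resid = "CYS",
                     elety = "SG", x = 3.8 * (cys - 1), y = y,
                     z = sgOffset, stringsAsFactors = FALSE)
    rows <- rbind(rows, sg)
    rows <- rows[order(rows$resno, rows$elety), ]
  }
  rows
}

# Place the SG atoms of cysteines i and j at exactly `dist` apart.
placeBond <- function(atoms, chain, i, j, dist, z = -2) {
  mid <- 3.8 * ((i - 1) + (j - 1)) / 2
  for (p in c(i, j)) {
    sel <- atoms$chain == chain & atoms$resno == p & atoms$elety == "SG"
    atoms$x[sel] <- mid + ifelse(p == i, -dist / 2, dist / 2)
    atoms$z[sel] <- z
  }
  atoms
}

# Brute-force interface scan: all heavy-atom pairs across chains.
bruteInterface <- function(s, cutoff = 3.0) {
  a <- atomTable(s)
  out <- list()
  for (k in seq_len(nrow(a))) {
    for (l in seq_len(nrow(a))) {
      if (a$chain[k] == a$chain[l]) next
      d <- sqrt((a$x[k] - a$x[l])^2 + (a$y[k] - a$y[l])^2 +
                (a$z[k] - a$z[l])^2)
      if (d <= cutoff)
        out[[length(out) + 1L]] <- data.frame(
          chain = a$chain[k], resno = a$resno[k],
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chain = character(), resno = integer(),
                      stringsAsFactors = FALSE))
  u <- unique(do.call(rbind, out))
  u <- u[order(u$chain, u$resno), , drop = FALSE]
  rownames(u) <- NULL
  u
}

# Exhaustive global alignment score: enumerate every monotone matching
# between positions of a and b (unmatched positions are gap columns) and
# take the best total. Independent of any dynamic-programming recurrence.
oracleAlignScore <- function(a, b, mat, gap = -12) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  allMatchings <- function(i, j) {
    # matchings (2-col matrices of paired positions) using positions >= i/j
    res <- list(matrix(integer(0), ncol = 2))
    if (i > n || j > m) return(res)
    for (i2 in i:n) {
      for (j2 in j:m) {
        for (tail in allMatchings(i2 + 1L, j2 + 1L)) {
          res[[length(res) + 1L]] <- rbind(c(i2, j2), tail)
        }
      }
    }
    res
  }
  best <- -Inf
  for (mm in allMatchings(1L, 1L)) {
    k <- nrow(mm)
    sc <- gap * (n + m - 2 * k)
    if (k > 0) sc <- sc + sum(mat[cbind(a[mm[, 1]], b[mm[, 2]])])
    if (sc > best) best <- sc
  }
  best
}

# Sequence-mode loop table with given interior peptides (for composition
# tests; positions are synthesized around each interior).
newLoopSetForTest <- function(interiors) {
  n <- length(interiors)
  data.frame(id = if (n) sprintf("P%02d", seq_len(n)) else character(0),
             chain = rep(NA_character_, n),
             cysI = rep(1L, n),
             cysJ = nchar(interiors) + 2L,
             interior = interiors,
             interiorLength = nchar(interiors),
             stringsAsFactors = FALSE)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Brute-force mimicry hits: O(|H| * |V| * |X|) over an explicit edge list.
bruteMimicry <- function(humanLoops, viralLoops, edges, simThreshold = 0.5) {
  adj <- function(a, b) any((edges$a == a & edges$b == b) |
                            (edges$a == b & edges$b == a))
  nodes <- unique(c(edges$a, edges$b))
  hits <- list()
  for (h in seq_len(nrow(humanLoops))) {
    for (v in seq_len(nrow(viralLoops))) {
      sim <- loopSimilarity(humanLoops$interior[h],
                            viralLoops$interior[v])$similarity
      if (sim <= simThreshold) next
      H <- humanLoops$accession[h]
      V <- viralLoops$accession[v]
      shared <- sort(Filter(function(x) x != H && x != V &&
                              adj(H, x) && adj(V, x), nodes))
      if (length(shared) == 0) next
      hits[[length(hits) + 1L]] <- data.frame(
        humanAccession = H, viralAccession = V, similarity = sim,
        sharedInteractors = paste(shared, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(humanAccession = character(),
                      viralAccession = character(), similarity = numeric(),
                      sharedInteractors = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# Loops + alignments fixture for the conservation stage: `nLoops` planted
# cys-flanked loops with 4-residue interiors in one synthetic alignment.
plantedConservationSet <- function(nLoops = 20, boost = 0.3, seed = 1,
                                   nRows = 50) {
  gap <- 16
  starts <- seq(5, by = gap, length.out = nLoops)
  lr <- do.call(rbind, lapply(starts, function(s) loopRegion(s, s + 5)))
  ms <- msaSpec(nRows = nRows, length = max(starts) + 15, loopRegions = lr,
                loopBoost = boost, seed = seed)
  aln <- makeConservationMsa(ms)
  ref <- as.character(aln[[1]])
  loops <- data.frame(id = "ref", chain = NA_character_,
                      cysI = as.integer(starts),
                      cysJ = as.integer(starts + 5),
                      interior = substring(ref, starts + 1, starts + 4),
                      family = "", stringsAsFactors = FALSE)
  list(loops = loops, alignments = list(ref = aln))
}
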