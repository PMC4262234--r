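# Geometric detection of short disulphide-bonded loops and the knot-exclusion
# rules shared by structure and sequence modes.

# Conflict rules between candidate bonds on the same chain/sequence. Returns
# a logical keep-vector. Rules:
#   * bonds sharing a cysteine endpoint exclude each other;
#   * interleaved spans i1 < i2 < j1 < j2 (knot-like) exclude each other;
#   * a bond whose interior contains a cysteine engaged in another bond is
#     excluded (this also covers the outer bond of a nested pair).
dropKnotted <- function(i, j) {
  n <- length(i)
  keep <- rep(TRUE, n)
  if (n <= 1L) return(keep)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      shared <- length(intersect(c(i[a], j[a]), c(i[b], j[b]))) > 0L
      interleaved <- (i[a] < i[b] & i[b] < j[a] & j[a] < j[b]) |
                     (i[b] < i[a] & i[a] < j[b] & j[b] < j[a])
      if (shared || interleaved) {
        keep[a] <- FALSE
        keep[b] <- FALSE
        next
      }
      aInsideB <- (i[a] > i[b] & i[a] < j[b]) | (j[a] > i[b] & j[a] < j[b])
      bInsideA <- (i[b] > i[a] & i[b] < j[a]) | (j[b] > i[a] & j[b] < j[a])
      if (bInsideA) keep[a] <- FALSE  # a's interior holds b's cysteine
      if (aInsideB) keep[b] <- FALSE
    }
  }
  keep
}

#' Detect short disulphide-bonded loops in a structure
#'
#' Tests every same-chain cysteine pair whose sequence separation allows a
#' short loop, and keeps pairs whose S-gamma--S-gamma distance falls inside
#' `bondWindow` (the canonical disulphide bond length is about 2.05 Angstrom)
#' and whose interior length (residues strictly between the cysteines) lies
#' in `interiorRange`. Knot-like arrangements are then removed: interleaved
#' spans, bonds sharing a cysteine, and loops whose interior contains a
#' cysteine engaged in another detected bond. Cysteines lacking an S-gamma
#' atom cannot be tested and are skipped with a warning.
#'
#' @param s A [ProteinStructure].
#' @param interiorRange Inclusive `c(min, max)` bounds on interior length
#'   (default 2--9, the structure-mode definition).
#' @param bondWindow `c(lo, hi)` S-gamma distance window in Angstrom
#'   (default `c(1.6, 2.5)`).
#' @param maxSpan Maximum total loop length, cysteines included (default 11).
#' @return A [LoopSet] in structure mode, sorted by (chain, cysI).
#' @export
#' @examples
#' s <- makeLoopStructure(structureSpec(loopPlants = loopPlant("A", 5, 10)))
#' detectDisulphideLoops(s)
detectDisulphideLoops <- function(s, interiorRange = c(2L, 9L),
                                  bondWindow = c(1.6, 2.5),
                                  maxSpan = 11L) {
  stopifnot(is(s, "ProteinStructure"),
            length(interiorRange) == 2L, length(bondWindow) == 2L,
            interiorRange[1] <= interiorRange[2],
            bondWindow[1] <= bondWindow[2])
  a <- s@atoms
  cys <- unique(a[a$resid == "CYS", c("chain", "resno")])
  out <- list()
  for (ch in unique(cys$chain)) {
    pos <- sort(cys$resno[cys$chain == ch])
    if (length(pos) < 2L) next
    sg <- a[a$chain == ch & a$resid == "CYS" & a$elety == "SG",
            c("resno", "x", "y", "z")]
    noSG <- setdiff(pos, sg$resno)
    if (length(noSG) > 0L)
      warning(sprintf("chain %s: cysteine(s) %s lack S-gamma atoms; skipped",
                      ch, paste(noSG, collapse = ", ")), call. = FALSE)
    pos <- setdiff(pos, noSG)
    if (length(pos) < 2L) next
    cand <- NULL
    for (ii in seq_len(length(pos) - 1L)) {
      for (jj in (ii + 1L):length(pos)) {
        pi <- pos[ii]; pj <- pos[jj]
        interior <- pj - pi - 1L
        if (interior < interiorRange[1] || interior > interiorRange[2]) next
        if (pj - pi + 1L > maxSpan) next
        si <- sg[match(pi, sg$resno), c("x", "y", "z")]
        sj <- sg[match(pj, sg$resno), c("x", "y", "z")]
        d <- sqrt(sum((as.numeric(si) - as.numeric(sj))^2))
        if (d < bondWindow[1] || d > bondWindow[2]) next
        cand <- rbind(cand, data.frame(i = pi, j = pj,
                                       stringsAsFactors = FALSE))
      }
    }
    if (is.null(cand)) next
    keep <- dropKnotted(cand$i, cand$j)
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) next
    seq1 <- residueSequence(a, ch)
    out[[ch]] <- data.frame(
      id = s@id, chain = ch, cysI = cand$i, cysJ = cand$j,
      interior = vapply(seq_len(nrow(cand)), function(k)
        paste(seq1$aa[seq1$resno > cand$i[k] & seq1$resno < cand$j[k]],
              collapse = ""), character(1)),
      stringsAsFactors = FALSE)
  }
  loops <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(id = character(), chain = character(), cysI = integer(),
               cysJ = integer(), interior = character(),
               stringsAsFactors = FALSE)
  loops <- loops[order(loops$chain, loops$cysI), , drop = FALSE]
  loops$interiorLength <- loops$cysJ - loops$cysI - 1L
  newLoopSet(loops, "structure")
}

# One-letter residue sequence of a chain, keyed by residue number.
residueSequence <- function(atoms, chain) {
  r <- unique(atoms[atoms$chain == chain, c("resno", "resid")])
  aa <- AA_321[r$resid]
  aa[is.na(aa)] <- "X"
  data.frame(resno = r$resno, aa = unname(aa), stringsAsFactors = FALSE)
}

#' Collapse redundant loops to one representative structure each
#'
#' Structures of the same protein frequently repeat the same loop; one
#' representative per (accession, cysI, cysJ) is kept, chosen as the
#' lexicographically smallest structure id so the choice is deterministic.
#'
#' @param loops data.frame with at least columns `accession`, `cysI`, `cysJ`
#'   and `structureId` (extra columns are carried through).
#' @return The de-duplicated data.frame, original column order preserved.
#' @export
deduplicateLoops <- function(loops) {
  stopifnot(is.data.frame(loops),
            all(c("accession", "cysI", "cysJ", "structureId") %in%
                names(loops)))
  if (nrow(loops) == 0L) return(loops)
  key <- paste(loops$accession, loops$cysI, loops$cysJ, sep = "\r")
  ord <- order(key, loops$structureId)
  picked <- loops[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  picked[order(match(rownames(picked), rownames(loops))), , drop = FALSE]
}
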