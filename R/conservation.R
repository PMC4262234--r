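# Jensen-Shannon conservation scoring and the loop-vs-juxtapeptide statistic.

GAP_CHARS <- c("-", ".")

alignmentMatrix <- function(aln) {
  if (is(aln, "AAStringSet") || is(aln, "XStringSet"))
    aln <- as.character(aln)
  if (!is.character(aln) || length(aln) == 0L)
    stop("alignment is empty", call. = FALSE)
  w <- nchar(aln)
  if (length(unique(w)) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  do.call(rbind, strsplit(aln, "", fixed = TRUE))
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Generalized Jensen-Shannon divergence with mixture weight lambda, log base
# 2, which is bounded by the binary entropy of lambda (attained for
# distributions with disjoint support).
jsDivergence <- function(p, q, lambda = 0.5) {
  m <- lambda * p + (1 - lambda) * q
  shannon(m) - lambda * shannon(p) - (1 - lambda) * shannon(q)
}

#' Jensen-Shannon divergence conservation profile
#'
#' Scores each alignment column by the Jensen-Shannon divergence between the
#' column's amino-acid distribution (gaps and non-standard letters excluded)
#' and a background distribution, normalized to \[0, 1\] by the divergence
#' maximum and scaled by `(1 - gap fraction)` so gappy columns score low.
#' All-gap columns score 0. An optional symmetric window replaces each score
#' by the mean over `window` columns on each side (0 = off).
#'
#' @param aln An [Biostrings::AAStringSet] or character vector of equal-width
#'   aligned sequences.
#' @param background Named amino-acid frequency vector summing to 1.
#' @param window Half-width of the symmetric smoothing window (default 0).
#' @param lambda Mixture weight of the divergence (default 0.5, the
#'   symmetric case).
#' @return A [ConservationProfile].
#' @export
#' @examples
#' aln <- c("ACDEF", "ACDEF", "ACDEW")
#' conservationScores(jsConservation(aln))
jsConservation <- function(aln, background = blosum62Background(),
                           window = 0L, lambda = 0.5) {
  background <- checkBackground(background)
  if (lambda <= 0 || lambda >= 1)
    stop("lambda must lie strictly between 0 and 1", call. = FALSE)
  M <- alignmentMatrix(aln)
  n <- nrow(M)
  L <- ncol(M)
  maxDiv <- -(lambda * log2(lambda) + (1 - lambda) * log2(1 - lambda))
  # per-column counts over the fixed alphabet, vectorized via tabulate
  codes <- matrix(match(M, AA_ALPHABET), nrow = n)
  gapFrac <- colMeans(matrix(M %in% GAP_CHARS, nrow = n))
  score <- numeric(L)
  for (k in seq_len(L)) {
    cnt <- tabulate(codes[, k], nbins = 20L)
    tot <- sum(cnt)
    if (tot == 0L) { score[k] <- 0; next }
    p <- cnt / tot
    score[k] <- jsDivergence(p, background, lambda) / maxDiv *
      (1 - gapFrac[k])
  }
  score <- pmin(1, pmax(0, score))
  if (window > 0L) {
    sm <- vapply(seq_len(L), function(k) {
      idx <- max(1L, k - window):min(L, k + window)
      mean(score[idx])
    }, numeric(1))
    score <- sm
  }
  new("ConservationProfile", score = score, gapFraction = gapFrac,
      background = background, window = as.integer(window))
}

#' Map a loop's reference positions to alignment columns
#'
#' The first alignment row is the reference; its non-gap positions define
#' the mapping from sequence coordinates to columns. A loop's terminal
#' cysteines are considered conserved when at least one homolog row carries
#' a cysteine at *both* terminal columns (a gap or any other residue at
#' either terminal disqualifies that homolog).
#'
#' @param loop One loop row with `cysI` and `cysJ` reference positions.
#' @param aln The alignment ([Biostrings::AAStringSet] or character), row 1
#'   the reference.
#' @return list with `interiorCols`, `terminalCols` and `cysConserved`.
#' @export
mapLoopColumns <- function(loop, aln) {
  if (is(loop, "LoopSet")) {
    stopifnot(length(loop) == 1L)
    loop <- loopTable(loop)
  }
  M <- alignmentMatrix(aln)
  refMap <- which(!(M[1, ] %in% GAP_CHARS))
  if (loop$cysJ > length(refMap) || loop$cysI < 1L)
    stop(sprintf("loop (%d, %d) falls off the reference sequence (length %d)",
                 loop$cysI, loop$cysJ, length(refMap)), call. = FALSE)
  terminalCols <- refMap[c(loop$cysI, loop$cysJ)]
  interiorCols <- refMap[seq(loop$cysI + 1L,
                             length.out = loop$cysJ - loop$cysI - 1L)]
  cysConserved <- FALSE
  if (nrow(M) > 1L) {
    hom <- M[-1, , drop = FALSE]
    cysConserved <- any(hom[, terminalCols[1]] == "C" &
                        hom[, terminalCols[2]] == "C")
  }
  list(interiorCols = interiorCols, terminalCols = terminalCols,
       cysConserved = cysConserved)
}

#' Loop-interior vs juxtapeptide-flank conservation difference
#'
#' The interior mean is taken over the loop's interior columns only (the
#' terminal cysteine columns are excluded, since bond-forming cysteines are
#' conserved for structural reasons). The flank ("juxtapeptide") mean is
#' taken over up to `flankWidth` reference positions on each side of the
#' loop, skipping positions that fall off the sequence or inside any other
#' annotated loop span. A loop with no usable flank position is flagged
#' (`usableFlank = FALSE`, `difference = NA`) and should be excluded from
#' distributions.
#'
#' @param profile A [ConservationProfile] of the loop's alignment.
#' @param loop One loop row (`id`, `cysI`, `cysJ`, optionally `family`).
#' @param aln The alignment used for `profile` (row 1 = reference).
#' @param flankWidth Flank width per side in residues (default 4).
#' @param otherLoops Optional data.frame of the other loops on the same
#'   protein (`cysI`, `cysJ`), whose spans are excluded from the flank.
#' @return One-row data.frame: `id`, `cysI`, `cysJ`, `interiorMean`,
#'   `flankMean`, `difference`, `cysConserved`, `usableFlank`, `family`.
#' @export
loopFlankDifference <- function(profile, loop, aln, flankWidth = 4L,
                                otherLoops = NULL) {
  stopifnot(is(profile, "ConservationProfile"))
  if (is(loop, "LoopSet")) {
    stopifnot(length(loop) == 1L)
    loop <- loopTable(loop)
  }
  if (loop$cysJ - loop$cysI - 1L < 1L)
    stop("loop has an empty interior", call. = FALSE)
  mp <- mapLoopColumns(loop, aln)
  score <- profile@score
  M <- alignmentMatrix(aln)
  refLen <- sum(!(M[1, ] %in% GAP_CHARS))
  refMap <- which(!(M[1, ] %in% GAP_CHARS))

  flankPos <- c(seq(loop$cysI - flankWidth, loop$cysI - 1L),
                seq(loop$cysJ + 1L, loop$cysJ + flankWidth))
  flankPos <- flankPos[flankPos >= 1L & flankPos <= refLen]
  if (!is.null(otherLoops) && nrow(otherLoops) > 0L) {
    inOther <- vapply(flankPos, function(p)
      any(p >= otherLoops$cysI & p <= otherLoops$cysJ), logical(1))
    flankPos <- flankPos[!inOther]
  }
  interiorMean <- mean(score[mp$interiorCols])
  usable <- length(flankPos) > 0L
  flankMean <- if (usable) mean(score[refMap[flankPos]]) else NA_real_
  data.frame(id = loop$id, cysI = loop$cysI, cysJ = loop$cysJ,
             interiorMean = interiorMean, flankMean = flankMean,
             difference = interiorMean - flankMean,
             cysConserved = mp$cysConserved, usableFlank = usable,
             family = loop$family %||% "",
             stringsAsFactors = FALSE)
}

#' Run the conservation survey over a set of loops and their alignments
#'
#' Convenience orchestrator: scores each protein's alignment once with
#' [jsConservation()], computes one [loopFlankDifference()] record per loop
#' (flanks exclude the spans of the protein's other loops), and collects the
#' per-position scores at each distance from the bond-forming cysteines for
#' [positionalProfile()].
#'
#' @param loops A sequence-mode [LoopSet].
#' @param alignments Named list of alignments, one per accession appearing
#'   in `loops` (names are accessions; row 1 of each is the reference).
#' @param background,window Passed to [jsConservation()].
#' @param flankWidth Flank width per side (default 4).
#' @param requireCysConserved Keep only loops whose terminal cysteines are
#'   conserved in at least one homolog (default `TRUE`, mirroring the rule
#'   that only aligned loops are scored).
#' @param maxDist Maximum distance from a cysteine for positional scores.
#' @return list with `records` (one row per usable loop) and `positions`
#'   (long data.frame of per-distance inside/outside scores).
#' @export
conservationSurvey <- function(loops, alignments,
                               background = blosum62Background(),
                               window = 0L, flankWidth = 4L,
                               requireCysConserved = TRUE, maxDist = 4L) {
  tab <- if (is(loops, "LoopSet")) loopTable(loops) else loops
  if (!"family" %in% names(tab)) tab$family <- ""
  recs <- list()
  poss <- list()
  for (acc in unique(tab$id)) {
    aln <- alignments[[acc]]
    if (is.null(aln)) {
      warning("no alignment for accession ", acc, "; skipped",
              call. = FALSE)
      next
    }
    prof <- jsConservation(aln, background = background, window = window)
    M <- alignmentMatrix(aln)
    refMap <- which(!(M[1, ] %in% GAP_CHARS))
    refLen <- length(refMap)
    sub <- tab[tab$id == acc, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      loop <- sub[k, ]
      others <- sub[-k, c("cysI", "cysJ"), drop = FALSE]
      rec <- loopFlankDifference(prof, loop, aln, flankWidth = flankWidth,
                                 otherLoops = others)
      if (requireCysConserved && !rec$cysConserved) next
      recs[[length(recs) + 1L]] <- rec

      inOther <- function(p) nrow(others) > 0L &&
        any(p >= others$cysI & p <= others$cysJ)
      for (d in seq_len(maxDist)) {
        pieces <- list(
          c(loop$cysI + d, "left", "inside"),
          c(loop$cysI - d, "left", "outside"),
          c(loop$cysJ - d, "right", "inside"),
          c(loop$cysJ + d, "right", "outside"))
        for (pc in pieces) {
          p <- as.integer(pc[1])
          if (p < 1L || p > refLen) next
          if (pc[3] == "inside" && (p <= loop$cysI || p >= loop$cysJ)) next
          if (pc[3] == "outside" && inOther(p)) next
          poss[[length(poss) + 1L]] <- data.frame(
            id = acc, cysI = loop$cysI, cysJ = loop$cysJ,
            side = pc[2], distance = d, location = pc[3],
            score = prof@score[refMap[p]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty <- data.frame(id = character(), cysI = integer(), cysJ = integer(),
                      side = character(), distance = integer(),
                      location = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  list(records = if (length(recs)) do.call(rbind, recs) else NULL,
       positions = if (length(poss)) do.call(rbind, poss) else empty)
}

#' Positional conservation profile around the bond-forming cysteines
#'
#' For each distance d = 1..`maxDist` from a terminal cysteine, compares the
#' conservation of residues d positions *inside* the loop with residues d
#' positions *outside*, pooled over all loops, with a one-sided
#' Mann-Whitney U test (alternative: inside more conserved).
#'
#' @param positions Long data.frame as returned in
#'   `conservationSurvey()$positions`.
#' @param maxDist Maximum distance to report (default 4).
#' @return data.frame with one row per distance: sample sizes, means,
#'   standard errors and the one-sided p-value; distances with fewer than
#'   two contributing loops on either side are reported as `NA` ("missing").
#' @export
positionalProfile <- function(positions, maxDist = 4L) {
  out <- lapply(seq_len(maxDist), function(d) {
    sub <- positions[positions$distance == d, , drop = FALSE]
    ins <- sub[sub$location == "inside", , drop = FALSE]
    outs <- sub[sub$location == "outside", , drop = FALSE]
    nLoop <- function(x) nrow(unique(x[c("id", "cysI", "cysJ")]))
    if (nLoop(ins) < 2L || nLoop(outs) < 2L) {
      return(data.frame(distance = d, nInside = nrow(ins),
                        nOutside = nrow(outs), insideMean = NA_real_,
                        outsideMean = NA_real_, insideSE = NA_real_,
                        outsideSE = NA_real_, p = NA_real_))
    }
    mw <- mannWhitneyU(ins$score, outs$score, alternative = "greater")
    data.frame(distance = d, nInside = nrow(ins), nOutside = nrow(outs),
               insideMean = mean(ins$score), outsideMean = mean(outs$score),
               insideSE = sd(ins$score) / sqrt(nrow(ins)),
               outsideSE = sd(outs$score) / sqrt(nrow(outs)),
               p = mw$p)
  })
  do.call(rbind, out)
}

#' Preferentially conserved loops and their family tally
#'
#' Selects records whose interior-vs-flank conservation difference strictly
#' exceeds `threshold` (default 0.30) and tallies them by protein family;
#' records without a family label are pooled as `"Other"`.
#'
#' @param records Record data.frame from [conservationSurvey()] /
#'   [loopFlankDifference()].
#' @param threshold Strict lower bound on the difference (default 0.30).
#' @return list with `records` (the qualifying subset) and `tally`
#'   (data.frame `family`, `count`, descending; counts sum to the subset
#'   size).
#' @export
preferentiallyConserved <- function(records, threshold = 0.30) {
  stopifnot(is.data.frame(records), "difference" %in% names(records))
  sub <- records[!is.na(records$difference) &
                 records$difference > threshold, , drop = FALSE]
  fam <- sub$family %||% rep("", nrow(sub))
  fam[is.na(fam) | fam == ""] <- "Other"
  if (length(fam) == 0L) {
    tally <- data.frame(family = character(), count = integer(),
                        stringsAsFactors = FALSE)
    rownames(sub) <- NULL
    return(list(records = sub, tally = tally))
  }
  tally <- as.data.frame(table(family = fam), stringsAsFactors = FALSE)
  names(tally) <- c("family", "count")
  tally$count <- as.integer(tally$count)
  tally <- tally[order(-tally$count, tally$family), , drop = FALSE]
  rownames(tally) <- NULL
  rownames(sub) <- NULL
  list(records = sub, tally = tally)
}
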