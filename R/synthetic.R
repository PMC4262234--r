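# Synthetic fixtures with planted signal: toy structures, alignments,
# prediction profiles and interaction networks. The geometry is deliberately
# schematic -- an extended chain with 3.8 A C-alpha spacing and explicitly
# placed S-gamma atoms -- because every quantity the survey tests (S-S
# distance, inter-chain contact distance, surface exposure) is purely metric.

#' Specify a planted disulphide loop
#'
#' @param chain Chain identifier (single letter).
#' @param i,j 1-based residue positions of the two cysteines (`i < j`).
#' @param dist Target S-gamma--S-gamma distance in Angstrom (default 2.05,
#'   the canonical disulphide bond length).
#' @return One-row data.frame suitable for `structureSpec(loopPlants = ...)`.
#' @export
loopPlant <- function(chain, i, j, dist = 2.05) {
  data.frame(chain = chain, i = as.integer(i), j = as.integer(j),
             dist = dist, stringsAsFactors = FALSE)
}

#' Specification of a synthetic multi-chain structure
#'
#' Parameters of the toy structures written by [makeLoopStructure()]. Chains
#' are parallel extended strands laid along x with identical atom offsets, so
#' the minimum heavy-atom distance between adjacent chains is exactly
#' `interChainGap`.
#'
#' @param nChains Number of chains (labelled `A`, `B`, ...).
#' @param chainLength Residues per chain.
#' @param loopPlants data.frame of planted loops (see [loopPlant()]); rbind
#'   several rows to plant several loops.
#' @param interChainGap Minimum heavy-atom distance between chains, Angstrom.
#' @param seed Integer seed controlling the (non-cysteine) residue identities.
#' @return A list of class `"structureSpec"`.
#' @export
#' @examples
#' structureSpec(loopPlants = loopPlant("A", 5, 10, 2.05))
structureSpec <- function(nChains = 2L, chainLength = 20L,
                          loopPlants = NULL, interChainGap = 6,
                          seed = 1L) {
  if (interChainGap <= 0) stop("interChainGap must be > 0", call. = FALSE)
  if (nChains < 1L || chainLength < 1L)
    stop("nChains and chainLength must be >= 1", call. = FALSE)
  if (is.null(loopPlants))
    loopPlants <- loopPlant("A", 1, 2)[0, ]
  stopifnot(is.data.frame(loopPlants),
            all(c("chain", "i", "j", "dist") %in% names(loopPlants)))
  for (k in seq_len(nrow(loopPlants))) {
    p <- loopPlants[k, ]
    if (!p$chain %in% LETTERS[seq_len(nChains)])
      stop(sprintf("plant %d: chain '%s' not in structure", k, p$chain),
           call. = FALSE)
    if (p$i < 1 || p$j > chainLength || p$i >= p$j)
      stop(sprintf("plant %d: cysteine positions (%d, %d) outside chain of length %d",
                   k, p$i, p$j, chainLength), call. = FALSE)
    if (p$dist <= 0)
      stop(sprintf("plant %d: target S-S distance must be > 0", k),
           call. = FALSE)
  }
  structure(list(nChains = as.integer(nChains),
                 chainLength = as.integer(chainLength),
                 loopPlants = loopPlants,
                 interChainGap = interChainGap,
                 seed = as.integer(seed)),
            class = "structureSpec")
}

# Fixed intra-residue atom offsets (dx, dz) relative to the C-alpha; every
# chain uses the same offsets so inter-chain separation is exactly the y gap.
.RES_OFFSETS <- data.frame(
  elety = c("N", "CA", "C", "O", "CB"),
  elesy = c("N", "C", "C", "O", "C"),
  dx = c(-1.2, 0.0, 1.2, 1.2, 0.0),
  dz = c(0.6, 0.0, 0.6, 1.8, -1.5),
  stringsAsFactors = FALSE)

#' Generate a toy structure with planted disulphide loops
#'
#' Writes a parseable single-MODEL PDB file in which every planted loop's two
#' cysteines carry S-gamma atoms at the requested distance (exact to well
#' under 0.01 Angstrom) and chains are parallel strands separated by exactly
#' `interChainGap`. Non-cysteine residue identities are drawn (seeded) from a
#' small set of non-cysteine amino acids. Output is deterministic for a fixed
#' spec and seed.
#'
#' @param spec A [structureSpec()].
#' @param file Optional output path; when given, a PDB file is written there.
#' @return (Invisibly) the generated [ProteinStructure].
#' @export
makeLoopStructure <- function(spec, file = NULL) {
  stopifnot(inherits(spec, "structureSpec"))
  withSeed(spec$seed, {
    pool <- c("ALA", "GLY", "SER", "THR", "LEU", "VAL", "GLU", "LYS",
              "ASP", "PHE")
    chains <- LETTERS[seq_len(spec$nChains)]
    rows <- vector("list", spec$nChains)
    for (ci in seq_along(chains)) {
      ch <- chains[ci]
      y <- (ci - 1L) * spec$interChainGap
      resid <- sample(pool, spec$chainLength, replace = TRUE)
      plants <- spec$loopPlants[spec$loopPlants$chain == ch, , drop = FALSE]
      cysPos <- unique(c(plants$i, plants$j))
      resid[cysPos] <- "CYS"
      xs <- 3.8 * (seq_len(spec$chainLength) - 1L)
      at <- do.call(rbind, lapply(seq_len(spec$chainLength), function(r) {
        data.frame(chain = ch, resno = r, resid = resid[r],
                   elety = .RES_OFFSETS$elety, elesy = .RES_OFFSETS$elesy,
                   x = xs[r] + .RES_OFFSETS$dx, y = y,
                   z = .RES_OFFSETS$dz, stringsAsFactors = FALSE)
      }))
      # place S-gamma pairs symmetrically about the plant midpoint; each
      # plant gets its own z shelf so plants cannot contact one another
      if (nrow(plants) > 0) {
        sg <- do.call(rbind, lapply(seq_len(nrow(plants)), function(k) {
          p <- plants[k, ]
          mid <- (xs[p$i] + xs[p$j]) / 2
          zsh <- -3.0 - 1.5 * (k - 1L)
          data.frame(chain = ch, resno = c(p$i, p$j), resid = "CYS",
                     elety = "SG", elesy = "S",
                     x = c(mid - p$dist / 2, mid + p$dist / 2),
                     y = y, z = zsh, stringsAsFactors = FALSE)
        }))
        at <- rbind(at, sg)
      }
      at <- at[order(at$resno, match(at$elety,
                                     c(.RES_OFFSETS$elety, "SG"))), ]
      rows[[ci]] <- at
    }
    atoms <- do.call(rbind, rows)
    rownames(atoms) <- NULL
    s <- new("ProteinStructure", id = "synthetic", atoms = atoms)
    if (!is.null(file)) {
      writePdbAtoms(atoms, file)
      s@id <- sub("\\.[^.]*$", "", basename(file))
    }
    invisible(s)
  })
}

# ---- alignments -------------------------------------------------------------

#' Specify a loop region inside a synthetic alignment
#'
#' @param start,end 1-based reference positions of the terminal cysteines.
#' @param cysFlanked Should both terminals be invariant cysteines in every
#'   row (default `TRUE`)?
#' @return One-row data.frame for `msaSpec(loopRegions = ...)`.
#' @export
loopRegion <- function(start, end, cysFlanked = TRUE) {
  data.frame(start = as.integer(start), end = as.integer(end),
             cysFlanked = cysFlanked, stringsAsFactors = FALSE)
}

#' Specification of a synthetic multiple sequence alignment
#'
#' Row 1 is the ungapped reference (the per-column consensus itself); every
#' other row copies the column consensus with probability `baseConservation`
#' (plus `loopBoost` inside loop interiors) and otherwise draws from the
#' background distribution. The default `baseConservation` of 0.6 places the
#' generator at the operating point where the Jensen-Shannon column score
#' responds to a copy-probability boost with approximately unit gain, so a
#' planted `loopBoost` is recovered on the score scale (see the vignette).
#'
#' @param nRows Number of sequences including the reference.
#' @param length Alignment columns.
#' @param background Named amino-acid frequency vector summing to 1.
#' @param baseConservation Probability that a row copies the column consensus
#'   outside loop interiors.
#' @param loopRegions data.frame of loop regions (see [loopRegion()]).
#' @param loopBoost Additive increment to `baseConservation` strictly inside
#'   loop regions; `baseConservation + loopBoost` must not exceed 1.
#' @param seed Integer seed.
#' @return A list of class `"msaSpec"`.
#' @export
msaSpec <- function(nRows = 50L, length = 100L,
                    background = blosum62Background(),
                    baseConservation = 0.6, loopRegions = NULL,
                    loopBoost = 0.3, seed = 1L) {
  background <- checkBackground(background)
  if (baseConservation < 0 || loopBoost < 0 ||
      baseConservation + loopBoost > 1)
    stop("need 0 <= baseConservation and baseConservation + loopBoost <= 1",
         call. = FALSE)
  if (is.null(loopRegions)) loopRegions <- loopRegion(1, 2)[0, ]
  stopifnot(is.data.frame(loopRegions),
            all(c("start", "end", "cysFlanked") %in% names(loopRegions)))
  if (nrow(loopRegions) > 0) {
    if (any(loopRegions$start < 1) || any(loopRegions$end > length) ||
        any(loopRegions$start >= loopRegions$end))
      stop("loop regions must lie within [1, length] with start < end",
           call. = FALSE)
  }
  structure(list(nRows = as.integer(nRows), length = as.integer(length),
                 background = background,
                 baseConservation = baseConservation,
                 loopRegions = loopRegions, loopBoost = loopBoost,
                 seed = as.integer(seed)),
            class = "msaSpec")
}

#' Generate a synthetic alignment with planted loop-interior conservation
#'
#' @param spec An [msaSpec()].
#' @param file Optional path; when given the alignment is written there as
#'   aligned FASTA.
#' @return (Invisibly) an [Biostrings::AAStringSet] whose first element
#'   (named `"ref"`) is the ungapped reference sequence.
#' @export
makeConservationMsa <- function(spec, file = NULL) {
  stopifnot(inherits(spec, "msaSpec"))
  lr <- spec$loopRegions
  if (nrow(lr) > 1) {
    o <- order(lr$start)
    s <- lr$start[o]; e <- lr$end[o]
    if (any(s[-1] <= e[-length(e)]))
      stop("loop regions overlap", call. = FALSE)
  }
  withSeed(spec$seed, {
    L <- spec$length; n <- spec$nRows
    bg <- spec$background
    consensus <- sample(names(bg), L, replace = TRUE, prob = bg)
    p <- rep(spec$baseConservation, L)
    for (k in seq_len(nrow(lr))) {
      int <- seq(lr$start[k] + 1L, length.out = max(0L, lr$end[k] - lr$start[k] - 1L))
      p[int] <- spec$baseConservation + spec$loopBoost
      if (lr$cysFlanked[k]) {
        consensus[c(lr$start[k], lr$end[k])] <- "C"
        p[c(lr$start[k], lr$end[k])] <- 1
      }
    }
    rows <- matrix("", nrow = n, ncol = L)
    rows[1, ] <- consensus
    if (n > 1) {
      copy <- matrix(runif((n - 1L) * L), nrow = n - 1L) <
        matrix(p, nrow = n - 1L, ncol = L, byrow = TRUE)
      draw <- matrix(sample(names(bg), (n - 1L) * L, replace = TRUE,
                            prob = bg), nrow = n - 1L)
      cons <- matrix(consensus, nrow = n - 1L, ncol = L, byrow = TRUE)
      rows[-1, ] <- ifelse(copy, cons, draw)
    }
    seqs <- apply(rows, 1L, paste, collapse = "")
    names(seqs) <- c("ref", sprintf("hom%03d", seq_len(n - 1L)))
    aln <- Biostrings::AAStringSet(seqs)
    if (!is.null(file)) Biostrings::writeXStringSet(aln, file, width = 80L)
    invisible(aln)
  })
}

# ---- interaction networks ---------------------------------------------------

#' Specification of a synthetic interaction network
#'
#' Human nodes are labelled `HUM0001...`, viral nodes `VIR0001...`. Each
#' planted triangle (H, V, X) contributes the two edges H--X and V--X, so
#' that H and V share the interactor X. Noise edges are sampled uniformly
#' among node pairs and rejected if they would hand any planted (H, V) pair
#' an interactor that was not planted.
#'
#' @param nHuman,nVirus Node counts per taxon.
#' @param plantedTriangles data.frame with columns `h`, `v`, `x` naming the
#'   human loop protein, viral loop protein and shared human interactor of
#'   each planted triangle (see [plantedTriangle()]).
#' @param noiseEdges Number of random extra edges.
#' @param seed Integer seed.
#' @return A list of class `"networkSpec"`.
#' @export
networkSpec <- function(nHuman = 10L, nVirus = 5L, plantedTriangles = NULL,
                        noiseEdges = 0L, seed = 1L) {
  if (nHuman < 0 || nVirus < 0 || noiseEdges < 0)
    stop("counts must be >= 0", call. = FALSE)
  if (is.null(plantedTriangles)) plantedTriangles <- plantedTriangle("", "", "")[0, ]
  stopifnot(is.data.frame(plantedTriangles),
            all(c("h", "v", "x") %in% names(plantedTriangles)))
  humans <- sprintf("HUM%04d", seq_len(nHuman))
  viruses <- sprintf("VIR%04d", seq_len(nVirus))
  for (k in seq_len(nrow(plantedTriangles))) {
    t <- plantedTriangles[k, ]
    if (anyDuplicated(c(t$h, t$v, t$x)))
      stop(sprintf("triangle %d: members must be distinct", k), call. = FALSE)
    if (!t$h %in% humans || !t$x %in% humans || !t$v %in% viruses)
      stop(sprintf("triangle %d: members must be existing HUM/VIR node ids", k),
           call. = FALSE)
  }
  structure(list(nHuman = as.integer(nHuman), nVirus = as.integer(nVirus),
                 plantedTriangles = plantedTriangles,
                 noiseEdges = as.integer(noiseEdges),
                 seed = as.integer(seed)),
            class = "networkSpec")
}

#' @rdname networkSpec
#' @param h,v,x Node identifiers of one planted triangle.
#' @export
plantedTriangle <- function(h, v, x) {
  data.frame(h = h, v = v, x = x, stringsAsFactors = FALSE)
}

#' Generate a PSI-MITAB 2.5 interaction file with planted mimicry triangles
#'
#' @param spec A [networkSpec()].
#' @param file Optional path; when given, one PSI-MITAB 2.5 line is written
#'   per edge (tab-delimited, 15 columns, `uniprotkb:` accessions, taxid
#'   columns `9606` for human and `10239` labelled `virus` for viral nodes).
#' @return (Invisibly) a data.frame of edges with columns `a`, `b`, `taxonA`,
#'   `taxonB`.
#' @export
makeInteractionNetwork <- function(spec, file = NULL) {
  stopifnot(inherits(spec, "networkSpec"))
  humans <- sprintf("HUM%04d", seq_len(spec$nHuman))
  viruses <- sprintf("VIR%04d", seq_len(spec$nVirus))
  taxon <- c(setNames(rep("human", length(humans)), humans),
             setNames(rep("virus", length(viruses)), viruses))
  tri <- spec$plantedTriangles
  edges <- unique(rbind(
    data.frame(a = tri$h, b = tri$x, stringsAsFactors = FALSE),
    data.frame(a = tri$v, b = tri$x, stringsAsFactors = FALSE)))

  edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  sharedOf <- function(ed, h, v) {
    na <- unique(c(ed$b[ed$a == h], ed$a[ed$b == h]))
    nb <- unique(c(ed$b[ed$a == v], ed$a[ed$b == v]))
    setdiff(intersect(na, nb), c(h, v))
  }
  plantedShared <- lapply(seq_len(nrow(tri)), function(k)
    sort(tri$x[tri$h == tri$h[k] & tri$v == tri$v[k]]))

  withSeed(spec$seed, {
    nodes <- c(humans, viruses)
    added <- 0L; attempts <- 0L
    maxAttempts <- max(10L, 10L * spec$noiseEdges)
    while (added < spec$noiseEdges) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("could not place noise edges without creating unplanted ",
             "triangles (attempt cap reached)", call. = FALSE)
      pair <- sample(nodes, 2L)
      if (edgeKey(pair[1], pair[2]) %in% edgeKey(edges$a, edges$b)) next
      cand <- rbind(edges, data.frame(a = pair[1], b = pair[2],
                                      stringsAsFactors = FALSE))
      ok <- TRUE
      for (k in seq_len(nrow(tri))) {
        if (!identical(sort(sharedOf(cand, tri$h[k], tri$v[k])),
                       plantedShared[[k]])) { ok <- FALSE; break }
      }
      if (!ok) next
      edges <- cand
      added <- added + 1L
    }
    edges$taxonA <- unname(taxon[edges$a])
    edges$taxonB <- unname(taxon[edges$b])
    rownames(edges) <- NULL
    if (!is.null(file)) {
      taxid <- function(t) ifelse(t == "human", "taxid:9606(human)",
                                  "taxid:10239(virus)")
      lines <- vapply(seq_len(nrow(edges)), function(k) {
        paste(c(paste0("uniprotkb:", edges$a[k]),
                paste0("uniprotkb:", edges$b[k]),
                "-", "-", "-", "-",
                "psi-mi:\"MI:0045\"(experimental interaction detection)",
                "-", "-",
                taxid(edges$taxonA[k]), taxid(edges$taxonB[k]),
                "psi-mi:\"MI:0915\"(physical association)",
                "psi-mi:\"MI:0469\"(synthetic)", "-", "-"),
              collapse = "\t")
      }, character(1))
      con <- file(file, open = "wb")
      writeLines(lines, con, sep = "\n")
      close(con)
    }
    invisible(edges)
  })
}

# ---- prediction profiles ----------------------------------------------------

#' Generate a per-residue structure-state prediction profile
#'
#' Emulates the input format of sequence-based secondary-structure (3-state
#' H/E/C) and solvent-accessibility (2-state exposed/buried) predictors.
#' Positions inside `coilRegions` are labelled `C`, inside `sheetRegions`
#' `E`, everything else `H`; positions inside `exposedRegions` are labelled
#' `e` (exposed), everything else `b` (buried).
#'
#' @param sequence Amino-acid string.
#' @param coilRegions,sheetRegions,exposedRegions Lists of `c(start, end)`
#'   spans (1-based, inclusive). A position covered by both a coil and a
#'   sheet span is contradictory and raises an error.
#' @param file Optional path; when given a TSV (`pos`, `res`, `ss`, `acc`)
#'   with a header line is written.
#' @return (Invisibly) the prediction data.frame.
#' @export
makePredictionProfile <- function(sequence, coilRegions = NULL,
                                  sheetRegions = NULL,
                                  exposedRegions = NULL, file = NULL) {
  res <- splitSeq(sequence)
  n <- length(res)
  cover <- function(regions) {
    idx <- logical(n)
    for (sp in regions %||% list()) {
      sp <- checkSpan(sp, n, "prediction span")
      idx[sp[1]:sp[2]] <- TRUE
    }
    idx
  }
  coil <- cover(coilRegions)
  sheet <- cover(sheetRegions)
  if (any(coil & sheet))
    stop("contradictory spans: position(s) ",
         paste(which(coil & sheet), collapse = ", "),
         " labelled both coil and sheet", call. = FALSE)
  ss <- rep("H", n)
  ss[sheet] <- "E"
  ss[coil] <- "C"
  acc <- ifelse(cover(exposedRegions), "e", "b")
  out <- data.frame(pos = seq_len(n), res = res, ss = ss, acc = acc,
                    stringsAsFactors = FALSE)
  if (!is.null(file))
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
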