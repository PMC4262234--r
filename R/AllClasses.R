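# S4 containers for the survey. Data slots are plain data.frames so results
# stay printable and rbind-able; accessors below are the supported interface.

#' ProteinStructure: heavy-atom coordinates of a (multi-chain) structure
#'
#' Holds the heavy atoms of a parsed structure, one row per atom, with 1-based
#' author residue numbering per chain. Hydrogens, waters and HETATM ligands
#' are excluded at parse time by [readStructure()].
#'
#' @slot id Structure identifier (file stem by default).
#' @slot atoms data.frame with columns `chain`, `resno`, `resid` (3-letter),
#'   `elety` (atom name, e.g. `"CA"`, `"SG"`), `elesy` (element symbol),
#'   `x`, `y`, `z` (Angstrom).
#' @aliases ProteinStructure-class
#' @export
setClass("ProteinStructure",
         representation(id = "character", atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("atom coordinates must be finite")
  for (ch in unique(a$chain)) {
    r <- a$resno[a$chain == ch]
    if (any(diff(unique(r)) <= 0) || is.unsorted(r))
      return(sprintf("residue numbers not increasing within chain %s", ch))
  }
  TRUE
})

#' LoopSet: a collection of short disulphide-bonded loops
#'
#' One row per loop. In structure mode loops carry the chain and structure id
#' they were detected in; in sequence mode they come from annotation records
#' and `chain` is `NA`.
#'
#' @slot loops data.frame with columns `id` (structure or protein accession),
#'   `chain`, `cysI`, `cysJ` (1-based indices of the bond-forming cysteines),
#'   `interior` (one-letter interior sequence) and `interiorLength`.
#' @slot mode `"structure"` or `"sequence"`.
#' @aliases LoopSet-class
#' @export
setClass("LoopSet",
         representation(loops = "data.frame", mode = "character"))

setValidity("LoopSet", function(object) {
  l <- object@loops
  need <- c("id", "chain", "cysI", "cysJ", "interior", "interiorLength")
  if (!all(need %in% names(l)))
    return(paste("loops must have columns:", paste(need, collapse = ", ")))
  if (!object@mode %in% c("structure", "sequence"))
    return("mode must be 'structure' or 'sequence'")
  if (nrow(l) > 0) {
    if (any(l$cysJ - l$cysI - 1L != l$interiorLength))
      return("interiorLength inconsistent with cysI/cysJ")
    if (any(nchar(l$interior) != l$interiorLength))
      return("interior string length inconsistent with interiorLength")
  }
  TRUE
})

#' SasaProfile: per-residue solvent-accessible surface area
#'
#' @slot areas data.frame with columns `chain`, `resno`, `area` (Angstrom^2).
#' @slot context `"monomer"` (a single chain evaluated in isolation),
#'   `"complex"` (all chains together) or `"subset"`.
#' @slot probeRadius Probe sphere radius in Angstrom.
#' @slot nPoints Sphere sample points per atom.
#' @aliases SasaProfile-class
#' @export
setClass("SasaProfile",
         representation(areas = "data.frame", context = "character",
                        probeRadius = "numeric", nPoints = "integer"))

setValidity("SasaProfile", function(object) {
  a <- object@areas
  if (!all(c("chain", "resno", "area") %in% names(a)))
    return("areas must have columns chain, resno, area")
  if (any(a$area < 0)) return("areas must be non-negative")
  if (!object@context %in% c("monomer", "complex", "subset"))
    return("context must be monomer, complex or subset")
  TRUE
})

#' InterfaceMap: residues in contact with another protein chain
#'
#' A residue is interfacial when any of its heavy atoms lies within `cutoff`
#' of a heavy atom of a different chain. Rows are (chain, residue, partner
#' chain) triples, so a residue contacting two partners appears twice.
#'
#' @slot residues data.frame with columns `chain`, `resno`, `partner`.
#' @slot cutoff Contact distance cutoff in Angstrom.
#' @aliases InterfaceMap-class
#' @export
setClass("InterfaceMap",
         representation(residues = "data.frame", cutoff = "numeric"))

setValidity("InterfaceMap", function(object) {
  r <- object@residues
  if (!all(c("chain", "resno", "partner") %in% names(r)))
    return("residues must have columns chain, resno, partner")
  if (object@cutoff <= 0) return("cutoff must be positive")
  TRUE
})

#' ConservationProfile: per-column conservation of an alignment
#'
#' @slot score Numeric vector in \[0, 1\], one value per alignment column.
#' @slot gapFraction Fraction of gap characters per column.
#' @slot background Named background amino-acid frequency vector (sums to 1).
#' @slot window Half-width of the symmetric smoothing window (0 = off).
#' @aliases ConservationProfile-class
#' @export
setClass("ConservationProfile",
         representation(score = "numeric", gapFraction = "numeric",
                        background = "numeric", window = "integer"))

setValidity("ConservationProfile", function(object) {
  if (any(object@score < -1e-9 | object@score > 1 + 1e-9))
    return("scores must lie in [0, 1]")
  if (length(object@score) != length(object@gapFraction))
    return("score and gapFraction lengths differ")
  if (abs(sum(object@background) - 1) > 1e-9)
    return("background must sum to 1")
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  ch <- vapply(split(a$resno, a$chain),
               function(r) length(unique(r)), integer(1))
  cat("ProteinStructure '", object@id, "': ",
      length(ch), " chain(s), ", nrow(a), " heavy atoms\n", sep = "")
  cat("  residues per chain: ",
      paste(sprintf("%s=%d", names(ch), ch), collapse = ", "), "\n", sep = "")
})

setMethod("show", "LoopSet", function(object) {
  cat("LoopSet (", object@mode, " mode): ", nrow(object@loops),
      " loop(s)\n", sep = "")
  if (nrow(object@loops) > 0) print(head(object@loops, 6))
})

setMethod("show", "SasaProfile", function(object) {
  cat("SasaProfile (", object@context, "): ", nrow(object@areas),
      " residues, probe ", object@probeRadius, " A, ",
      object@nPoints, " points/atom\n", sep = "")
})

setMethod("show", "InterfaceMap", function(object) {
  cat("InterfaceMap: ", nrow(unique(object@residues[c("chain", "resno")])),
      " interface residue(s) at cutoff ", object@cutoff, " A\n", sep = "")
})

setMethod("show", "ConservationProfile", function(object) {
  cat("ConservationProfile: ", length(object@score), " columns, window ",
      object@window, ", mean score ",
      round(mean(object@score), 3), "\n", sep = "")
})

# ---- length methods ---------------------------------------------------------

#' @export
setMethod("length", "LoopSet", function(x) nrow(x@loops))

# ---- accessors --------------------------------------------------------------

#' Accessors for dsloop S4 containers
#'
#' `loopTable()` returns the loop data.frame of a [LoopSet];
#' `atomTable()` the atom data.frame of a [ProteinStructure]; `chainIds()`
#' its chain identifiers; `sasaTable()` the per-residue area table of a
#' [SasaProfile]; `interfaceResidues()` the unique interface residues of an
#' [InterfaceMap] (optionally for one chain); `conservationScores()` the
#' per-column score vector of a [ConservationProfile].
#'
#' @param x The object.
#' @param chain Optional chain id filter (interfaceResidues).
#' @return A data.frame (or vector) copied out of the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
loopTable <- function(x) {
  stopifnot(is(x, "LoopSet"))
  x@loops
}

#' @rdname accessors
#' @export
loopMode <- function(x) {
  stopifnot(is(x, "LoopSet"))
  x@mode
}

#' @rdname accessors
#' @export
atomTable <- function(x) {
  stopifnot(is(x, "ProteinStructure"))
  x@atoms
}

#' @rdname accessors
#' @export
structureId <- function(x) {
  stopifnot(is(x, "ProteinStructure"))
  x@id
}

#' @rdname accessors
#' @export
chainIds <- function(x) {
  stopifnot(is(x, "ProteinStructure"))
  unique(x@atoms$chain)
}

#' @rdname accessors
#' @export
sasaTable <- function(x) {
  stopifnot(is(x, "SasaProfile"))
  x@areas
}

#' @rdname accessors
#' @export
sasaContext <- function(x) {
  stopifnot(is(x, "SasaProfile"))
  x@context
}

#' @rdname accessors
#' @export
interfaceResidues <- function(x, chain = NULL) {
  stopifnot(is(x, "InterfaceMap"))
  r <- unique(x@residues[c("chain", "resno")])
  if (!is.null(chain)) r <- r[r$chain == chain, , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' @rdname accessors
#' @export
interfaceContacts <- function(x) {
  stopifnot(is(x, "InterfaceMap"))
  x@residues
}

#' @rdname accessors
#' @export
conservationScores <- function(x) {
  stopifnot(is(x, "ConservationProfile"))
  x@score
}

#' @rdname accessors
#' @export
gapFractions <- function(x) {
  stopifnot(is(x, "ConservationProfile"))
  x@gapFraction
}

# Internal constructor helpers ------------------------------------------------

newLoopSet <- function(loops, mode) {
  if (nrow(loops) == 0) {
    loops <- data.frame(id = character(), chain = character(),
                        cysI = integer(), cysJ = integer(),
                        interior = character(), interiorLength = integer(),
                        stringsAsFactors = FALSE)
  }
  rownames(loops) <- NULL
  new("LoopSet", loops = loops, mode = mode)
}
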