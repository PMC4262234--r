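# Protein-protein interface mapping and loop interface coverage.

#' Find interface residues between protein chains
#'
#' A residue is an interface residue when any of its heavy atoms lies within
#' `cutoff` Angstrom (inclusive, matching the reading of "within") of a heavy
#' atom belonging to a different chain. The map is symmetric by construction:
#' each qualifying atom pair contributes a residue on both chains.
#'
#' @param s A [ProteinStructure]; a single-chain structure yields an empty
#'   map.
#' @param cutoff Contact distance cutoff in Angstrom (default 3.0).
#' @return An [InterfaceMap].
#' @export
findInterfaceResidues <- function(s, cutoff = 3.0) {
  stopifnot(is(s, "ProteinStructure"), cutoff > 0)
  a <- s@atoms
  chains <- unique(a$chain)
  res <- list()
  if (length(chains) >= 2L) {
    for (ci in seq_len(length(chains) - 1L)) {
      for (cj in (ci + 1L):length(chains)) {
        A <- a[a$chain == chains[ci], , drop = FALSE]
        B <- a[a$chain == chains[cj], , drop = FALSE]
        D <- crossDist(as.matrix(A[, c("x", "y", "z")]),
                       as.matrix(B[, c("x", "y", "z")]))
        hit <- which(D <= cutoff, arr.ind = TRUE)
        if (nrow(hit) == 0L) next
        res[[length(res) + 1L]] <- unique(data.frame(
          chain = chains[ci], resno = A$resno[hit[, 1]],
          partner = chains[cj], stringsAsFactors = FALSE))
        res[[length(res) + 1L]] <- unique(data.frame(
          chain = chains[cj], resno = B$resno[hit[, 2]],
          partner = chains[ci], stringsAsFactors = FALSE))
      }
    }
  }
  residues <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(chain = character(), resno = integer(),
               partner = character(), stringsAsFactors = FALSE)
  residues <- residues[order(residues$chain, residues$resno,
                             residues$partner), , drop = FALSE]
  rownames(residues) <- NULL
  new("InterfaceMap", residues = residues, cutoff = cutoff)
}

#' Fraction of a chain's interface occupied by a disulphide loop
#'
#' Measures how much of the loop chain's protein-protein interface falls
#' inside the loop span (both cysteines and interior). Two modes:
#'
#' * `"residue_count"` — fraction of the chain's interface residues lying in
#'   the loop span.
#' * `"buried_area"` — fraction of the chain's interface buried surface area
#'   contributed by loop residues, where each residue's buried area is
#'   `max(0, monomer SASA - complex SASA)`.
#'
#' A loop whose share exceeds 0.5 (strictly) is flagged as occupying the
#' majority of the interface.
#'
#' @param loop A single-row loop (one row of [loopTable()], or a [LoopSet]
#'   of length one).
#' @param imap An [InterfaceMap] for the structure.
#' @param sasaMono,sasaCplx [SasaProfile]s of the loop's chain in monomer and
#'   complex context; required for `buried_area` mode.
#' @param mode `"buried_area"` (default) or `"residue_count"`.
#' @return One-row data.frame: `id`, `chain`, `cysI`, `cysJ`, `mode`,
#'   `loopShare`, `nLoopInterface`, `nChainInterface`, `noInterface`,
#'   `majorityOfInterface`.
#' @export
loopInterfaceCoverage <- function(loop, imap, sasaMono = NULL,
                                  sasaCplx = NULL,
                                  mode = c("buried_area", "residue_count")) {
  mode <- match.arg(mode)
  if (is(loop, "LoopSet")) {
    stopifnot(length(loop) == 1L)
    loop <- loopTable(loop)
  }
  stopifnot(is.data.frame(loop), nrow(loop) == 1L,
            is(imap, "InterfaceMap"))
  ch <- loop$chain
  iface <- interfaceResidues(imap, chain = ch)$resno
  span <- seq.int(loop$cysI, loop$cysJ)
  loopIface <- intersect(span, iface)

  if (length(iface) == 0L) {
    share <- 0
    noInterface <- TRUE
  } else if (mode == "residue_count") {
    share <- length(loopIface) / length(iface)
    noInterface <- FALSE
  } else {
    if (is.null(sasaMono) || is.null(sasaCplx))
      stop("buried_area mode needs monomer and complex SasaProfiles",
           call. = FALSE)
    dsasa <- function(prof) {
      t <- sasaTable(prof)
      t <- t[t$chain == ch, , drop = FALSE]
      if (nrow(t) == 0L)
        stop("chain '", ch, "' absent from ", sasaContext(prof),
             " SASA profile", call. = FALSE)
      setNames(t$area, t$resno)
    }
    am <- dsasa(sasaMono)
    ac <- dsasa(sasaCplx)
    buried <- function(resnos) {
      key <- as.character(resnos)
      if (!all(key %in% names(am)) || !all(key %in% names(ac)))
        stop("interface residue(s) missing from SASA profiles", call. = FALSE)
      sum(pmax(0, am[key] - ac[key]))
    }
    tot <- buried(iface)
    share <- if (tot > 0) buried(loopIface) / tot else 0
    noInterface <- FALSE
  }
  data.frame(id = loop$id, chain = ch, cysI = loop$cysI, cysJ = loop$cysJ,
             mode = mode, loopShare = share,
             nLoopInterface = length(loopIface),
             nChainInterface = length(iface),
             noInterface = noInterface,
             majorityOfInterface = share > 0.5,
             stringsAsFactors = FALSE)
}
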