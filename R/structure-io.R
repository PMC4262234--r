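# PDB input. Parsing is delegated to bio3d::read.pdb; this layer applies the
# survey's atom policy: heavy atoms only, HETATM/waters dropped, alternate
# locations resolved to the highest-occupancy record (ties broken towards
# altloc "A", then first occurrence).

#' Read a PDB-format structure file
#'
#' Loads the heavy (non-hydrogen) protein atoms of a PDB file into a
#' [ProteinStructure]. HETATM records (ligands, waters, metals) are ignored.
#' When a file contains several MODEL blocks only the first is kept.
#' Alternate-location groups are reduced to a single atom: highest occupancy
#' wins, ties go to altloc `"A"`.
#'
#' @param file Path to a PDB-format text file containing at least one ATOM
#'   record.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @return A [ProteinStructure].
#' @export
#' @examples
#' pdb <- makeLoopStructure(structureSpec(loopPlants = loopPlant("A", 5, 10)),
#'                          file = tempfile(fileext = ".pdb"))
#' readStructure(pdb)
readStructure <- function(file, id = NULL) {
  if (!file.exists(file)) stop("no such file: ", file, call. = FALSE)
  lines <- readLines(file, warn = FALSE)
  atomLines <- grep("^ATOM  ", lines)
  if (length(atomLines) == 0L)
    stop("no ATOM records in '", file, "'", call. = FALSE)

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse '", file, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]

  bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
  if (length(bad) > 0L) {
    # locate the offending record in the original file for the error message
    ln <- atomLines[min(bad[1], length(atomLines))]
    stop(sprintf("unparseable ATOM record at line %d of '%s'", ln, file),
         call. = FALSE)
  }

  # element symbol: prefer the PDB element column, fall back to the first
  # non-digit character of the atom name
  sym <- toupper(trimws(a$elesy))
  miss <- is.na(sym) | sym == ""
  if (any(miss))
    sym[miss] <- substr(gsub("[0-9]", "", trimws(a$elety[miss])), 1L, 1L)
  a$elesy <- sym

  keep <- !(sym %in% c("H", "D")) & !(a$resid %in% c("HOH", "DOD"))
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L)
    stop("no heavy protein atoms in '", file, "'", call. = FALSE)

  a$chain[is.na(a$chain)] <- " "
  a$o[is.na(a$o)] <- 1

  # resolve altlocs within each (chain, resno, atom name) group
  a$alt[is.na(a$alt)] <- ""
  if (any(a$alt != "")) {
    key <- paste(a$chain, a$resno, a$elety, sep = "\r")
    ord <- order(-a$o, a$alt != "A", a$alt, seq_len(nrow(a)))
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(key[ord]), , drop = FALSE]
    a <- a[order(match(a$chain, unique(a$chain)), a$resno), , drop = FALSE]
  }

  atoms <- data.frame(chain = a$chain, resno = as.integer(a$resno),
                      resid = a$resid, elety = trimws(a$elety),
                      elesy = a$elesy,
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  new("ProteinStructure",
      id = id %||% sub("\\.[^.]*$", "", basename(file)),
      atoms = atoms)
}

# Fixed-width ATOM record writer shared by the synthetic generator. Produces
# a minimal single-MODEL dialect: sequential atom numbers, occupancy 1.00,
# B-factor 0.00, TER after each chain, END last.
writePdbAtoms <- function(atoms, file) {
  con <- file(file, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  n <- 0L
  out <- character(0)
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      n <- n + 1L
      name <- sub$elety[k]
      # PDB atom-name column convention: 1-letter elements start in column 14
      namefmt <- if (nchar(name) < 4L) sprintf(" %-3s", name)
                 else sprintf("%-4s", name)
      out <- c(out, sprintf(
        "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        n, namefmt, sub$resid[k], ch, sub$resno[k],
        sub$x[k], sub$y[k], sub$z[k], 1, 0, sub$elesy[k]))
    }
    n <- n + 1L
    last <- sub[nrow(sub), ]
    out <- c(out, sprintf("TER   %5d      %3s %1s%4d",
                          n, last$resid, ch, last$resno))
  }
  out <- c(out, "END")
  writeLines(out, con, sep = "\n")
  invisible(file)
}
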