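# Sequence-level disulphide annotations (Uniprot-style, abstracted to a TSV
# contract) and the loop extraction / composition operations built on them.

#' Read a disulphide-bond annotation table
#'
#' The expected tab-delimited format has a header row and columns
#' `accession`, `sequence`, `bonds` and optionally `family`. The `bonds`
#' field lists bonds as `a-b` tokens separated by commas, 1-based inclusive;
#' a token suffixed `:inter` marks an interchain bond (retained but
#' flagged). Every annotated position must be a cysteine in `sequence`.
#'
#' @param file Path to the TSV.
#' @param strict When `TRUE` (default) any record whose bond positions are
#'   not cysteines raises one error reporting all offending records; when
#'   `FALSE` the offending records are dropped with a warning.
#' @return data.frame with one row per bond: `accession`, `sequence`,
#'   `posA`, `posB`, `intrachain`, `family`.
#' @export
readDisulphideAnnotations <- function(file, strict = TRUE) {
  tab <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("accession", "sequence", "bonds") %in% names(tab)))
    stop("annotation file needs columns: accession, sequence, bonds",
         call. = FALSE)
  if (!"family" %in% names(tab)) tab$family <- ""
  tab$family[is.na(tab$family)] <- ""
  rows <- list()
  problems <- character(0)
  for (r in seq_len(nrow(tab))) {
    acc <- tab$accession[r]
    sq <- tab$sequence[r]
    tokens <- strsplit(tab$bonds[r], ",", fixed = TRUE)[[1]]
    tokens <- trimws(tokens[nzchar(trimws(tokens))])
    for (tk in tokens) {
      inter <- grepl(":inter$", tk)
      core <- sub(":inter$", "", tk)
      m <- regmatches(core, regexec("^([0-9]+)-([0-9]+)$", core))[[1]]
      if (length(m) != 3L)
        stop(sprintf("malformed bond token '%s' at line %d of '%s'",
                     tk, r + 1L, file), call. = FALSE)
      a <- as.integer(m[2]); b <- as.integer(m[3])
      if (a > b) { tmp <- a; a <- b; b <- tmp }
      if (b > nchar(sq) || a < 1L)
        stop(sprintf("bond %d-%d outside sequence (length %d) at line %d",
                     a, b, nchar(sq), r + 1L), call. = FALSE)
      if (substr(sq, a, a) != "C" || substr(sq, b, b) != "C") {
        problems <- c(problems,
                      sprintf("%s: bond %d-%d not on cysteines", acc, a, b))
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(accession = acc, sequence = sq, posA = a, posB = b,
                   intrachain = !inter, family = tab$family[r],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(problems) > 0L) {
    msg <- paste0("annotation validation failed for ", length(problems),
                  " bond(s):\n  ", paste(problems, collapse = "\n  "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(accession = character(), sequence = character(),
                      posA = integer(), posB = integer(),
                      intrachain = logical(), family = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Extract short disulphide-bonded loops from annotations
#'
#' Keeps intrachain bonds whose interior length (residues strictly between
#' the cysteines) lies in `interiorRange` (sequence-mode default 2--8) and
#' that survive the knot rules applied per accession against *all* annotated
#' intrachain bonds: interleaved spans and bonds sharing a cysteine exclude
#' each other, and a loop whose interior contains another bond's cysteine is
#' excluded.
#'
#' @param anns Annotation data.frame from [readDisulphideAnnotations()].
#' @param interiorRange Inclusive `c(min, max)` interior-length bounds.
#' @return A [LoopSet] in sequence mode (the `id` column is the accession).
#' @export
extractShortLoops <- function(anns, interiorRange = c(2L, 8L)) {
  stopifnot(is.data.frame(anns),
            all(c("accession", "sequence", "posA", "posB", "intrachain") %in%
                names(anns)))
  out <- list()
  for (acc in unique(anns$accession)) {
    sub <- anns[anns$accession == acc & anns$intrachain, , drop = FALSE]
    if (nrow(sub) == 0L) next
    keep <- dropKnotted(sub$posA, sub$posB)
    sub <- sub[keep, , drop = FALSE]
    len <- sub$posB - sub$posA - 1L
    sub <- sub[len >= interiorRange[1] & len <= interiorRange[2], ,
               drop = FALSE]
    if (nrow(sub) == 0L) next
    out[[acc]] <- data.frame(
      id = acc, chain = NA_character_, cysI = sub$posA, cysJ = sub$posB,
      interior = substr(sub$sequence, sub$posA + 1L, sub$posB - 1L),
      family = sub$family, stringsAsFactors = FALSE)
  }
  loops <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(id = character(), chain = character(), cysI = integer(),
               cysJ = integer(), interior = character(),
               family = character(), stringsAsFactors = FALSE)
  loops$interiorLength <- loops$cysJ - loops$cysI - 1L
  newLoopSet(loops[order(loops$id, loops$cysI),
                   c("id", "chain", "cysI", "cysJ", "interior",
                     "interiorLength", "family")],
             "sequence")
}

#' Amino-acid composition of loop interiors
#'
#' Frequencies over interior residues only -- the bond-forming terminal
#' cysteines are never counted (interior cysteines, were the length rules to
#' admit any, would count as C).
#'
#' @param loops A [LoopSet] (or its [loopTable()]).
#' @param background Named background frequency vector for the ratio column.
#' @return data.frame: `aa`, `loopFreq`, `backgroundFreq`, `ratio`, ordered
#'   by the standard alphabet. `loopFreq` sums to 1.
#' @export
loopComposition <- function(loops, background = blosum62Background()) {
  background <- checkBackground(background)
  tab <- if (is(loops, "LoopSet")) loopTable(loops) else loops
  residues <- unlist(strsplit(tab$interior, "", fixed = TRUE))
  residues <- residues[residues %in% AA_ALPHABET]
  if (length(residues) == 0L)
    stop("no interior residues to tally", call. = FALSE)
  counts <- table(factor(residues, levels = AA_ALPHABET))
  freq <- as.numeric(counts) / sum(counts)
  data.frame(aa = AA_ALPHABET, loopFreq = freq,
             backgroundFreq = as.numeric(background),
             ratio = ifelse(background > 0, freq / as.numeric(background),
                            NA_real_),
             stringsAsFactors = FALSE)
}
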