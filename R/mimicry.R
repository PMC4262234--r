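# Host-virus loop mimicry: sequence-based loop prediction, self-normalized
# BLOSUM62 similarity, PSI-MITAB parsing and shared-interactor triangles.

.dsloopCache <- new.env(parent = emptyenv())

# BLOSUM62 from the Biostrings data sets, cached per session.
blosum62Matrix <- function() {
  if (is.null(.dsloopCache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .dsloopCache$BLOSUM62 <- e$BLOSUM62
  }
  .dsloopCache$BLOSUM62
}

# Global (Needleman-Wunsch) or local (Smith-Waterman) optimal alignment
# score under a linear gap model: every gap position costs `gap` (the
# open-equals-extend case the survey uses, -12).
alignScore <- function(a, b, mat, gap, type = "global") {
  n <- length(a); m <- length(b)
  S <- mat[a, b, drop = FALSE]
  if (type == "global") {
    prev <- gap * (0:m)
    for (i in seq_len(n)) {
      cur <- numeric(m + 1L)
      cur[1] <- gap * i
      for (j in seq_len(m)) {
        cur[j + 1L] <- max(prev[j] + S[i, j],   # substitute
                           prev[j + 1L] + gap,  # gap in b
                           cur[j] + gap)        # gap in a
      }
      prev <- cur
    }
    prev[m + 1L]
  } else {
    best <- 0
    prev <- numeric(m + 1L)
    for (i in seq_len(n)) {
      cur <- numeric(m + 1L)
      for (j in seq_len(m)) {
        cur[j + 1L] <- max(0, prev[j] + S[i, j], prev[j + 1L] + gap,
                           cur[j] + gap)
        if (cur[j + 1L] > best) best <- cur[j + 1L]
      }
      prev <- cur
    }
    best
  }
}

#' Self-normalized similarity of two disulphide-loop interiors
#'
#' Aligns the two interior peptides (flanking cysteines must already be
#' stripped) with an optimal pairwise dynamic-programming alignment under
#' BLOSUM62 and a linear gap penalty (opening = extension = -12, i.e. three
#' times the most negative BLOSUM62 substitution score, which strongly
#' favours equal-length alignments), and normalizes the raw score by the
#' target interior's self-alignment score. The measure is asymmetric: the
#' target (conventionally the viral loop) provides the normalizer, and
#' `similarity <= 1` always, with equality for identical interiors.
#'
#' @param query,target Interior peptide strings over the 20 standard amino
#'   acids; both non-empty. `target` is the self-normalizing side.
#' @param gap Per-position gap penalty (default -12).
#' @param matrix Substitution matrix (default BLOSUM62 from Biostrings).
#' @param type `"global"` (default) or `"local"` alignment.
#' @return One-row data.frame: `query`, `target`, `raw`, `self`,
#'   `similarity`.
#' @export
#' @examples
#' loopSimilarity("ELQW", "ELGW")  # 18 / 26
loopSimilarity <- function(query, target, gap = -12, matrix = NULL,
                           type = c("global", "local")) {
  type <- match.arg(type)
  matrix <- matrix %||% blosum62Matrix()
  q <- splitSeq(query)
  t <- splitSeq(target)
  if (length(q) == 0L || length(t) == 0L)
    stop("loop interiors must be non-empty", call. = FALSE)
  badQ <- setdiff(q, AA_ALPHABET)
  badT <- setdiff(t, AA_ALPHABET)
  if (length(badQ) || length(badT))
    stop("non-standard residue(s): ",
         paste(unique(c(badQ, badT)), collapse = ", "), call. = FALSE)
  raw <- alignScore(q, t, matrix, gap, type)
  self <- alignScore(t, t, matrix, gap, type)
  if (self <= 0)
    stop("target self-alignment score is not positive", call. = FALSE)
  data.frame(query = query, target = target, raw = raw, self = self,
             similarity = raw / self, stringsAsFactors = FALSE)
}

#' Predict disulphide-loop candidates from sequence and structure states
#'
#' Applies the four sequence-level rules for plausible disulphide-bonded
#' loops: a window (1) starts and ends with cysteine, (2) contains no
#' internal cysteine, (3) has no interior position predicted as helix or
#' sheet, and (4) is predicted more exposed than buried -- a strict majority
#' of exposed labels over the whole cysteine-to-cysteine window; an exact
#' tie is excluded. All qualifying (possibly overlapping) windows are
#' reported.
#'
#' @param sequence Amino-acid string.
#' @param ss Per-residue 3-state secondary-structure labels (`"H"`, `"E"`,
#'   `"C"`), as a character vector or single string.
#' @param acc Per-residue 2-state accessibility labels (`"e"` exposed,
#'   `"b"` buried).
#' @param maxTotalLength Maximum window length including both cysteines
#'   (default 10, "under 11 residues").
#' @param interiorMin Minimum interior length (default 2).
#' @return data.frame with one row per candidate: `start`, `end`,
#'   `interior`, `meanExposure`.
#' @export
predictSequenceLoops <- function(sequence, ss, acc, maxTotalLength = 10L,
                                 interiorMin = 2L) {
  res <- splitSeq(sequence)
  if (length(ss) == 1L && nchar(ss[1]) > 1L) ss <- splitSeq(ss)
  if (length(acc) == 1L && nchar(acc[1]) > 1L) acc <- splitSeq(acc)
  n <- length(res)
  if (length(ss) != n || length(acc) != n)
    stop(sprintf("prediction length mismatch: sequence %d, ss %d, acc %d",
                 n, length(ss), length(acc)), call. = FALSE)
  cys <- which(res == "C")
  out <- list()
  if (length(cys) >= 2L) {
    for (ii in seq_len(length(cys) - 1L)) {
      for (jj in (ii + 1L):length(cys)) {
        i <- cys[ii]; j <- cys[jj]
        if (j - i + 1L > maxTotalLength) break
        if (j - i - 1L < interiorMin) next
        interior <- seq(i + 1L, j - 1L)
        if (any(res[interior] == "C")) next             # rule 2
        if (any(ss[interior] %in% c("H", "E"))) next    # rule 3
        win <- seq(i, j)
        nExp <- sum(acc[win] == "e")
        if (nExp * 2L <= length(win)) next              # rule 4, strict
        out[[length(out) + 1L]] <- data.frame(
          start = i, end = j,
          interior = paste(res[interior], collapse = ""),
          meanExposure = nExp / length(win), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      interior = character(), meanExposure = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read a per-residue prediction profile TSV
#'
#' Counterpart of [makePredictionProfile()]: a headered TSV with columns
#' `pos`, `res`, `ss`, `acc`.
#'
#' @param file Path to the TSV.
#' @return data.frame with those four columns, ordered by position.
#' @export
readPredictionProfile <- function(file) {
  t <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("pos", "res", "ss", "acc")
  if (!all(need %in% names(t)))
    stop("prediction file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  t[order(t$pos), need]
}

# ---- PSI-MITAB --------------------------------------------------------------

# Pull a uniprot-style accession out of a MITAB identifier field; isoform
# suffixes (P04004-2) collapse to the parent accession.
mitabAccession <- function(field) {
  parts <- strsplit(field, "|", fixed = TRUE)[[1]]
  up <- grep("^uniprotkb:", parts, value = TRUE)
  pick <- if (length(up) > 0) up[1] else if (length(parts) > 0 &&
                                             grepl(":", parts[1]))
    parts[1] else NA_character_
  if (is.na(pick)) return(NA_character_)
  acc <- sub("^[^:]+:", "", pick)
  acc <- sub("\"(.*)\"", "\\1", acc)
  acc <- sub("-[0-9]+$", "", acc)
  if (nzchar(acc)) acc else NA_character_
}

mitabTaxon <- function(field, virusTaxids) {
  if (is.na(field) || field %in% c("-", ""))
    return("other")
  id <- sub("^taxid:(-?[0-9]+).*$", "\\1", field)
  if (id == "9606") return("human")
  if (id %in% as.character(virusTaxids)) return("virus")
  if (grepl("virus", field, ignore.case = TRUE)) return("virus")
  "other"
}

#' Parse PSI-MITAB 2.5 interaction files into a network
#'
#' Extracts interactor accessions from the first two columns of each
#' tab-delimited line (preferring `uniprotkb:`-prefixed identifiers;
#' isoform suffixes are stripped so interactions match at protein level)
#' and taxa from the taxid columns (10 and 11). Lines with fewer than two
#' parsable interactor identifiers, self-loops, and comment lines (`#`)
#' are skipped; the number skipped is reported with a message. Duplicate
#' edges across files/lines are merged with the union of their source tags
#' (file names).
#'
#' @param files Character vector of PSI-MITAB 2.5 file paths.
#' @param virusTaxids Taxon ids (besides any taxon field containing the
#'   word "virus") classified as viral; default covers the generic virus
#'   superkingdom id 10239. Taxid 9606 is always human; everything else is
#'   `"other"`.
#' @return An undirected [igraph::igraph] graph; vertices carry a `taxon`
#'   attribute, edges a `sources` attribute.
#' @export
readMitab <- function(files, virusTaxids = c(10239)) {
  edges <- list()
  skipped <- 0L
  for (f in files) {
    if (!file.exists(f)) stop("cannot read MITAB file: ", f, call. = FALSE)
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 2L) { skipped <- skipped + 1L; next }
      a <- mitabAccession(fields[1])
      b <- mitabAccession(fields[2])
      if (is.na(a) || is.na(b) || a == b) { skipped <- skipped + 1L; next }
      ta <- mitabTaxon(if (length(fields) >= 10L) fields[10] else NA,
                       virusTaxids)
      tb <- mitabTaxon(if (length(fields) >= 11L) fields[11] else NA,
                       virusTaxids)
      if (a > b) { tmp <- a; a <- b; b <- tmp; tmp <- ta; ta <- tb; tb <- tmp }
      edges[[length(edges) + 1L]] <- data.frame(
        a = a, b = b, taxonA = ta, taxonB = tb, source = basename(f),
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L)
    message("readMitab: skipped ", skipped,
            " line(s) without two parsable interactor ids")
  if (length(edges) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    return(g)
  }
  ed <- do.call(rbind, edges)
  key <- paste(ed$a, ed$b, sep = "|")
  ed <- ed[order(key, ed$source), , drop = FALSE]
  key <- paste(ed$a, ed$b, sep = "|")
  src <- vapply(split(ed$source, key), function(s)
    paste(sort(unique(s)), collapse = ";"), character(1))
  first <- ed[!duplicated(key), , drop = FALSE]
  first$sources <- unname(src[paste(first$a, first$b, sep = "|")])

  taxon <- c(setNames(first$taxonA, first$a), setNames(first$taxonB, first$b))
  # a node seen with conflicting labels keeps the most specific (non-other)
  taxon <- tapply(taxon, names(taxon), function(t) {
    t <- unique(t)
    if (length(t) == 1L) t else setdiff(t, "other")[1] %||% "other"
  })
  verts <- data.frame(name = names(taxon), taxon = unname(unlist(taxon)),
                      stringsAsFactors = FALSE)
  verts <- verts[order(verts$name), , drop = FALSE]
  igraph::graph_from_data_frame(
    first[order(first$a, first$b), c("a", "b", "sources")],
    directed = FALSE, vertices = verts)
}

#' Find host-virus loop mimicry candidates
#'
#' For every (human loop, viral loop) pair whose self-normalized similarity
#' strictly exceeds `simThreshold`, emits a hit when the interaction network
#' contains at least one shared interactor X -- a protein interacting with
#' both the human loop protein H and the viral loop protein V (the H--X,
#' V--X triangle that suggests the viral loop co-opts the host loop's
#' partner). Hits are sorted by descending similarity.
#'
#' @param humanLoops,viralLoops data.frames with columns `accession` and
#'   `interior` (flanking cysteines already stripped); extra columns are
#'   ignored.
#' @param graph An interaction network from [readMitab()] (any igraph graph
#'   with vertex names works).
#' @param simThreshold Strict similarity threshold (default 0.50).
#' @param ... Passed to [loopSimilarity()] (gap, matrix, type).
#' @return data.frame with one row per hit: `humanAccession`, `humanLoop`,
#'   `viralAccession`, `viralLoop`, `similarity`, `nShared`,
#'   `sharedInteractors` (`;`-joined, sorted).
#' @export
findMimicryCandidates <- function(humanLoops, viralLoops, graph,
                                  simThreshold = 0.50, ...) {
  stopifnot(is.data.frame(humanLoops), is.data.frame(viralLoops),
            all(c("accession", "interior") %in% names(humanLoops)),
            all(c("accession", "interior") %in% names(viralLoops)))
  nodes <- igraph::V(graph)$name %||% character(0)
  neigh <- function(acc) {
    if (!acc %in% nodes) return(character(0))
    igraph::neighbors(graph, acc)$name
  }
  hits <- list()
  for (h in seq_len(nrow(humanLoops))) {
    for (v in seq_len(nrow(viralLoops))) {
      sim <- loopSimilarity(humanLoops$interior[h], viralLoops$interior[v],
                            ...)$similarity
      if (sim <= simThreshold) next
      shared <- setdiff(intersect(neigh(humanLoops$accession[h]),
                                  neigh(viralLoops$accession[v])),
                        c(humanLoops$accession[h], viralLoops$accession[v]))
      if (length(shared) == 0L) next
      hits[[length(hits) + 1L]] <- data.frame(
        humanAccession = humanLoops$accession[h],
        humanLoop = humanLoops$interior[h],
        viralAccession = viralLoops$accession[v],
        viralLoop = viralLoops$interior[v],
        similarity = sim, nShared = length(shared),
        sharedInteractors = paste(sort(shared), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(humanAccession = character(), humanLoop = character(),
                      viralAccession = character(), viralLoop = character(),
                      similarity = numeric(), nShared = integer(),
                      sharedInteractors = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(-out$similarity, out$humanAccession, out$viralAccession), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
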