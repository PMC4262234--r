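# Orchestration: flat key-value config, the three survey stages, histogram
# data for the figure analogues, and a run manifest.

pipelineDefaults <- function() {
  list(
    # stage toggles
    run_structures = FALSE, run_conservation = FALSE, run_mimicry = FALSE,
    # structure survey
    structure_dir = "", interior_min = 2L, interior_max = 9L,
    bond_lo = 1.6, bond_hi = 2.5, max_span = 11L,
    sasa_threshold = 2.5, contact_cutoff = 3.0,
    coverage_mode = "buried_area", probe_radius = 1.4, sasa_points = 960L,
    # conservation survey
    annotations_file = "", msa_dir = "", flank_width = 4L,
    conservation_threshold = 0.30, window = 0L,
    require_cys_conserved = TRUE, seq_interior_min = 2L,
    seq_interior_max = 8L, max_dist = 4L,
    hist_breaks = seq(-1, 1, by = 0.05),
    # mimicry
    human_loops_file = "", viral_loops_file = "", mitab_files = character(),
    sim_threshold = 0.50, gap_penalty = -12, alignment_type = "global",
    virus_taxids = c(10239),
    # general
    out_dir = ".", seed = 1L)
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the documented defaults. Unknown keys are
#' rejected, and threshold-type values are range-checked. Settings can come
#' from a YAML file of flat key-value pairs, a list, or both (the list
#' overrides the file).
#'
#' @param file Optional YAML config file.
#' @param ... Named settings overriding file and defaults.
#' @return Validated config list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(file = NULL, ...) {
  cfg <- pipelineDefaults()
  user <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("no such config file: ", file, call. = FALSE)
    user <- yaml::read_yaml(file)
  }
  dots <- list(...)
  user[names(dots)] <- dots
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(user)] <- user

  if (cfg$interior_min < 0 || cfg$interior_min > cfg$interior_max)
    stop("need 0 <= interior_min <= interior_max", call. = FALSE)
  if (cfg$bond_lo <= 0 || cfg$bond_lo > cfg$bond_hi)
    stop("need 0 < bond_lo <= bond_hi", call. = FALSE)
  if (cfg$sasa_threshold < 0 || cfg$contact_cutoff <= 0)
    stop("sasa_threshold must be >= 0 and contact_cutoff > 0", call. = FALSE)
  if (!cfg$coverage_mode %in% c("buried_area", "residue_count"))
    stop("coverage_mode must be buried_area or residue_count", call. = FALSE)
  if (cfg$sim_threshold < 0 || cfg$sim_threshold > 1)
    stop("sim_threshold must lie in [0, 1]", call. = FALSE)
  if (!cfg$alignment_type %in% c("global", "local"))
    stop("alignment_type must be global or local", call. = FALSE)
  if (cfg$flank_width < 1) stop("flank_width must be >= 1", call. = FALSE)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Histogram counts with half-open bins
#'
#' Bins are half-open `[lo, hi)`; the last bin is closed so its upper edge
#' is included. Values outside the edge range are not counted but reported.
#'
#' @param x Numeric values.
#' @param breaks Strictly increasing bin edges.
#' @return list with `edges`, `counts` (length `length(edges) - 1`) and
#'   `outOfRange`.
#' @export
#' @examples
#' histogramCounts(c(0.1, 0.1, 0.9), c(0, 0.5, 1))
histogramCounts <- function(x, breaks) {
  if (any(diff(breaks) <= 0) || length(breaks) < 2L)
    stop("breaks must be strictly increasing with at least 2 edges",
         call. = FALSE)
  x <- x[!is.na(x)]
  nb <- length(breaks) - 1L
  inRange <- x >= breaks[1] & x <= breaks[length(breaks)]
  bin <- findInterval(x[inRange], breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = nb)
  list(edges = breaks, counts = counts, outOfRange = sum(!inRange))
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the disulphide-loop survey pipeline
#'
#' Executes the enabled stages in order (structures, conservation, mimicry),
#' writes per-stage TSV outputs and histogram data under `out_dir`, and a
#' YAML manifest (`manifest.yaml`) holding the config snapshot, input file
#' checksums and per-stage counts. Identical config and inputs produce
#' byte-identical outputs.
#'
#' Stage inputs: the structure stage scans `structure_dir` for `*.pdb`
#' files; the conservation stage reads `annotations_file` (see
#' [readDisulphideAnnotations()]) and per-accession alignments
#' `<accession>.fasta` in `msa_dir`; the mimicry stage reads human and viral
#' loop TSVs (columns `accession`, `interior`) plus `mitab_files`.
#'
#' @param config A [pipelineConfig()].
#' @return (Invisibly) the manifest list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- character(0)
  if (config$run_structures) {
    if (!dir.exists(config$structure_dir))
      stop("structure_dir does not exist: ", config$structure_dir,
           call. = FALSE)
    inputs <- c(inputs, list.files(config$structure_dir, "\\.pdb$",
                                   full.names = TRUE))
  }
  if (config$run_conservation) {
    if (!file.exists(config$annotations_file))
      stop("annotations_file does not exist: ", config$annotations_file,
           call. = FALSE)
    if (!dir.exists(config$msa_dir))
      stop("msa_dir does not exist: ", config$msa_dir, call. = FALSE)
    inputs <- c(inputs, config$annotations_file,
                list.files(config$msa_dir, "\\.fasta$", full.names = TRUE))
  }
  if (config$run_mimicry) {
    need <- c(config$human_loops_file, config$viral_loops_file,
              config$mitab_files)
    miss <- need[!file.exists(need)]
    if (length(miss) > 0L)
      stop("missing mimicry input(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    inputs <- c(inputs, need)
  }

  manifest <- list(
    tool = "dsloop", version = as.character(packageVersion("dsloop")),
    config = unclass(config),
    inputs = as.list(setNames(unname(md5sum(inputs)), basename(inputs))),
    counts = list(), stages = list())

  if (config$run_structures) {
    st <- surveyStructures(config)
    writeTsv(st$table, file.path(config$out_dir, "structure_loops.tsv"))
    manifest$counts$loopsDetected <- nrow(st$table)
    manifest$counts$surfaceLoops <- sum(st$table$surfaceLoop)
    manifest$counts$interfaceLoops <- sum(st$table$nInterfaceResidues > 0)
    manifest$counts$majorityCoverageLoops <-
      sum(st$table$majorityOfInterface)
    manifest$stages$structures <- "complete"
  }
  if (config$run_conservation) {
    cs <- surveyConservation(config)
    writeTsv(cs$records, file.path(config$out_dir,
                                   "conservation_records.tsv"))
    writeTsv(cs$positional, file.path(config$out_dir,
                                      "conservation_positional.tsv"))
    hg <- histogramCounts(cs$records$difference, config$hist_breaks)
    writeTsv(data.frame(binStart = hg$edges[-length(hg$edges)],
                        binEnd = hg$edges[-1], count = hg$counts),
             file.path(config$out_dir, "conservation_difference_hist.tsv"))
    manifest$counts$conservationRecords <- nrow(cs$records)
    manifest$counts$preferentiallyConservedLoops <- nrow(cs$conserved$records)
    manifest$stages$conservation <- "complete"
  }
  if (config$run_mimicry) {
    hits <- surveyMimicry(config)
    writeTsv(hits, file.path(config$out_dir, "mimicry_hits.tsv"))
    manifest$counts$mimicryHits <- nrow(hits)
    manifest$stages$mimicry <- "complete"
  }
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}

# structure stage over a directory of PDB files
surveyStructures <- function(config) {
  files <- sort(list.files(config$structure_dir, "\\.pdb$",
                           full.names = TRUE))
  rows <- list()
  for (f in files) {
    s <- readStructure(f)
    loops <- detectDisulphideLoops(
      s, interiorRange = c(config$interior_min, config$interior_max),
      bondWindow = c(config$bond_lo, config$bond_hi),
      maxSpan = config$max_span)
    if (length(loops) == 0L) next
    imap <- findInterfaceResidues(s, cutoff = config$contact_cutoff)
    cplx <- computeSasa(s, probeRadius = config$probe_radius,
                        nPoints = config$sasa_points)
    surface <- classifySurface(cplx, threshold = config$sasa_threshold)
    monoCache <- list()
    lt <- loopTable(loops)
    for (k in seq_len(nrow(lt))) {
      loop <- lt[k, ]
      ch <- loop$chain
      if (is.null(monoCache[[ch]]))
        monoCache[[ch] ] <- computeSasa(s, chains = ch,
                                        probeRadius = config$probe_radius,
                                        nPoints = config$sasa_points)
      cov <- loopInterfaceCoverage(loop, imap, monoCache[[ch]], cplx,
                                   mode = config$coverage_mode)
      span <- seq.int(loop$cysI, loop$cysJ)
      nSurf <- sum(surface$chain == ch & surface$resno %in% span)
      rows[[length(rows) + 1L]] <- data.frame(
        structureId = s@id, chain = ch, cysI = loop$cysI,
        cysJ = loop$cysJ, interior = loop$interior,
        nSurfaceResidues = nSurf, surfaceLoop = nSurf > 0L,
        nInterfaceResidues = cov$nLoopInterface,
        coverageMode = cov$mode, loopShare = cov$loopShare,
        majorityOfInterface = cov$majorityOfInterface,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structureId = character(), chain = character(),
               cysI = integer(), cysJ = integer(), interior = character(),
               nSurfaceResidues = integer(), surfaceLoop = logical(),
               nInterfaceResidues = integer(), coverageMode = character(),
               loopShare = numeric(), majorityOfInterface = logical(),
               stringsAsFactors = FALSE)
  list(table = tab)
}

surveyConservation <- function(config) {
  anns <- readDisulphideAnnotations(config$annotations_file)
  loops <- extractShortLoops(anns, interiorRange = c(config$seq_interior_min,
                                                     config$seq_interior_max))
  accs <- unique(loopTable(loops)$id)
  alignments <- list()
  for (acc in accs) {
    f <- file.path(config$msa_dir, paste0(acc, ".fasta"))
    if (file.exists(f)) alignments[[acc]] <- readAAStringSet(f)
  }
  surv <- conservationSurvey(
    loops, alignments, window = config$window,
    flankWidth = config$flank_width,
    requireCysConserved = config$require_cys_conserved,
    maxDist = config$max_dist)
  records <- surv$records %||%
    data.frame(id = character(), cysI = integer(), cysJ = integer(),
               interiorMean = numeric(), flankMean = numeric(),
               difference = numeric(), cysConserved = logical(),
               usableFlank = logical(), family = character(),
               stringsAsFactors = FALSE)
  records <- records[records$usableFlank, , drop = FALSE]
  list(records = records,
       positional = positionalProfile(surv$positions,
                                      maxDist = config$max_dist),
       conserved = preferentiallyConserved(
         records, threshold = config$conservation_threshold))
}

surveyMimicry <- function(config) {
  human <- read.delim(config$human_loops_file, stringsAsFactors = FALSE)
  viral <- read.delim(config$viral_loops_file, stringsAsFactors = FALSE)
  graph <- readMitab(config$mitab_files, virusTaxids = config$virus_taxids)
  findMimicryCandidates(human, viral, graph,
                        simThreshold = config$sim_threshold,
                        gap = config$gap_penalty,
                        type = config$alignment_type)
}
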