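# ---- sequence-based loop prediction ----------------------------------------

test_that("sequences without cysteine pairs yield no predictions", {
  n <- 8
  expect_equal(nrow(predictSequenceLoops(strrep("A", n), rep("C", n),
                                         rep("e", n))), 0L)
})

test_that("an all-coil all-exposed window is predicted with its interior", {
  sq <- "ACDEFGC"
  p <- makePredictionProfile(sq, coilRegions = list(c(1, 7)),
                             exposedRegions = list(c(1, 7)))
  out <- predictSequenceLoops(sq, p$ss, p$acc)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 2L)
  expect_equal(out$end, 7L)
  expect_equal(out$interior, "DEFG")
})

test_that("helix or sheet in the interior rejects the window", {
  sq <- "ACDEFGC"
  for (state in c("H", "E")) {
    ss <- rep("C", 7)
    ss[4] <- state
    expect_equal(nrow(predictSequenceLoops(sq, ss, rep("e", 7))), 0L)
  }
})

test_that("internal cysteines and over-long windows are rejected", {
  # internal cysteine between the terminals
  sq1 <- "ACDCFGC"   # C at 2,4,7: window 2..7 has internal C
  out1 <- predictSequenceLoops(sq1, rep("C", 7), rep("e", 7))
  expect_false(any(out1$start == 2 & out1$end == 7))
  # total length 11 > default 10
  sq2 <- paste0("C", strrep("A", 9), "C")
  expect_equal(nrow(predictSequenceLoops(sq2, rep("C", 11),
                                         rep("e", 11))), 0L)
  # total length 10 passes
  sq3 <- paste0("C", strrep("A", 8), "C")
  expect_equal(nrow(predictSequenceLoops(sq3, rep("C", 10),
                                         rep("e", 10))), 1L)
})

test_that("the exposure rule is a strict majority over the window", {
  sq <- "CAAAC"  # window of 5
  accMajority <- c("e", "e", "e", "b", "b")
  expect_equal(nrow(predictSequenceLoops(sq, rep("C", 5), accMajority)), 1L)
  accMinority <- c("e", "e", "b", "b", "b")
  expect_equal(nrow(predictSequenceLoops(sq, rep("C", 5), accMinority)), 0L)
  # exact 50% tie on an even window is excluded
  sq6 <- "CAAAAC"
  accTie <- c("e", "e", "e", "b", "b", "b")
  expect_equal(nrow(predictSequenceLoops(sq6, rep("C", 6), accTie)), 0L)
})

test_that("prediction length mismatches raise an error", {
  expect_error(predictSequenceLoops("CAAC", rep("C", 3), rep("e", 4)),
               "length mismatch")
})

# ---- similarity scoring -----------------------------------------------------

test_that("self-similarity is exactly one", {
  for (pep in c("ELGW", "KRR", "NSSTDS", "A", "W")) {
    expect_equal(loopSimilarity(pep, pep)$similarity, 1)
  }
})

test_that("hand-verified interior pairs score as expected", {
  s1 <- loopSimilarity("ELQW", "ELGW")
  expect_equal(s1$raw, 18)
  expect_equal(s1$self, 26)
  expect_equal(s1$similarity, 18 / 26, tolerance = 1e-12)

  s2 <- loopSimilarity("KGR", "KRR")
  expect_equal(s2$raw, 8)
  expect_equal(s2$self, 15)
  expect_equal(s2$similarity, 8 / 15, tolerance = 1e-12)
})

test_that("global scores match the exhaustive matching oracle", {
  mat <- blosum62()
  set.seed(7)
  aas <- rownames(mat)[1:20]
  for (k in 1:12) {
    a <- paste(sample(aas, sample(1:4, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:4, 1), replace = TRUE), collapse = "")
    got <- loopSimilarity(a, b)$raw
    expect_equal(got, oracleAlignScore(a, b, mat, -12),
                 info = paste(a, b))
  }
})

test_that("global and local scores match the established aligner", {
  mat <- blosum62()
  set.seed(8)
  aas <- rownames(mat)[1:20]
  for (k in 1:10) {
    a <- paste(sample(aas, sample(2:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:8, 1), replace = TRUE), collapse = "")
    expect_equal(
      loopSimilarity(a, b)$raw,
      Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                    gapOpening = 0, gapExtension = 12,
                                    type = "global", scoreOnly = TRUE),
      info = paste("global", a, b))
    expect_equal(
      loopSimilarity(a, b, type = "local")$raw,
      Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                    gapOpening = 0, gapExtension = 12,
                                    type = "local", scoreOnly = TRUE),
      info = paste("local", a, b))
  }
})

test_that("similarity never exceeds one", {
  set.seed(9)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (k in 1:200) {
    a <- paste(sample(aas, sample(1:9, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:9, 1), replace = TRUE), collapse = "")
    expect_lte(loopSimilarity(a, b)$similarity, 1)
  }
})

test_that("empty and non-standard interiors are rejected", {
  expect_error(loopSimilarity("", "ELGW"), "non-empty")
  expect_error(loopSimilarity("ELQW", "ELXW"), "non-standard residue")
  expect_error(loopSimilarity("ELBW", "ELGW"), "non-standard residue")
})

# ---- PSI-MITAB parsing ------------------------------------------------------

mitabLine <- function(a, b, ta = "taxid:9606(human)",
                      tb = "taxid:9606(human)") {
  paste(c(a, b, "-", "-", "-", "-", "-", "-", "-", ta, tb,
          "-", "-", "-", "-"), collapse = "\t")
}

test_that("distinct MITAB lines become distinct edges with taxa", {
  f <- tempfile()
  writeLines(c(
    mitabLine("uniprotkb:P1", "uniprotkb:P2"),
    mitabLine("uniprotkb:P1", "uniprotkb:V1",
              tb = "taxid:10239(virus)"),
    mitabLine("uniprotkb:P2", "uniprotkb:P3")), f)
  g <- readMitab(f)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(igraph::vcount(g), 4L)
  taxa <- setNames(igraph::V(g)$taxon, igraph::V(g)$name)
  expect_equal(unname(taxa["V1"]), "virus")
  expect_equal(unname(taxa["P1"]), "human")
})

test_that("duplicate pairs across files merge with both source tags", {
  f1 <- tempfile(fileext = "a.txt")
  f2 <- tempfile(fileext = "b.txt")
  writeLines(mitabLine("uniprotkb:P1", "uniprotkb:P2"), f1)
  writeLines(mitabLine("uniprotkb:P2", "uniprotkb:P1"), f2)
  g <- readMitab(c(f1, f2))
  expect_equal(igraph::ecount(g), 1L)
  src <- igraph::edge_attr(g, "sources")
  expect_match(src, basename(f1), fixed = TRUE)
  expect_match(src, basename(f2), fixed = TRUE)
})

test_that("empty files yield an empty graph", {
  f <- tempfile()
  writeLines(character(0), f)
  g <- readMitab(f)
  expect_equal(igraph::vcount(g), 0L)
  expect_equal(igraph::ecount(g), 0L)
})

test_that("unparsable lines are skipped with a reported count", {
  f <- tempfile()
  writeLines(c(mitabLine("uniprotkb:P1", "uniprotkb:P2"),
               "garbage-line-without-tabs",
               mitabLine("-", "uniprotkb:P9")), f)
  expect_message(g <- readMitab(f), "skipped 2")
  expect_equal(igraph::ecount(g), 1L)
})

test_that("isoform suffixes collapse to the parent accession", {
  f <- tempfile()
  writeLines(c(mitabLine("uniprotkb:P04004-2", "uniprotkb:P2"),
               mitabLine("uniprotkb:P04004", "uniprotkb:P2")), f)
  g <- readMitab(f)
  expect_equal(igraph::ecount(g), 1L)
  expect_true("P04004" %in% igraph::V(g)$name)
})

test_that("missing files are an error", {
  expect_error(readMitab("/nonexistent/file.txt"), "cannot read")
})

# ---- mimicry candidates -----------------------------------------------------

test_that("empty graphs and sub-threshold pairs yield no hits", {
  hl <- data.frame(accession = "H1", interior = "ELQW")
  vl <- data.frame(accession = "V1", interior = "ELGW")
  g0 <- igraph::make_empty_graph(directed = FALSE)
  expect_equal(nrow(findMimicryCandidates(hl, vl, g0)), 0L)

  f <- tempfile()
  writeLines(c(mitabLine("uniprotkb:H1", "uniprotkb:X1"),
               mitabLine("uniprotkb:V1", "uniprotkb:X1",
                         ta = "taxid:10239(virus)")), f)
  g <- readMitab(f)
  # similarity 0.69 > 0.5: one hit through the shared interactor X1
  hits <- findMimicryCandidates(hl, vl, g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$sharedInteractors, "X1")
  # raise the threshold above the pair's similarity: no hits
  expect_equal(nrow(findMimicryCandidates(hl, vl, g,
                                          simThreshold = 0.75)), 0L)
  # dissimilar interiors fall below the default threshold
  vl2 <- data.frame(accession = "V1", interior = "PPPP")
  expect_equal(nrow(findMimicryCandidates(hl, vl2, g)), 0L)
})

test_that("hits equal brute-force enumeration on random seeded graphs", {
  interiors <- c("ELQW", "ELGW", "KGR", "KRR", "NSSTDS", "TVSTD", "RAP")
  for (seed in 1:6) {
    spec <- networkSpec(nHuman = 8, nVirus = 4,
                        plantedTriangles = rbind(
                          plantedTriangle("HUM0001", "VIR0001", "HUM0005"),
                          plantedTriangle("HUM0002", "VIR0002", "HUM0006")),
                        noiseEdges = 6, seed = seed)
    f <- tempfile()
    edges <- makeInteractionNetwork(spec, file = f)
    g <- readMitab(f)
    set.seed(seed)
    hl <- data.frame(accession = sprintf("HUM%04d", 1:3),
                     interior = sample(interiors, 3))
    vl <- data.frame(accession = sprintf("VIR%04d", 1:2),
                     interior = sample(interiors, 2))
    got <- findMimicryCandidates(hl, vl, g)
    want <- bruteMimicry(hl, vl, edges)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      key <- function(d) sort(paste(d$humanAccession, d$viralAccession,
                                    d$sharedInteractors))
      expect_equal(key(got), key(want))
    }
  }
})

test_that("results are invariant to MITAB file and line order", {
  l1 <- mitabLine("uniprotkb:H1", "uniprotkb:X1")
  l2 <- mitabLine("uniprotkb:V1", "uniprotkb:X1",
                  ta = "taxid:10239(virus)")
  l3 <- mitabLine("uniprotkb:H1", "uniprotkb:X2")
  l4 <- mitabLine("uniprotkb:V1", "uniprotkb:X2",
                  ta = "taxid:10239(virus)")
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile(); f4 <- tempfile()
  writeLines(c(l1, l2, l3, l4), f1)
  writeLines(c(l4, l3, l2, l1), f2)
  writeLines(c(l3, l1), f3); writeLines(c(l2, l4), f4)
  hl <- data.frame(accession = "H1", interior = "ELQW")
  vl <- data.frame(accession = "V1", interior = "ELGW")
  h1 <- findMimicryCandidates(hl, vl, readMitab(f1))
  h2 <- findMimicryCandidates(hl, vl, readMitab(f2))
  h3 <- findMimicryCandidates(hl, vl, readMitab(c(f3, f4)))
  expect_equal(h1$sharedInteractors, "X1;X2")
  expect_equal(h1[c("humanAccession", "viralAccession", "similarity",
                    "sharedInteractors")],
               h2[c("humanAccession", "viralAccession", "similarity",
                    "sharedInteractors")])
  expect_equal(h1$sharedInteractors, h3$sharedInteractors)
})
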