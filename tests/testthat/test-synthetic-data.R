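test_that("generated structures are deterministic and round-trip through detection", {
  spec <- structureSpec(nChains = 2, chainLength = 18,
                        loopPlants = loopPlant("A", 10, 15, 2.05),
                        interChainGap = 6, seed = 11)
  f1 <- tempfile(fileext = ".pdb")
  f2 <- tempfile(fileext = ".pdb")
  makeLoopStructure(spec, file = f1)
  makeLoopStructure(spec, file = f2)
  expect_identical(readLines(f1), readLines(f2))

  s <- readStructure(f1)
  loops <- loopTable(detectDisulphideLoops(s))
  expect_equal(nrow(loops), 1L)
  expect_equal(loops$cysI, 10L)
  expect_equal(loops$cysJ, 15L)
  expect_equal(loops$interiorLength, 4L)

  # the planted S-gamma pair sits at the requested distance
  a <- atomTable(s)
  sg <- a[a$elety == "SG", ]
  d <- sqrt(sum((sg[1, c("x", "y", "z")] - sg[2, c("x", "y", "z")])^2))
  expect_lt(abs(d - 2.05), 0.01)
})

test_that("structures without planted loops contain no detectable loops", {
  s <- makeLoopStructure(structureSpec(nChains = 1, chainLength = 15,
                                       seed = 2))
  expect_equal(length(detectDisulphideLoops(s)), 0L)
})

test_that("chains at a sub-cutoff gap form an interface on both chains", {
  s <- makeLoopStructure(structureSpec(nChains = 2, chainLength = 10,
                                       interChainGap = 2.9, seed = 3))
  imap <- findInterfaceResidues(s, cutoff = 3.0)
  res <- interfaceResidues(imap)
  expect_true(all(c("A", "B") %in% res$chain))
  expect_identical(res, bruteInterface(s, 3.0))
})

test_that("structure spec validation catches impossible plants", {
  expect_error(structureSpec(loopPlants = loopPlant("A", 10, 30),
                             chainLength = 20), "outside chain")
  expect_error(structureSpec(loopPlants = loopPlant("C", 2, 8),
                             nChains = 2), "chain 'C'")
  expect_error(structureSpec(interChainGap = 0), "interChainGap")
  expect_error(structureSpec(loopPlants = loopPlant("A", 5, 9, dist = -1)),
               "distance")
})

test_that("msa consensus frequencies match the generating probability", {
  ms <- msaSpec(nRows = 200, length = 80, baseConservation = 0.6,
                loopBoost = 0, seed = 5)
  aln <- makeConservationMsa(ms)
  M <- do.call(rbind, strsplit(as.character(aln), ""))
  cons <- M[1, ]
  # homolog rows only; per column the agreement probability is the copy
  # probability plus the chance a background draw coincides with consensus
  agree <- colMeans(M[-1, , drop = FALSE] ==
                    matrix(cons, nrow(M) - 1, ncol(M), byrow = TRUE))
  p <- 0.6 + 0.4 * unname(blosum62Background()[cons])
  se <- sqrt(p * (1 - p) / (nrow(M) - 1))
  z <- abs(agree - p) / se
  # individual columns stay within binomial noise (a rare 3-SD excursion
  # among 80 columns is expected); nothing should stray far
  expect_gte(mean(z < 3), 0.95)
  expect_lt(max(z), 5)
})

test_that("cys-flanked loop terminals are invariant cysteines in every row", {
  ms <- msaSpec(nRows = 30, length = 40,
                loopRegions = loopRegion(10, 17), seed = 6)
  M <- do.call(rbind, strsplit(as.character(makeConservationMsa(ms)), ""))
  expect_true(all(M[, 10] == "C"))
  expect_true(all(M[, 17] == "C"))
})

test_that("degenerate full conservation yields zero loop-flank difference", {
  ms <- msaSpec(nRows = 20, length = 40, baseConservation = 1,
                loopBoost = 0, loopRegions = loopRegion(10, 17), seed = 7)
  aln <- makeConservationMsa(ms)
  # under a uniform background every fully conserved column scores the
  # same, so interior and flank means coincide exactly
  uniform <- setNames(rep(1 / 20, 20), names(blosum62Background()))
  prof <- jsConservation(aln, background = uniform)
  loop <- data.frame(id = "ref", cysI = 10L, cysJ = 17L, family = "")
  rec <- loopFlankDifference(prof, loop, aln)
  expect_equal(rec$difference, 0, tolerance = 1e-12)
  expect_true(all(conservationScores(prof) ==
                  conservationScores(prof)[1]))
})

test_that("without a planted boost the mean loop-flank difference is null", {
  diffs <- vapply(1:30, function(sd) {
    set <- plantedConservationSet(nLoops = 4, boost = 0, seed = 100 + sd,
                                  nRows = 30)
    surv <- conservationSurvey(set$loops, set$alignments)
    mean(surv$records$difference)
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 0.01)
})

test_that("overlapping loop regions are rejected", {
  ms <- msaSpec(length = 40,
                loopRegions = rbind(loopRegion(5, 12), loopRegion(10, 18)))
  expect_error(makeConservationMsa(ms), "overlap")
})

test_that("alignment generation is deterministic per seed", {
  ms <- msaSpec(nRows = 10, length = 30, seed = 42,
                loopRegions = loopRegion(5, 10))
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  makeConservationMsa(ms, file = f1)
  makeConservationMsa(ms, file = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("interaction networks plant exactly the requested triangles", {
  spec <- networkSpec(nHuman = 8, nVirus = 4,
                      plantedTriangles = rbind(
                        plantedTriangle("HUM0001", "VIR0001", "HUM0003"),
                        plantedTriangle("HUM0002", "VIR0002", "HUM0004")),
                      noiseEdges = 10, seed = 9)
  edges <- makeInteractionNetwork(spec)
  adj <- function(a, b) any((edges$a == a & edges$b == b) |
                            (edges$a == b & edges$b == a))
  expect_true(adj("HUM0001", "HUM0003") && adj("VIR0001", "HUM0003"))
  expect_true(adj("HUM0002", "HUM0004") && adj("VIR0002", "HUM0004"))
  # brute-force: planted pairs share exactly their planted interactor
  nodes <- unique(c(edges$a, edges$b))
  shared <- function(h, v) sort(Filter(function(x) x != h && x != v &&
                                         adj(h, x) && adj(v, x), nodes))
  expect_identical(shared("HUM0001", "VIR0001"), "HUM0003")
  expect_identical(shared("HUM0002", "VIR0002"), "HUM0004")
})

test_that("empty network spec produces an empty edge list", {
  edges <- makeInteractionNetwork(networkSpec(nHuman = 3, nVirus = 2,
                                              noiseEdges = 0, seed = 1))
  expect_equal(nrow(edges), 0L)
})

test_that("network files are deterministic and valid PSI-MITAB", {
  spec <- networkSpec(nHuman = 5, nVirus = 2,
                      plantedTriangles = plantedTriangle("HUM0001",
                                                         "VIR0001",
                                                         "HUM0002"),
                      noiseEdges = 3, seed = 12)
  f1 <- tempfile(); f2 <- tempfile()
  makeInteractionNetwork(spec, file = f1)
  makeInteractionNetwork(spec, file = f2)
  expect_identical(readLines(f1), readLines(f2))
  fields <- strsplit(readLines(f1)[1], "\t")[[1]]
  expect_length(fields, 15L)
  expect_match(fields[1], "^uniprotkb:")
  expect_match(fields[10], "^taxid:")
})

test_that("network spec validation rejects malformed triangles", {
  expect_error(networkSpec(plantedTriangles =
                             plantedTriangle("HUM0001", "VIR0001",
                                             "HUM0001")),
               "distinct")
  expect_error(networkSpec(nHuman = 2, nVirus = 1,
                           plantedTriangles =
                             plantedTriangle("HUM0009", "VIR0001",
                                             "HUM0002")),
               "existing")
})

test_that("prediction profiles label spans and validate contradictions", {
  p <- makePredictionProfile("ACDEFGC", coilRegions = list(c(1, 7)),
                             exposedRegions = list(c(1, 7)))
  expect_true(all(p$ss == "C"))
  expect_true(all(p$acc == "e"))

  p2 <- makePredictionProfile("ACDEFGC", coilRegions = list(c(1, 3)),
                              sheetRegions = list(c(5, 6)))
  expect_identical(p2$ss, c("C", "C", "C", "H", "E", "E", "H"))

  expect_error(makePredictionProfile("ACDEFGC",
                                     coilRegions = list(c(1, 4)),
                                     sheetRegions = list(c(3, 6))),
               "contradictory")
  expect_error(makePredictionProfile("ACD", coilRegions = list(c(2, 9))),
               "out of bounds")
})

test_that("prediction profile files round-trip through the reader", {
  f <- tempfile(fileext = ".tsv")
  p <- makePredictionProfile("CAAGGC", coilRegions = list(c(1, 6)),
                             exposedRegions = list(c(2, 5)), file = f)
  expect_identical(readPredictionProfile(f), p)
})
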