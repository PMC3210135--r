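mkCorr <- function(seqsA, seqsB, famA = "famS", famB = "famT",
                   memA = "dS1", memB = "dT1") {
  new("CorrespondenceMap", familyA = famA, familyB = famB, memberA = memA,
      memberB = memB,
      pairs = data.frame(
        keyA = vapply(seqsA, function(i)
          paste("A", i, "", "ALA", sep = "|"), ""),
        keyB = vapply(seqsB, function(i)
          paste("A", i, "", "ALA", sep = "|"), ""),
        stringsAsFactors = FALSE),
      sourceTag = "test")
}

mkRegion <- function(id, fam, ifaceIds, cols) {
  new("BindingRegion", regionId = id, familyId = fam,
      columnSet = as.integer(cols), interfaceIds = ifaceIds,
      origin = "observed", cutoffUsed = 0, coverage = NA_real_,
      sourceRegionIds = character(), sourceFamilyIds = character(),
      predictedInterfaces = data.frame(sourceInterfaceId = character(),
                                       ligandType = character(),
                                       stringsAsFactors = FALSE))
}

mkPred <- function(id, fam, cols, cov = 0.8, srcReg = "BR_1",
                   srcFam = "famS") {
  new("BindingRegion", regionId = id, familyId = fam,
      columnSet = as.integer(cols), interfaceIds = character(),
      origin = "predicted", cutoffUsed = NA_real_, coverage = cov,
      sourceRegionIds = srcReg, sourceFamilyIds = srcFam,
      predictedInterfaces = data.frame(sourceInterfaceId = "IF_1",
                                       ligandType = "protein",
                                       stringsAsFactors = FALSE))
}

test_that("region transfer computes coverage and target columns", {
  tgt <- mkAln("famT", "dT1", nRes = 30)
  src <- mkIface("IF_1", "dS1", 1:8, fam = "famS", ligType = "dna")
  region <- mkRegion("BR_1", "famS", "IF_1", 0:7)

  # full correspondence -> coverage 1, all eight columns transferred
  p <- transferRegion(region, list(src), mkCorr(1:8, 11:18), tgt)
  expect_equal(coverage(p), 1.0)
  expect_equal(columnSet(p), 10:17)
  expect_equal(regionOrigin(p), "predicted")
  expect_equal(p@sourceFamilyIds, "famS")
  expect_equal(p@predictedInterfaces$ligandType, "dna")

  # brute-force count: 4 of 8 residues have a counterpart -> coverage 0.5
  corr4 <- mkCorr(c(1, 2, 3, 4, 20, 21, 22, 23), 11:18)
  mappedOracle <- sum(1:8 %in% c(1, 2, 3, 4, 20, 21, 22, 23)) / 8
  p4 <- transferRegion(region, list(src), corr4, tgt, threshold = 0.5)
  expect_equal(coverage(p4), mappedOracle)
  expect_equal(coverage(p4), 0.5)

  # 3 of 8 mapped: below the 0.5 threshold, nothing emitted
  corr3 <- mkCorr(c(1, 2, 3, 20, 21, 22, 23, 24), 11:18)
  expect_null(transferRegion(region, list(src), corr3, tgt, threshold = 0.5))

  # family mismatch and bad thresholds are errors
  expect_error(transferRegion(mkRegion("BR_2", "famQ", "IF_1", 0:7),
                              list(src), mkCorr(1:8, 11:18), tgt),
               "famQ")
  expect_error(transferRegion(region, list(src), mkCorr(1:8, 11:18), tgt,
                              threshold = 1.01), "threshold")
})

test_that("coverage only depends on the residue sets, not their labels", {
  tgt <- mkAln("famT", "dT1", nRes = 30)
  src <- mkIface("IF_1", "dS1", 4:11, fam = "famS")
  region <- mkRegion("BR_1", "famS", "IF_1", 3:10)
  p <- transferRegion(region, list(src), mkCorr(4:11, 14:21), tgt)
  # same geometry under shifted residue numbering
  src2 <- mkIface("IF_1", "dS1", 104:111, fam = "famS")
  corr2 <- mkCorr(104:111, 14:21)
  corr2@pairs$keyA <- vapply(104:111, function(i)
    paste("A", i, "", "ALA", sep = "|"), "")
  p2 <- transferRegion(region, list(src2), corr2, tgt)
  expect_equal(coverage(p2), coverage(p))
})

test_that("raising the threshold never yields more predictions", {
  tgt <- mkAln("famT", "dT1", nRes = 30)
  set.seed(31)
  regions <- list(); srcIfaces <- list()
  for (k in 1:6) {
    seqs <- sort(sample(1:20, 8))
    srcIfaces[[k]] <- mkIface(paste0("IF_", k), "dS1", seqs, fam = "famS")
    regions[[k]] <- mkRegion(paste0("BR_", k), "famS", paste0("IF_", k),
                             seqs - 1L)
  }
  corr <- mkCorr(1:12, 11:22)
  counts <- vapply(c(0.25, 0.5, 0.75, 1.0), function(thr) {
    sum(vapply(seq_along(regions), function(k)
      !is.null(transferRegion(regions[[k]], srcIfaces[k], corr, tgt,
                              threshold = thr)), TRUE))
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("redundant predictions merge by overlap with provenance kept", {
  p1 <- mkPred("BR_p1", "famT", 5:9, cov = 0.6, srcFam = "famS")
  p2 <- mkPred("BR_p2", "famT", 5:9, cov = 0.9, srcFam = "famU")
  merged <- deduplicatePredictions(list(p1, p2), cutoff = 0)
  expect_length(merged, 1L)
  expect_setequal(merged[[1]]@sourceFamilyIds, c("famS", "famU"))
  expect_equal(coverage(merged[[1]]), 0.9)

  # disjoint predictions stay apart
  p3 <- mkPred("BR_p3", "famT", 20:24)
  expect_length(deduplicatePredictions(list(p1, p3), cutoff = 0), 2L)

  # chained overlap merges transitively, like the clustering oracle
  q1 <- mkPred("BR_q1", "famT", 1:4)
  q2 <- mkPred("BR_q2", "famT", 3:7)
  q3 <- mkPred("BR_q3", "famT", 6:10)
  merged <- deduplicatePredictions(list(q1, q2, q3), cutoff = 0)
  oracle <- transitiveClosureClusters(list(1:4, 3:7, 6:10), 0)
  expect_equal(length(merged), length(unique(oracle)))
  expect_equal(columnSet(merged[[1]]), 1:10)

  expect_error(deduplicatePredictions(list(p1, mkPred("x", "famZ", 1:3))),
               "multiple target families")
})

test_that("predictions overlapping observed regions corroborate, not duplicate", {
  obs <- mkRegion("BR_1", "famT", "IF_9", 5:9)
  pNew <- mkPred("BR_p1", "famT", 20:24)
  pDup <- mkPred("BR_p2", "famT", 6:8)
  sp <- splitCorroborating(list(pNew, pDup), list(obs), cutoff = 0)
  expect_length(sp$novel, 1L)
  expect_equal(regionId(sp$novel[[1]]), "BR_p1")
  expect_equal(sp$corroborating$predictionId, "BR_p2")
  expect_equal(sp$corroborating$observedRegionId, "BR_1")
})

test_that("families with only predictions are isolated correctly", {
  obsT <- mkRegion("BR_1", "famT", "IF_1", 1:3)
  predT <- mkPred("BR_2", "famT", 10:12)
  predU <- mkPred("BR_3", "famU", 1:4)
  h <- assembleHierarchy(list(obsT, predT, predU), list(), cutoff = 0)
  expect_equal(familiesWithOnlyPredictions(h), "famU")
  expect_equal(familiesWithOnlyPredictions(
    assembleHierarchy(list(), list(), 0)), character())
})

test_that("correspondence maps load from TSV and validate one-to-one pairs", {
  txt <- c(paste("family_a", "member_a", "chain_a", "seq_a", "icode_a",
                 "res_a", "family_b", "member_b", "chain_b", "seq_b",
                 "icode_b", "res_b", sep = "\t"),
           "famS\tdS1\tA\t1\t.\tALA\tfamT\tdT1\tA\t11\t.\tALA",
           "famS\tdS1\tA\t2\t.\tALA\tfamT\tdT1\tA\t12\t.\tALA")
  cm <- readCorrespondenceMap(txt)
  expect_equal(cm@familyA, "famS")
  expect_equal(nrow(cm@pairs), 2L)
  expect_equal(cm@pairs$keyA[1], "A|1||ALA")
  dup <- c(txt, "famS\tdS1\tA\t1\t.\tALA\tfamT\tdT1\tA\t13\t.\tALA")
  expect_error(readCorrespondenceMap(dup), "one-to-one")
})
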