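test_that("random networks are reachable from the receptor", {
  net <- randomSignedNetwork(40, seed = 2)
  expect_equal(nodeIds(net)[1], "EGFR")
  reach <- bfsReachable(edgeTable(net), "EGFR")
  expect_setequal(reach, nodeIds(net))
  # deterministic under seed
  net2 <- randomSignedNetwork(40, seed = 2)
  expect_identical(edgeTable(net2), edgeTable(net))
})

test_that("ground-truth sampling is seeded and spectrally rescaled", {
  net <- randomSignedNetwork(25, seed = 4)
  gt1 <- sampleGroundTruth(net, seed = 9)
  gt2 <- sampleGroundTruth(net, seed = 9)
  expect_identical(weightMatrix(gt1), weightMatrix(gt2))
  # weights carry the curated signs
  expect_true(all(sign(weightMatrix(gt1)[signMatrix(net) != 0]) ==
                    signMatrix(net)[signMatrix(net) != 0]))
  # spectral radius of |W| equals the target (eigendecomposition oracle)
  rho <- max(Mod(eigen(abs(weightMatrix(gt1)), only.values = TRUE)$values))
  expect_equal(rho, 0.9, tolerance = 1e-3)
  # all-activating network: all sampled weights nonnegative
  ed <- edgeTable(net); ed$sign <- 1
  netPos <- signedNetwork(ed, nodes = nodeIds(net))
  gtPos <- sampleGroundTruth(netPos, seed = 3)
  expect_true(all(weightMatrix(gtPos) >= 0))
  empty <- methods::new("SignedNetwork", nodes = character(0),
                        edges = data.frame(source = character(0),
                                           target = character(0),
                                           sign = numeric(0)),
                        adjacency = matrix(0, 0, 0),
                        signs = matrix(0, 0, 0))
  expect_error(sampleGroundTruth(empty), "empty network")
})

test_that("site counts follow the exponential law and sites are named", {
  net <- randomSignedNetwork(409, seed = 6)
  gt <- sampleGroundTruth(net, seed = 7)
  gt <- assignSites(gt, meanSites = 2, seed = 8)
  counts <- table(factor(gt@assignment@siteNodes, levels = nodeIds(net)))
  expect_equal(mean(counts), 2, tolerance = 0.2 * 2)   # within 20%
  expect_true(all(grepl("^.+:S\\d+$", siteIds(gt@assignment))))
  expect_true(all(gt@siteScales > 0))
})

test_that("the site transform is anchored at zero and at unit scale", {
  pr <- asNamespace("phosphoRNN")
  expect_equal(pr$.siteTransform(0, 1, 3), 0)        # log2(1) = 0
  expect_equal(pr$.siteTransform(1, 1, 1), 1)        # log2(2) = 1
  # silent node (max 0) stays identically zero
  expect_equal(pr$.siteTransform(0, 0, 2), 0)
})

test_that("generated timecourses are seeded, shaped and drug-responsive", {
  gt <- smallGroundTruth(nNodes = 15, noiseSd = 0)
  # zero drugs: single stimulated sample on the standard 10-point grid
  ds0 <- generateTimecourse(gt, character(0))
  expect_equal(dim(intensities(ds0@timecourse))[2:3], c(10, 1))
  expect_equal(timePoints(ds0@timecourse),
               c(0, 1, 2, 3, 5, 8, 10, 15, 20, 50))
  # bit-identical under a fixed seed at zero noise
  dsA <- smallDataset(gt, nDrugs = 2, seed = 5)
  dsB <- smallDataset(gt, nDrugs = 2, seed = 5)
  expect_identical(intensities(dsA@timecourse), intensities(dsB@timecourse))
  expect_error(generateTimecourse(gt, "DRUG_NOPE"), "unknown drug")
})

test_that("inhibiting the receptor collapses responses to baseline", {
  gt <- smallGroundTruth(nNodes = 15, noiseSd = 0)
  gt@drugTargets$DRUG_EGFR <- "EGFR"
  ds <- generateTimecourse(gt, "DRUG_EGFR")
  v <- intensities(ds@timecourse)
  late <- 5:10
  ctrlAmp <- mean(abs(v[, late, 1]))
  drugAmp <- mean(abs(v[, late, 2]))
  expect_lt(drugAmp, 0.15 * ctrlAmp)
})

test_that("sites on one node are monotone transforms of each other", {
  gt <- smallGroundTruth(nNodes = 15, noiseSd = 0)
  ds <- smallDataset(gt, nDrugs = 1)
  nodes <- gt@assignment@siteNodes
  shared <- names(which(table(nodes) >= 2))[1]
  skip_if(is.na(shared))
  sites <- which(nodes == shared)[1:2]
  v <- intensities(ds@timecourse)
  a <- as.numeric(v[sites[1], , ])
  b <- as.numeric(v[sites[2], , ])
  skip_if(sd(a) == 0)
  expect_equal(cor(a, b, method = "spearman"), 1)
})

test_that("label shuffling permutes measurements and records the map", {
  gt <- smallGroundTruth(nNodes = 15)
  ds <- smallDataset(gt, nDrugs = 3)
  sh <- shuffleLabels(ds, seed = 2)
  perm <- sh@metadata$labelPermutation
  expect_false(all(perm == seq_along(perm)))    # identity excluded
  expect_equal(intensities(sh@timecourse),
               intensities(ds@timecourse)[, , perm])
  # two samples: the swap
  ds2 <- smallDataset(gt, nDrugs = 1)
  sh2 <- shuffleLabels(ds2, seed = 1)
  expect_equal(sh2@metadata$labelPermutation, c(2, 1))
  expect_error(shuffleLabels(generateTimecourse(gt, character(0))),
               "at least 2")
})

test_that("datasets round-trip through the plain-text formats bit-exactly", {
  gt <- smallGroundTruth(nNodes = 12)
  ds <- smallDataset(gt, nDrugs = 2)
  dir <- withr::local_tempdir()
  writeSyntheticDataset(ds, dir)
  back <- readSyntheticDataset(dir)
  expect_identical(unname(intensities(back@timecourse)),
                   unname(intensities(ds@timecourse)))
  expect_identical(timePoints(back@timecourse), timePoints(ds@timecourse))
  expect_identical(siteIds(back@assignment), siteIds(ds@assignment))
  expect_identical(sort(colnames(back@design@drugMatrix)),
                   sort(colnames(ds@design@drugMatrix)))
  expect_identical(back@metadata$noiseSd, ds@metadata$noiseSd)
})
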