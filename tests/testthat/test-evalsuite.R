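test_that("time-zero baseline subtraction zeroes every trajectory start", {
  v <- array(0, c(2, 3, 2))
  v[1, , 1] <- c(1, 3, 4)
  v[2, , 1] <- 2              # constant trajectory
  v[, , 2] <- v[, , 1] + 1
  tc <- phosphoTimeCourse(v, c("a:S1", "b:S1"), c(0, 5, 10), c("s1", "s2"))
  sub <- baselineSubtractT0(tc)
  expect_equal(intensities(sub)[1, , 1], c(0, 2, 3))
  expect_equal(intensities(sub)[2, , 1], c(0, 0, 0))
  # idempotent
  expect_equal(intensities(baselineSubtractT0(sub)), intensities(sub))
  tcNo0 <- phosphoTimeCourse(v, c("a:S1", "b:S1"), c(1, 5, 10), c("s1", "s2"))
  expect_error(baselineSubtractT0(tcNo0), "t = 0")
})

test_that("differential Pearson matches the textbook formula", {
  expect_equal(pearsonDifferential(c(1, 2, 3), c(5, 6, 7), 0, 4), 1)
  expect_equal(pearsonDifferential(c(3, 2, 1), c(1, 2, 3)), -1)
  set.seed(7)
  pred <- rnorm(100); obs <- rnorm(100)
  pc <- rnorm(100); oc <- rnorm(100)
  dp <- pred - pc; do <- obs - oc
  oracle <- sum((dp - mean(dp)) * (do - mean(do))) /
    sqrt(sum((dp - mean(dp))^2) * sum((do - mean(do))^2))
  expect_equal(pearsonDifferential(pred, obs, pc, oc), oracle)
  # subtraction consistency: zero controls give plain Pearson
  expect_equal(pearsonDifferential(pred, obs, 0, 0), cor(pred, obs))
  expect_error(pearsonDifferential(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("the naive baseline averages the remaining drugs", {
  R <- rbind(d1 = c(1, 2), d2 = c(3, 4), d3 = c(5, 6))
  expect_equal(naiveDrugBaseline("d3", R), c(2, 3))
  expect_equal(naiveDrugBaseline("d1", R[1:2, ]), c(3, 4))  # single remaining
  expect_equal(naiveDrugBaseline("d3", R[c(2, 1, 3), ]),
               naiveDrugBaseline("d3", R))                  # order invariant
  expect_error(naiveDrugBaseline("d1", R[1, , drop = FALSE]), "no remaining")
})

test_that("bootstrap comparison resolves clear wins and ties", {
  set.seed(1)
  obs <- rnorm(50)
  pA <- obs + rnorm(50, sd = 0.01)   # essentially perfect
  pB <- -obs                         # anti-correlated
  p <- bootstrapCompare(pA, pB, obs, nBoot = 2000, seed = 3)
  expect_lte(p, 1 / 2001 + 1e-12)    # no resample can reverse the order
  pTie <- bootstrapCompare(pA, pA, obs, nBoot = 2000, seed = 3)
  expect_equal(pTie, 0.5, tolerance = 0.01)  # ties split by symmetry
  expect_identical(bootstrapCompare(pA, pB, obs, nBoot = 500, seed = 9),
                   bootstrapCompare(pA, pB, obs, nBoot = 500, seed = 9))
  expect_error(bootstrapCompare(1:2, 1:2, 1:2), "at least 3")
})

test_that("up/down ROC labels by threshold and scores continuously", {
  obs <- c(2, 1.5, 0.2, -0.3, -1.2, -2, 0.4, 0.1)
  auc <- updownROC(obs, obs, fcThreshold = 1)
  expect_equal(unname(auc["up"]), 1)
  expect_equal(unname(auc["down"]), 1)
  # independent scores give chance-level AUC
  set.seed(11)
  obs2 <- rnorm(10000); pred2 <- rnorm(10000)
  auc2 <- updownROC(pred2, obs2, fcThreshold = 1)
  expect_equal(unname(auc2["up"]), 0.5, tolerance = 0.03)
  expect_equal(unname(auc2["down"]), 0.5, tolerance = 0.03)
  # threshold beyond the data: undefined, reported missing
  expect_true(all(is.na(updownROC(obs, obs, fcThreshold = 10))))
})

test_that("the CV rule flags near-zero means as undefined", {
  pr <- asNamespace("phosphoRNN")
  M <- rbind(c(1, 3), c(2, 2), c(1e-6, -1e-6))
  cv <- pr$.cvStats(M)
  expect_equal(cv[1], sd(c(1, 3)) / 2)           # = sqrt(2)/2 ~ 0.707
  expect_equal(cv[1], sqrt(2) / 2)
  expect_equal(cv[2], 0)
  expect_true(is.na(cv[3]))
})

test_that("kinase-substrate inference flags direct downregulated sites", {
  # toy cascade: EGFR -> KIN -> SUB, with a bystander node off the path
  edges <- data.frame(source = c("EGFR", "KIN", "EGFR"),
                      target = c("KIN", "SUB", "BYST"),
                      sign = 1)
  net <- signedNetwork(edges)
  sa <- siteAssignment(c("SUB:S1", "BYST:S1", "KIN:S1"),
                       c("SUB", "BYST", "KIN"))
  design <- perturbationDesign(
    "CTRL", ligandMatrix = matrix(1, 1, 1, dimnames = list(NULL, "EGF")),
    ligandReceptors = list(EGF = "EGFR"))
  model <- phosphoModel(net, sa, design, times = c(0, 5, 20), L = 30,
                        seed = 1, siteMapMode = "identity")
  model <- fixAnchors(model, c(0, 10, 29))
  # wire strong activating weights so inhibition of KIN silences SUB
  W <- matrix(0, 4, 4, dimnames = list(nodeIds(net), nodeIds(net)))
  W["KIN", "EGFR"] <- 0.8; W["SUB", "KIN"] <- 0.8; W["BYST", "EGFR"] <- 0.8
  model@params$W <- W
  model@params$b <- rep(0, 4)
  reference <- data.frame(kinase = c("KIN", "KIN"),
                          site = c("SUB:S1", "BYST:S1"))
  res <- inferKinaseSubstrates(model, "KIN", reference, threshold = -0.05)
  expect_equal(res$KIN$validated, "SUB:S1")
  expect_equal(res$KIN$database_only, "BYST:S1")  # listed but not direct/hit
  expect_length(res$KIN$predicted_only, 0)
  # the three lists partition the candidate set
  all3 <- unlist(res$KIN)
  expect_false(any(duplicated(all3)))
  expect_error(inferKinaseSubstrates(model, "NOPE", reference), "absent")
})

test_that("naive differential inference thresholds observed changes", {
  obsS <- c("A:S1" = 1, "B:S1" = 2, "C:S1" = 3)
  ref <- data.frame(kinase = "K", site = c("A:S1", "C:S1"))
  same <- naiveDEInference(obsS, obsS, ref, "K", threshold = 0.5)
  expect_length(same$validated, 0)
  expect_length(same$predicted_only, 0)
  expect_setequal(same$database_only, c("A:S1", "C:S1"))
  obsI <- obsS; obsI["A:S1"] <- -1    # one large difference
  hit <- naiveDEInference(obsI, obsS, ref, "K", threshold = 0.5)
  expect_equal(hit$validated, "A:S1")
  expect_equal(attr(hit, "threshold"), 0.5)
  expect_error(naiveDEInference(c(x = 1), c(y = 2), ref, "K"), "shared")
})

test_that("the fully connected variant nests the prior-masked model", {
  gt <- smallGroundTruth(nNodes = 8)
  ds <- smallDataset(gt, nDrugs = 1, times = c(0, 5, 20), L = 30)
  model <- phosphoModel(gt@network, ds@assignment, ds@design,
                        times = timePoints(ds@timecourse), L = 30, seed = 2)
  expect_message(noPkn <- makeNoPknVariant(model), "64 trainable")
  # with identical (masked) weights the trajectories coincide
  expect_equal(intensities(predictModel(noPkn, ds@design)),
               intensities(predictModel(model, ds@design)))
})

test_that("linear interpolation recovers a linear-in-time synthetic site", {
  # data linear in time: interpolation between neighbors is exact
  times <- c(0, 2, 4, 6, 8)
  v <- array(0, c(4, 5, 2))
  set.seed(3)
  slope <- rnorm(8)
  for (s in 1:2) v[, , s] <- outer(slope[(s - 1) * 4 + 1:4], times)
  tc <- phosphoTimeCourse(v, paste0("g", 1:4, ":S1"), times, c("a", "b"))
  ds <- methods::new("SyntheticDataset",
                     design = perturbationDesign(c("a", "b")),
                     timecourse = tc,
                     assignment = siteAssignment(paste0("g", 1:4, ":S1"),
                                                 paste0("g", 1:4)),
                     groundTruth = NULL, metadata = list())
  res <- runInterpolationProtocol(ds, heldOutTimes = 4, strategy = "linear")
  expect_gt(res$r, 0.999)
  expect_error(runInterpolationProtocol(ds, heldOutTimes = 0,
                                        strategy = "linear"), "t = 0")
})
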