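test_that("maskedMSE averages over observed entries only", {
  expect_equal(maskedMSE(c(1, 2), c(1, 2), c(TRUE, TRUE)), 0)
  expect_equal(maskedMSE(c(1, 3), c(0, 0), c(TRUE, FALSE)), 1)
  expect_error(maskedMSE(1, 0, FALSE), "no observed entries")
})

test_that("sign penalty punishes mode-of-action violations quadratically", {
  signs <- matrix(c(0, 1, -1, 0), 2, 2)
  Wok <- matrix(c(0, 0.4, -0.2, 0), 2, 2)
  expect_equal(signViolationPenalty(Wok, signs), 0)
  Wbad <- matrix(c(0, -0.3, -0.2, 0), 2, 2)   # +1 edge with weight -0.3
  expect_equal(signViolationPenalty(Wbad, signs), 0.09)
  # numerical gradient points back toward zero for the violating weight
  pr <- asNamespace("phosphoRNN")
  g <- pr$.signPenaltyGrad(Wbad, signs)
  eps <- 1e-6
  Wp <- Wbad; Wp[2, 1] <- Wbad[2, 1] + eps
  Wm <- Wbad; Wm[2, 1] <- Wbad[2, 1] - eps
  num <- (signViolationPenalty(Wp, signs) -
            signViolationPenalty(Wm, signs)) / (2 * eps)
  expect_equal(g[2, 1], num, tolerance = 1e-6)
  expect_lt(g[2, 1], 0)     # gradient descent increases W toward 0
})

test_that("spectral penalty activates above the target radius", {
  expect_equal(spectralPenalty(matrix(0, 3, 3)), 0)
  expect_equal(spectralPenalty(diag(c(2, 0)), target = 0.95, nIter = 60),
               1.05^2, tolerance = 1e-4)
})

test_that("training is reproducible and frozen at zero learning rate", {
  gt <- smallGroundTruth(nNodes = 10)
  ds <- smallDataset(gt, nDrugs = 2, times = c(0, 2, 8, 20), L = 40)
  model <- phosphoModel(gt@network, ds@assignment, ds@design,
                        times = timePoints(ds@timecourse), L = 40, seed = 3)
  cfg0 <- trainingConfig(learningRate = 0, epochs = 3, seed = 5)
  fit0 <- trainModel(model, ds@timecourse, ds@design, cfg0)
  expect_identical(fit0$model@params, model@params)   # bit-exact

  cfg <- trainingConfig(epochs = 5, seed = 9)
  fitA <- trainModel(model, ds@timecourse, ds@design, cfg)
  fitB <- trainModel(model, ds@timecourse, ds@design, cfg)
  expect_identical(fitA$loss, fitB$loss)
  expect_identical(fitA$model@params, fitB$model@params)
})

test_that("loss components are nonnegative and sum to the total", {
  gt <- smallGroundTruth(nNodes = 10)
  ds <- smallDataset(gt, nDrugs = 2, times = c(0, 2, 8, 20), L = 40)
  model <- phosphoModel(gt@network, ds@assignment, ds@design,
                        times = timePoints(ds@timecourse), L = 40, seed = 3)
  fit <- trainModel(model, ds@timecourse, ds@design,
                    trainingConfig(epochs = 10, seed = 1))
  loss <- fit$loss
  expect_true(all(loss$mse >= 0 & loss$l2 >= 0 & loss$sign >= 0 &
                    loss$spectral >= 0))
  expect_equal(loss$total, loss$mse + loss$l2 + loss$sign + loss$spectral)
})

test_that("training reduces the masked MSE on a small synthetic instance", {
  gt <- smallGroundTruth(nNodes = 10)
  ds <- smallDataset(gt, nDrugs = 2)
  model <- phosphoModel(gt@network, ds@assignment, ds@design,
                        times = timePoints(ds@timecourse), seed = 2)
  fit <- trainModel(model, ds@timecourse, ds@design,
                    trainingConfig(epochs = 300, seed = 4))
  expect_lt(tail(fit$loss$mse, 1), 0.5 * fit$loss$mse[1])
  # the loss curve decreases overall: late mean below early mean
  q <- nrow(fit$loss) %/% 4
  expect_lt(mean(tail(fit$loss$total, q)), mean(head(fit$loss$total, q)))
})

test_that("non-finite losses abort with the offending component named", {
  gt <- smallGroundTruth(nNodes = 8)
  ds <- smallDataset(gt, nDrugs = 1, times = c(0, 5, 20), L = 30)
  tc <- ds@timecourse
  tc@values[1, 2, 1] <- Inf
  model <- phosphoModel(gt@network, ds@assignment, ds@design,
                        times = timePoints(tc), L = 30, seed = 1)
  expect_error(trainModel(model, tc, ds@design,
                          trainingConfig(epochs = 2, seed = 1)),
               "non-finite loss component.*mse")
})

test_that("end-to-end gradients match finite differences", {
  pr <- asNamespace("phosphoRNN")
  set.seed(42)
  net <- randomSignedNetwork(6, avgDegree = 2, seed = 3)
  gt <- sampleGroundTruth(net, seed = 5)
  gt <- assignSites(gt, meanSites = 1.5, seed = 6)
  ds <- generateTimecourse(gt, drugs = names(gt@drugTargets)[1],
                           times = c(0, 1, 3, 8, 20), L = 12, seed = 7)
  model <- phosphoModel(net, ds@assignment, ds@design,
                        times = timePoints(ds@timecourse), L = 12, seed = 11)
  model@params$deltaRaw <- rnorm(5, sd = 0.3)
  model@params$alpha <- 0.4
  model@params$uRaw <- 0.2
  s <- 2
  obs <- intensities(ds@timecourse)[, , s]
  mk <- validMask(ds@timecourse)[, , s]
  applied <- colnames(ds@design@drugMatrix)[ds@design@drugMatrix[s, ] != 0]
  X <- buildInputs(ds@design[s], net, model@params$ligandRaw,
                   model@params$drugRaw)
  sg <- pr$.sampleLossGrad(model, X, obs, mk, "EGF", applied)
  lossOf <- function(m) {
    Xm <- buildInputs(ds@design[s], m@network, m@params$ligandRaw,
                      m@params$drugRaw)
    fwd <- pr$.modelForward(m, Xm)
    sum(((matrix(fwd$Y, nrow(obs), ncol(obs)) - obs) * mk)^2) / sum(mk)
  }
  eps <- 1e-6
  for (nm in c("W", "b", "drugRaw", "E", "W1", "w2", "deltaRaw", "uRaw",
               "alpha")) {
    p <- model@params[[nm]]
    idxs <- if (nm == "W") which(adjacencyMatrix(net) == 1)[1:6]
            else utils::head(seq_along(p), 6)
    for (i in idxs) {
      m1 <- model; m1@params[[nm]][i] <- p[i] + eps
      m2 <- model; m2@params[[nm]][i] <- p[i] - eps
      num <- (lossOf(m1) - lossOf(m2)) / (2 * eps)
      expect_equal(as.numeric(sg$grads[[nm]])[i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("trained edge weights recover the generating signs and order", {
  gt <- smallGroundTruth(nNodes = 20, noiseSd = 0)
  ds <- smallDataset(gt, nDrugs = 3)
  model <- phosphoModel(gt@network, ds@assignment, ds@design,
                        times = timePoints(ds@timecourse), seed = 1)
  fit <- trainModel(model, ds@timecourse, ds@design,
                    trainingConfig(epochs = 300, seed = 1))
  sup <- which(adjacencyMatrix(gt@network) == 1)
  expect_gt(cor(fit$model@params$W[sup], weightMatrix(gt)[sup]), 0.3)
})

test_that("gradient noise decays with the schedule and clipping is smooth", {
  pr <- asNamespace("phosphoRNN")
  # cosine warm restarts: lr restarts at the period boundary
  lr <- sapply(1:20, pr$.cosineRestartLR, lr0 = 1, period = 10)
  expect_equal(lr[1], 1)
  expect_equal(lr[11], 1)          # restart
  expect_lt(lr[10], 0.05)
  # smooth clipping: norm-preserving below, bounded above
  expect_equal(pr$.smoothClipScale(0.01, 5) * 0.01, 0.01, tolerance = 1e-5)
  expect_lt(pr$.smoothClipScale(1e3, 5) * 1e3, 5 + 1e-9)
})
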