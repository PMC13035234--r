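test_that("the anchor upper bound is a scaled sigmoid", {
  expect_equal(computeUpperBound(0, 150), 75)
  expect_equal(computeUpperBound(50, 150), 150, tolerance = 1e-6)
  expect_equal(computeUpperBound(-50, 150), 0, tolerance = 1e-6)
  expect_error(computeUpperBound(0, 1))
})

test_that("anchors are strictly increasing with fixed endpoints", {
  set.seed(8)
  for (i in 1:200) {          # random (deltaRaw, alpha, u) draws
    K <- sample(3:12, 1)
    delta <- rnorm(K, sd = 2)
    alpha <- rnorm(1, sd = 2)
    u <- runif(1, 1, 149)
    m <- computeAnchors(delta, alpha, u)
    expect_equal(m[1], 0)
    expect_equal(m[K], u)              # g(alpha, 1) = 1
    expect_true(all(diff(m) > 0))
  }
  # alpha -> 0 limit: anchors become affine in the normalized cumsum
  delta <- c(0.3, -0.2, 1, 0.5)
  cs <- cumsum(log1p(exp(delta)))
  cn <- (cs - cs[1]) / (cs[4] - cs[1])
  m0 <- computeAnchors(delta, 0, 20)
  expect_equal(m0[-1], (20 * cn)[-1], tolerance = 1e-6)
  expect_error(computeAnchors(0.5, 0, 10), "at least 2")
})

test_that("soft indexing is exact at integers and linear between them", {
  v <- c(5, 7, 1, 4, 9)
  expect_equal(softIndex(v, 2), v[3])                       # m = 2.0 exactly
  expect_equal(softIndex(v, 1.25), 0.75 * v[2] + 0.25 * v[3])
  expect_equal(softIndex(v, 0.82), 0.18 * v[1] + 0.82 * v[2])
  # piecewise linearity between the bracketing steps
  ms <- seq(1, 2, by = 0.1)
  out <- softIndex(v, ms)
  expect_equal(unname(diff(out)), rep(0.1 * (v[3] - v[2]), 10))
  # derivative wrt m matches finite differences
  f <- function(m) softIndex(v, m)
  expect_equal((f(1.3 + 1e-6) - f(1.3 - 1e-6)) / 2e-6, v[3] - v[2],
               tolerance = 1e-4)
  # out-of-range anchors are clamped with a warning
  expect_warning(res <- softIndex(v, 10), "clamped")
  expect_equal(res, v[5])
  # matrix input: last dimension indexes steps
  M <- rbind(v, 2 * v)
  expect_equal(softIndex(M, c(0, 1.5))[2, 2], 2 * (v[2] + v[3]) / 2)
})

test_that("anchor gradients match finite differences", {
  pr <- asNamespace("phosphoRNN")
  set.seed(3)
  for (alpha in c(-1.2, 0, 1e-8, 0.7)) {
    delta <- rnorm(5, sd = 0.8)
    uRaw <- 0.4
    ag <- pr$.anchorsWithGrad(delta, alpha, uRaw, 150)
    eps <- 1e-6
    anchorsOf <- function(d, a, u)
      computeAnchors(d, a, computeUpperBound(u, 150))
    for (i in 1:5) {
      d1 <- delta; d1[i] <- delta[i] + eps
      d2 <- delta; d2[i] <- delta[i] - eps
      num <- (anchorsOf(d1, alpha, uRaw) - anchorsOf(d2, alpha, uRaw)) /
        (2 * eps)
      expect_equal(ag$dDelta[, i], num, tolerance = 1e-4)
    }
    num <- (anchorsOf(delta, alpha + eps, uRaw) -
              anchorsOf(delta, alpha - eps, uRaw)) / (2 * eps)
    expect_equal(ag$dAlpha, num, tolerance = 1e-4)
    num <- (anchorsOf(delta, alpha, uRaw + eps) -
              anchorsOf(delta, alpha, uRaw - eps)) / (2 * eps)
    expect_equal(ag$dURaw, num, tolerance = 1e-4)
  }
})

test_that("the literal reweighting variant is kept behind a flag", {
  delta <- c(0.1, 0.4, -0.3)
  u <- 30
  m <- computeAnchors(delta, 0.5, u, variant = "literal")
  expect_equal(m[1], 0)
  expect_equal(m[3], u)
  # at alpha = 0 the literal reading collapses interior anchors to u
  mCollapse <- computeAnchors(delta, 0, u, variant = "literal")
  expect_equal(mCollapse[2], u)
})

test_that("one-to-one anchors map the k-th time to step k", {
  expect_equal(oneToOneAnchors(c(0, 1, 2, 5, 8, 12), 150), 0:5)
  expect_equal(oneToOneAnchors(0, 150), 0)
  expect_error(oneToOneAnchors(seq_len(151), 150), "more timepoints")
})

test_that("anchors are recovered from a dense reference site", {
  # model-generated reference: known anchors, four monotone temporal
  # profiles, three sampling schemes
  L <- 50
  t <- 0:(L - 1)
  profiles <- list(cosine = cos(pi * t / (L - 1)),
                   polynomial = (t / (L - 1))^2,
                   sigmoid = 1 / (1 + exp(-0.3 * (t - 25))),
                   sqrt = sqrt(t / (L - 1)))
  set.seed(21)
  schemes <- list(uniform = seq(0, L - 1, length.out = 8),
                  exponential = (L - 1) * (seq(0, 1, length.out = 8))^2,
                  random = sort(c(0, runif(6, 1, L - 2), L - 1)))
  for (profile in profiles) {
    for (anchors in schemes) {
      meas <- softIndex(profile, anchors)
      rec <- fitAnchorsFromReferenceSite(profile, meas)
      expect_lt(max(abs(rec - anchors)), 1 + 1e-9)  # within one step
    }
  }
  # strictly monotone reference with an intermediate target: unique interior
  rec <- fitAnchorsFromReferenceSite(t, c(0, 10.25, 40))
  expect_equal(rec, c(0, 10.25, 40), tolerance = 0.011)
  # flat reference carries no timing information
  expect_error(fitAnchorsFromReferenceSite(rep(1, 20), c(1, 1, 1)), "flat")
})

test_that("anchors export as a two-column TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAnchors(c(0, 1, 5), c(0, 0.82, 14.2), path)
  tab <- read.delim(path)
  expect_identical(names(tab), c("time_minutes", "fractional_step"))
  expect_equal(tab$fractional_step, c(0, 0.82, 14.2))
})
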