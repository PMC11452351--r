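# Simulation module: coalescent backend, selection trajectories, and
# the rescaled forward sweep engine with founder-lineage tracking.

eqDem <- demographyPreset("equilibrium")

test_that("neutral backend: determinism, zero-mu limit, diversity matches 4*Ne*mu", {
  a <- simulateNeutral(eqDem, nHap = 12, lengthBp = 5e4, reps = 2, seed = 91)
  b <- simulateNeutral(eqDem, nHap = 12, lengthBp = 5e4, reps = 2, seed = 91)
  expect_identical(alleles(a[[1]]), alleles(b[[1]]))
  expect_identical(physPos(a[[2]]), physPos(b[[2]]))
  # zero mutation rate -> zero segregating sites (empty replicates)
  z <- simulateNeutral(eqDem, nHap = 10, lengthBp = 5e4, mu = 0, reps = 2,
                       seed = 3)
  expect_true(all(vapply(z, is.null, logical(1))))
  # mean pairwise diversity per bp ~ theta = 4*Ne*mu = 0.001
  reps <- simulateNeutral(eqDem, nHap = 10, lengthBp = 5e4, reps = 120,
                          seed = 17)
  pis <- vapply(reps, function(hm) {
    if (is.null(hm)) return(0)
    f <- derivedFreq(hm)
    n <- nHap(hm)
    sum(2 * f * (1 - f) * n / (n - 1)) / 5e4
  }, numeric(1))
  expect_equal(mean(pis) * 1e3, 1, tolerance = 0.15)
})

test_that("neutral equilibrium site-frequency spectrum follows the 1/i law", {
  reps <- simulateNeutral(eqDem, nHap = 10, lengthBp = 5e4, reps = 200,
                          seed = 23)
  counts <- integer(9)
  for (hm in reps) {
    if (is.null(hm)) next
    k <- colSums(alleles(hm))
    counts <- counts + tabulate(k, nbins = 9)
  }
  expected <- sum(counts) * (1 / 1:9) / sum(1 / 1:9)
  # sites within a replicate are linked, so a chi-square count test is
  # anticonservative; bound the per-class relative deviation instead
  expect_true(all(abs(counts / expected - 1) < 0.2))
  expect_gt(cor(counts, expected), 0.99)
})

test_that("neutral trajectories are martingales; strong selection fixes", {
  set.seed(31)
  finals <- replicate(400, {
    tr <- simulateTrajectory("sgv", N = 100, gens = 30, s = 0, f0 = 0.3)
    tr$freq[length(tr$freq)]
  })
  expect_lt(abs(mean(finals) - 0.3), 0.03)
  # 2Ns >> 1 from f0 = 0.5: fixation essentially certain
  set.seed(32)
  up <- replicate(40, {
    tr <- simulateTrajectory("sgv", N = 100, gens = 150, s = 0.5, f0 = 0.5)
    tr$freq[length(tr$freq)]
  })
  expect_gt(mean(up), 0.95)
  # monotone rise in expectation: mean trajectory is non-decreasing
  set.seed(33)
  mat <- replicate(60, simulateTrajectory("sgv", N = 100, gens = 40,
                                          s = 0.5, f0 = 0.2)$freq)
  expect_true(all(diff(rowMeans(mat)) > -0.01))
  # determinism under a fixed seed
  set.seed(7); t1 <- simulateTrajectory("srm", N = 100, gens = 50, s = 0.2,
                                        thetaB = 10)
  set.seed(7); t2 <- simulateTrajectory("srm", N = 100, gens = 50, s = 0.2,
                                        thetaB = 10)
  expect_identical(t1, t2)
})

test_that("sweep engine honours filters, windows and determinism", {
  h <- simulateSweep(mode = "hard", nHap = 200, lengthBp = 2e5, s = 0.05,
                     onset = c(200, 1500), targetFreq = c(0.5, 0.7),
                     NeSim = 500, reps = 4, seed = 41)
  expect_true(all(vapply(h, function(s) s@founders, integer(1)) == 1L))
  expect_true(all(vapply(h, function(s) s@sampleFreq, numeric(1)) >= 0.45))
  expect_true(all(vapply(h, function(s) s@sampleFreq, numeric(1)) <= 0.75))
  # the selected site column is the beneficial allele at the recorded
  # frequency
  for (s in h)
    expect_equal(mean(alleles(s@hm)[, s@selectedSite]), s@sampleFreq)
  r <- simulateSweep(mode = "srm", nHap = 200, lengthBp = 2e5, s = 0.02,
                     thetaB = 50, onset = c(100, 2000),
                     targetFreq = c(0.4, 0.6), NeSim = 500, reps = 4,
                     seed = 42)
  expect_true(all(vapply(r, function(s) s@founders, integer(1)) >= 2L))
  # determinism
  r2 <- simulateSweep(mode = "srm", nHap = 200, lengthBp = 2e5, s = 0.02,
                      thetaB = 50, onset = c(100, 2000),
                      targetFreq = c(0.4, 0.6), NeSim = 500, reps = 4,
                      seed = 42)
  expect_identical(alleles(r[[2]]@hm), alleles(r2[[2]]@hm))
  expect_identical(r[[1]]@founders, r2[[1]]@founders)
})

test_that("founder-lineage counts rise with theta_b and with f0", {
  nrep <- 30L
  mf <- function(mode, ...) {
    sims <- simulateSweep(mode = mode, nHap = 200, lengthBp = 1.5e5,
                          onset = c(100, 2000), targetFreq = c(0.4, 0.7),
                          NeSim = 500, reps = nrep, seed = 51, ...)
    mean(vapply(sims, function(s) s@founders, integer(1)))
  }
  th <- vapply(c(5, 10, 50), function(t)
    mf("srm", s = 0.02, thetaB = t), numeric(1))
  expect_true(all(diff(th) > 0))
  f0s <- vapply(c(0.05, 0.1, 0.2), function(f)
    mf("sgv", s = 0.02, f0 = f), numeric(1))
  expect_true(all(diff(f0s) > 0))
})

test_that("rescaling level does not shift the focal cluster statistic", {
  # same biological scenario at Q = 10 and Q = 5: mean unstandardized
  # iHSL at the sweep site must be statistically indistinguishable
  runQ <- function(NeSim, seed) {
    sims <- simulateSweep(mode = "srm", nHap = 200, lengthBp = 1.5e5,
                          s = 0.02, thetaB = 10, onset = c(100, 2000),
                          targetFreq = c(0.5, 0.7), NeSim = NeSim,
                          reps = 25, seed = seed)
    vapply(sims, function(s) {
      fr <- scores(scoreSites(s@hm, sites = s@selectedSite, minFreq = 0))
      fr$uiHSL
    }, numeric(1))
  }
  u10 <- runQ(1000, 61)   # Q = 10
  u5 <- runQ(2000, 62)    # Q = 5
  expect_gt(t.test(u10, u5)$p.value, 0.01)
})

test_that("standing-variation mode seeds selection from a variant near f0", {
  g <- simulateSweep(mode = "sgv", nHap = 200, lengthBp = 2e5, s = 0.05,
                     f0 = 0.2, onset = c(100, 800),
                     targetFreq = c(0.4, 0.7), NeSim = 500, reps = 4,
                     seed = 71)
  for (s in g) {
    expect_gte(s@founders, 2L)
    # trajectory starts near the standing frequency (the standing
    # variant is matched within the picker's count tolerance)
    expect_lt(abs(s@trajectory[1] - 0.2), 0.04)
  }
})
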