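# Core cluster statistics: diameter rule, EHH, iHH, log-ratios,
# frequency-bin standardization, and the brute-force oracle agreement.

test_that("cluster diameter rule s = min(max(ceil(r|Hc|), 8), |Hc|)", {
  set.seed(1)
  mk <- function(nc) {
    # nc derived + nc ancestral haplotypes, random flanks
    a <- matrix(rbinom(2 * nc * 11, 1, 0.5), 2 * nc, 11)
    a[, 6] <- rep(c(1L, 0L), each = nc)
    storage.mode(a) <- "integer"
    HaplotypeMatrix(a, physPos = 1:11, genPos = (1:11) / 100)
  }
  expect_equal(localCluster(mk(100), 6, 1, r = 0.1)$s, 10)
  expect_equal(localCluster(mk(20), 6, 1, r = 0.1)$s, 8)   # floor at 8
  cl <- localCluster(mk(5), 6, 1, r = 0.1)
  expect_equal(cl$s, 5)                                     # capped at |Hc|
  expect_setequal(cl$members, 1:5)                          # whole class
  expect_equal(localCluster(mk(37), 6, 2, r = 1)$s, 37)     # r=1: class
  expect_true(1 %in% localCluster(mk(100), 6, 1)$members)   # focal included
})

test_that("EHH partitions pair counts correctly", {
  a <- rbind(c(1L, 1L, 1L), c(1L, 1L, 1L), c(1L, 1L, 0L), c(1L, 0L, 1L))
  hm <- HaplotypeMatrix(a, physPos = 1:3, genPos = (1:3) / 100)
  # all identical over the stretch
  expect_equal(ehhCluster(hm, 1, 1:4, 1), 1)
  # 4 members, two types of size 2 over stretch 1..2: (1+1)/C(4,2)
  a2 <- rbind(c(1L, 1L), c(1L, 1L), c(1L, 0L), c(1L, 0L))
  hm2 <- HaplotypeMatrix(a2, physPos = 1:2, genPos = (1:2) / 100)
  expect_equal(ehhCluster(hm2, 1, 1:4, 2), 1 / 3)
  # all pairwise distinct
  a3 <- rbind(c(1L, 1L, 1L), c(1L, 1L, 0L), c(1L, 0L, 1L), c(1L, 0L, 0L))
  hm3 <- HaplotypeMatrix(a3, physPos = 1:3, genPos = (1:3) / 100)
  expect_equal(ehhCluster(hm3, 1, 1:4, 3), 0)
  expect_error(ehhCluster(hm, 1, 2, 2), "degenerate")
})

test_that("iHH trapezoids: rectangle, single-step triangle, zero map", {
  m <- 11L; core <- 6L
  # identical haplotypes: EHH = 1 everywhere, iHH = total genetic span
  a <- matrix(1L, 4, m)
  g <- seq(0, 1, length.out = m)
  hm <- HaplotypeMatrix(a, physPos = 1:m, genPos = g)
  expect_equal(ihhCluster(hm, core, 1:4), g[m] - g[1])
  # pair distinct at the immediate neighbours: EHH drops 1 -> 0 after a
  # single marker per side, one trapezoid 0.5*(1+0)*g each
  a2 <- matrix(0L, 2, m); a2[, core] <- 1L
  a2[2, core - 1] <- 1L; a2[2, core + 1] <- 1L
  hm2 <- HaplotypeMatrix(a2, physPos = 1:m, genPos = (1:m) * 0.2)
  expect_equal(ihhCluster(hm2, core, 1:2), 0.5 * 0.2 * 2)
  # all inter-marker distances zero
  hm3 <- HaplotypeMatrix(a2, physPos = 1:m, genPos = rep(0, m))
  expect_equal(ihhCluster(hm3, core, 1:2), 0)
})

test_that("r = 1 collapses iHHL to iHH; subfamily structure makes iHHL larger", {
  hm <- subfamilyToy()
  r1 <- ihhlAllele(hm, 11, 1L, r = 1)
  expect_identical(r1$iHHL, r1$iHH)
  # sFloor = 2 so the s-rule resolves the two 3-haplotype subfamilies
  rr <- ihhlAllele(hm, 11, 1L, r = 0.34, sFloor = 2)
  expect_gt(rr$iHHL, rr$iHH)
  expect_gt(uRiHS(rr$iHHL, rr$iHH), 0)
  # cross-check both against the direct pair-counting oracle
  expect_equal(rr$iHH, oracleIhh(alleles(hm), genPos(hm), 1:6, 11),
               tolerance = 1e-12)
  expect_equal(rr$iHHL,
               oracleIhhl(alleles(hm), genPos(hm), 11, 1L, 0.34, sFloor = 2),
               tolerance = 1e-12)
})

test_that("log-ratio statistics behave as defined", {
  expect_equal(uiHSL(2, 2), 0)
  expect_equal(uiHSL(exp(1) * 3, 3), 1)
  expect_equal(uiHSL(2, 5), -uiHSL(5, 2))
  expect_error(uiHSL(0, 1), "log-ratio")
  expect_equal(uRiHS(4, 4), 0)
  expect_error(uRiHS(1, 0), "log-ratio")
})

test_that("thresholds and p-value conventions match the printed points", {
  th <- sweepThresholds()
  expect_equal(round(th[["iHSL"]], 4), 2.3263)
  expect_equal(round(th[["RiHSL"]], 4), 9.2103)
  # one-tailed exceedance of 2.3263 is 1%; upper-tail chi2_2 of 9.2103 is 1%
  expect_equal(1 - pnorm(th[["iHSL"]]), 0.01, tolerance = 1e-6)
  expect_equal(exp(-th[["RiHSL"]] / 2), 0.01, tolerance = 1e-6)
  # closed form equals the chi-square upper tail everywhere
  x <- c(0.1, 1, 5, 9.2103, 20)
  expect_equal(exp(-x / 2), pchisq(x, 2, lower.tail = FALSE))
})

test_that("frequency-bin standardization: z-scores, sample-SD convention, degenerate bins", {
  set.seed(3)
  fr <- data.frame(freq = runif(500, 0.05, 0.95),
                   uiHSL = rnorm(500, 1, 2),
                   uRiHS1 = abs(rnorm(500)), uRiHS0 = abs(rnorm(500)))
  model <- fitNormalization(fr, nBins = 10, minBinCount = 20)
  z <- hapsweep:::.standardizeVec(fr$uiHSL, fr$freq, model, "uiHSL")
  grp <- model@group[hapsweep:::.binIndex(fr$freq, model@edges)]
  for (g in unique(grp)) {
    expect_equal(mean(z[grp == g]), 0, tolerance = 1e-12)
    expect_equal(sd(z[grp == g]), 1, tolerance = 1e-12)
  }
  # two-value bin standardizes to +-1/sqrt(2) under the sample-SD (n-1)
  # convention
  fr2 <- data.frame(freq = c(0.4, 0.6), uiHSL = c(0, 2))
  m2 <- fitNormalization(fr2, nBins = 1, minBinCount = 2)
  z2 <- hapsweep:::.standardizeVec(fr2$uiHSL, fr2$freq, m2, "uiHSL")
  expect_equal(z2, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # constant-valued bin errors
  fr3 <- data.frame(freq = runif(30), uiHSL = rep(1.5, 30))
  expect_error(fitNormalization(fr3, nBins = 1, minBinCount = 2),
               "degenerate")
  # underfilled bins merge with a neighbour rather than failing
  fr4 <- data.frame(freq = c(runif(40, 0.0, 0.1), runif(3, 0.85, 0.95)),
                    uiHSL = rnorm(43))
  m4 <- fitNormalization(fr4, nBins = 10, minBinCount = 20)
  expect_true(length(unique(m4@group)) < 10)
})

test_that("scoreSites output respects definitions and flags", {
  hm <- randomHm(24, 120, seed = 11)
  st <- scoreSites(hm, r = 0.3, L = 30, sFloor = 2)
  fr <- scores(st)
  ok <- fr$status == "ok"
  expect_true(any(ok))
  expect_equal(fr$uiHSL[ok], log(fr$iHHL1[ok] / fr$iHHL0[ok]))
  expect_true(all(fr$freq >= 0.05 & fr$freq <= 0.95))
  expect_true(all(fr$iHH1[ok] >= 0 & fr$iHH0[ok] >= 0))
  # sites near the chromosome edge are flagged
  expect_true(all(fr$edge[fr$site <= 30]))
  # standardized pipeline: RiHSL identity and p-values
  st2 <- scoreSites(hm, r = 0.3, L = 30, sFloor = 2, standardize = TRUE,
                    nBins = 5, minBinCount = 10)
  fr2 <- scores(st2)
  okz <- is.finite(fr2$iHSL) & is.finite(fr2$RiHS)
  expect_equal(fr2$RiHSL[okz], fr2$iHSL[okz]^2 + fr2$RiHS[okz]^2)
  expect_true(all(fr2$p_ihsl[okz] > 0 & fr2$p_ihsl[okz] <= 1))
  expect_equal(fr2$p_ihsl[okz], 2 * pnorm(-abs(fr2$iHSL[okz])))
})

test_that("EHH curves are in [0,1] and non-increasing away from the core", {
  for (seed in 1:4) {
    hm <- randomHm(18, 80, seed = seed)
    a <- alleles(hm)
    freq <- colMeans(a)
    core <- which(freq >= 0.3 & freq <= 0.7)
    core <- core[which.min(abs(core - 40L))]
    rows <- which(a[, core] == a[1, core])
    curve <- hapsweep:::cpp_ehh_curve(a, rows - 1L, core - 1L, 0L,
                                      ncol(a) - 1L)
    expect_true(all(curve >= 0 & curve <= 1))
    right <- curve[core:ncol(a)]
    left <- rev(curve[1:core])
    expect_true(all(diff(right) <= 1e-12))
    expect_true(all(diff(left) <= 1e-12))
    # spot-check against the string-partition oracle
    for (mk in c(core - 7L, core + 5L))
      expect_equal(curve[mk], oracleEhh(a, rows, core, mk),
                   tolerance = 1e-12)
  }
})

test_that("production scoring agrees with the brute-force oracle on small fixtures", {
  for (seed in c(5, 9, 13)) {
    hm <- randomHm(20, 60, seed = seed)
    a <- alleles(hm); g <- genPos(hm)
    freq <- colMeans(a)
    sites <- which(freq >= 0.2 & freq <= 0.8)[1:3]
    st <- scoreSites(hm, sites = sites, r = 0.3, L = 20, sFloor = 2,
                     minFreq = 0.2)
    fr <- scores(st)
    for (i in seq_len(nrow(fr))) {
      if (fr$status[i] != "ok") next
      expect_equal(fr$iHHL1[i],
                   oracleIhhl(a, g, fr$site[i], 1L, 0.3, L = 20, sFloor = 2),
                   tolerance = 1e-12)
      expect_equal(fr$iHHL0[i],
                   oracleIhhl(a, g, fr$site[i], 0L, 0.3, L = 20, sFloor = 2),
                   tolerance = 1e-12)
      expect_equal(fr$iHH1[i],
                   oracleIhh(a, g, which(a[, fr$site[i]] == 1L), fr$site[i],
                             L = 20), tolerance = 1e-12)
    }
  }
})

test_that("flipping ancestral/derived at the core flips the sign of uiHSL", {
  for (seed in c(2, 8)) {
    hm <- randomHm(20, 80, seed = seed)
    freq <- colMeans(alleles(hm))
    site <- which(freq >= 0.3 & freq <= 0.7)[1]
    st1 <- scores(scoreSites(hm, sites = site, r = 0.3, L = 25, sFloor = 2))
    hm2 <- flipPolarity(hm, site)
    st2 <- scores(scoreSites(hm2, sites = site, r = 0.3, L = 25, sFloor = 2))
    expect_equal(st2$uiHSL, -st1$uiHSL, tolerance = 1e-12)
    expect_equal(st2$uRiHS1, st1$uRiHS0, tolerance = 1e-12)
  }
})
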