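# Comparator statistics: iHS as the r=1 special case, nSL shared-stretch
# lengths, and the window haplotype-homozygosity statistics.

test_that("iHS is bit-for-bit iHSL with r = 1", {
  hm <- randomHm(20, 100, seed = 21)
  st1 <- scoreSites(hm, r = 1, L = 30)
  st2 <- ihsScan(hm, L = 30)
  expect_identical(scores(st1)$uiHSL, scores(st2)$uiHSL)
  expect_identical(scores(st1)$iHH1, scores(st2)$iHH1)
  expect_identical(statistic(st2), "iHS")
  # with r = 1 the cluster and class integrals coincide exactly, so the
  # cluster-to-class ratio vanishes (and is reported as undefined by the
  # iHS scan)
  fr <- scores(st1)
  ok <- fr$status == "ok"
  expect_identical(fr$iHHL1[ok], fr$iHH1[ok])
  expect_true(all(abs(fr$uRiHS1[ok]) < 1e-15))
  expect_true(all(is.na(scores(st2)$uRiHS1)))
})

test_that("a homogeneous derived class drives uiHS strongly positive", {
  set.seed(5)
  m <- 61L; core <- 31L
  derived <- matrix(rep(rbinom(m, 1, 0.5), 10), 10, byrow = TRUE)
  ancestral <- matrix(rbinom(10 * m, 1, 0.5), 10)
  a <- rbind(derived, ancestral)
  a[1:10, core] <- 1L; a[11:20, core] <- 0L
  storage.mode(a) <- "integer"
  hm <- HaplotypeMatrix(a, physPos = seq_len(m) * 10,
                        genPos = seq_len(m) * 0.01)
  fr <- scores(ihsScan(hm, sites = core, L = 30))
  expect_gt(fr$uiHSL, 1)
})

test_that("nSL matches the brute-force pairwise shared-stretch oracle", {
  for (seed in c(31, 32)) {
    hm <- randomHm(16, 90, seed = seed)
    a <- alleles(hm)
    freq <- colMeans(a)
    sites <- which(freq >= 0.25 & freq <= 0.75)[1:3]
    raw <- hapsweep:::cpp_nsl_sites(a, sites - 1L, 500L, 2L)
    for (i in seq_along(sites)) {
      if (raw$status[i] != "ok") next
      c1 <- which(a[, sites[i]] == 1L)
      c0 <- which(a[, sites[i]] == 0L)
      expect_equal(raw$SL1[i], oracleNslMeanL(a, c1, sites[i]),
                   tolerance = 1e-12)
      expect_equal(raw$SL0[i], oracleNslMeanL(a, c0, sites[i]),
                   tolerance = 1e-12)
    }
  }
})

test_that("nSL is zero for mirror-image classes and honours the cap", {
  # both classes with identical internal structure -> log-ratio 0
  m <- 41L; core <- 21L
  set.seed(9)
  block <- matrix(rbinom(6 * m, 1, 0.5), 6)
  a <- rbind(block, block)
  a[1:6, core] <- 1L; a[7:12, core] <- 0L
  storage.mode(a) <- "integer"
  hm <- HaplotypeMatrix(a, physPos = seq_len(m), genPos = seq_len(m) / 100)
  fr <- scores(nslScan(hm, sites = core))
  expect_equal(fr$uiHSL, 0, tolerance = 1e-12)
  # a fully identical class is capped at 1 + cap per side
  a2 <- a; a2[1:6, ] <- a2[rep(1L, 6), ]
  a2[7:12, core] <- 0L
  # make the ancestral class all-distinct right next to the core
  a2[7:12, core - 1] <- c(0L, 1L, 0L, 1L, 0L, 1L)
  a2[7:12, core + 1] <- c(0L, 0L, 1L, 1L, 0L, 1L)
  a2[7:12, core + 2] <- c(0L, 1L, 1L, 0L, 1L, 0L)
  hm2 <- HaplotypeMatrix(a2, physPos = seq_len(m), genPos = seq_len(m) / 100)
  raw <- hapsweep:::cpp_nsl_sites(alleles(hm2), core - 1L, 5L, 2L)
  expect_equal(raw$SL1, 1 + 5 + 5)   # cap binds both sides
  expect_equal(raw$SL1, oracleNslMeanL(alleles(hm2), 1:6, core, cap = 5))
})

test_that("H-statistics match the closed forms", {
  m <- 21L
  # all haplotypes identical
  a <- matrix(rep(rbinom(m, 1, 0.5), 8), 8, byrow = TRUE)
  storage.mode(a) <- "integer"
  a[, 1] <- c(1L, rep(0L, 7))  # keep the matrix polymorphic somewhere
  hm <- HaplotypeMatrix(a, physPos = seq_len(m), genPos = seq_len(m) / 100)
  h <- hStats(hm, 11, w = 11)
  expect_equal(h$H12, 1); expect_equal(h$H2H1, 0)
  # n all-distinct haplotypes: H1 = 1/n, H12 = (n + 2)/n^2
  n <- 10L
  a2 <- diag(n); storage.mode(a2) <- "integer"
  hm2 <- HaplotypeMatrix(a2, physPos = seq_len(n), genPos = seq_len(n) / 100)
  h2 <- hStats(hm2, (n + 1L) %/% 2L, w = n - 1L)
  expect_equal(h2$H1, 1 / n)
  expect_equal(h2$H12, (2 / n)^2 + (n - 2) / n^2)
  # two classes at 50/50
  a3 <- rbind(matrix(1L, 5, 10), matrix(0L, 5, 10))
  a3[, 1] <- rep(c(1L, 0L), 5)
  hm3 <- HaplotypeMatrix(a3, physPos = 1:10, genPos = (1:10) / 100)
  h3 <- hStats(hm3, 6, w = 9)
  expect_equal(h3$H1, 0.5); expect_equal(h3$H12, 1)
  expect_equal(h3$H2H1, 0.5)
})

test_that("H-statistic invariants: bounds, H12 >= H1, permutation invariance", {
  for (seed in c(41, 42)) {
    hm <- randomHm(15, 60, seed = seed)
    h <- hStats(hm, 30, w = 21)
    expect_true(h$H1 > 0 && h$H1 <= 1)
    expect_true(h$H12 >= h$H1 && h$H12 <= 1)
    expect_true(h$H2H1 >= 0 && h$H2H1 < 1)
    perm <- sample(nHap(hm))
    hmP <- HaplotypeMatrix(alleles(hm)[perm, ], physPos = physPos(hm),
                           genPos = genPos(hm))
    hP <- hStats(hmP, 30, w = 21)
    expect_equal(hP, h)
  }
})

test_that("window sweep skips oversized windows and best-window selection works", {
  hm <- randomHm(12, 50, seed = 50)
  expect_warning(v <- h12WindowSweep(hm, 25, sizes = c(21L, 1001L)),
                 "skipped")
  expect_named(v, "21")
  # constructed power table: neutral-only scores give ~1% power by the
  # threshold definition; a shifted sweep column wins
  set.seed(7)
  neutral <- cbind(`21` = runif(400), `51` = runif(400))
  sweep <- cbind(`21` = runif(300), `51` = runif(300, 0.5, 1.5))
  out <- h12BestWindow(sweep, neutral)
  expect_equal(attr(out, "best"), 51L)
  fprLike <- h12BestWindow(neutral, neutral)
  expect_true(all(abs(fprLike$power - 0.01) < 0.02))
})

test_that("nSL equals iHS-with-unit-distances once haplotype identity is exhausted", {
  # with unit inter-marker distances and EHH reaching 0 inside the scan
  # range on both sides, the trapezoid integral equals the rectangle sum
  # plus exactly 1, so uiHS == unSL site by site (hence identical ranks)
  hm <- randomHm(20, 200, seed = 60, blocks = 8)
  genPos(hm) <- seq_len(nSites(hm)) * 1.0
  a <- alleles(hm)
  freq <- colMeans(a)
  cand <- which(freq >= 0.3 & freq <= 0.7 & seq_along(freq) > 70 &
                  seq_along(freq) < 130)
  exhausted <- vapply(cand, function(s) {
    all(vapply(0:1, function(al) {
      rows <- which(a[, s] == al)
      cv <- hapsweep:::cpp_ehh_curve(a, rows - 1L, s - 1L, 0L, ncol(a) - 1L)
      cv[1] == 0 && cv[length(cv)] == 0
    }, logical(1)))
  }, logical(1))
  sites <- cand[exhausted]
  expect_gt(length(sites), 3)
  ihs <- scores(ihsScan(hm, sites = sites, L = 400, ehhCutoff = 0))$uiHSL
  nsl <- scores(nslScan(hm, sites = sites, cap = 500))$uiHSL
  expect_equal(ihs, nsl, tolerance = 1e-12)
  expect_equal(order(ihs), order(nsl))
})
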