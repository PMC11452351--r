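# Nearest-neighbour sweep-type classification, core-SNP detection and
# region calling with the soft-shoulder correction.

refToy <- function(n = 300, seed = 1) {
  set.seed(seed)
  centers <- list(neutral = c(0, 0), hard = c(4, -1), soft = c(3, 4))
  pts <- do.call(rbind, lapply(names(centers), function(lb)
    data.frame(iHSL = rnorm(n, centers[[lb]][1], 0.7),
               RiHS = rnorm(n, centers[[lb]][2], 0.7), label = lb)))
  ReferenceDistribution(pts, provenance = list(model = "toy"))
}

test_that("kNN classification matches an exhaustive-distance oracle", {
  ref <- refToy()
  p <- refPoints(ref)
  set.seed(2)
  queries <- cbind(runif(40, -2, 6), runif(40, -3, 6))
  got <- classifySite(queries, ref, k = 25)
  oracle <- apply(queries, 1, function(q) {
    d <- sqrt((p$iHSL - q[1])^2 + (p$RiHS - q[2])^2)
    nn <- order(d)[1:25]
    tab <- sort(table(p$label[nn]), decreasing = TRUE)
    if (sum(tab == max(tab)) > 1) p$label[order(d)[1]] else names(tab)[1]
  })
  expect_identical(got, oracle)
  # cloud centers classify to their own label
  expect_identical(classifySite(c(0, 0), ref, k = 200), "neutral")
  expect_identical(classifySite(c(4, -1), ref, k = 200), "hard")
  expect_identical(classifySite(c(3, 4), ref, k = 200), "soft")
})

test_that("degenerate references behave per contract", {
  one <- ReferenceDistribution(
    data.frame(iHSL = rnorm(250), RiHS = rnorm(250), label = "soft"))
  expect_identical(classifySite(c(-3, 10), one, k = 200), "soft")
  # 200 coincident soft points at the query dominate distant others
  pts <- rbind(data.frame(iHSL = 1, RiHS = 1,
                          label = rep("soft", 200)),
               data.frame(iHSL = rnorm(300, 30), RiHS = rnorm(300, 30),
                          label = rep("hard", 300)))
  expect_identical(classifySite(c(1, 1), ReferenceDistribution(pts),
                                k = 200), "soft")
  expect_error(classifySite(c(0, 0), one, k = 500), "fewer than k")
})

test_that("core-SNP detection follows the neighbourhood-proportion rule", {
  mkst <- function(p) {
    n <- length(p)
    new("ScoreTable",
        frame = data.frame(site = seq_len(n), pos_bp = seq_len(n) * 1000,
                           freq = 0.5, iHSL = 1, RiHS = 0,
                           p_rihsl = p, label = "unscored"),
        statistic = "iHSL", params = list())
  }
  # no significant SNPs -> empty set
  expect_length(findCoreSnps(mkst(rep(0.5, 20))), 0)
  # all significant -> all core
  expect_identical(findCoreSnps(mkst(rep(1e-5, 15))), 1:15)
  # 11 sites, 3 contiguous significant (6..8), window 2, minProp 0.5:
  # core iff the 4-neighbourhood holds >= 2 significant SNPs
  p <- rep(0.5, 11); p[6:8] <- 1e-5
  got <- findCoreSnps(mkst(p), window = 2, minProp = 0.5)
  sig <- p < 0.001
  byHand <- which(vapply(1:11, function(i) {
    nb <- setdiff(max(1, i - 2):min(11, i + 2), i)
    sum(sig[nb]) / length(nb) >= 0.5
  }, logical(1)))
  expect_identical(got, byHand)
  expect_identical(byHand, 5:9)  # enumerated by hand
})

test_that("region calling groups runs, labels by leading SNP, and is idempotent", {
  ref <- refToy()
  n <- 60
  p <- rep(0.5, n)
  p[10:20] <- 1e-6; p[45:50] <- 1e-4
  set.seed(3)
  fr <- data.frame(site = 1:n, pos_bp = (1:n) * 1e3, freq = 0.5,
                   iHSL = rnorm(n, 0.2, 0.2), RiHS = rnorm(n, 0.2, 0.2),
                   p_rihsl = p, label = "unscored",
                   stringsAsFactors = FALSE)
  # leading SNP of run 1 sits in the hard cloud; its flanks in the soft
  # cloud (the soft-shoulder pattern)
  fr$iHSL[10:20] <- 3; fr$RiHS[10:20] <- 4
  fr$p_rihsl[15] <- 1e-9; fr$iHSL[15] <- 4; fr$RiHS[15] <- -1
  fr$iHSL[45:50] <- 3; fr$RiHS[45:50] <- 4
  st <- new("ScoreTable", frame = fr, statistic = "iHSL", params = list())
  st <- classifyScores(st, ref, k = 50, pCut = 0.001)
  expect_identical(scores(st)$label[15], "hard")
  expect_identical(scores(st)$label[16], "soft")
  cores <- findCoreSnps(st, window = 3, minProp = 0.5)
  out <- callRegions(st, cores, ref, maxGap = 5, k = 50)
  regs <- out$regions
  expect_s4_class(regs, "GRanges")
  expect_equal(length(regs), 2L)   # two runs separated by > maxGap
  expect_identical(regs$label[1], "hard")   # leading SNP decides
  expect_equal(regs$leadRow[1], 15L)
  # members revised: the soft shoulder flank now carries the hard label
  expect_identical(scores(out$scores)$label[16], "hard")
  # leading SNP inside its region
  expect_true(all(regs$leadPos >= GenomicRanges::start(regs) &
                    regs$leadPos <= GenomicRanges::end(regs)))
  # idempotence: re-running on the revised table changes nothing
  out2 <- callRegions(out$scores, findCoreSnps(out$scores, window = 3,
                                               minProp = 0.5),
                      ref, maxGap = 5, k = 50)
  expect_identical(scores(out2$scores)$label, scores(out$scores)$label)
  expect_equal(out2$regions$leadRow, regs$leadRow)
  # empty core set -> empty output
  none <- callRegions(st, integer(), ref)
  expect_equal(length(none$regions), 0L)
})

test_that("reference TSV round-trips", {
  ref <- refToy(n = 40)
  path <- tempfile(fileext = ".tsv")
  writeReference(ref, path)
  back <- readReference(path)
  expect_equal(refPoints(back)$iHSL, refPoints(ref)$iHSL)
  expect_identical(refPoints(back)$label, refPoints(ref)$label)
  expect_identical(back@provenance$model, "toy")
})
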