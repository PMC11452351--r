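# Brute-force oracles, written independently of the production C++ path:
# EHH by direct string partitioning, iHH by explicit trapezoid sums,
# shared-stretch lengths by pairwise scanning.

oracleEhh <- function(a, rows, core, marker) {
  cols <- seq(min(core, marker), max(core, marker))
  key <- apply(a[rows, cols, drop = FALSE], 1, paste, collapse = "")
  nh <- table(key)
  k <- length(rows)
  sum(nh * (nh - 1)) / (k * (k - 1))
}

# production stopping rules: L markers per side, window edge, EHH below
# cutoff (final trapezoid included)
oracleIhh <- function(a, gpos, rows, core, L = 400, cutoff = 0.05) {
  m <- ncol(a)
  total <- 0
  for (dir in c(1, -1)) {
    prev <- 1
    steps <- 0
    i <- core + dir
    while (i >= 1 && i <= m && steps < L) {
      cur <- oracleEhh(a, rows, core, i)
      total <- total + 0.5 * (prev + cur) * abs(gpos[i] - gpos[i - dir])
      prev <- cur
      steps <- steps + 1
      if (cur < cutoff || cur <= 0) break
      i <- i + dir
    }
  }
  total
}

# the full class-level definition: mean over focals of the cluster iHH,
# clusters re-derived by explicit Hamming sorting
oracleIhhl <- function(a, gpos, site, allele, r, L = 400, cutoff = 0.05,
                       sFloor = 8) {
  rows <- which(a[, site] == allele)
  nc <- length(rows)
  s <- min(max(ceiling(r * nc), sFloor), nc)
  lo <- max(1, site - L); hi <- min(ncol(a), site + L)
  if (s >= nc) return(oracleIhh(a, gpos, rows, site, L, cutoff))
  vals <- vapply(rows, function(f) {
    d <- vapply(rows, function(j)
      sum(a[f, lo:hi] != a[j, lo:hi]), numeric(1))
    others <- setdiff(seq_len(nc), match(f, rows))
    ord <- others[order(d[others], rows[others])]
    mem <- c(f, rows[ord[seq_len(s)]])
    oracleIhh(a, gpos, mem, site, L, cutoff)
  }, numeric(1))
  mean(vals)
}

# mean pairwise shared-stretch length in SNPs (core included), capped
# per side
oracleNslMeanL <- function(a, rows, core, cap = 500) {
  m <- ncol(a)
  pairs <- utils::combn(rows, 2)
  L <- apply(pairs, 2, function(pr) {
    right <- 0
    i <- core + 1
    while (i <= m && right < cap && a[pr[1], i] == a[pr[2], i]) {
      right <- right + 1; i <- i + 1
    }
    left <- 0
    i <- core - 1
    while (i >= 1 && left < cap && a[pr[1], i] == a[pr[2], i]) {
      left <- left + 1; i <- i - 1
    }
    1 + left + right
  })
  mean(L)
}

# random fixture with block-correlated columns (crude LD) so EHH decays
# gradually rather than instantly
randomHm <- function(n, m, seed, blocks = 4) {
  set.seed(seed)
  anc <- matrix(rbinom(blocks * m, 1, 0.4), blocks, m)
  who <- sample.int(blocks, n, replace = TRUE)
  a <- anc[who, , drop = FALSE]
  flip <- matrix(rbinom(n * m, 1, 0.06), n, m)
  a <- (a + flip) %% 2
  storage.mode(a) <- "integer"
  bad <- colSums(a) %in% c(0L, n)
  a[1, bad] <- 1L - a[1, bad]
  HaplotypeMatrix(a, physPos = seq_len(m) * 100,
                  genPos = cumsum(runif(m, 0.001, 0.003)))
}

# two-subfamily toy: identical within subfamilies, divergent between;
# all carry the derived core allele, flanked by an equally sized
# ancestral class
subfamilyToy <- function() {
  set.seed(42)
  core <- 11L
  m <- 21L
  famA <- rep(c(1L, 0L), length.out = m)
  famB <- rep(c(0L, 1L), length.out = m)
  anc1 <- rbinom(m, 1, 0.5)
  a <- rbind(
    matrix(rep(famA, 3), 3, byrow = TRUE),
    matrix(rep(famB, 3), 3, byrow = TRUE),
    matrix(rep(anc1, 2), 2, byrow = TRUE),
    matrix(rbinom(4 * m, 1, 0.5), 4))
  a[1:6, core] <- 1L
  a[7:12, core] <- 0L
  storage.mode(a) <- "integer"
  HaplotypeMatrix(a, physPos = seq_len(m) * 1000,
                  genPos = seq_len(m) * 0.01)
}
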