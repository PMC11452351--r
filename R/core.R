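## Haplotype-cluster sweep statistics.
##
## For a core site x0 with derived/ancestral classes H1/H0, each focal
## haplotype gets a local cluster (itself plus its s nearest class
## neighbours by Hamming distance over a window of L SNPs per side,
## s = min(max(ceil(r*|Hc|), 8), |Hc|)).  EHH is integrated over genetic
## distance within each cluster (iHH), averaged over focals (iHHL), and
## the statistics are log-ratios:
##   uiHSL   = ln(iHHL1 / iHHL0)     sweep detection (hard and soft)
##   uRiHS_c = ln(iHHL_c / iHH_c)    softness of the sweeping class
## both z-standardized within derived-allele-frequency bins, and combined
## as RiHSL = iHSL^2 + RiHS^2 (~ chi-square_2 under neutrality).

#' One-percent critical values for the sweep statistics
#'
#' The one-tailed standard-normal 1% point used for iHSL/iHS/nSL power
#' (2.3263) and the upper-tail 1% point of the chi-square distribution
#' with 2 df used for RiHSL (9.2103).
#' @return named numeric vector with elements `iHSL` and `RiHSL`.
#' @examples round(sweepThresholds(), 4)
#' @export
sweepThresholds <- function() {
  c(iHSL = stats::qnorm(0.99), RiHSL = stats::qchisq(0.99, df = 2))
}

#' Local haplotype cluster around a core site
#'
#' The focal haplotype plus its `s` nearest neighbours among haplotypes
#' carrying the same core allele, by Hamming distance over the local
#' window (`L` SNPs per side of the core, edge-truncated).  The diameter
#' rule is `s = min(max(ceil(r * |Hc|), sFloor), |Hc|)`; when `s = |Hc|`
#' the cluster is the whole allele class.  Distance ties at the s-th
#' neighbour are broken by haplotype index, so the cluster is
#' deterministic.
#'
#' @param hm a [HaplotypeMatrix-class].
#' @param site core site index (1-based).
#' @param focal focal haplotype index (1-based).
#' @param r cluster-size fraction (default 0.1; \code{r = 1} gives the whole
#'   class, reducing iHSL to iHS).
#' @param L window half-length in SNPs.
#' @param sFloor lower bound on the cluster diameter.
#' @return list with `members` (haplotype indices, focal first), `s`,
#'   `focal`, and the core `allele`.
#' @export
localCluster <- function(hm, site, focal, r = 0.1, L = 400L, sFloor = 8L) {
  a <- alleles(hm)
  allele <- a[focal, site]
  rows <- which(a[, site] == allele)
  nc <- length(rows)
  if (nc < 2L) stop("allele class of the focal haplotype has fewer than 2 members")
  s <- min(max(ceiling(r * nc), sFloor), nc)
  if (s >= nc) {
    members <- c(focal, setdiff(rows, focal))
  } else {
    lo <- max(1L, site - L); hi <- min(ncol(a), site + L)
    d <- cpp_hamming(a, rows - 1L, lo - 1L, hi - 1L)
    f <- match(focal, rows)
    others <- setdiff(seq_len(nc), f)
    ord <- others[order(d[f, others], rows[others])]
    members <- c(focal, rows[ord[seq_len(s)]])
  }
  list(members = members, s = s, focal = focal, allele = allele)
}

#' EHH of a haplotype set at a marker
#'
#' Probability that two haplotypes drawn from `members` are identical
#' over the stretch from the core site to `marker` (both inclusive).
#'
#' @inheritParams localCluster
#' @param members haplotype indices (>= 2).
#' @param marker marker site index.
#' @return homozygosity in `[0, 1]`.
#' @export
ehhCluster <- function(hm, site, members, marker) {
  if (length(members) < 2L) stop("degenerate cluster: need >= 2 members")
  a <- alleles(hm)
  cols <- seq(min(site, marker), max(site, marker))
  key <- apply(a[members, cols, drop = FALSE], 1L, paste, collapse = "")
  nh <- table(key)
  sum(nh * (nh - 1)) / (length(members) * (length(members) - 1))
}

#' Integrated EHH (iHH) of a haplotype set
#'
#' Trapezoidal integral of the EHH curve over genetic distance, both
#' directions from the core.  Extension stops per side at `L` markers,
#' the chromosome end, or once EHH falls below `ehhCutoff` (the final
#' trapezoid is included).
#'
#' @inheritParams ehhCluster
#' @param ehhCutoff EHH truncation level (0 disables).
#' @return non-negative value in genetic-distance units (cM).
#' @export
ihhCluster <- function(hm, site, members, L = 400L, ehhCutoff = 0.05) {
  if (length(members) < 2L) stop("degenerate cluster: need >= 2 members")
  if (any(members < 1L | members > nHap(hm)))
    stop("cluster member index out of range")
  cpp_ihh_cluster(alleles(hm), genPos(hm), members - 1L, site - 1L,
                  as.integer(L), ehhCutoff)
}

#' Class-wise iHHL and iHH at a core site
#'
#' `iHHL_c` is the mean of cluster iHH over focal haplotypes of allele
#' class `c`; `iHH_c` is the iHH of the whole class (the \code{r = 1} special
#' case, identical for every focal choice).
#'
#' @inheritParams localCluster
#' @param allele core allele class, 0 or 1.
#' @param ehhCutoff EHH truncation level.
#' @return list with `iHHL`, `iHH`, `s` and the class size `n`.
#' @export
ihhlAllele <- function(hm, site, allele, r = 0.1, L = 400L,
                       ehhCutoff = 0.05, sFloor = 8L) {
  rows <- which(alleles(hm)[, site] == allele)
  if (length(rows) < 2L) stop("allele class has fewer than 2 members: unscorable")
  ihh <- ihhCluster(hm, site, rows, L, ehhCutoff)
  s <- min(max(ceiling(r * length(rows)), sFloor), length(rows))
  if (s >= length(rows)) {
    ihhl <- ihh
  } else {
    vals <- vapply(rows, function(j) {
      cl <- localCluster(hm, site, j, r, L, sFloor)
      ihhCluster(hm, site, cl$members, L, ehhCutoff)
    }, numeric(1))
    ihhl <- mean(vals)
  }
  list(iHHL = ihhl, iHH = ihh, s = s, n = length(rows))
}

#' Unstandardized log-ratio statistics
#'
#' `uiHSL = ln(iHHL1 / iHHL0)`; `uRiHS_c = ln(iHHL_c / iHH_c)`.  Both
#' require strictly positive inputs; otherwise the site is unscorable.
#' @param iHHL1,iHHL0 class-wise local-cluster integrals.
#' @return the log-ratio.
#' @export
uiHSL <- function(iHHL1, iHHL0) {
  if (!all(is.finite(c(iHHL1, iHHL0))) || iHHL1 <= 0 || iHHL0 <= 0)
    stop("undefined log-ratio: iHHL must be positive")
  log(iHHL1 / iHHL0)
}

#' @rdname uiHSL
#' @param iHHLc,iHHc local-cluster and whole-class integrals for one class.
#' @export
uRiHS <- function(iHHLc, iHHc) {
  if (!all(is.finite(c(iHHLc, iHHc))) || iHHLc <= 0 || iHHc <= 0)
    stop("undefined log-ratio: iHH must be positive")
  log(iHHLc / iHHc)
}

#' Scan sites with the haplotype-cluster statistics
#'
#' Computes the unstandardized statistics at every scorable site (derived
#' allele frequency within `[minFreq, 1 - minFreq]`, both allele classes
#' of size >= `minClass`).  Standardization is a separate step
#' ([fitNormalization()] + [standardizeScores()]), or set
#' `standardize = TRUE` to fit the frequency-bin model on this scan
#' itself (the genome-scan usage).
#'
#' @inheritParams localCluster
#' @param sites site indices to score; default all scorable sites.
#' @param minFreq scorability bound on derived allele frequency.
#' @param ehhCutoff EHH truncation level for the integrals.
#' @param minClass minimum allele-class size.
#' @param standardize fit and apply frequency-bin standardization using
#'   this scan's own sites.
#' @param neighborPool where a focal haplotype's nearest neighbours are
#'   drawn from.  `"class"` (default) restricts candidates to the
#'   focal's own allele class, the choice under which \code{r = 1} reduces
#'   exactly to iHS; `"all"` ranks every other haplotype by local
#'   Hamming distance, with the identity stretch starting at the core
#'   site itself so neighbours carrying the opposite core allele break
#'   homozygosity immediately.  The two pools give nearly identical
#'   scores in practice because nearest neighbours over the local
#'   window almost always share the core allele.
#' @param ... passed to [fitNormalization()] when `standardize = TRUE`.
#' @return a [ScoreTable-class].  Unscorable sites keep `NA` statistics
#'   with a reason code in `status`; edge-truncated windows are flagged.
#' @export
scoreSites <- function(hm, sites = NULL, r = 0.1, L = 400L,
                       minFreq = 0.05, ehhCutoff = 0.05, minClass = 2L,
                       sFloor = 8L, standardize = FALSE,
                       neighborPool = c("class", "all"), ...) {
  neighborPool <- match.arg(neighborPool)
  a <- alleles(hm)
  freq <- colMeans(a)
  if (is.null(sites))
    sites <- which(freq >= minFreq & freq <= 1 - minFreq)
  else {
    sites <- as.integer(sites)
    drop <- freq[sites] < minFreq | freq[sites] > 1 - minFreq
    if (any(drop)) sites <- sites[!drop]
  }
  if (!length(sites)) stop("no scorable site (frequency filter)")
  raw <- cpp_score_sites(a, genPos(hm), sites - 1L, r, as.integer(L),
                         ehhCutoff, as.integer(minClass), as.integer(sFloor),
                         neighborPool == "all")
  ok <- raw$status == "ok"
  fr <- data.frame(
    site = sites,
    pos_bp = physPos(hm)[sites],
    pos_cM = genPos(hm)[sites],
    freq = raw$freq1,
    uiHSL = ifelse(ok, log(raw$iHHL1 / raw$iHHL0), NA_real_),
    uRiHS1 = ifelse(ok, log(raw$iHHL1 / raw$iHH1), NA_real_),
    uRiHS0 = ifelse(ok, log(raw$iHHL0 / raw$iHH0), NA_real_),
    iHHL1 = raw$iHHL1, iHHL0 = raw$iHHL0,
    iHH1 = raw$iHH1, iHH0 = raw$iHH0,
    iHSL = NA_real_, RiHS = NA_real_, RiHSL = NA_real_,
    p_ihsl = NA_real_, p_rihsl = NA_real_,
    label = NA_character_,
    edge = raw$edge, status = raw$status,
    stringsAsFactors = FALSE
  )
  st <- new("ScoreTable", frame = fr, statistic = "iHSL",
            params = list(r = r, L = L, minFreq = minFreq,
                          ehhCutoff = ehhCutoff, sFloor = sFloor,
                          neighborPool = neighborPool))
  if (standardize) {
    model <- fitNormalization(st, ...)
    st <- standardizeScores(st, model)
  }
  st
}

## bin index of frequencies given edges (values on an edge go left,
## matching cut(..., right = TRUE) with the lowest edge inclusive)
.binIndex <- function(freq, edges) {
  idx <- findInterval(freq, edges, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[freq <= edges[1]] <- 1L
  idx[idx > length(edges) - 1L] <- length(edges) - 1L
  idx
}

#' Fit the frequency-bin standardization model
#'
#' Equal-width bins on derived allele frequency over (0, 1); bins with
#' fewer than `minBinCount` scorable sites are merged with their nearest
#' (adjacent) neighbour until every group is filled.  Means and sample
#' standard deviations (n - 1 denominator) are computed per group for
#' every unstandardized statistic present (`uiHSL`, `uRiHS1`, `uRiHS0`).
#'
#' @param x a [ScoreTable-class], a list of them (pooled), or a
#'   data.frame with a `freq` column and unstandardized columns.
#' @param nBins number of equal-width bins.
#' @param minBinCount minimum scorable sites per bin before merging.
#' @return a [NormalizationModel-class].
#' @export
fitNormalization <- function(x, nBins = 50L, minBinCount = 20L) {
  fr <- .normFrame(x)
  statCols <- intersect(c("uiHSL", "uRiHS1", "uRiHS0"), names(fr))
  statCols <- statCols[vapply(statCols, function(cn)
    any(is.finite(fr[[cn]])), logical(1))]
  if (!length(statCols)) stop("no unstandardized statistic column found")
  keep <- is.finite(fr$freq) & is.finite(fr[[statCols[1]]])
  fr <- fr[keep, , drop = FALSE]
  if (!nrow(fr)) stop("no scorable sites to fit the normalization")
  edges <- seq(0, 1, length.out = nBins + 1L)
  bin <- .binIndex(fr$freq, edges)
  cnt <- tabulate(bin, nbins = nBins)
  ## iteratively merge the smallest underfilled group into its nearest
  ## non-empty neighbour until every occupied group is filled
  group <- seq_len(nBins)
  repeat {
    gs <- tapply(cnt, group, sum)
    ids <- as.integer(names(gs)); gs <- as.vector(gs)
    nonempty <- ids[gs > 0]
    under <- ids[gs > 0 & gs < minBinCount]
    if (!length(under) || length(nonempty) <= 1L) break
    b <- under[which.min(gs[match(under, ids)])]
    cand <- setdiff(nonempty, b)
    tgt <- cand[which.min(abs(cand - b))]
    group[group == b] <- tgt
  }
  if (sum(cnt) < minBinCount)
    stop("too few scorable sites for any frequency bin")
  stats <- lapply(statCols, function(colnm) {
    v <- fr[[colnm]]
    g <- group[bin]
    fin <- is.finite(v)
    agg <- do.call(rbind, lapply(split(v[fin], g[fin]), function(z)
      c(mean = mean(z), sd = stats::sd(z), n = length(z))))
    out <- data.frame(group = as.integer(rownames(agg)), mean = agg[, "mean"],
                      sd = agg[, "sd"], n = as.integer(agg[, "n"]))
    if (any(!is.finite(out$sd) | out$sd <= 0))
      stop(sprintf("degenerate (constant) frequency bin for %s", colnm))
    out
  })
  names(stats) <- statCols
  new("NormalizationModel", edges = edges, group = as.integer(group),
      stats = stats)
}

.normFrame <- function(x) {
  if (is(x, "ScoreTable")) return(x@frame)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    return(do.call(rbind, lapply(x, function(el) {
      fr <- .normFrame(el)
      fr[intersect(c("freq", "uiHSL", "uRiHS1", "uRiHS0"), names(fr))]
    })))
  }
  stop("cannot interpret input as score frame(s)")
}

.standardizeVec <- function(v, freq, model, statName) {
  s <- model@stats[[statName]]
  if (is.null(s)) return(rep(NA_real_, length(v)))
  bin <- .binIndex(freq, model@edges)
  g <- model@group[bin]
  i <- match(g, s$group)
  ## frequencies falling in a group absent from the model (possible when
  ## applying to new data): use the nearest fitted group
  if (anyNA(i)) {
    miss <- which(is.na(i))
    i[miss] <- vapply(g[miss], function(gg)
      which.min(abs(s$group - gg)), integer(1))
  }
  (v - s$mean[i]) / s$sd[i]
}

#' Standardize a ScoreTable with a fitted model
#'
#' z-standardizes `uiHSL` into `iHSL` and `uRiHS1`/`uRiHS0` into the
#' class-resolved `RiHS` (class 1 when `iHSL >= 0`, class 0 otherwise),
#' forms the composite `RiHSL = iHSL^2 + RiHS^2`, and attaches p-values:
#' `p_ihsl = 2 * pnorm(-|iHSL|)` (two-sided normal) and
#' `p_rihsl = exp(-RiHSL / 2)` (upper-tail chi-square with 2 df).
#'
#' @param st a [ScoreTable-class] with unstandardized columns.
#' @param model a [NormalizationModel-class].
#' @return the `ScoreTable` with standardized columns filled in.
#' @export
standardizeScores <- function(st, model) {
  fr <- st@frame
  fr$iHSL <- .standardizeVec(fr$uiHSL, fr$freq, model, "uiHSL")
  if (all(c("uRiHS1", "uRiHS0") %in% names(fr))) {
    z1 <- .standardizeVec(fr$uRiHS1, fr$freq, model, "uRiHS1")
    z0 <- .standardizeVec(fr$uRiHS0, fr$freq, model, "uRiHS0")
    fr$RiHS <- ifelse(fr$iHSL >= 0, z1, z0)
    fr$RiHSL <- fr$iHSL^2 + fr$RiHS^2
    fr$p_rihsl <- pmin(exp(-fr$RiHSL / 2), 1)
  }
  fr$p_ihsl <- pmin(2 * stats::pnorm(-abs(fr$iHSL)), 1)
  initialize(st, frame = fr)
}
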