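## Comparator statistics: iHS (the r = 1 special case of the cluster
## scan), nSL (SNP-count integration, no genetic map needed), and the
## window haplotype-homozygosity statistics H1/H12/H2H1.

#' iHS scan
#'
#' iHS is the \code{r = 1} special case of the cluster scan: every local
#' cluster is the whole allele class, so `iHHL_c = iHH_c` and the
#' log-ratio is the classical whole-class EHH integral ratio.  The code
#' path is shared with [scoreSites()].
#'
#' @inheritParams scoreSites
#' @return a [ScoreTable-class] with `statistic == "iHS"`.
#' @export
ihsScan <- function(hm, sites = NULL, L = 400L, minFreq = 0.05,
                    ehhCutoff = 0.05, minClass = 2L, standardize = FALSE,
                    ...) {
  st <- scoreSites(hm, sites = sites, r = 1, L = L, minFreq = minFreq,
                   ehhCutoff = ehhCutoff, minClass = minClass,
                   neighborPool = "class")
  ## the cluster-to-class ratio is identically zero at r = 1: mark the
  ## RiHS family undefined rather than standardizing a constant
  fr <- st@frame
  fr$uRiHS1 <- fr$uRiHS0 <- NA_real_
  fr$RiHS <- fr$RiHSL <- fr$p_rihsl <- NA_real_
  st <- initialize(st, frame = fr)
  st@statistic <- "iHS"
  if (standardize) {
    model <- fitNormalization(st, ...)
    st <- standardizeScores(st, model)
  }
  st
}

#' nSL scan
#'
#' iHS-style log-ratio where the integration measure is SNP count rather
#' than genetic distance: for each allele class the mean over haplotype
#' pairs of the number of consecutive markers (core included, capped at
#' `cap` markers per side) over which the pair is identical.  No genetic
#' map is required.
#'
#' @inheritParams scoreSites
#' @param cap maximum extension in SNPs per side.
#' @return a [ScoreTable-class] with `statistic == "nSL"`; the
#'   unstandardized log-ratio lives in `uiHSL` and its z-score in `iHSL`
#'   (column names are shared across scans, the `statistic` slot
#'   disambiguates).
#' @export
nslScan <- function(hm, sites = NULL, cap = 500L, minFreq = 0.05,
                    minClass = 2L, standardize = FALSE, ...) {
  a <- alleles(hm)
  freq <- colMeans(a)
  if (is.null(sites))
    sites <- which(freq >= minFreq & freq <= 1 - minFreq)
  else {
    sites <- as.integer(sites)
    sites <- sites[freq[sites] >= minFreq & freq[sites] <= 1 - minFreq]
  }
  if (!length(sites)) stop("no scorable site (frequency filter)")
  raw <- cpp_nsl_sites(a, sites - 1L, as.integer(cap), as.integer(minClass))
  ok <- raw$status == "ok" & is.finite(raw$SL1) & is.finite(raw$SL0) &
    raw$SL1 > 0 & raw$SL0 > 0
  fr <- data.frame(
    site = sites,
    pos_bp = physPos(hm)[sites],
    pos_cM = genPos(hm)[sites],
    freq = raw$freq1,
    uiHSL = ifelse(ok, log(raw$SL1 / raw$SL0), NA_real_),
    SL1 = raw$SL1, SL0 = raw$SL0,
    iHSL = NA_real_, p_ihsl = NA_real_,
    label = NA_character_,
    status = ifelse(ok, "ok", as.character(raw$status)),
    stringsAsFactors = FALSE
  )
  st <- new("ScoreTable", frame = fr, statistic = "nSL",
            params = list(cap = cap, minFreq = minFreq))
  if (standardize) {
    model <- fitNormalization(st, ...)
    st <- standardizeScores(st, model)
  }
  st
}

#' Window haplotype-homozygosity statistics H1, H12, H2/H1
#'
#' Haplotype frequencies `p1 >= p2 >= ...` are taken over full window
#' haplotypes in a window of `w` SNPs centered on `site`
#' (edge-truncated, flagged): `H1 = sum(p_i^2)`,
#' `H12 = (p1 + p2)^2 + sum_{i>=3} p_i^2`, `H2/H1 = (H1 - p1^2) / H1`.
#'
#' @inheritParams scoreSites
#' @param site center site index.
#' @param w window size in SNPs (odd).
#' @return named list `H1`, `H12`, `H2H1`, plus `truncated`.
#' @export
hStats <- function(hm, site, w = 1001L) {
  if (w %% 2L != 1L || w < 1L) stop("window size must be odd and positive")
  a <- alleles(hm)
  half <- (w - 1L) %/% 2L
  lo <- max(1L, site - half); hi <- min(ncol(a), site + half)
  key <- apply(a[, lo:hi, drop = FALSE], 1L, paste, collapse = "")
  p <- sort(as.vector(table(key)) / nrow(a), decreasing = TRUE)
  H1 <- sum(p^2)
  H12 <- if (length(p) >= 2L) (p[1] + p[2])^2 + sum(p[-(1:2)]^2) else H1
  list(H1 = H1, H12 = H12, H2H1 = (H1 - p[1]^2) / H1,
       truncated = (site - half < 1L) || (site + half > ncol(a)))
}

#' H12 across candidate window sizes
#'
#' Computes H12 at each window size centered on `site`; sizes larger
#' than the number of sites are skipped with a warning.  The power-based
#' selection of the best size against matched neutral simulations is
#' [h12BestWindow()].
#'
#' @inheritParams hStats
#' @param sizes candidate window sizes (SNPs, odd).
#' @return named numeric vector of H12 values (names = sizes).
#' @export
h12WindowSweep <- function(hm, site,
                           sizes = c(21L, 51L, 101L, 201L, 401L, 1001L,
                                     2001L)) {
  keep <- sizes <= nSites(hm)
  if (any(!keep))
    warning(sprintf("window size(s) %s exceed the number of sites; skipped",
                    paste(sizes[!keep], collapse = ", ")))
  sizes <- sizes[keep]
  vapply(sizes, function(w) hStats(hm, site, w)$H12,
         numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(as.character(sizes))
}

#' Best H12 window by power at 1% FPR
#'
#' Given per-replicate H12 values for sweep and matched neutral
#' simulations at each candidate size, the significance threshold per
#' size is the empirical 99th percentile of the neutral scores, and the
#' best size maximizes the proportion of sweep scores exceeding it.
#'
#' @param sweepH12 matrix, replicates x sizes (column names = sizes).
#' @param neutralH12 matrix, neutral replicates x the same sizes.
#' @return data.frame with `size`, `threshold`, `power`, and attribute
#'   `best` (the winning size).
#' @export
h12BestWindow <- function(sweepH12, neutralH12) {
  sweepH12 <- as.matrix(sweepH12); neutralH12 <- as.matrix(neutralH12)
  if (!identical(colnames(sweepH12), colnames(neutralH12)))
    stop("sweep and neutral H12 matrices must share window sizes")
  out <- data.frame(
    size = as.integer(colnames(sweepH12)),
    threshold = apply(neutralH12, 2L, stats::quantile, probs = 0.99,
                      names = FALSE),
    power = NA_real_
  )
  out$power <- vapply(seq_len(ncol(sweepH12)), function(i)
    mean(sweepH12[, i] > out$threshold[i]), numeric(1))
  attr(out, "best") <- out$size[which.max(out$power)]
  out
}
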