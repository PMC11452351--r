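## Sweep-type classification against a simulated reference distribution,
## plus the soft-shoulder core-SNP/region correction.

#' Construct a reference distribution
#'
#' @param points data.frame with columns `iHSL`, `RiHS` (both already
#'   z-standardized) and `label` in neutral/hard/soft.
#' @param provenance demographic model and parameter ranges.
#' @return a [ReferenceDistribution-class].
#' @export
ReferenceDistribution <- function(points, provenance = list()) {
  points$label <- as.character(points$label)
  new("ReferenceDistribution",
      points = points[c("iHSL", "RiHS", "label")], provenance = provenance)
}

#' Classify a site by k nearest reference points
#'
#' Euclidean distance in the standardized (iHSL, RiHS) plane (both
#' coordinates are z-scores, so no further scaling); the call is the
#' modal label among the `k` nearest reference points, with majority
#' ties resolved by the label of the single nearest point.  Neighbour
#' selection is deterministic: ties in distance are broken by reference
#' row order.
#'
#' @param point numeric length-2 `(iHSL, RiHS)` or a two-column matrix
#'   of query points.
#' @param ref a [ReferenceDistribution-class] with at least `k` points.
#' @param k neighbour count.
#' @return character label(s), one per query.
#' @export
classifySite <- function(point, ref, k = 200L) {
  p <- refPoints(ref)
  if (nrow(p) < k) stop("reference has fewer than k points")
  q <- if (is.matrix(point) || is.data.frame(point)) {
    as.matrix(point)[, 1:2, drop = FALSE]
  } else matrix(point[1:2], ncol = 2L)
  storage.mode(q) <- "double"
  rx <- p$iHSL; ry <- p$RiHS; lab <- p$label
  vapply(seq_len(nrow(q)), function(i) {
    d2 <- (rx - q[i, 1])^2 + (ry - q[i, 2])^2
    nn <- order(d2)[seq_len(k)]   # order() is stable: ties by row order
    tab <- table(lab[nn])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else lab[nn[1]]
  }, character(1))
}

#' Attach sweep-type labels to a score table
#'
#' Classifies every row with finite standardized scores (optionally only
#' those significant at `pCut` on `pColumn`); other rows keep the label
#' `"unscored"`.
#'
#' @param st a standardized [ScoreTable-class].
#' @param ref a [ReferenceDistribution-class].
#' @param k neighbour count for [classifySite()].
#' @param pCut optional significance cut; `NULL` classifies all rows.
#' @param pColumn p-value column used for the cut.
#' @return the `ScoreTable` with the `label` column filled.
#' @export
classifyScores <- function(st, ref, k = 200L, pCut = NULL,
                           pColumn = "p_rihsl") {
  fr <- st@frame
  sel <- is.finite(fr$iHSL) & is.finite(fr$RiHS)
  if (!is.null(pCut)) sel <- sel & !is.na(fr[[pColumn]]) &
      fr[[pColumn]] < pCut
  fr$label <- "unscored"
  if (any(sel))
    fr$label[sel] <- classifySite(cbind(fr$iHSL[sel], fr$RiHS[sel]), ref, k)
  initialize(st, frame = fr)
}

#' Identify significant core SNPs
#'
#' A SNP is a core SNP iff the proportion of significant SNPs
#' (p < `sigP` on `pColumn`) among its nearest `window` scored SNPs on
#' each side (edge-truncated; the SNP itself excluded) is at least
#' `minProp`.  Significance is one-sided by default
#' (`positiveOnly = TRUE`): only sites with standardized iHSL > 0 count,
#' matching the derived-allele orientation of the detection test --
#' flanking sites of a sweep often carry extreme *negative* iHSL
#' (the swept background is their ancestral class) and are not
#' sweep-typing candidates.
#'
#' @inheritParams classifyScores
#' @param sigP significance threshold (background SNPs have p >= sigP).
#' @param window neighbourhood half-width in scored SNPs.
#' @param minProp minimum significant proportion in the neighbourhood.
#' @param positiveOnly restrict significance to iHSL > 0.
#' @return integer vector of core row indices into `scores(st)`.
#' @export
findCoreSnps <- function(st, sigP = 0.001, window = 50L, minProp = 0.2,
                         pColumn = "p_rihsl", positiveOnly = TRUE) {
  p <- st@frame[[pColumn]]
  if (is.null(p)) stop(sprintf("no column '%s' in the score table", pColumn))
  sig <- !is.na(p) & p < sigP
  if (positiveOnly && !is.null(st@frame$iHSL))
    sig <- sig & !is.na(st@frame$iHSL) & st@frame$iHSL > 0
  n <- length(sig)
  if (!any(sig)) return(integer())
  cs <- cumsum(sig)
  prop <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - window); hi <- min(n, i + window)
    cnt <- cs[hi] - (if (lo > 1L) cs[lo - 1L] else 0L) - sig[i]
    denom <- hi - lo  # neighbourhood size excluding self
    if (denom == 0L) 0 else cnt / denom
  }, numeric(1))
  which(prop >= minProp)
}

#' Call sweep regions and correct soft shoulders
#'
#' Maximal runs of core SNPs (gaps of up to `maxGap` non-core scored
#' SNPs allowed) become regions.  Each region takes the sweep type of
#' its leading SNP (smallest p-value; ties by order), and the labels of
#' all significant member SNPs are overwritten by the region label --
#' the soft-shoulder correction, under which soft-labeled flanks of a
#' hard sweep are revised to hard.
#'
#' @inheritParams classifyScores
#' @inheritParams findCoreSnps
#' @param coreSnps core row indices from [findCoreSnps()].
#' @param maxGap largest run gap (in scored SNPs) bridged within a region.
#' @param sigP significance threshold used when revising member labels.
#' @return list with `regions` (a [GenomicRanges::GRanges] with label,
#'   leading-SNP row/position/p-value) and `scores` (the revised
#'   `ScoreTable`).
#' @export
callRegions <- function(st, coreSnps, ref, maxGap = 10L, k = 200L,
                        sigP = 0.001, pColumn = "p_rihsl",
                        positiveOnly = TRUE) {
  fr <- st@frame
  empty <- GenomicRanges::GRanges()
  if (!length(coreSnps))
    return(list(regions = empty, scores = st))
  coreSnps <- sort(unique(as.integer(coreSnps)))
  runId <- cumsum(c(1L, diff(coreSnps) > maxGap + 1L))
  p <- fr[[pColumn]]
  if (positiveOnly && !is.null(fr$iHSL))
    p[is.na(fr$iHSL) | fr$iHSL <= 0] <- 2   # sweep-typing candidates only
  regs <- lapply(unname(split(coreSnps, runId)), function(idx) {
    span <- seq(min(idx), max(idx))
    lead <- span[which.min(p[span])]
    lab <- classifySite(c(fr$iHSL[lead], fr$RiHS[lead]), ref, k)
    list(from = min(idx), to = max(idx), lead = lead, label = lab)
  })
  chrom <- if (!is.null(attr(st, "chrom"))) attr(st, "chrom") else "chr1"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(
      start = vapply(regs, function(z) fr$pos_bp[z$from], numeric(1)),
      end = vapply(regs, function(z) fr$pos_bp[z$to], numeric(1))),
    label = vapply(regs, function(z) z$label, character(1)),
    leadRow = vapply(regs, function(z) z$lead, integer(1)),
    leadPos = vapply(regs, function(z) fr$pos_bp[z$lead], numeric(1)),
    leadP = vapply(regs, function(z) p[z$lead], numeric(1)),
    fromRow = vapply(regs, function(z) z$from, integer(1)),
    toRow = vapply(regs, function(z) z$to, integer(1)))
  ## revise member labels: significant SNPs inside a region inherit the
  ## region's type
  for (z in regs) {
    span <- seq(z$from, z$to)
    memb <- span[!is.na(p[span]) & p[span] < sigP]
    fr$label[memb] <- z$label
  }
  list(regions = gr, scores = initialize(st, frame = fr))
}

#' Write / read a reference distribution as TSV
#'
#' Columns `iHSL`, `RiHS`, `label` plus provenance key=value columns.
#' @param ref a [ReferenceDistribution-class].
#' @param path file path.
#' @return `readReference` returns a [ReferenceDistribution-class].
#' @export
writeReference <- function(ref, path) {
  p <- refPoints(ref)
  prov <- ref@provenance
  scal <- prov[vapply(prov, function(v)
    is.atomic(v) && length(v) == 1L, logical(1))]
  if (length(scal)) for (nm in names(scal)) p[[paste0("prov_", nm)]] <- scal[[nm]]
  utils::write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReference
#' @export
readReference <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  provCols <- grep("^prov_", names(p), value = TRUE)
  prov <- lapply(provCols, function(cn) p[[cn]][1])
  names(prov) <- sub("^prov_", "", provCols)
  ReferenceDistribution(p[c("iHSL", "RiHS", "label")], provenance = prov)
}
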