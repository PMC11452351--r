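#' Build a HaplotypeMatrix
#'
#' @param alleles 0/1 matrix, haplotypes in rows, sites in columns.
#' @param physPos physical positions in bp, strictly increasing.
#' @param genPos genetic positions in cM.  If `NULL`, a constant-rate map
#'   of `cmPerMb` cM/Mb is applied (recorded in the metadata).
#' @param sampleLabels optional haplotype identifiers.
#' @param chrom chromosome name (used in interval output).
#' @param cmPerMb constant-rate fallback, cM per Mb (1.25 corresponds to
#'   a uniform recombination rate of 1.25e-8 per bp per generation).
#' @param metadata free-form provenance list.
#' @return a [HaplotypeMatrix-class] object.
#' @examples
#' hm <- HaplotypeMatrix(matrix(c(0, 1, 1, 0, 0, 1), 2), physPos = c(10, 20, 30))
#' nHap(hm); nSites(hm)
#' @export
HaplotypeMatrix <- function(alleles, physPos, genPos = NULL,
                            sampleLabels = character(), chrom = "chr1",
                            cmPerMb = 1.25, metadata = list()) {
  storage.mode(alleles) <- "integer"
  if (is.null(genPos)) {
    genPos <- physPos * cmPerMb * 1e-6
    metadata$genPosSource <- sprintf("constant %.4g cM/Mb", cmPerMb)
  }
  new("HaplotypeMatrix", alleles = alleles, physPos = as.numeric(physPos),
      genPos = as.numeric(genPos), sampleLabels = sampleLabels,
      chrom = chrom, metadata = metadata)
}

#' @rdname HaplotypeMatrix
#' @param x a `HaplotypeMatrix`.
#' @param sites site indices (default all sites).
#' @param value replacement genetic positions (cM).
#' @aliases alleles physPos genPos genPos<- nHap nSites derivedFreq
#' @export
setMethod("alleles", "HaplotypeMatrix", function(x) x@alleles)

#' @rdname HaplotypeMatrix
#' @export
setMethod("physPos", "HaplotypeMatrix", function(x) x@physPos)

#' @rdname HaplotypeMatrix
#' @export
setMethod("genPos", "HaplotypeMatrix", function(x) x@genPos)

#' @rdname HaplotypeMatrix
#' @export
setReplaceMethod("genPos", "HaplotypeMatrix", function(x, value) {
  x@genPos <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname HaplotypeMatrix
#' @export
setMethod("nHap", "HaplotypeMatrix", function(x) nrow(x@alleles))

#' @rdname HaplotypeMatrix
#' @export
setMethod("nSites", "HaplotypeMatrix", function(x) ncol(x@alleles))

#' @rdname HaplotypeMatrix
#' @export
setMethod("derivedFreq", "HaplotypeMatrix", function(x, sites) {
  if (missing(sites)) sites <- seq_len(ncol(x@alleles))
  colMeans(x@alleles[, sites, drop = FALSE])
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cat(sprintf("HaplotypeMatrix: %d haplotypes x %d sites (%s)\n",
              nrow(object@alleles), ncol(object@alleles), object@chrom))
  rng <- range(object@physPos)
  cat(sprintf("  positions %.0f-%.0f bp, %.4f-%.4f cM\n",
              rng[1], rng[2], min(object@genPos), max(object@genPos)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Polarity flip of a HaplotypeMatrix at given sites
#'
#' Swaps the ancestral/derived coding (0 <-> 1) at the given sites;
#' useful for polarization checks.
#' @param x a `HaplotypeMatrix`.
#' @param sites sites to flip (default all).
#' @return the recoded `HaplotypeMatrix`.
#' @export
flipPolarity <- function(x, sites = seq_len(nSites(x))) {
  a <- x@alleles
  a[, sites] <- 1L - a[, sites]
  initialize(x, alleles = a)
}

#' @rdname ScoreTable
#' @param x a `ScoreTable`.
#' @aliases scores statistic
#' @export
setMethod("scores", "ScoreTable", function(x) x@frame)

#' @rdname ScoreTable
#' @export
setMethod("statistic", "ScoreTable", function(x) x@statistic)

setMethod("show", "ScoreTable", function(object) {
  fr <- object@frame
  cat(sprintf("ScoreTable (%s): %d sites\n", object@statistic, nrow(fr)))
  if ("iHSL" %in% names(fr) && any(is.finite(fr$iHSL)))
    cat(sprintf("  standardized range: [%.3f, %.3f]\n",
                min(fr$iHSL, na.rm = TRUE), max(fr$iHSL, na.rm = TRUE)))
  if ("status" %in% names(fr))
    cat("  status:", paste(sprintf("%s=%d", names(table(fr$status)),
                                   table(fr$status)), collapse = " "), "\n")
})

setMethod("as.data.frame", "ScoreTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@frame)

#' @rdname ReferenceDistribution
#' @param x a `ReferenceDistribution`.
#' @aliases refPoints
#' @export
setMethod("refPoints", "ReferenceDistribution", function(x) x@points)

setMethod("show", "ReferenceDistribution", function(object) {
  tab <- table(object@points$label)
  cat("ReferenceDistribution:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (!is.null(object@provenance$model))
    cat("  model:", object@provenance$model, "\n")
})

setMethod("show", "SweepSimResult", function(object) {
  cat(sprintf(
    "SweepSimResult: %s sweep, sample freq %.3f, %d founder lineage(s)\n",
    if (!is.null(object@params$mode)) object@params$mode else "?",
    object@sampleFreq, object@founders))
  cat(sprintf("  %d haplotypes x %d sites, selected site %d\n",
              nHap(object@hm), nSites(object@hm), object@selectedSite))
})
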