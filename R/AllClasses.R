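#' @import methods
NULL

#' Phased, polarized haplotype matrix
#'
#' Container for `n` phased haplotypes typed at `m` biallelic sites, coded
#' 0 (ancestral) / 1 (derived), with per-site physical positions (bp) and
#' genetic positions (cM).  Missing genotypes are not supported: scoring
#' assumes a complete 0/1 matrix.
#'
#' @slot alleles integer matrix, haplotypes in rows, sites in columns.
#' @slot physPos numeric vector of physical positions (bp), strictly
#'   increasing.
#' @slot genPos numeric vector of genetic positions (cM), non-decreasing.
#' @slot sampleLabels character vector of haplotype identifiers.
#' @slot chrom single chromosome name used in interval output.
#' @slot metadata free-form provenance list (e.g. simulation parameters).
#' @aliases HaplotypeMatrix-class
#' @exportClass HaplotypeMatrix
setClass("HaplotypeMatrix",
  representation(
    alleles = "matrix",
    physPos = "numeric",
    genPos = "numeric",
    sampleLabels = "character",
    chrom = "character",
    metadata = "list"
  )
)

setValidity("HaplotypeMatrix", function(object) {
  a <- object@alleles
  msg <- character()
  if (nrow(a) < 2L) msg <- c(msg, "need at least 2 haplotypes")
  if (ncol(a) < 1L) msg <- c(msg, "need at least 1 site")
  if (anyNA(a)) msg <- c(msg, "missing genotypes are not supported")
  else if (!all(a == 0L | a == 1L)) msg <- c(msg, "alleles must be 0/1")
  if (length(object@physPos) != ncol(a))
    msg <- c(msg, "physPos length must equal the number of sites")
  else if (ncol(a) > 1L && any(diff(object@physPos) <= 0))
    msg <- c(msg, "physPos must be strictly increasing")
  if (length(object@genPos) != ncol(a))
    msg <- c(msg, "genPos length must equal the number of sites")
  else if (ncol(a) > 1L && any(diff(object@genPos) < 0))
    msg <- c(msg, "genPos must be non-decreasing")
  if (length(object@sampleLabels) &&
      length(object@sampleLabels) != nrow(a))
    msg <- c(msg, "sampleLabels length must equal the number of haplotypes")
  if (length(object@chrom) != 1L) msg <- c(msg, "chrom must be a single name")
  if (length(msg)) msg else TRUE
})

#' Demographic model specification
#'
#' Named preset or explicit parameters for the neutral coalescent
#' backend: constant size, exponential growth, bottlenecks, or the
#' three-population out-of-Africa model.
#'
#' @slot model backend model name ("equilibrium", "growth",
#'   "bottleneck", "ooa").
#' @slot params model parameters in natural units (sizes in diploids,
#'   times in generations, rates per generation).
#' @slot name preset label.
#' @aliases Demography-class
#' @exportClass Demography
setClass("Demography",
  representation(model = "character", params = "list", name = "character")
)

setValidity("Demography", function(object) {
  if (!object@model %in% c("equilibrium", "growth", "bottleneck", "ooa"))
    return("unknown demographic model")
  sz <- object@params[intersect(
    c("Ne", "ne_anc", "ne_now", "N_A", "N_AF", "N_B"),
    names(object@params))]
  if (length(sz) && any(unlist(sz) <= 0)) return("sizes must be positive")
  TRUE
})

#' Per-site sweep-statistic table
#'
#' One row per scored site with the unstandardized and standardized
#' statistics, p-values and (after classification) the sweep-type label.
#' The standard columns are `site`, `pos_bp`, `pos_cM`, `freq`, `uiHSL`,
#' `iHSL`, `RiHS`, `RiHSL`, `p_ihsl`, `p_rihsl`, `label`.
#'
#' @slot frame the underlying `data.frame`.
#' @slot statistic which scan produced the table ("iHSL", "iHS", "nSL").
#' @slot params scan parameters (r, L, cutoffs, ...).
#' @aliases ScoreTable-class
#' @exportClass ScoreTable
setClass("ScoreTable",
  representation(frame = "data.frame", statistic = "character",
                 params = "list")
)

setValidity("ScoreTable", function(object) {
  need <- c("site", "pos_bp", "freq")
  miss <- setdiff(need, names(object@frame))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (length(object@statistic) != 1L) return("statistic must be length 1")
  if ("RiHSL" %in% names(object@frame)) {
    v <- object@frame$RiHSL
    if (any(v < 0, na.rm = TRUE)) return("RiHSL must be non-negative")
  }
  TRUE
})

#' Frequency-bin standardization model
#'
#' Per-frequency-bin means and standard deviations used to z-standardize
#' unstandardized scores (removing the allele-age confounding of the raw
#' log-ratios).  Bins are equal-width on derived allele frequency;
#' underfilled bins are merged with their nearest neighbour.
#'
#' @slot edges numeric bin edges over (0, 1).
#' @slot group integer group id per bin after merging.
#' @slot stats named list (one entry per statistic) of data.frames with
#'   columns `group`, `mean`, `sd`, `n`.
#' @aliases NormalizationModel-class
#' @exportClass NormalizationModel
setClass("NormalizationModel",
  representation(edges = "numeric", group = "integer", stats = "list")
)

setValidity("NormalizationModel", function(object) {
  if (length(object@edges) < 2L) return("need at least one bin")
  if (length(object@group) != length(object@edges) - 1L)
    return("group must map every bin")
  for (nm in names(object@stats)) {
    s <- object@stats[[nm]]
    if (!all(c("group", "mean", "sd", "n") %in% names(s)))
      return("stats entries need group/mean/sd/n")
    if (any(!is.finite(s$sd)) || any(s$sd <= 0))
      return(sprintf("non-positive SD in a bin of %s", nm))
  }
  TRUE
})

#' Labeled simulated reference distribution
#'
#' Standardized (iHSL, RiHS) points from demographic-model simulations,
#' labeled neutral / hard / soft, used for nearest-neighbour sweep-type
#' classification.
#'
#' @slot points data.frame with columns `iHSL`, `RiHS`, `label`.
#' @slot provenance demographic model and parameter ranges.
#' @aliases ReferenceDistribution-class
#' @exportClass ReferenceDistribution
setClass("ReferenceDistribution",
  representation(points = "data.frame", provenance = "list")
)

setValidity("ReferenceDistribution", function(object) {
  p <- object@points
  if (!all(c("iHSL", "RiHS", "label") %in% names(p)))
    return("points needs columns iHSL, RiHS, label")
  if (!all(p$label %in% c("neutral", "hard", "soft")))
    return("labels must be neutral/hard/soft")
  if (!all(is.finite(p$iHSL)) || !all(is.finite(p$RiHS)))
    return("reference points must be finite")
  TRUE
})

#' Simulated sweep replicate
#'
#' A simulated [HaplotypeMatrix] plus the metadata needed for
#' benchmarking: the index of the selected site, the realized sample
#' frequency of the beneficial allele, the number of founder lineages
#' (distinct onset-ancestor haplotype backgrounds with descendants in the
#' sample), the allele-frequency trajectory, and the parameters/seed.
#'
#' @slot hm the simulated [HaplotypeMatrix].
#' @slot selectedSite column index of the beneficial site (1-based).
#' @slot sampleFreq realized derived-allele frequency in the sample.
#' @slot founders founder-lineage count in the sample.
#' @slot trajectory per-generation population frequency of the beneficial
#'   allele (simulation scale).
#' @slot params simulation parameters including the seed.
#' @aliases SweepSimResult-class
#' @exportClass SweepSimResult
setClass("SweepSimResult",
  representation(hm = "HaplotypeMatrix", selectedSite = "integer",
                 sampleFreq = "numeric", founders = "integer",
                 trajectory = "numeric", params = "list")
)

setValidity("SweepSimResult", function(object) {
  if (object@founders < 1L) return("founder count must be >= 1")
  if (object@selectedSite < 1L ||
      object@selectedSite > ncol(object@hm@alleles))
    return("selectedSite out of range")
  TRUE
})
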