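#' @rdname HaplotypeMatrix
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname HaplotypeMatrix
#' @export
setGeneric("physPos", function(x) standardGeneric("physPos"))

#' @rdname HaplotypeMatrix
#' @export
setGeneric("genPos", function(x) standardGeneric("genPos"))

#' @rdname HaplotypeMatrix
#' @export
setGeneric("genPos<-", function(x, value) standardGeneric("genPos<-"))

#' @rdname HaplotypeMatrix
#' @export
setGeneric("nHap", function(x) standardGeneric("nHap"))

#' @rdname HaplotypeMatrix
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname HaplotypeMatrix
#' @export
setGeneric("derivedFreq", function(x, sites) standardGeneric("derivedFreq"))

#' @rdname ScoreTable
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname ScoreTable
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))

#' @rdname ReferenceDistribution
#' @export
setGeneric("refPoints", function(x) standardGeneric("refPoints"))
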