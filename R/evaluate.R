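## Benchmark utilities: power / FPR at a 1% false-positive rate,
## localization of the adaptive site, and classification accuracy.

#' Power at a 1% false-positive rate
#'
#' For the standardized normal statistics (iHSL, iHS, nSL) the
#' threshold is the one-tailed 1% point 2.3263; for the composite
#' RiHSL it is the upper-tail chi-square(2) point 9.2103 with the
#' additional requirement iHSL > 0; for H12 the threshold is the
#' empirical 99th percentile of `neutralScores`.
#'
#' @param x per-replicate focal statistic values (standardized), or
#'   for `method = "RiHSL"` a data.frame/list with elements `RiHSL`
#'   and `iHSL`.
#' @param method statistic type.
#' @param threshold override the default threshold.
#' @param neutralScores neutral replicate scores (required for H12).
#' @return list with `power`, `n`, `threshold`, `method`.
#' @export
powerAt1pct <- function(x, method = c("iHSL", "iHS", "nSL", "RiHSL", "H12"),
                        threshold = NULL, neutralScores = NULL) {
  method <- match.arg(method)
  if (method == "RiHSL") {
    if (is.null(x$RiHSL) || is.null(x$iHSL))
      stop("RiHSL power needs both RiHSL and iHSL values")
    if (is.null(threshold)) threshold <- sweepThresholds()[["RiHSL"]]
    v <- x$RiHSL; keep <- is.finite(v) & is.finite(x$iHSL)
    if (!any(keep)) stop("no finite scores")
    hit <- v[keep] > threshold & x$iHSL[keep] > 0
    return(list(power = mean(hit), n = sum(keep), threshold = threshold,
                method = method))
  }
  if (method == "H12") {
    if (is.null(threshold)) {
      if (is.null(neutralScores))
        stop("H12 power needs neutral scores for the empirical threshold")
      threshold <- stats::quantile(neutralScores, 0.99, names = FALSE)
    }
  } else if (is.null(threshold)) {
    threshold <- sweepThresholds()[["iHSL"]]
  }
  v <- x[is.finite(x)]
  if (!length(v)) stop("no finite scores")
  list(power = mean(v > threshold), n = length(v), threshold = threshold,
       method = method)
}

#' False-positive rate at a threshold
#'
#' [powerAt1pct()] applied to neutral replicates: the proportion of
#' neutral scores exceeding the threshold.
#' @param neutralScores neutral statistic values.
#' @param threshold decision threshold (default the one-tailed 1%
#'   normal point).
#' @return proportion in `[0, 1]`.
#' @export
fprAt <- function(neutralScores, threshold = sweepThresholds()[["iHSL"]]) {
  v <- neutralScores[is.finite(neutralScores)]
  if (!length(v)) stop("no finite scores")
  mean(v > threshold)
}

#' Peak distance and rank of the adaptive site
#'
#' Peak distance is the physical distance between the most significant
#' scored site and the true adaptive site; rank is the 1-based position
#' of the true site when sites are sorted by decreasing significance
#' (`|iHSL|` by default).  Equal maxima resolve to the peak nearest the
#' true site; if the true site is unscored the rank is `NA` and the
#' result is flagged.
#'
#' @param st a standardized [ScoreTable-class].
#' @param trueSite site index (into the haplotype matrix) of the true
#'   adaptive site.
#' @param truePos physical position of the true site (required if
#'   `trueSite` is unscored).
#' @param significance column transform: "abs_iHSL" (default) or
#'   "p_rihsl".
#' @return list with `peakDistance`, `rank`, `trueScored`.
#' @export
peakAndRank <- function(st, trueSite, truePos = NULL,
                        significance = c("abs_iHSL", "p_rihsl")) {
  significance <- match.arg(significance)
  fr <- st@frame
  sig <- switch(significance,
                abs_iHSL = abs(fr$iHSL),
                p_rihsl = -log(fr$p_rihsl))
  keep <- is.finite(sig)
  if (!any(keep)) stop("no scored sites")
  fr <- fr[keep, , drop = FALSE]; sig <- sig[keep]
  row <- match(trueSite, fr$site)
  if (is.na(row) && is.null(truePos))
    stop("true site unscored: supply truePos for the peak distance")
  tp <- if (!is.na(row)) fr$pos_bp[row] else truePos
  peaks <- which(sig == max(sig))
  peak <- peaks[which.min(abs(fr$pos_bp[peaks] - tp))]
  rk <- if (!is.na(row)) {
    as.integer(rank(-sig, ties.method = "min")[row])
  } else NA_integer_
  list(peakDistance = abs(fr$pos_bp[peak] - tp), rank = rk,
       trueScored = !is.na(row))
}

#' Confusion matrix and accuracy of sweep-type calls
#'
#' Restricts to calls significant at `pCut`, tabulates true against
#' called labels over neutral/hard/soft, and reports the accuracy as
#' the mean of the per-class diagonal proportions (mean per-class
#' recall over classes present).
#'
#' @param true true labels from simulation.
#' @param called classifier labels.
#' @param p per-call p-values used for the restriction (`NULL` keeps
#'   all calls).
#' @param pCut significance cut.
#' @return list with `table` (3x3 counts, true in rows), `accuracy`,
#'   and `n`.
#' @export
classificationAccuracy <- function(true, called, p = NULL, pCut = 0.01) {
  lev <- c("neutral", "hard", "soft")
  keep <- rep(TRUE, length(true))
  if (!is.null(p)) keep <- !is.na(p) & p < pCut
  if (!any(keep)) stop("no calls pass the significance restriction")
  tt <- factor(true[keep], levels = lev)
  cc <- factor(called[keep], levels = lev)
  tab <- table(true = tt, called = cc)
  present <- rowSums(tab) > 0
  recall <- diag(tab)[present] / rowSums(tab)[present]
  list(table = tab, accuracy = mean(recall), n = sum(keep))
}
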