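## Readers and writers: phased VCF with ancestral-allele polarization,
## ms-format haplotype blocks, genetic maps with linear interpolation,
## and the score-table / region TSV formats.

#' Read a phased VCF into a HaplotypeMatrix
#'
#' Biallelic SNPs only; every genotype must be phased ("|") and called.
#' The ancestral allele is resolved from an INFO annotation
#' (case-insensitive match against REF or ALT); sites whose ancestral
#' state cannot be resolved are dropped and counted.  Alleles are
#' recoded so 0 = ancestral, 1 = derived.
#'
#' @param path VCF file (plain or gzipped).
#' @param aaField INFO key carrying the ancestral allele.
#' @param onBad "error" aborts on unphased/missing genotypes or
#'   non-SNP/multiallelic records; "drop" drops the offending sites
#'   (counts reported in the metadata).
#' @param cmPerMb constant-rate genetic-map fallback (cM/Mb); use
#'   [interpolateGmap()] and `genPos<-` for a real map.
#' @return a [HaplotypeMatrix-class]; dropped-site counts are in
#'   `metadata(x)$dropped`.
#' @export
readPhasedVcf <- function(path, aaField = "AA",
                          onBad = c("error", "drop"), cmPerMb = 1.25) {
  onBad <- match.arg(onBad)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  pos <- as.numeric(fix[, "POS"])
  chrom <- unname(fix[1, "CHROM"])
  snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt)
  gt <- vcfR::extract.gt(v, element = "GT")
  phased <- !is.na(gt) & grepl("^[01]\\|[01]$", gt)
  badGeno <- rowSums(!phased) > 0L
  aa <- toupper(vcfR::extract.info(v, element = aaField))
  aa <- sub("\\|.*$", "", aa)  # tolerate AA=a|x|x annotations
  aaRef <- !is.na(aa) & aa == toupper(ref)
  aaAlt <- !is.na(aa) & aa == toupper(alt)
  unresolved <- !(aaRef | aaAlt)
  bad <- !snp | badGeno
  if (any(bad) && onBad == "error")
    stop(sprintf(
      "%d site(s) are multiallelic/non-SNP or carry unphased/missing genotypes",
      sum(bad)))
  keep <- which(!bad & !unresolved)
  if (!length(keep)) stop("no usable site in the VCF")
  o <- order(pos[keep])
  keep <- keep[o]
  gtk <- gt[keep, , drop = FALSE]
  m <- length(keep)
  a1 <- matrix(as.integer(substr(gtk, 1L, 1L)), nrow = m)
  a2 <- matrix(as.integer(substr(gtk, 3L, 3L)), nrow = m)
  n <- 2L * ncol(gtk)
  al <- matrix(0L, nrow = n, ncol = m)
  al[seq(1L, n, by = 2L), ] <- t(a1)
  al[seq(2L, n, by = 2L), ] <- t(a2)
  flip <- aaAlt[keep]
  if (any(flip)) al[, flip] <- 1L - al[, flip]
  labs <- as.vector(rbind(paste0(colnames(gtk), "_1"),
                          paste0(colnames(gtk), "_2")))
  HaplotypeMatrix(al, physPos = pos[keep], sampleLabels = labs,
                  chrom = chrom, cmPerMb = cmPerMb,
                  metadata = list(
                    dropped = c(bad = sum(bad),
                                unpolarized = sum(unresolved & !bad)),
                    source = path))
}

#' Read a genetic map
#'
#' Whitespace/tab table with columns chromosome, physical position
#' (bp), rate, cumulative cM (header optional; a 3-column file is read
#' as chrom/bp/cM).
#'
#' @param path map file.
#' @return data.frame with columns `chrom`, `bp`, `cM`, sorted by
#'   position, bp strictly increasing within chromosome.
#' @export
readGeneticMap <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- !grepl("^\\S+\\s+[0-9.]+\\s", first) ||
    grepl("[A-Za-z]{2}", sub("^\\S+\\s+", "", first))
  tab <- utils::read.table(path, header = hasHeader,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("genetic map needs at least 3 columns")
  out <- data.frame(chrom = as.character(tab[[1]]),
                    bp = as.numeric(tab[[2]]),
                    cM = as.numeric(tab[[ncol(tab)]]))
  out <- out[order(out$chrom, out$bp), ]
  if (any(unlist(tapply(out$bp, out$chrom, function(x) diff(x) <= 0))))
    stop("map positions must be strictly increasing within chromosome")
  if (any(unlist(tapply(out$cM, out$chrom, function(x) diff(x) < 0))))
    stop("map cM must be non-decreasing within chromosome")
  out
}

#' Interpolate genetic positions from a map
#'
#' Piecewise-linear interpolation of cumulative cM at the query
#' positions; beyond the map ends the terminal segment's rate is
#' extrapolated (or a constant rate with `rule = "constant"` and
#' `cmPerMb`).
#'
#' @param gmap data.frame from [readGeneticMap()] (or with columns
#'   `bp`, `cM`).
#' @param physPos query positions (bp).
#' @param chrom chromosome to use when the map covers several.
#' @param rule "terminal" extrapolates with the first/last segment
#'   rate; "constant" uses `cmPerMb` beyond the ends.
#' @param cmPerMb rate for `rule = "constant"`.
#' @return numeric cM at the query positions.
#' @export
interpolateGmap <- function(gmap, physPos, chrom = NULL,
                            rule = c("terminal", "constant"),
                            cmPerMb = 1.25) {
  rule <- match.arg(rule)
  if (!is.null(chrom) && "chrom" %in% names(gmap))
    gmap <- gmap[gmap$chrom == chrom, , drop = FALSE]
  if (!nrow(gmap)) stop("empty genetic map")
  bp <- gmap$bp; cM <- gmap$cM
  if (nrow(gmap) == 1L) {
    rate <- if (rule == "constant") cmPerMb * 1e-6 else 0
    return(cM[1] + (physPos - bp[1]) * rate)
  }
  out <- stats::approx(bp, cM, xout = physPos, rule = 2)$y
  k <- length(bp)
  rateLo <- if (rule == "constant") cmPerMb * 1e-6 else
    (cM[2] - cM[1]) / (bp[2] - bp[1])
  rateHi <- if (rule == "constant") cmPerMb * 1e-6 else
    (cM[k] - cM[k - 1]) / (bp[k] - bp[k - 1])
  lo <- physPos < bp[1]; hi <- physPos > bp[k]
  out[lo] <- cM[1] - (bp[1] - physPos[lo]) * rateLo
  out[hi] <- cM[k] + (physPos[hi] - bp[k]) * rateHi
  out
}

#' Read ms-format haplotype blocks
#'
#' Parses the text convention of coalescent simulators: replicates
#' introduced by `//`, then `segsites:`, `positions:` (relative, scaled
#' by `lengthBp`), then one 0/1 row per haplotype.
#'
#' @param path ms-format file.
#' @param lengthBp segment length used to scale relative positions to
#'   bp.
#' @param rec uniform recombination rate used for the genetic
#'   positions (cM = bp * rec * 100).
#' @return list of [HaplotypeMatrix-class] (zero-site replicates yield
#'   `NULL` entries).
#' @export
readMs <- function(path, lengthBp = 1, rec = 1.25e-8) {
  lines <- readLines(path)
  starts <- grep("^//", lines)
  if (!length(starts)) stop("no ms replicate block ('//' line) found")
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    i <- starts[b] + 1L
    if (i > length(lines) || !grepl("^segsites:", lines[i]))
      stop(sprintf("malformed ms block at line %d: expected 'segsites:'", i))
    S <- as.integer(sub("^segsites:\\s*", "", lines[i]))
    if (is.na(S)) stop(sprintf("malformed segsites count at line %d", i))
    if (S == 0L) { out[b] <- list(NULL); next }
    i <- i + 1L
    if (i > length(lines) || !grepl("^positions:", lines[i]))
      stop(sprintf("malformed ms block at line %d: expected 'positions:'", i))
    pos <- as.numeric(strsplit(trimws(sub("^positions:", "", lines[i])),
                               "\\s+")[[1]])
    if (length(pos) != S)
      stop(sprintf("position count mismatch at line %d", i))
    i <- i + 1L
    rows <- character()
    while (i <= length(lines) && grepl("^[01]+$", lines[i])) {
      rows <- c(rows, lines[i]); i <- i + 1L
    }
    if (!length(rows))
      stop(sprintf("no haplotype rows in ms block ending at line %d", i))
    if (any(nchar(rows) != S))
      stop(sprintf("haplotype row length mismatch in block at line %d", i))
    al <- matrix(0L, nrow = length(rows), ncol = S)
    for (rI in seq_along(rows))   # charToRaw: fast parse of long 0/1 rows
      al[rI, ] <- as.integer(charToRaw(rows[rI])) - 48L
    bp <- pos * lengthBp
    keep <- c(TRUE, diff(bp) > 0)
    out[[b]] <- HaplotypeMatrix(al[, keep, drop = FALSE],
                                physPos = bp[keep],
                                genPos = bp[keep] * rec * 100,
                                metadata = list(source = "ms"))
  }
  out
}

#' Write HaplotypeMatrix objects as an ms-format file
#'
#' @param hmList a [HaplotypeMatrix-class] or list of them.
#' @param path output file.
#' @param lengthBp segment length used to normalize positions.
#' @return the path, invisibly.
#' @export
writeMs <- function(hmList, path, lengthBp = 1) {
  if (is(hmList, "HaplotypeMatrix")) hmList <- list(hmList)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ms %d %d", nHap(hmList[[1]]), length(hmList)), con)
  for (hm in hmList) {
    writeLines("\n//", con)
    writeLines(sprintf("segsites: %d", nSites(hm)), con)
    writeLines(paste("positions:",
                     paste(sprintf("%.10f", physPos(hm) / lengthBp),
                           collapse = " ")), con)
    writeLines(apply(alleles(hm), 1L, paste, collapse = ""), con)
  }
  invisible(path)
}

#' Write / read a score table as TSV
#'
#' The standard columns (site, pos_bp, pos_cM, freq, uiHSL, iHSL,
#' RiHS, RiHSL, p_ihsl, p_rihsl, label) plus a statistic-name column.
#'
#' @param st a [ScoreTable-class].
#' @param path file path.
#' @return `readScoreTable` returns a [ScoreTable-class].
#' @export
writeScoreTable <- function(st, path) {
  fr <- st@frame
  fr$statistic <- st@statistic
  utils::write.table(fr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
  fr <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  statName <- if ("statistic" %in% names(fr)) fr$statistic[1] else "iHSL"
  fr$statistic <- NULL
  new("ScoreTable", frame = fr, statistic = statName, params = list())
}

#' Write called sweep regions as BED-style TSV
#'
#' Columns: chrom, start, end, label, leading-SNP position and
#' p-value.
#' @param regions `GRanges` from [callRegions()].
#' @param path file path.
#' @export
writeRegions <- function(regions, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions),
    label = regions$label,
    leadPos = regions$leadPos,
    leadP = regions$leadP)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
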