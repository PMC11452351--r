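## Simulation module: neutral coalescent segments (msprime backend),
## allele-frequency trajectories with selection, and a rescaled forward
## Wright-Fisher sweep engine with founder-lineage tracking.

#' Demographic model presets
#'
#' Named presets: `equilibrium` (Ne = 10,000); `growth` (1,000 growing
#' to 20,000 over the last 1,000 generations, 0.3%/generation);
#' `mild_bottleneck` / `severe_bottleneck` (size reduced to 0.5x / 0.1x
#' starting 300 generations ago, lasting 50 generations); the same with
#' a 400-generation duration as `mild_bottleneck_400` /
#' `severe_bottleneck_400`; and `ooa_YRI` / `ooa_CEU` / `ooa_CHB`, the
#' three-population out-of-Africa model with parameters read from the
#' packaged Gravel-2011 config.
#'
#' @param name preset name.
#' @param Ne baseline diploid effective size for the single-population
#'   presets.
#' @return a [Demography-class].
#' @examples demographyPreset("equilibrium")
#' @export
demographyPreset <- function(name = c("equilibrium", "growth",
                                      "mild_bottleneck", "severe_bottleneck",
                                      "mild_bottleneck_400",
                                      "severe_bottleneck_400",
                                      "ooa_YRI", "ooa_CEU", "ooa_CHB"),
                             Ne = 10000) {
  name <- match.arg(name)
  if (name == "equilibrium")
    return(new("Demography", model = "equilibrium",
               params = list(Ne = Ne), name = name))
  if (name == "growth")
    return(new("Demography", model = "growth",
               params = list(ne_anc = 1000, ne_now = 20000, duration = 1000),
               name = name))
  if (grepl("bottleneck", name)) {
    frac <- if (grepl("severe", name)) 0.1 else 0.5
    dur <- if (grepl("400$", name)) 400 else 50
    return(new("Demography", model = "bottleneck",
               params = list(Ne = Ne, frac = frac, start = 300,
                             duration = dur), name = name))
  }
  pop <- c(ooa_YRI = "AFR", ooa_CEU = "EUR", ooa_CHB = "ASN")[[name]]
  cfgFile <- system.file("extdata", "ooa_gravel2011.yaml",
                         package = "hapsweep", mustWork = TRUE)
  p <- yaml::read_yaml(cfgFile)
  p$sample_pop <- pop
  new("Demography", model = "ooa", params = p, name = name)
}

setMethod("show", "Demography", function(object) {
  cat(sprintf("Demography preset '%s' (model: %s)\n", object@name,
              object@model))
})

.pythonBin <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter on PATH (needed for the coalescent backend)")
}

.msBackend <- function(cfg, lengthBp, rec) {
  script <- system.file("python", "sim_neutral.py", package = "hapsweep",
                        mustWork = TRUE)
  cfgFile <- tempfile(fileext = ".json")
  outFile <- tempfile(fileext = ".ms")
  on.exit(unlink(c(cfgFile, outFile)), add = TRUE)
  jsonlite::write_json(cfg, cfgFile, auto_unbox = TRUE, digits = NA)
  res <- system2(.pythonBin(), c(script, cfgFile, outFile),
                 stdout = TRUE, stderr = TRUE)
  code <- attr(res, "status")
  if (!is.null(code) && code != 0)
    stop("coalescent backend failed:\n", paste(res, collapse = "\n"))
  readMs(outFile, lengthBp = lengthBp, rec = rec)
}

#' Simulate neutral segments under a demographic model
#'
#' Coalescent-with-recombination samples via the msprime backend;
#' ancestral allele is 0 at every site by construction (binary
#' infinite-sites mutations).  With a rescaling factor `Q > 1`,
#' population sizes and times are divided by Q and per-generation rates
#' multiplied by Q, leaving the population-scaled parameters (theta,
#' rho) unchanged; genetic positions of the returned matrices always
#' use the natural-scale recombination rate.
#'
#' @param dem a [Demography-class] (see [demographyPreset()]).
#' @param nHap number of sampled haplotypes.
#' @param lengthBp segment length in bp.
#' @param mu mutation rate per bp per generation.
#' @param rec recombination rate per bp per generation.
#' @param reps number of replicates.
#' @param seed backend random seed (positive integer).
#' @param Q rescaling factor.
#' @return list of [HaplotypeMatrix-class] objects (length `reps`).
#' @export
simulateNeutral <- function(dem, nHap, lengthBp = 2e6, mu = 2.5e-8,
                            rec = 1.25e-8, reps = 1L, seed = 1L, Q = 1) {
  stopifnot(is(dem, "Demography"), nHap >= 2, mu >= 0, rec >= 0)
  cfg <- c(list(model = dem@model, n_hap = nHap, length = lengthBp,
                mu = mu, rec = rec, reps = reps,
                seed = max(1L, as.integer(seed)), Q = Q),
           if (dem@model == "ooa") list(ooa = dem@params)
           else dem@params)
  .msBackend(cfg, lengthBp = lengthBp, rec = rec)
}

#' Simulate a beneficial-allele frequency trajectory
#'
#' Forward Wright-Fisher binomial sampling with genic selection
#' (genotype fitnesses 1, 1+s/2, 1+s) at a population size of `N`
#' diploids, rejection-sampled until the final population frequency
#' falls in `targetWindow`.  Modes: `sgv` starts from standing
#' frequency `f0`; `srm` starts absent with recurrent origins at rate
#' `thetaB / (4N)` per copy per generation; `hard` injects a single
#' de-novo origin at the selection onset (so the founder lineage is
#' unique by construction).
#'
#' @param mode one of "sgv", "srm", "hard".
#' @param N diploid population size at simulation scale.
#' @param gens number of generations of selection.
#' @param s selection coefficient (per copy, at simulation scale).
#' @param f0 standing initial frequency (sgv).
#' @param thetaB population-scaled beneficial mutation rate `4*N*mu_b`
#'   at the `N` used here (invariant under rescaling).
#' @param targetWindow final-frequency acceptance window `c(lo, hi)`.
#' @param maxTries rejection budget.
#' @return list with `carriers` (copies per generation, after
#'   reproduction and new origins), `origins` (new origins per
#'   generation), `freq` (trajectory including the initial state),
#'   `tries`, and `accepted`.  Errors when the budget is exhausted,
#'   reporting the acceptance rate.
#' @export
simulateTrajectory <- function(mode = c("sgv", "srm", "hard"), N, gens, s,
                               f0 = NULL, thetaB = NULL,
                               targetWindow = c(0, 1), maxTries = 2000L) {
  mode <- match.arg(mode)
  stopifnot(N >= 2, gens >= 1, s >= 0)
  n2 <- 2L * as.integer(N)
  if (mode == "sgv") {
    if (is.null(f0) || f0 <= 0 || f0 >= 1) stop("sgv needs 0 < f0 < 1")
    k0 <- max(1L, round(n2 * f0))
    muB <- 0
  } else if (mode == "srm") {
    if (is.null(thetaB) || thetaB < 0) stop("srm needs thetaB >= 0")
    k0 <- 0L
    muB <- thetaB / (4 * N)
  } else {
    k0 <- 0L   # hard: one de-novo origin injected at onset
    muB <- 0
  }
  logGrow <- log1p(s)   # optimistic per-generation growth bound
  for (try in seq_len(maxTries)) {
    k <- k0
    carriers <- integer(gens); origins <- integer(gens)
    dead <- FALSE
    for (t in seq_len(gens)) {
      if (t == 1L && mode == "hard") {
        k <- 1L; carriers[1] <- 1L; origins[1] <- 1L
        next
      }
      p <- k / n2
      w1 <- 1 + s / 2 + p * s / 2   # marginal fitness of the allele
      w0 <- 1 + p * s / 2
      psel <- if (k > 0) p * w1 / (p * w1 + (1 - p) * w0) else 0
      ktrans <- stats::rbinom(1L, n2, psel)
      o <- if (muB > 0 && ktrans < n2)
        stats::rbinom(1L, n2 - ktrans, muB) else 0L
      k <- ktrans + o
      carriers[t] <- k; origins[t] <- o
      ## fail fast on paths that can no longer reach the target window:
      ## fixation is absorbing; and even granting every remaining origin
      ## plus growth at (1+s) per generation (twice the true marginal
      ## advantage) the window's lower edge must be attainable
      if (k == n2 && targetWindow[2] < 1) { dead <- TRUE; break }
      rem <- gens - t
      if (targetWindow[1] > 0) {
        kOpt <- k + if (muB > 0) ceiling(2 * n2 * muB * rem) else 0
        if (kOpt == 0L ||
            (log(kOpt / n2) + rem * logGrow < log(targetWindow[1]))) {
          dead <- TRUE; break
        }
      }
    }
    if (dead) next
    pf <- k / n2
    okOrigin <- mode != "srm" || sum(origins) >= 1L
    if (okOrigin && pf >= targetWindow[1] && pf <= targetWindow[2])
      return(list(carriers = carriers, origins = origins,
                  freq = c(k0, carriers) / n2, tries = try,
                  accepted = TRUE))
  }
  stop(sprintf(
    "trajectory rejection budget exhausted (%d tries, acceptance rate < %.2g)",
    maxTries, 1 / maxTries))
}

## Compress a natural-scale trajectory (per-generation carrier counts at
## 2*Ne) to the rescaled clock: one step per Q generations, counts scaled
## to 2*NeSim.  Keeping the conditioning at natural scale preserves the
## diffusion-bridge shape of accepted paths (per-generation selection at
## s*Q is far outside the diffusion limit and produces spuriously
## bottlenecked conditioned paths); the compressed path conserves the
## pairwise coalescence intensity sum(1/k_t dt).
.compressTrajectory <- function(traj, Q, NeSim, Ne) {
  gens <- length(traj$carriers)
  Tr <- max(1L, as.integer(ceiling(gens / Q)))
  ratio <- NeSim / Ne
  k <- integer(Tr); o <- integer(Tr)
  for (t in seq_len(Tr)) {
    gHi <- min(gens, t * Q)
    kn <- traj$carriers[gHi]
    k[t] <- if (kn > 0L) max(1L, as.integer(round(kn * ratio))) else 0L
    gLo <- (t - 1L) * Q + 1L
    on <- sum(traj$origins[gLo:gHi])
    o[t] <- min(on, k[t])
  }
  ## transmitted carriers need ancestors: where the previous step has
  ## none, the whole count must come from new origins
  prev <- if (length(traj$freq)) max(0L, as.integer(round(
    traj$freq[1] * 2 * Ne * ratio))) else 0L
  for (t in seq_len(Tr)) {
    if (prev == 0L && k[t] > o[t]) o[t] <- k[t]
    prev <- k[t]
  }
  list(carriers = k, origins = o)
}

## pick the standing variant closest to the requested frequency near the
## segment center; returns the column index or NA
.pickStandingSite <- function(hm, f0, tol = NULL) {
  a <- alleles(hm)
  n <- nrow(a)
  target <- max(1L, round(n * f0))
  if (is.null(tol)) tol <- max(2L, round(0.15 * target))
  cnt <- colSums(a)
  ok <- which(abs(cnt - target) <= tol & cnt > 0L & cnt < n)
  if (!length(ok)) return(NA_integer_)
  center <- (physPos(hm)[1] + physPos(hm)[nSites(hm)]) / 2
  ok[which.min(abs(physPos(hm)[ok] - center))]
}

#' Simulate selective-sweep haplotype samples
#'
#' Rescaled forward Wright-Fisher simulation of the full haplotype
#' population, conditioned on an accepted frequency trajectory.  The
#' standing base population is a neutral coalescent sample of `2*NeSim`
#' haplotypes under `dem` (rescaled by `Q = Ne/NeSim`); for `sgv` the
#' beneficial allele is an existing segregating site of frequency ~`f0`
#' nearest the segment center, for `srm`/`hard` new beneficial
#' mutations arise at the center position.  Founder lineages are the
#' distinct onset-time ancestors of the core locus with descendants in
#' the sample; `founderFilter` applies the retention rules (hard:
#' exactly 1; soft: at least 2).
#'
#' @inheritParams simulateNeutral
#' @inheritParams simulateTrajectory
#' @param mode sweep type: "sgv", "srm" or "hard".
#' @param nHap sample size (haplotypes) drawn from the final population.
#' @param s selection coefficient per copy at natural scale (it becomes
#'   `s * Q` at simulation scale); scalar or range `c(lo, hi)` drawn
#'   uniformly per attempt.  Ignored when `alpha` is given.
#' @param alpha optional scaled selection intensity `2 * Ne * s`;
#'   scalar or range drawn uniformly per attempt.
#' @param f0 standing frequency (sgv); scalar or range drawn uniformly
#'   per attempt.
#' @param onset selection onset in generations ago at natural scale;
#'   scalar or range drawn uniformly per attempt.
#' @param targetFreq acceptance window for the final population
#'   frequency.
#' @param sampleWindow window the realized sample frequency must fall
#'   in (defaults to `targetFreq` widened by 0.05).
#' @param Ne natural-scale reference effective size.
#' @param NeSim rescaled effective size actually simulated
#'   (`Q = Ne/NeSim`).
#' @param founderFilter "hard" keeps founder count == 1, "soft" keeps
#'   counts of 2 or more, "none" keeps all; "auto" picks by mode.
#' @param reps number of retained replicates to produce.
#' @param maxTries per-base-replicate budget of forward runs.
#' @param trajTries rejection budget per trajectory.
#' @param maxBases overall budget of base populations per retained
#'   replicate.
#' @param seed integer seed (all randomness, including the backend's,
#'   derives from it).
#' @return a list of [SweepSimResult-class] objects (length `reps`).
#' @export
simulateSweep <- function(mode = c("sgv", "srm", "hard"),
                          dem = demographyPreset("equilibrium"),
                          nHap = 1000L, lengthBp = 2e6, mu = 2.5e-8,
                          rec = 1.25e-8, s = 0.02, alpha = NULL, f0 = 0.1,
                          thetaB = NULL, onset = c(100, 2000),
                          targetFreq = c(0.25, 0.85), sampleWindow = NULL,
                          Ne = 10000, NeSim = 1000,
                          founderFilter = c("auto", "none", "hard", "soft"),
                          reps = 1L, maxTries = 600L, trajTries = 10L,
                          maxBases = 40L, seed = 1L) {
  mode <- match.arg(mode)
  founderFilter <- match.arg(founderFilter)
  if (founderFilter == "auto")
    founderFilter <- if (mode == "hard") "hard" else "soft"
  Q <- Ne / NeSim
  n2 <- 2L * as.integer(NeSim)
  if (nHap > n2) stop("nHap cannot exceed the simulated population size")
  if (is.null(sampleWindow))
    sampleWindow <- c(max(0, targetFreq[1] - 0.05),
                      min(1, targetFreq[2] + 0.05))
  set.seed(as.integer(seed))
  drawIn <- function(x) if (base::length(x) == 2L)
    stats::runif(1, x[1], x[2]) else x
  out <- vector("list", reps)
  got <- 0L
  baseBuf <- list(); baseUsed <- 0L; basesTotal <- 0L
  chunk <- max(4L, min(50L, reps))
  nextBase <- function() {
    if (baseUsed >= base::length(baseBuf)) {
      baseBuf <<- simulateNeutral(dem, nHap = n2, lengthBp = lengthBp,
                                  mu = mu, rec = rec, reps = chunk,
                                  seed = sample.int(2147483600L, 1L), Q = Q)
      baseUsed <<- 0L
    }
    baseUsed <<- baseUsed + 1L
    basesTotal <<- basesTotal + 1L
    baseBuf[[baseUsed]]
  }
  while (got < reps) {
    if (basesTotal > maxBases * reps)
      stop(sprintf(
        "sweep rejection budget exhausted: %d retained from %d bases",
        got, basesTotal))
    base <- nextBase()
    for (try in seq_len(maxTries)) {
      si <- if (!is.null(alpha)) drawIn(alpha) / (2 * Ne) else drawIn(s)
      f0i <- drawIn(f0)
      onseti <- drawIn(onset)
      gensNat <- max(1L, as.integer(round(onseti)))
      coreCol <- NA_integer_
      if (mode == "sgv") {
        coreCol <- .pickStandingSite(base, f0i)
        if (is.na(coreCol)) break  # base lacks a usable standing variant
        carriers0 <- alleles(base)[, coreCol] == 1L
        f0eff <- mean(carriers0)
      } else {
        carriers0 <- rep(FALSE, n2)
        f0eff <- NA_real_
      }
      ## condition the allele-frequency path at natural scale, then
      ## compress it to the rescaled clock for the haplotype engine
      traj <- tryCatch(
        simulateTrajectory(mode, N = Ne, gens = gensNat, s = si,
                           f0 = if (mode == "sgv") f0eff else NULL,
                           thetaB = thetaB, targetWindow = targetFreq,
                           maxTries = trajTries),
        error = function(e) NULL)
      if (is.null(traj)) next
      ctraj <- .compressTrajectory(traj, Q, NeSim, Ne)
      a <- alleles(base); pos <- physPos(base)
      if (mode == "sgv") {
        corePos <- pos[coreCol]
        a <- a[, -coreCol, drop = FALSE]
        pos <- pos[-coreCol]
      } else corePos <- lengthBp / 2
      fwd <- cpp_forward_sweep(a, pos, carriers0, ctraj$carriers,
                               ctraj$origins,
                               rec_per_gen = rec * Q * lengthBp,
                               mut_per_gen = mu * Q * lengthBp,
                               L_bp = lengthBp, core_pos = corePos,
                               n_sample = as.integer(nHap))
      if (is.na(fwd$core_col)) next
      sf <- fwd$sample_core_count / nHap
      if (sf < sampleWindow[1] || sf > sampleWindow[2]) next
      if (founderFilter == "hard" && fwd$founders != 1L) next
      if (founderFilter == "soft" && fwd$founders < 2L) next
      keep <- c(TRUE, diff(fwd$pos) > 0)  # guard against position ties
      hm <- HaplotypeMatrix(fwd$alleles[, keep, drop = FALSE],
                            physPos = fwd$pos[keep],
                            genPos = fwd$pos[keep] * rec * 100,
                            metadata = list(source = "forward_sweep",
                                            mode = mode))
      coreOut <- sum(keep[seq_len(fwd$core_col)])
      got <- got + 1L
      out[[got]] <- new("SweepSimResult", hm = hm,
                        selectedSite = as.integer(coreOut),
                        sampleFreq = sf, founders = as.integer(fwd$founders),
                        trajectory = traj$freq,
                        params = list(mode = mode, s = si, f0 = f0i,
                                      thetaB = thetaB, onset = onseti,
                                      Ne = Ne, NeSim = NeSim, Q = Q,
                                      seed = seed, tries = try,
                                      founderFilter = founderFilter))
      break
    }
  }
  out
}

#' Build a labeled simulated reference distribution
#'
#' Simulates neutral, hard-sweep and soft-sweep replicates under an
#' out-of-Africa (or other) demographic model with parameters drawn
#' from the classifier's training ranges -- soft: standing frequency
#' `f0 ~ U(0.01, 0.2)`; hard: single de-novo origin; both with scaled
#' selection intensity `alpha = 2*Ne*s ~ U(50, 1000)` and onset
#' `~ U(0, 2000)` generations ago; retention window 0.05--0.95 on the
#' sample frequency -- scores the focal site of every retained
#' replicate, fits the frequency-bin standardization on the neutral
#' scores, and returns the labeled standardized (iHSL, RiHS) points.
#'
#' @inheritParams simulateSweep
#' @param nPerClass retained replicates per class.
#' @param alphaRange scaled selection intensity `2*Ne*s` range.
#' @param f0Range standing-frequency range for the soft class.
#' @param onsetRange onset range (generations ago, natural scale).
#' @param retention sample-frequency retention window.
#' @param scoreParams list passed on to [scoreSites()] (r, L, ...).
#' @param normSitesPerRep neutral sites scored per neutral replicate
#'   for the standardization pool.
#' @return list with `ref` (a [ReferenceDistribution-class]), `norm`
#'   (the [NormalizationModel-class] to standardize query scores with),
#'   and `counts` (achieved per-class counts; a warning is emitted if a
#'   class is underfilled).
#' @export
buildReference <- function(dem = demographyPreset("ooa_YRI"),
                           nPerClass = 2000L, nHap = 216L, lengthBp = 2e6,
                           mu = 2.5e-8, rec = 1.25e-8,
                           alphaRange = c(50, 1000), f0Range = c(0.01, 0.2),
                           onsetRange = c(0, 2000), retention = c(0.05, 0.95),
                           Ne = 10000, NeSim = 1000, seed = 1L,
                           scoreParams = list(), normSitesPerRep = 25L,
                           maxTries = 300L) {
  set.seed(as.integer(seed))
  Q <- Ne / NeSim
  scoreFocal <- function(hm, site) {
    do.call(scoreSites, c(list(hm, sites = site, minFreq = 0), scoreParams))
  }
  ## neutral class + standardization pool (streamed in chunks to keep
  ## memory flat)
  neutFrames <- list()
  neutFocal <- list()
  done <- 0L
  while (done < nPerClass) {
    chunk <- min(50L, nPerClass - done)
    neut <- simulateNeutral(dem, nHap = nHap, lengthBp = lengthBp, mu = mu,
                            rec = rec, reps = chunk,
                            seed = sample.int(2147483600L, 1L), Q = Q)
    for (hm in neut) {
      if (is.null(hm)) next
      freq <- derivedFreq(hm)
      ok <- which(freq >= 0.05 & freq <= 0.95)
      if (!length(ok)) next
      center <- ok[which.min(abs(physPos(hm)[ok] - lengthBp / 2))]
      pool <- ok[unique(round(seq(1, length(ok),
                                  length.out = min(normSitesPerRep,
                                                   length(ok)))))]
      pool <- sort(unique(c(pool, center)))
      st <- do.call(scoreSites, c(list(hm, sites = pool), scoreParams))
      fr <- scores(st)
      neutFrames[[length(neutFrames) + 1L]] <-
        fr[c("freq", "uiHSL", "uRiHS1", "uRiHS0")]
      neutFocal[[length(neutFocal) + 1L]] <- fr[fr$site == center, ,
                                                drop = FALSE]
    }
    done <- done + chunk
    rm(neut)
  }
  norm <- fitNormalization(do.call(rbind, neutFrames))
  stdPoints <- function(frames) {
    fr <- do.call(rbind, frames)
    fr <- fr[is.finite(fr$uiHSL) & is.finite(fr$uRiHS1) &
               is.finite(fr$uRiHS0), , drop = FALSE]
    z <- .standardizeVec(fr$uiHSL, fr$freq, norm, "uiHSL")
    z1 <- .standardizeVec(fr$uRiHS1, fr$freq, norm, "uRiHS1")
    z0 <- .standardizeVec(fr$uRiHS0, fr$freq, norm, "uRiHS0")
    data.frame(iHSL = z, RiHS = ifelse(z >= 0, z1, z0))
  }
  sweepClass <- function(modeLabel) {
    sims <- simulateSweep(
      mode = if (modeLabel == "hard") "hard" else "sgv", dem = dem,
      nHap = nHap, lengthBp = lengthBp, mu = mu, rec = rec,
      alpha = alphaRange, f0 = f0Range, onset = onsetRange,
      targetFreq = retention, sampleWindow = retention, Ne = Ne,
      NeSim = NeSim, reps = nPerClass, maxTries = maxTries,
      seed = sample.int(2147483600L, 1L))
    lapply(sims, function(sim)
      scores(scoreFocal(sim@hm, sim@selectedSite)))
  }
  hardFrames <- sweepClass("hard")
  softFrames <- sweepClass("soft")
  ptsN <- stdPoints(neutFocal)
  ptsH <- stdPoints(hardFrames)
  ptsS <- stdPoints(softFrames)
  counts <- c(neutral = nrow(ptsN), hard = nrow(ptsH), soft = nrow(ptsS))
  if (any(counts < nPerClass))
    warning(sprintf("underfilled reference classes: %s",
                    paste(sprintf("%s=%d", names(counts), counts),
                          collapse = " ")))
  pts <- rbind(
    cbind(ptsN, label = "neutral"),
    cbind(ptsH, label = "hard"),
    cbind(ptsS, label = "soft"))
  list(ref = ReferenceDistribution(
         pts, provenance = list(model = dem@name, nPerClass = nPerClass,
                                nHap = nHap, lengthBp = lengthBp,
                                seed = seed)),
       norm = norm, counts = counts)
}
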