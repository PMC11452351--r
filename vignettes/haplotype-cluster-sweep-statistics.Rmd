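---
title: "Detecting and classifying selective sweeps from local haplotype clusters"
author: "hapsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying selective sweeps from local haplotype clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A hard selective sweep drives a beneficial allele up from a single
founder haplotype, dragging one long haplotype to high frequency;
extended haplotype homozygosity (EHH) statistics such as iHS detect the
resulting excess of long identical haplotypes around the selected
allele.  A soft sweep — selection on standing genetic variation (SGV)
or on recurrently arising mutations (SRM) — lifts *several* founder
haplotypes at once.  Whole-class EHH then collapses quickly (the
founder families differ from each other), and iHS loses power even
though each founder family is internally near-identical.

`hapsweep` implements local-cluster EHH statistics that recover this
within-family signal, a simulation-based nearest-neighbour classifier
that labels significant sites as hard or soft, and a soft-shoulder
correction for the flanks of hard sweeps, together with the comparator
statistics (iHS, nSL, H12) and the simulation machinery needed to
benchmark all of them.

## The statistics

For a core site $x_0$ with derived class $H_1$ and ancestral class
$H_0$ (0/1 coded, polarized), the local cluster of a focal haplotype
$h_j$ is $h_j$ plus its $s$ nearest neighbours by Hamming distance over
a window of $L$ SNPs per side, with diameter

$$ s = \min(\max(\lceil r\,|H_c|\rceil,\ 8),\ |H_c|), \qquad r = 0.1 .$$

EHH of a haplotype set at marker $x_i$ is the probability that two
members drawn without replacement are identical over the stretch from
the core to $x_i$ (both inclusive); iHH is the trapezoidal integral of
EHH over genetic distance, both directions from the core.  Averaging
cluster iHH over focal haplotypes of a class gives $\mathrm{iHHL}_c$;
the whole-class integral $\mathrm{iHH}_c$ is the classical (iHS-style)
quantity, and is what every cluster reduces to at $r = 1$.  The
statistics are

$$ \mathrm{uiHSL} = \ln\frac{\mathrm{iHHL}_1}{\mathrm{iHHL}_0}, \qquad
   \mathrm{uRiHS}_c = \ln\frac{\mathrm{iHHL}_c}{\mathrm{iHH}_c}, $$

z-standardized within derived-allele-frequency bins (allele age is a
strong confounder of raw haplotype length), with the RiHS class picked
by the sign of the standardized iHSL ($c=1$ if $\mathrm{iHSL}\ge 0$).
The composite $\mathrm{RiHSL} = \mathrm{iHSL}^2 + \mathrm{RiHS}^2$ is
approximately $\chi^2_2$ under neutrality.  P-values are
$2\Phi(-|\mathrm{iHSL}|)$ and the upper tail $e^{-\mathrm{RiHSL}/2}$;
the 1% working points are 2.3263 (one-tailed normal) and 9.2103
($\chi^2_2$).  The $\chi^2$ p-value is deliberately the *upper* tail:
the lower tail would make large scores non-significant, which is
inconsistent with using 9.2103 as a 1% detection threshold.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `r` | 0.1 | cluster diameter fraction; `r = 1` recovers iHS |
| `L` | 400 SNPs | half-window for distances and integration |
| `sFloor` | 8 | lower bound on the cluster diameter |
| `ehhCutoff` | 0.05 | EHH level at which integration stops (per walk) |
| `minFreq` | 0.05 | scorability bound on derived allele frequency |
| `nBins`, `minBinCount` | 50, 20 | frequency bins; underfilled bins merge |
| `k` | 200 | nearest reference points for classification |
| `sigP`, `window`, `minProp`, `maxGap` | 0.001, 50, 0.2, 10 | soft-shoulder core-SNP / region parameters |

Numerical conventions worth knowing:

* **Integration truncation.** Each EHH walk stops at the earlier of
  $L$ markers, the chromosome end (the site is then flagged `edge`),
  or EHH falling below `ehhCutoff`; the final trapezoid is included.
  The cutoff matches common iHS practice; setting it to 0 integrates to
  the full window and changes scores only marginally on our
  simulations.
* **Ties.** Hamming ties at the $s$-th neighbour resolve by haplotype
  index; equal significance maxima in localization resolve to the peak
  nearest the true site; kNN majority ties fall back to the single
  nearest point.  Everything is deterministic under a fixed seed.
* **Standard deviations** use the sample ($n-1$) convention, so a
  two-point bin standardizes to $\pm 1/\sqrt 2$; a constant-valued bin
  is an error rather than a silent zero-division.
* **Cluster membership** is the focal haplotype plus $s$ neighbours
  ($|H_j| = s + 1$); when $s = |H_c|$ the cluster is the whole class.
* **Neighbour pool.** Candidates for a focal's neighbours are its own
  allele class (`neighborPool = "class"`), which is what makes
  `r = 1` collapse exactly onto iHS.  A literal
  anyone-may-be-a-neighbour variant (`"all"`, with the identity
  stretch starting at the core site itself) is provided; empirically
  the two are nearly indistinguishable because nearest neighbours over
  an 801-SNP window essentially always share the core allele.

## Classification and the soft shoulder

Significant sites are classified by the modal label among the `k`
nearest labeled points — Euclidean distance in the standardized
(iHSL, RiHS) plane — of a simulated reference distribution built under
a demographic model (`buildReference()`): neutral replicates, hard
sweeps (single de-novo origin, scaled intensity
$\alpha = 2N_e s \sim U(50, 1000)$, onset $\sim U(0, 2000)$
generations), and soft sweeps (standing frequency
$f_0 \sim U(0.01, 0.2)$, same $\alpha$ and onset), retaining sample
frequencies in (0.05, 0.95) and applying the founder-lineage filters
(hard: exactly one; soft: at least two).

Hard sweeps leak soft-looking signals into their flanks (the *soft
shoulder*): partially recombined copies of the sweeping haplotype mimic
multiple founder families.  The correction declares a SNP a *core* SNP
when the proportion of significant SNPs among its `window` scored
neighbours per side reaches `minProp`, joins runs of core SNPs (gaps up
to `maxGap`) into regions, labels each region by its most significant
SNP, and overwrites the labels of the significant members — so
soft-labeled flanks of a hard region are revised to hard.  Region
significance is one-sided (`positiveOnly = TRUE`): only sites with
standardized iHSL > 0 are sweep-typing candidates, matching the
derived-allele orientation of the one-tailed detection rule.  This
matters in practice — flanking variants of a hard sweep often carry
extreme *negative* iHSL (the swept haplotype is their ancestral-allele
background), and without the one-sided rule such a site can become the
"leading SNP" even though it lies outside the reference clouds
entirely.  The window, proportion, and gap defaults are package
choices (the correction is described in the literature only up to "a
predefined threshold"); region calling is idempotent.

## The simulator

Neutral segments come from the msprime coalescent (bundled Python
backend, ms-format text interface): constant size ($N_e$ = 10,000),
exponential growth (1,000 → 20,000 over the last 1,000 generations),
mild/severe bottlenecks (to 0.5×/0.1× for 50 generations starting 300
generations ago; 400-generation variants are provided because both
durations circulate for these scenarios), and a three-population human
out-of-Africa model with the Gravel-2011 parameters shipped as a
versioned YAML config (sampling YRI-, CEU- or CHB-like populations
with 2×108, 2×99, 2×103 haplotypes).  Defaults: 2 Mb segments,
$\mu = 2.5\times10^{-8}$, $\rho = 1.25\times10^{-8}$ per bp per
generation.

Sweeps use a rescaled forward Wright–Fisher engine on full haplotypes:
a factor $Q = N_e/N_{e,\mathrm{sim}}$ divides sizes and times and
multiplies $s$, $\mu$, $\rho$, leaving the population-scaled dynamics
unchanged (a property the test suite checks by comparing $Q = 10$ and
$Q = 5$).  The standing base population is a coalescent sample of
$2N_{e,\mathrm{sim}}$ haplotypes; the beneficial-allele trajectory is
simulated first (genic selection, fitnesses $1, 1+s/2, 1+s$) and
rejection-sampled into the requested present-day frequency window, and
haplotype transmission is then conditioned on it.  Modes:

* **SGV** — the beneficial allele is an existing segregating site of
  frequency ≈ $f_0$ nearest the segment centre.  A neutral standing
  variant at frequency $f_0$ is the single-origin-drifted-to-$f_0$
  object conditioned on its *current* frequency (rather than on first
  passage); we use it because it carries the correct founder haplotype
  structure at no cost.
* **SRM** — recurrent origins at rate $\theta_b/(4N)$ per copy per
  generation ($\theta_b \in \{5, 10, 50\}$ in the benchmark grids).
* **hard** — a single origin injected at onset ($\theta_b = 0.01$ in
  the source grids is operationally a single origin).

Founder lineages are tracked exactly: every onset-time carrier gets a
label inherited by the core locus, and the founder count is the number
of distinct labels among sampled carriers.  "Selection intensities
$U(50, 1000)$" are read as $\alpha = 2N_e s$ with $N_e = 10^4$
(the usual ms/msms convention); equilibrium grids use per-copy
$s \in \{0.01, 0.02, 0.05\}$ directly.

What the generator does *not* emulate: gene conversion, mutation-rate
or recombination-rate heterogeneity along the segment, background
selection, and post-onset demographic change during the forward phase
(out-of-Africa sweeps run at a constant rescaled size seeded by the
demographically correct standing sample).  Passing tests therefore
speak to the statistics' behaviour under clean coalescent/WF dynamics,
not to robustness against those real-data complications.

## Desk-scale benchmark sizes

The packaged tests and the acceptance script reproduce the simulation
study at reduced size, chosen once as a compromise a laptop can carry:
neutral calibration at 100 replicates of 2 Mb with 1,000 haplotypes;
power grids with 400 haplotypes, 300 kb segments,
$N_{e,\mathrm{sim}} = 500$, and 60 replicates per selection intensity
binned by realized sample frequency (conditioning each cell on its
frequency bin and binning realized frequencies are the same ensemble;
the latter needs no per-cell rejection); a YRI-like classification
reference at 500 points per class (full scale uses 100,000) with 200
kb segments, plus 150-point-per-class CHB/CEU references for the
mismatched-reference robustness check; FPR robustness at 400
haplotypes, 1 Mb, 24 recombination×mutation conditions × 12
replicates.  Where a power or accuracy value is compared against a
full-scale number, the reduced sample size and reference size matter,
and this section is where those sizes are recorded.

## Known limitations

* Requires phased haplotypes with ancestral/derived polarization and a
  genetic map (linear interpolation, terminal-rate extrapolation);
  missing genotypes and multiallelic sites are rejected, matching the
  method's published scope.
* Sample sizes below ~50 haplotypes cannot resolve sub-haplotype
  cluster structure.
* Only partial (incomplete) sweeps are detectable; early-stage
  balancing selection mimics a sweep.
* With desk-scale references built by the rescaled forward engine, the
  hard/soft clouds in the (iHSL, RiHS) plane separate less than
  full-scale results report: our held-out sweep-type accuracy is
  ~0.70–0.75 rather than >0.9.  The detection side (iHSL power
  ordering over iHS/H12/nSL, FPR calibration, χ² behaviour of RiHSL)
  reproduces well; the classification margin appears to be sensitive
  to the structured-coalescent machinery and the 100,000-point
  references used at full scale, which are out of desk-scale reach.
  The acceptance suite reports this number honestly rather than tuning
  around it.

## A worked call sequence

```{r example}
library(hapsweep)

## scan a phased, polarized VCF
hm <- readPhasedVcf("phased.vcf", aaField = "AA")
gmap <- readGeneticMap("chr2.gmap")
genPos(hm) <- interpolateGmap(gmap, physPos(hm))
st <- scoreSites(hm, standardize = TRUE)

## classify significant sites against a simulated reference
built <- buildReference(demographyPreset("ooa_CHB"), nPerClass = 2000,
                        nHap = 206, seed = 1)
st <- classifyScores(st, built$ref, pCut = 0.01)
regions <- callRegions(st, findCoreSnps(st), built$ref)
writeRegions(regions$regions, "sweeps.bed")
```
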