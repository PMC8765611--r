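---
title: "Haplotype-homozygosity selection scans with ehhscan: models, estimators and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-homozygosity selection scans with ehhscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehhscan)
```

## The problem and the statistics

A hard selective sweep drags one long haplotype to high frequency faster
than recombination and mutation can break it down. Extended haplotype
homozygosity (EHH) quantifies this: for a focal marker $s$ and core allele
$a$, $EHH^a_{s,t}$ is the probability that two randomly drawn chromosomes
carrying $a$ at $s$ are identical over the whole interval between $s$ and a
flanking marker $t$. With $K_{s,t}$ distinct shared haplotypes of sizes
$n_k$ among the $n_a$ carriers,

$$EHH^a_{s,t} = \frac{1}{n_a(n_a-1)} \sum_{k=1}^{K_{s,t}} n_k (n_k - 1).$$

The curve starts at 1 at the focal marker and decays on each side. Its
integral over physical position, iHH (one value per core allele), summarizes
how far homozygosity extends. Under the stepwise-constant curve definition
with no cutoff, iHH is *identical* to the average length of the pairwise
shared haplotypes around $s$ — the package carries an independent pairwise
implementation (`pairwise_shared_lengths()`) exactly to cross-check the
partition/integration machinery, and the equality to $10^{-9}$ is part of
the test suite.

Three statistics are built from the integrals:

* **iHS** (within population): $\,\mathrm{uniHS}(s) = \ln(iHH_A/iHH_D)$ for
  ancestral and derived core alleles, standardized within bins of derived
  allele frequency $p_s$, because the neutral expectation of uniHS depends
  strongly on $p_s$.
* **XP-EHH** (between populations): the pooled-sample analogue EHHS ignores
  the core allele; $\ln(iES_{pop1}/iES_{pop2})$ is standardized by mean and
  standard deviation, unbinned.
* **Rsb**: like XP-EHH, but each EHHS curve is first normalized by its value
  at the focal marker ($inES = iES/EHHS_{s,s}$), and the standardization
  centers on the *median* while still scaling by the standard deviation
  (taken about the mean, as the statistic's definition literally combines
  the two — a deliberate asymmetry we preserve and test).

## Estimators for unphased and unpolarized data

When phase is unknown, only the two chromosomes within a diploid individual
can be compared: under Hardy–Weinberg proportions the fraction of
individuals homozygous over the whole interval estimates the same
homozygosity. Writing $I^a_{s,t}$ for individuals homozygous for $a$ at $s$
and identical (homozygous) at every marker between $s$ and $t$,

$$\widehat{EHH}^a_{s,t} = I^a_{s,t} / I^a_{s,s}, \qquad
  \widehat{EHHS}_{s,t} = I_{s,t} / I_{s,s}.$$

The unphased EHHS is 1 at the focal marker by construction, so iES and inES
coincide and unphased XP-EHH equals unphased Rsb up to the centering
constant — a package invariant covered by a test. Because far fewer
comparisons support the unphased estimates, a few extremely long shared
haplotypes (which arise even under neutrality) dominate easily. Three
restrictions damp this noise, and are the defaults of
`scan_config("unphased")`:

* at least 10 homozygous sequences (5 individuals) per core allele at the
  focal marker (sample-wise for EHHS; per allele for iHS, on top of the
  usual MAF ≥ 0.05 filter),
* the integration cutoff raised from 0.05 to 0.10,
* integration stops when fewer than 4 sequences (2 individuals) remain
  homozygous.

When ancestral states are unknown, the ancestral/derived log-ratio is
replaced by most-frequent/second-most-frequent
(`allele_mode = "major_minor"`, ties broken towards the lower allele code
for determinism), and standardization is unbinned — binning by minor allele
frequency would mix derived frequencies $p$ and $1-p$, whose neutral
expectations differ. The resulting score distribution is skewed, which is
expected and documented rather than corrected.

## Curve integration: choices at the edges

* **Interpolation.** The default integrates the linearly interpolated curve
  (trapezoids) and stops at the interpolated cutoff crossing; the area above
  zero and below the cutoff up to the crossing is *included* — integration
  stops, the curve is not shifted. `curve_mode = "stepwise"` holds the
  nearer-to-focal value constant; it exists because that definition makes
  iHH equal the mean pairwise shared length and anchors the oracle tests.
* **Boundaries.** A side that reaches the chromosome end holds the last
  value out to the extent and flags the integral as truncated. Truncated
  markers stay in the score table (policy `"flag"`) but are excluded from
  the standardization moments and receive no standardized score, because
  boundary-capped haplotype lengths bias the moments; `"discard"` removes
  them entirely. A side with no markers contributes zero and is truncated.
* **Gaps.** `max_gap_bp` (off by default) stops integration at the last
  marker before any larger inter-marker gap — gap handling is an often
  overlooked parameter of these scans, so it is exposed explicitly rather
  than hidden.
* **Shared-haplotype boundary.** The boundary of a shared haplotype is
  placed at the first *differing* marker's position (not midway between
  markers), and integration starts at the focal marker's own position. A
  missing allele at the focal marker removes the sequence from the
  denominator; a missing allele mid-extension ends that sequence's
  participation in any shared haplotype there (a conservative mismatch that
  never lets missingness inflate homozygosity).

## Candidate regions

Extreme single markers are weaker evidence of a sweep than clusters of
extreme scores. `window_scan()` tiles each chromosome with overlapping
windows (defaults 250 kb width, 50 kb offset, matching common practice for
human-scale marker densities); a window qualifies when it holds more than
`min_markers` markers (default 150; the CLI halves this for unphased iHS,
tracking the roughly halved number of scoreable markers) and at least half
of its *scored* markers are beyond the threshold. Qualifying windows that
overlap or touch are merged. `calibrate_regions()` searches the observed
extremeness values for the largest threshold achieving a requested region
count; merging makes the count non-monotone across plateaus, so an exact
match may not exist and the closest count (preferring the higher threshold)
is returned — the documented tolerance is ±2 on simulated multi-chromosome
genomes. Marker counts use *attempted* markers (flagged ones included) while
the cluster fraction uses scored markers only, so "no markers" and "markers
without scores" remain distinguishable.

## The simulator and what it emulates

`simulate_neutral()` draws each chromosome from a sequential Markov
coalescent (SMC'): the marginal genealogy at every position is an exact
coalescent tree, so Watterson's expected number of segregating sites and the
$1/i$ site-frequency spectrum hold by construction; correlations *along* the
chromosome follow the SMC' approximation of the full ancestral recombination
graph, which is accurate for the homozygosity length scales probed here.
Mutations follow the infinite-sites model with uniform placement, 0 is
ancestral, and output is phased.

`simulate_sweep()` keeps the selective dynamics forward in time: a full
population of $2N$ sequences is drawn from the neutral generator, a single
beneficial mutation (fitness $1, 1+hs, 1+s$; fully dominant by default,
$2Ns = 500$) is injected at the chosen position, and discrete Wright–Fisher
generations with crossover and new mutation run until the allele's
*population* frequency is within ±0.02 of the target (0.5, 0.7 or 0.9), with
rejection sampling over trajectories (loss or overshoot restarts); the
"completed sweep" condition instead waits for fixation plus $0.01 \cdot 4N$
generations. The realized sample frequency is reported separately in the
truth table. Two-population nulls duplicate an ancestral population and let
both copies drift independently for $0.05 \cdot 4N$ generations.

Defaults are a desk-scale version of a human-like setting: $N = 500$
diploids, $L = 1$ Mb, and $4N\mu L = 4NrL = 1000$, i.e. population-scaled
rates of $\theta = \rho = 0.001$ per bp — the same *per-bp* scaled rates as a
classic human simulation, at 1/50 of the chromosome length. This preserves
the two length scales that matter: neutral shared haplotypes of a few kb and
sweep haplotypes of tens of kb, both well inside the chromosome. What the
generator does **not** emulate: recombination hotspots, demography beyond a
constant size and a clean split, gene conversion, and genotyping error — so
green tests certify the statistics' behaviour under the idealized model, not
performance on real data.

One master seed drives everything; per-chromosome seeds are drawn from it by
a fixed counter scheme, so any single chromosome can be reproduced without
regenerating the genome.

## Evaluation against truth

A called region is a true positive when its half-open interval contains a
truly selected site (a single bp); `scan_fdr()` reports
$FDR = 1 - TP/\#regions$. Power is per site: the fraction of true sites
inside at least one region. With the region count fixed by calibration,
FDR + per-region true-positive rate = 1 exactly.
`calibrate_power_threshold()` finds the threshold at which regions called on
a neutral genome cover a requested genome fraction (the "1% falsely
designated as selected" convention), within a 10% relative tolerance —
merging makes exact coverage unattainable. Coverage is quantized in units of
one window, so on small simulated genomes this calibration needs windows
much shorter than a chromosome; the test suite uses 50 kb windows on a
20 Mb neutral genome for exactly that reason.

## Problem sizes used by the test suite

The suite checks the estimator ordering (phased polarized iHS at or below
unphased iHS FDR, with unpolarized in between or above phased) on genomes of
50 chromosomes × 1 Mb with a sweep at 0.7 frequency at each center and
$n = 200$ sampled sequences, over 5 master seeds with region count
calibrated to 50 — one region per chromosome, the scaled-down analogue of
calling 100 regions on 100 chromosomes. Neutral calibration uses 200
replicates for Watterson's estimator and 500 replicates (at high
recombination, where sites are nearly independent and the multinomial
chi-square applies) for the spectrum test at $\alpha = 0.01$. Absolute FDR
values from human-scale 50 Mb × 100-chromosome scans are out of reach at
desk scale by design; the suite asserts the *ordering* of estimators, which
is the transferable claim.

## Known limitations

* The SMC' approximation slightly underestimates long-range linkage
  relative to the full ancestral recombination graph; this affects the tails
  of neutral shared-haplotype lengths, not the marginal site statistics.
* The unphased estimators assume Hardy–Weinberg proportions; inbreeding or
  strong substructure inflates homozygosity and hence the unphased scores.
* Cross-population scores are standardized without regard to allele
  frequencies; when derived frequencies differ systematically between
  populations their expectation is not exactly zero, and no two-dimensional
  binning is attempted (deliberately — bins dominated by differentially
  selected variants would defeat the purpose).
* No genetic-map support: integration is over physical distance, as in the
  simulations the method is validated on.
* No p-values: scores are used as outlier statistics with cluster-based
  region calling, not through the approximate normality of the null.

## A worked miniature

```{r example}
h <- hap_example("two_diploids")
h
cfg <- function(est) scan_config(est, ehh_cutoff = 0, min_support_stop = 0,
                                 curve_mode = "stepwise")
# mean within-individual shared length (unphased view): 35 bp
integrate_curve(ehh_allele(h, 5, 0, "unphased"), cfg("unphased"))$value
# mean all-pairs shared length (phased view): 30 bp
integrate_curve(ehh_allele(h, 5, 0, "phased"), cfg("phased"))$value
# the pairwise oracle agrees with the phased integral
attr(pairwise_shared_lengths(h, 5, 0), "mean_length")
```
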