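---
title: "Models and methods behind regbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind regbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regbind)
```

regbind packages the computational steps used when one bacterial
transcription factor is characterised end to end: mapping in vivo binding
with ChIP-seq enrichment tracks, locating and dissecting the binding site
in vitro with ReDCaT SPR, describing the site's direct-repeat structure,
and quantifying the regulatory consequences by RNA-seq classification and
qPCR. This vignette explains the models, the tunable parameters, the
synthetic-data generators the tests rely on, and the numerical decisions
that were genuinely open.

## ChIP enrichment

The enrichment statistic is a ratio of local to regional mean depth. For a
window of `window` nt (default 30) starting at `s` and advancing in `step`
nt (default 15), the value is the mean depth inside the window divided by
the mean depth over a `background` nt (default 3000) window centred on it.
Dividing by a *local* background rather than the genome-wide mean makes
the statistic robust to the broad coverage waves that replication and GC
biases impose on bacterial ChIP libraries, and makes it exactly scale
invariant — sequencing twice as deep changes nothing.

Decisions where the definition left room:

* **Replicon ends.** The background window is clipped to `[0, length)` and
  averaged over its clipped extent. The alternative — dropping windows
  whose full background does not fit — would discard 1.5 kb at each end of
  every replicon for no statistical gain.
* **Trailing partial window.** Windows exist only where the full `window`
  nt fit; a partial numerator window has no clean interpretation.
* **Zero background.** A window whose background mean is 0 (unmapped or
  empty regions) is masked rather than set to infinity, and masks
  propagate through subtraction and averaging. Averaging over replicates
  uses all unmasked values and masks a window only when every replicate is
  masked.
* **Order of operations.** Replicate enrichment tracks are averaged before
  control subtraction; both operations are per-window linear, so the order
  does not change the result, but one order had to be documented. A single
  control track may be subtracted from samples of several conditions.
* **Topology.** Replicons are treated as linear, with no wraparound — the
  organisms this statistic was built for carry linear chromosomes; for a
  circular replicon the first and last 1.5 kb of background are slightly
  truncated.
* **Region calling.** Maximal runs of at least `min_consecutive`
  (default 2) consecutive unmasked windows at or above the threshold are
  merged into half-open regions from the first window start to the last
  window end. Requiring two consecutive windows suppresses single-window
  Poisson spikes. The caller makes "no binding anywhere" a checkable
  output rather than a visual impression.

### What a planted peak looks like to this statistic

The simulator plants a site as a triangular coverage kernel of half-width
`fragment_width` (default 600 nt): if sonication fragments of length ~F
all contain the bound position, the probability that a fragment also
covers a position x nt away falls linearly to zero at |x| = F, which is
the fragment-overlap geometry of single-site binding. The expected
windowed enrichment at the site centre is then *not* the planted fold:
with the default geometry the 3000-nt background contains the entire
2·600-nt peak, inflating the denominator. Closed form, for fold φ:

* numerator mean: `1 + (φ − 1)(1 − (W/4)/F)` ≈ 9.89 for φ = 10
* background mean: `1 + (φ − 1)·F/B` = 2.8 for φ = 10
* expected ratio ≈ 3.53, i.e. ≈ 2.53 after control subtraction.

`expected_site_enrichment()` exposes this expectation, and the tests
assert convergence to it (location recovery — the subtracted-track
maximum within one fragment width of the planted centre — holds
regardless). Any intuition that the statistic should read back the
planted fold directly only holds when the background is much wider than
the fragment footprint.

## SPR with ReDCaT capture duplexes

ReDCaT (reusable DNA capture technology) anneals each ≤ 40-bp test duplex
to a chip-immobilised biotinylated linker via a constant 20-nt
single-stranded overhang (`CCTACCCTACGTCCTCCTGC`) on the bottom strand, so
the chip is regenerated between test sequences. Because SPR response is
proportional to bound mass, responses to duplexes of different mass are
compared on the %Rmax scale: `Rmax = (Ma/Ml)·Rl·n` for analyte mass Ma,
ligand mass Ml, capture response Rl and stoichiometry n (default one
analyte monomer per duplex), and `%Rmax = 100·Rprotein/Rmax`.

Decisions:

* **Ligand mass convention.** Ml is the mass of the complete captured
  species — both strands including the 20-nt overhang — since that is what
  sits on the chip when Rl is read. Masses use average 5'-OH monomer
  values (dAMP 313.21, dCMP 289.18, dGMP 329.21, dTMP 304.20, minus
  61.96 Da); monoisotopic masses are out of scope.
* **Analyte mass.** Supplied by the caller; if a tagged protein is flown,
  the tagged mass should be supplied.
* **Values above 100 %.** Permitted (noise at saturation) but flagged
  above 120 %, which usually indicates a wrong mass or stoichiometry.
* **Binding-loss threshold.** The footprint walker declares binding lost
  at the first truncation whose %Rmax falls below 20 % of the full-length
  response (configurable); published truncation panels report
  binding/no-binding qualitatively, so the cutoff had to be fixed
  somewhere, and 20 % separates "severely reduced" from "retained" in the
  simulated ladders across the tested energy ranges. If binding is never
  lost on a side, the region end is reported with a warning flag.
* **Tiling layout.** `n` oligos of length `L0` are placed at evenly
  spaced, rounded starts `round(i(L − L0)/(n − 1))`, which pins the first
  tile at 0, the last at the region end, and distributes the overlap
  evenly; exact published overlap schemes vary and are rarely printed.
* **Substitution randomisation.** Replaced repeat spans are overwritten
  with uniformly drawn bases (seeded); a GC-matching fraction is available
  when base composition must be preserved.

Protein properties are computed from sequence: molecular weight as the sum
of average residue masses plus one water, and pI by bisection on the net
charge under the Bjellqvist pKa set (side chains C 9.0, D 4.05, E 4.45,
Y 10.0, H 5.98, K 10.0, R 12.0; C-terminus 3.55; residue-specific
N-terminal pKa) to 0.01 pH. The tests cross-check both against the
independent implementations in seqinr.

## Direct repeats

`scan_consensus()` reports all positions matching a degenerate IUPAC
consensus; `X` is accepted as a synonym of N because operator consensi in
the literature are often written with X at free positions. Mismatches are
counted only at non-degenerate positions. De novo discovery
(`find_direct_repeats()`) enumerates unit lengths 8–14 by default, pairs
same-strand occurrences within `max_span` at Hamming distance ≤ 1, and
filters units below 1 bit/base of composition entropy, since biological
direct repeats of interest sit inside otherwise complex sequence while
homopolymer and dinucleotide runs pair everywhere.

One underlying repeat generates shifted and extended candidate variants
that pay extra mismatches for the shift. Containment-based redundancy
removal alone leaves those variants in the output, so candidates are
ranked by total internal mismatches, then unit length, and accepted
greedily, dropping any candidate whose every member overlaps an accepted
family. This collapses a clean two-copy repeat to exactly one reported
family.

Consensus summaries offer two policies: `minimal-iupac` (the smallest code
covering the observed bases, X when all four occur) and `strict`, which
writes the base only where all members agree and X otherwise — the policy
that reproduces X-notation consensi such as `CGXXCTCAAC` from members that
disagree at the free positions.

## Expression

Volcano classification is deliberately literal: `up` requires log2FC
strictly above 1 *and* P ≤ 0.01 (inclusive); `down` mirrors it. A gene at
exactly log2FC = 1 is not significant; a gene at exactly P = 0.01 is.
The P values are taken as given (unadjusted, as such fixed-cutoff volcano
summaries typically are); an `fdr` column passes through untouched.

The package does **not** re-implement negative-binomial GLM differential
expression — DE tables from edgeR/DESeq2 are inputs. `cpm_ttest_de()` (log2
ratio of group-mean CPM with a 0.5 pseudocount; Welch t-test on log-CPM)
exists only so the classifier can be exercised on synthetic counts, and is
documented as non-equivalent to a proper NB fit. Note one visible artefact
in its output: when all planted changes point the same way, CPM
normalisation absorbs part of the composition shift, so estimated log2
fold changes sit slightly below the planted value (≈ 2.5 for a planted 3
with 5 % DE genes) — the reason real pipelines use TMM-style
normalisation.

qPCR quantification follows the genomic-DNA dilution-series design: an OLS
standard curve `Cq = slope·log10(q) + intercept` per primer pair (at least
three distinct quantities required), amplification efficiency
`E = 10^(−1/slope) − 1`, starting quantities `SQ = 10^((Cq−intercept)/slope)`,
technical replicates averaged on the Cq scale before conversion, target SQ
divided by the group-mean reference-gene SQ ("corresponding samples" read
as per-group means, with per-sample pairing behind a flag), and group
means scaled so the baseline group is exactly 1.

## The synthetic generators, and what passing tests do not show

All generators are pure functions of their arguments including the seed.

* **Genomes/motifs** — i.i.d. bases at a chosen GC fraction; planted
  motifs are independent realizations of the degenerate consensus. Real
  promoters have codon structure, GC skew and overlapping signals; the
  generator only guarantees that planted sites are recoverable and
  chance hits quantifiable.
* **ChIP tracks** — Poisson counts around a flat background times the
  triangular site kernel (fragment half-width 600 nt, matching the
  300–1000 bp, ~600 bp-centred sonication range). No mappability
  structure, no replication-origin coverage gradient, no duplicate reads:
  passing recovery tests shows the statistic behaves as derived, not that
  real libraries are this clean.
* **SPR cycles** — single-site equilibrium occupancy θ = c/(c + KD) with
  `KD = baseline_kd · exp(ΣΔΔG/RT)`, RT = 0.593 kcal/mol (25 °C), Gaussian
  noise on both responses, and the analyte mass (default 28 kDa, a
  plausible His-tagged Xre-family regulator) turning occupancy into
  response units. Repeat ΔΔG values are placeholders chosen for test
  realism — they order affinities sensibly but are not measurements, and
  no kinetic (ka/kd) structure is modelled.
* **Counts** — gamma-spread gene means, two groups, NB sampling with
  dispersion 0.01 by default (biological CV 0.1, the standard figure for
  replicate cultures of a genetically identical organism), planted
  log2 fold changes on a chosen fraction of genes.

## Problem sizes and numerical choices

The test suite runs the enrichment oracle up to 20 kb tracks, ChIP
end-to-end simulations at 20 kb × depth 100, DE recovery at 2000 genes × 3
replicates per group, and 25-replicate convergence checks for the site
expectation — sizes chosen so the full suite completes in well under a
minute while keeping Monte-Carlo tolerances (3σ bounds, 5 % relative
error) meaningful. Exact identities (scale invariance, self-subtraction,
round trips) are asserted at 1e-9–1e-12; cross-implementation agreement
(seqinr pI) at 0.05 pH, reflecting small differences in terminal-pKa
handling. Bisection for pI runs on [0, 14] to 0.01 pH; the net charge is
monotone in pH, so the root is unique.

## Known limitations

* The enrichment caller is a thresholding device, not a peak model; it
  does not compute enrichment significance and is no substitute for
  likelihood-based callers when replicate-aware inference is needed.
* %Rmax analysis assumes a single analyte species of known mass and 1:1
  (or user-specified) stoichiometry; aggregated or partially active
  protein shows up as %Rmax far from 100 at saturation.
* The repeat finder is for short regulatory regions (≤ 10 kb), same-strand
  direct repeats only; inverted repeats and PWM/EM motif discovery are out
  of scope.
* The naive DE path is for exercising the classifier on synthetic data
  only.
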