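---
title: "A discriminative sequence model of nucleosome dyad positioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discriminative sequence model of nucleosome dyad positioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucpattern)
```

## The model

Nucleosomes wrap ~147 bp of DNA around a histone core, and the DNA between
adjacent cores (the linker) is typically AT-richer than the core. Averaged
over many nucleosomes aligned at their dyads (the central base pair of the
wrapped DNA), the per-position nucleotide composition shows broad, slowly
varying oscillations: GC content rises toward the core, the A and C curves
mirror the T and G curves across the dyad, and the extrema of the G and C
curves sit roughly 40 bp to either side of the dyad. `nucpattern`
implements a discriminative model built directly on these positional
patterns.

For a k-mer $m$ (k up to 3) and a window of odd width $W$ centered on a
candidate dyad, the *numeric representation* $N_S^m$ is a length-$W$ vector
with a 1 at the start offset of every exact, possibly overlapping match of
$m$ in the window sequence $S$ (the dinucleotide AA occurs four times, with
overlap, in AAAAA). The *pattern* $P_m$ is the average of $N_S^m$ and
$N_{\bar S}^m$ (the representation of the reverse complement, read in its
own 5'→3' frame) over all training windows, standardized to mean 0 and
variance 1 using population moments. Averaging both strands makes the
patterns of reverse-complementary k-mers exact mirror images,

$$P_{\bar m}(x) = P_m(-x - (k-1)),$$

with the $(k-1)$ shift arising from the start-offset convention; this
identity is distribution-free and the test suite asserts it to $10^{-9}$ on
arbitrary window sets. Because double-stranded DNA makes $m$ and $\bar m$
indistinguishable, the 4 + 16 + 64 k-mers collapse into 2 + 10 + 32 = 44
reverse-complement classes.

A query window is described by three features per class:

* **corr_fwd** — the correlation of the window with $P_m$: the forward
  indicator vector, and the reverse-strand indicator mapped back onto the
  forward axis (equivalently, a 1 at the *end* offset of every $\bar m$
  occurrence), are each standardized and dotted with $P_m$, each dot
  product divided by $W$, and summed. Each term is then exactly a Pearson
  coefficient, so the feature lies in $[-2, 2]$; the unnormalized sum
  differs only by a constant scale that the SVM weights absorb. An
  indicator with zero variance contributes 0.
* **corr_refl** — the same correlation against the reflection of $P_m$
  across the dyad axis (values reversed along the offset axis), capturing
  windows in which individual pattern components appear reversed.
* **count** — occurrences of the class on both strands, which lets the
  classifier distinguish "zero occurrences" from "a true lack of
  correlation".

The coordinate conventions were chosen so that two exact identities hold
for every class and any window: the learning-side mirror identity above
(both strands read in their own frame), and the scoring-side strand-flip
identity

$$\rho(\bar S, P) = \rho(S, \mathrm{reflect}(P)),$$

which requires the reverse-strand indicator to be mapped onto the forward
axis before the dot product. A consequence is that the correlation of a
window with $P_m$ equals its correlation with $P_{\bar m}$, which is why
features are defined per class (44 × 3 = 132 features) rather than per raw
k-mer.

A linear soft-margin SVM (hinge loss, L2 penalty, via `e1071`/libsvm) is
trained on positives (windows centered at dyads) against negatives centered
$L$ bp to either side of each dyad — twice as many negatives as positives —
and the resulting weight vector turns any window into a scalar *dyad
score* $w \cdot x + b$, whose sign classifies and whose magnitude expresses
confidence. The score is purely local: only $W$ bp of sequence enter a
prediction.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `W` | 301 bp | pattern/window width; performance saturates between ~301 and 351 bp, wide enough to see core *and* flanking linkers |
| `k_max` | 3 | longer k-mers multiply parameters exponentially for little gain |
| `L` | 110 bp | dyad-to-linker distance for negatives; discrimination is impossible at 0, peaks near half the repeat length, and degrades as $L$ approaches the neighbouring dyad |
| `smooth` | 11 bp | moving-average width for score traces |
| call window | 141 nt | exclusion window for local-maximum dyad calls |
| artifact interpolation | ±80 bp, 30 bp wide | removes cut-site composition bumps in patterns learned from fully sequenced MNase reads |
| `C` | 1.0 | SVM cost; the choice is this package's (feature scaling makes the fit insensitive to moderate changes) |

Features are standardized per column with training-set population moments
before fitting (counts and correlations live on different scales); the
population convention makes the fit exactly invariant under dataset
duplication with a correspondingly halved cost. The libsvm termination
tolerance is fixed at `1e-4`.

## Dyad calling from reads

For fully sequenced nucleosomal reads, each mapped read is drawn on the
genomic axis as a triangle of height 1 with the read as its base, apex at
the read midpoint (even-length reads place it at the left of the two
central positions, a convention this package fixes); summing the triangles
gives a dyad trace. Every strict local maximum within a centered 141-nt
window is called a dyad; plateaus and exact ties resolve to the leftmost
position, so calls are always at least 71 bp apart. Each call's confidence
is the number of reads overlapping it, and `top_fraction()` produces the
nested high-confidence subsets used to study how positioning consistency
affects discrimination.

## Evaluation

`roc_auc()` sweeps a threshold from the maximum score down, handling tied
scores as diagonal segments so the trapezoidal area equals the Mann–Whitney
statistic; it also reports the true-positive rate at a 10% false-positive
rate, the customary operating point. `loco_crossval()` evaluates each
chromosome with patterns and weights learned entirely from the others —
nothing from the held-out chromosome touches pattern learning or weight
fitting, which the per-fold training-chromosome manifest makes auditable —
and reports per-chromosome and pooled AUCs.

The significance of a learned pattern is quantified against an empirical
null: the observed statistic per nucleotide is the max–min range of its
trace across the 151-bp position-specific frequency matrix (PSFM) of the
dyad-aligned windows, and the null distribution is built from random sets
obtained by jittering every dyad uniformly within ±1000 bp. P-values use
the add-one estimator $(1 + \#\{\Delta_{null} \ge \Delta_{obs}\}) / (1 +
n_{sets})$, so the attainable floor is $1/(1+n_{sets})$; at desk scale the
default is 1,000 sets (the original analysis used 800,000, whose tail it
extrapolated — any such extrapolation here is the user's, and is clearly
an extrapolation, not an empirical p-value).

Spacing structure is examined by `interdyad_histogram()`, which overlays
the successive-distance histogram with the geometric probability mass that
purely random placement at the same mean spacing (default 165 bp, a
typical nucleosome repeat length) would produce. `anchored_profile()`
averages dyad-score traces across aligned, strand-oriented anchors
(transcription starts, repeat midpoints, CTCF-like sites).

`assign_variant()` partitions windows among the four permuted forms of the
canonical pattern (named AGCT, ACGT, TGCA, TCGA after the 5'→3' order of
the four curves' maxima). This correlation deliberately reads *only the
query strand*: the two-strand folded correlation used everywhere else is
provably identical for a variant and its reverse complement (the mono
curves come in mirror pairs), so it cannot separate AGCT from TCGA.
Windows whose best summed correlation does not exceed the threshold
(default 0.2, a choice of this package) fall into the no-match partition.

## The synthetic generator

`generator_spec()` defines everything the simulator does, and one seed
drives all of it (`simulate_genome()` uses `seed`, `simulate_reads()`
`seed + 1`, `simulate_windows()` `seed + 2`), so fixtures are byte-stable.
The planted per-offset profile emulates the qualitative geometry of the
real composition pattern — GC-rich core (Gaussian, amplitude 0.10), an
A-ramp falling 5'→3' (amplitude 0.16) with T its mirror, G/C bumps of
amplitude 0.20 at ∓40 bp, an optional 10-bp sinusoid (amplitude 0.05, on
by default, as in high-resolution yeast data), and optional cut-site
artifact bumps at ±80 bp — and is reverse-complement symmetric by
construction. Background bases are i.i.d. at GC fraction 0.4; dyads are
placed at a fixed (default) or geometric spacing with mean 165 bp; reads
are Normal(156, 10) in length (truncated at 100 bp) with Gaussian midpoint
jitter (sd 5) at depth 20.

Two deliberate choices:

* **Amplitudes.** The planted amplitudes are several-fold stronger than
  the subtle genome-average composition biases of real chromatin. Real
  analyses compensate weak per-position signal with enormous dyad counts
  (tens of thousands to hundreds of thousands); a desk-scale simulation
  with a couple of thousand dyads needs a proportionally cleaner signal to
  exercise the same qualitative behaviour (AUC well above 0.9 at `L` =
  110, the AUC(L) peak near half the repeat length, exact 0.5 at `L` = 0).
  Passing tests on this generator therefore demonstrate correctness of
  the machinery and recoverability of planted structure, not the effect
  size expected on real genomes.
* **Overlapping profiles.** At a 165-bp repeat with a 301-bp profile,
  neighbouring profiles necessarily overlap — exactly as real nucleosome
  windows overlap their neighbours. Each base follows the profile of its
  *nearest* dyad; the generator refuses only profiles wider than the mean
  spacing itself. A consequence is that genome-embedded windows show
  deterministic neighbour structure beyond ±82 bp, which is why clean
  parameter-recovery checks draw windows directly from the profile with
  `simulate_windows()`.

What the generator does *not* emulate: mappability and GC sequencing bias,
repeat families, transcription-factor competition, statistical positioning
against barriers, and the strand-offset short-tag geometry of
ChIP-seq-style data (dyad tables for such data are accepted as input
instead).

## Numerical choices and degenerate inputs

* Standardization uses population moments everywhere; a zero-variance
  pattern ("degenerate pattern") is an error, while zero-variance
  *indicator vectors* contribute 0 to correlations by convention.
* Windows that overrun a chromosome or contain N are skipped, never
  padded — padding would distort positional frequencies. Dropped windows
  keep their training mates.
* Even-length reads place the triangle apex at the left-central position;
  trace values are computed at integer positions.
* Ties in dyad calling resolve leftmost; ties at a `top_fraction()` cut
  break by (confidence desc, chrom, pos); tied best variants are
  no-match.
* Coordinates are 0-based throughout, dyads are the central nucleotide,
  read intervals are half-open — matching BED inputs.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on generated
data: two 200-kb chromosomes (~2,400 dyads) for cross-validation, 10,000
profile-drawn windows for parameter recovery, 1,000 random 301-mers for
counting oracles, a 100-kb contig at 20× depth for the dyad caller, 20
runs of 200 null sets (plus one run of 1,000) for the significance null,
and ~10,000 Bernoulli-placed positions for the spacing analysis. These
sizes were chosen as the smallest at which the sampling noise of each
check is comfortably below its assertion margin.

## Known limitations

The model scores positions independently; it does not enforce
non-overlap of adjacent nucleosomes (the natural dynamic-programming or
state-model post-processing layer is out of scope here). The NPS-style
caller for strand-offset short tags is likewise out of scope — externally
produced dyad tables serve that role. AUCs obtained on the synthetic
generator are not forecasts of performance on real genomes.
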