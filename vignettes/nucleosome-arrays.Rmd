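---
title: "Quantifying barrier-aligned nucleosome arrays and the remodeler ruler model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying barrier-aligned nucleosome arrays and the remodeler ruler model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucruler)
```

## The problem

Chromatin remodelers with spacing activity (ISW1a, ISW2, Chd1, INO80) convert
irregular nucleosomes into regular arrays that are phased relative to
"barriers": DNA-bound general regulatory factors (GRFs) such as Reb1,
double-strand break (DSB) ends, or neighboring nucleosomes. Two quantities
characterize such arrays in MNase-seq dyad coverage aligned at barrier sites:

* **distance to barrier** — from the barrier center to the proximal flank of
  the first nucleosome (flank = dyad − 73 bp for a 147 bp footprint), and
* **linker length** — flank-to-flank distance between adjacent nucleosomes,
  `linker_i = |peak_{i+1} − peak_i| − 147`.

This package implements (i) the processing recipe that extracts these
features from mapped single-end reads, (ii) a stochastic model of how a
remodeler-intrinsic "ruler" can set them by biasing nucleosome sliding
direction as a function of the distance to a barrier, and (iii) a synthetic
read generator with known ground truth so that every stage is testable
end-to-end without external data.

## Read processing and composite quantification

Mapped 50 bp single-end reads are shifted 73 bp in their 3' direction so the
shifted 5' position marks the nucleosome dyad, then replaced by a fixed 50 bp
dyad-centered fragment `[dyad − 25, dyad + 25)`. Whether the original
experiment extended reads symmetrically or directionally from the shifted
position is not knowable from the data processing description alone; we
center the window because downstream peak maxima are interpreted as dyads,
and the residual ±0.5 bp asymmetry of an even window cancels between plus-
and minus-strand reads and between up- and downstream averaging (see the
tie-break rule below). Fragments crossing a chromosome end are dropped, not
clipped, which keeps total coverage exactly 50 × the retained fragment count
— an invariant the tests assert.

Coverage is aligned at barrier sites into a sites × 2001 bp matrix (offsets
−1000..+1000, orientation-flipped for minus-strand sites), each row is
divided by its own mean ("normalized per site"; the mean is chosen so that
every site contributes equal weight and the composite is a weighted occupancy
shape), and columns are averaged into the composite profile. Sites whose
window does not fit their chromosome are excluded rather than zero-padded, to
avoid edge artifacts.

Site selection and grouping utilities mirror common practice: sites can be
ranked by the mean of an external signal in a 120 bp window at offsets
`[-280, -160)` (i.e., 160 bp upstream of the alignment point) with the top
12.5% selected (mean rather than sum — monotone-equivalent for a fixed
window), and GRF sites can be partitioned by motif orientation relative to
genes starting within 400 bp downstream (sense / antisense / divergent
promoter).

## Peak calling

The only published constraint on nucleosome peak determination in composites
is that maxima are called; the concrete algorithm here is an outward-seeded
windowed argmax, with every knob exposed in `peak_call_params()`:

* centered moving-average smoothing (`smooth_window`, default 15 bp, odd;
  edges handled by replication),
* first downstream peak = argmax over `[30, 280]` (`min_first_offset` keeps
  the barrier's own footprint out of the search),
* peak *k+1* = argmax over `[peak_k + 100, peak_k + 250]`, bracketing one
  nucleosome repeat (147 bp footprint plus 0–100 bp linker),
* calling stops when the window leaves the profile or a candidate falls below
  `min_prominence_fraction` (default 0.1) of the first peak's height,
* the upstream side is processed as a mirror image.

Tied maxima need care because jitter-free dyad coverage is a flat-topped
plateau (a 50 bp rectangle per dyad): a contiguous run of tied maxima
resolves to its center, which lands exactly on the dyad and makes the
recovered peak position invariant to the smoothing window (the tests vary it
over 9/15/21 bp); tied runs that are **not** contiguous resolve to the
smallest |offset|. A profile with no structure above the floor (e.g., an
unbiased ruler's uniform stationary density) yields an empty peak set rather
than an arbitrary argmax. Sub-bp interpolation of maxima is deliberately not
performed; all reported features are integer bp. At realistic depths
(hundreds of sites, ~100 reads per nucleosome, 15 bp jitter) individual peak
positions carry roughly ±1–2 bp of sampling noise, so differences between
up- and downstream values of a linker can reach a few bp even for perfectly
symmetric generative processes.

Up/downstream averaging happens **after** per-side feature computation, not
on the profiles, so an asymmetric peak height does not bias the averaged
distances.

## The synthetic generator

The generator emulates the geometry being measured: for each barrier site,
nucleosome *k* on the downstream side has mean dyad
`center + phasing + 73 + (k − 1)(147 + linker)`, mirrored upstream; defaults
(300 sites, phasing 80 bp, linker 60 bp, 3 nucleosomes per side, 100 reads
per dyad, balanced strands) match the scale of the in vitro reconstitution
conditions this methodology targets. Gaussian positional jitter (default
sd 15 bp — a modeling choice; the empirical spread of reconstituted
nucleosomes is not a published number) is applied independently per
nucleosome so the ground-truth mean spacing equals the parameter; a
cumulative ("random register") mode is available behind a flag. Jittered
dyads that would overlap are pushed apart to exactly one footprint by
isotonic regression on packing-transformed positions — the minimal
order-preserving L2 displacement. Reads invert the processing convention
exactly (plus 5' end at `dyad − 73`, minus at `dyad + 73`), which gives a
bit-exact round trip through `shift_reads_to_dyads()`; this identity is one
of the acceptance checks.

What the generator does **not** emulate: MNase sequence preference and
digestion-degree effects, sequence-dependent nucleosome positioning,
occupancy heterogeneity between sites, sub-nucleosomal and di-nucleosomal
fragments, and mapping artifacts. Passing recovery tests therefore
demonstrates correctness of the measurement pipeline, not robustness to
every bias of real MNase-seq.

## The ruler model

A remodeler ruler is modeled as a position-dependent bias on 1 bp sliding
moves of hard-core nucleosomes on a lattice with fixed barriers. For a gap
*d* between a nucleosome flank and the nearest obstacle edge on one side:

* region A (`0 ≤ d < a`): sliding toward the obstacle is disfavored,
  `r_toward = r0(1 − β)`, away favored `r_away = r0(1 + β)`;
* region B (`a ≤ d < a + b`): the reverse;
* region C (`d ≥ a + b`): unbiased, `r0` each way.

Three modes cover the qualitative variants: `reciprocal` (above; the total
rate `r_toward + r_away = 2 r0` is constant), `asymmetric` (only the toward
rate is modulated), and `kinetic_release` (reciprocal, with both rates scaled
by `1 − release_depth` exactly at `d = a`, making the equilibrium point a
total-rate minimum — the kinetic-release picture of positioning at the
locally poorest substrate). The published curves are schematic; the sharp
two-level parameterization is this package's concrete instantiation, with
region widths, bias, and mode all exposed because their true shapes are an
open experimental question.

**Rate composition.** When a nucleosome has obstacles on both sides, each
side's gap contributes an independent multiplicative factor:
`rate(left move) = r_toward(d_L) · r_away(d_R) / r0`, and symmetrically. With
a single barrier this reduces exactly to the birth–death chain
`(r_toward(d), r_away(d))` on the gap coordinate, and with two obstacles both
gaps act without any interaction term — the simplest composition consistent
with centering between two barriers.

**Equilibrium placement.** Detailed balance gives the stationary density in
closed form for a single nucleosome. With piecewise-constant rates the ratio
`π(d+1)/π(d) = r_away(d)/r_toward(d+1)` equals 1 exactly across the A/B
boundary, so reciprocal and asymmetric modes have an exact two-way tie of the
mode at `d = a − 1` and `d = a`; kinetic release breaks the tie in favor of
`d = a`. Tests and acceptance checks therefore require the mode within 1 bp
of `a`, which is the resolution the model itself supports.

**Simulation and oracles.** The simulator is a Gillespie continuous-time
Markov chain (compiled inner loop, R's RNG, time-weighted occupancy after a
burn-in). It is validated against two independent exact solutions computed in
plain R: the closed-form birth–death stationary distribution (single
nucleosome) and a sparse linear solve of the full master-equation generator
over all hard-core configurations (multi-nucleosome; capped at 2 × 10^5
configurations, beyond which the error message points to the simulator).
Barriers partition the lattice into independent segments, so the exact
solution factorizes per segment.

**Initialization and metastability.** The biased chain is strongly
metastable: a nucleosome captured at one barrier takes ~((1+β)/(1−β))^b
attempts to escape region B, so finite runs started far from a barrier carry
a transient and two-barrier runs may never commute between basins at large
β·b. Stationary quantities are therefore measured from chains initialized at
the equilibrium spacing (flank at gap `a`, or evenly packed when the domain
is too crowded) with a 10% burn-in; the two-barrier symmetry test uses a
narrow region B so the chain commutes within the simulated horizon. None of
this affects the exact oracles, which are what the simulator is compared to.

**Model properties checked.** With a = 40, β = 0.5: the steady-state linker
next to a DNA end stays at the ruler reach for N = 3, 6, 10 nucleosomes on a
2500 bp domain (clamping — density-independent spacing) and drops below it at
N = 14, where N(147 + 40) exceeds the domain (density response). Occupancy
profiles feed the same peak caller and feature quantification as MNase-seq
composites (`steady_state_features()`), with zero-density flanks trimmed so
support edges are not mistaken for peaks.

## Problem sizes and runtimes

The test suite and acceptance script use 300 sites × 3 nucleosomes per side ×
100 reads (the generator's default study conditions), 10^6 Gillespie events
for the single-nucleosome oracle comparison (L = 500), 2 × 10^7 events for
the reduced-footprint two-nucleosome comparison, and 4 × 10^5 time units per
density point of the clamping scan — sizes chosen so the whole suite runs in
well under a minute of compute while keeping Monte-Carlo error far from the
acceptance margins.

## Known limitations

* Features are measured on composites, not per locus; occupancy and
  positioning are not deconvolved.
* The ruler model is a caricature: point-like rate switches, 1 bp steps
  (step size is a parameter), rigid footprints, no eviction/exchange, no
  remodeler binding competition, and "soft" barriers only via a reduced
  effective footprint.
* The generator's jitter default (15 bp) is a modeling choice, and linker
  calling beyond the ±1 nucleosomes degrades at low coverage exactly as it
  does in real low-density reconstitutions.
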