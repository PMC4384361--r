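---
title: "Methods: wavelet analysis of polymerase kinetics with pausewave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet analysis of polymerase kinetics with pausewave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pausewave)
```

## The measurement and the question

A real-time single-molecule sequencer watches one DNA polymerase copy one
template and reports, for every incorporated base, the interpulse duration
(IPD): the seconds elapsed since the previous incorporation pulse. The IPD
track is a per-read kinetic signal aligned to sequence. Two questions
structure this package:

1. At which length scales does polymerase speed covary with nucleotide
   composition and with insert errors (wrong bases inserted into the read)?
2. Does a specific sequence pattern — a G-quadruplex motif, a Z-DNA-prone
   (CG)ₙ repeat, any regular expression over DNA — slow the polymerase as it
   passes, and at which base does the stall sit?

Both are answered with the Haar wavelet transform, in two different guises.

## The decimated Haar transform

For a signal of power-of-two length $N$, the low-pass pair
$h = (1/\sqrt2, 1/\sqrt2)$ and high-pass pair $g = (1/\sqrt2, -1/\sqrt2)$
are applied recursively: at the finest scale
$s^{(2)}_k = (x_{2k-1} + x_{2k})/\sqrt2$ and
$d^{(2)}_k = (x_{2k-1} - x_{2k})/\sqrt2$, and each coarser level transforms
the previous level's smooth coefficients. We label scales by the block
width in nucleotides ($2, 4, \dots, N$), not by the dyadic level index, so
the scale-$w$ smooth coefficient $k$ equals $w^{-1/2}$ times the sum of
block $k$ and the detail coefficient the normalized contrast between the
two half-blocks. Two identities anchor the numerics and are enforced by
tests:

* **Parseval**: $\sum x^2$ equals the total squared coefficient mass
  (details plus the final smooth), to $10^{-9}$ relative.
* **Orthonormality**: for i.i.d. standard-normal input, detail coefficients
  at every scale have mean $\to 0$ and second moment $\to 1$. This is why
  contrasting variation *across* scales is meaningful: plain
  window-averages shrink with window size by the law of large numbers,
  wavelet details do not.

The per-scale power fraction
$\mathrm{Power}_w = \sum_i (d^{(w)}_i)^2 / \sum_w\sum_i (d^{(w)}_i)^2$
summarizes where a track's variation lives. It is undefined for a constant
signal (zero detail energy); the package raises an error there rather than
returning NaN.

`haar_decompose()` requires a power-of-two length and refuses anything
else: trimming is the caller's explicit, visible act
(`concatenate_and_trim()`), never an implicit padding that would fabricate
data.

## Scale correlation of composition and kinetics

`correlate_tracks()` consumes six aligned tracks — the IPD, the insert
count, and four 0/1 nucleotide indicators — built by concatenating all
reads longer than 1,000 nt (strict inequality) in input order and trimming
the tail to the largest power of two at or below $2^{23}$. Coefficients
that straddle read boundaries are kept: the handful of discontinuities per
track is negligible against millions of positions, and the boundary
offsets are recorded and a `mask_boundaries` flag (default off) drops
boundary-spanning coefficients for sensitivity analysis. Pearson's
product-moment correlation is computed per unordered track pair per scale,
separately for smooth and detail coefficients; zero-variance coefficient
vectors (e.g. an absent base) yield a *missing* correlation, never a fake
zero. IPDs enter in raw seconds; a clearly-labelled `log_ipd` switch
applies `log1p` first as an extension, not the default.

The default reporting ceiling is scale 2048 (additionally bounded by half
the track length). Coarser scales are computable but their few coefficients
make correlations noisy.

## Causal smoothing and pause profiles

The decimated transform is shift-variant and attributes coefficients to
blocks, not bases. For profiling a window around a pattern site we instead
use a non-decimated (one coefficient per position) Haar smooth with a
deliberate asymmetry: the standard non-decimated transform at position $i$
sums $x_i, x_{i+1}, \dots$ — downstream bases the polymerase has not yet
synthesized. Reversing each read before transforming flips this into a
trailing window,
$s^{(2)}_i = (x_{i-1} + x_i)/\sqrt2$, so a pause is attributed to the base
at which it occurs and the bases *already* synthesized. The first
$w - 1$ positions of a read have no full trailing window and are reported
as undefined — padding (periodic or reflective) would invent kinetics
across read starts. Smooths are always computed within a single read,
never across read or window boundaries.

`find_sites()` scans a regular expression over the forward sequence and,
independently, over the reverse complement, reporting matches in forward
0-based half-open coordinates with a strand. Leftmost non-overlapping
semantics are the default; an `overlapping` flag restarts the scan one
position after each match start for dense tandem repeats. A palindromic
pattern (e.g. `CGCGCGCGCG`) therefore yields paired sites on both strands —
the doubling that turns 9 genomic regions into 18 strand-specific ones.

`extract_profiles()` aggregates, per window position, the raw IPD and the
2-nt/4-nt causal smooths over all (site, read) pairs where the read
synthesizes the site's strand and covers the position (partial coverage
contributes only covered positions; nothing is imputed). Strand separation
is strict — a pattern and its reverse complement share no observations —
because pausing is expected to be strand-asymmetric: a G-rich template
tract can fold into a quadruplex on one strand while its complement does
nothing. Summary statistics are the count, the mean (the plotted "average"
is a plain mean, and is labelled as such), and quantiles at 0.90 and 0.95
by default. The quantile rule is fixed to linear interpolation of order
statistics with rank $h = (n-1)p + 1$ (R's type 7), so results are
reproducible across implementations. The window is 128 nt with the pattern
start anchored at $\lfloor (W - \text{pattern length})/2 \rfloor$ by
default; both are configurable since no canonical anchor exists for
variable-length matches (the longest match length is used for the default
anchor).

## The simulator: what it emulates, what it does not

`simulate_reference()` / `simulate_reads()` generate the study conditions
every test runs under:

* **Baseline IPD**: log-normal per position, median 0.145–0.155 s by base
  identity, log-sd $\sigma = 1$. The medians put typical IPDs near 0.15 s
  with a heavy right tail under which IPDs beyond 1 s are rare, matching
  the background kinetics the analyses assume; the ±3% spread across bases
  keeps base identity a real but deliberately small kinetic covariate, so
  that composition explains only a little of the per-position variance and
  a pause-free window is statistically flat at desk-scale read depths.
* **Pauses**: at a fixed synthesis offset from each occurrence of a motif
  on the synthesized strand, with probability `p_pause` an
  Exponential(mean `tau`) duration is *added* to the baseline — structure
  resolution time adds to normal incorporation time, and the exponential
  supplies the heavy tail that pause quantiles key on. Motif occurrences
  are found by exact matching on both strands, so a palindromic motif
  pauses both strands symmetrically and a (GGC)ₙ-type motif pauses only
  the strand that carries it.
* **Inserts**: Poisson per position (default rate 0.01), recorded as the
  count of inserted bases immediately *following* an aligned position.
* **Reads**: uniform start, uniform length in a range, Bernoulli(1/2)
  strand; reverse-strand reads store the reverse complement of the forward
  slice in synthesis order.

Determinism: one Mersenne–Twister stream per operation, seeded from the
config (`seed` for the reference, `seed + 1` for reads) with a documented
draw order, making every output byte a pure function of the seed. The RNG
kind is recorded in run metadata.

The simulator does **not** emulate: mismatches or deletions, context-
dependent (dinucleotide or longer) kinetic signatures, modified bases, or
inter-molecule rate heterogeneity. Passing tests therefore demonstrate
that the pipeline recovers planted pause structure under a clean
heavy-tailed null — not that any particular biological structure forms in
real data, which the profiling method deliberately does not claim to
detect statistically.

## Numerical and design choices

* Double precision throughout; closeness tests at $10^{-9}$–$10^{-12}$ as
  stated per invariant, $10^{-10}$ relative for round trips.
* The Haar filter is fixed; there is no filter plug-in interface. The
  smooth half of the analysis is what the profiling uses, so non-decimated
  *detail* coefficients are not produced.
* Interchange format: a TSV with columns
  `read_id ref_name ref_pos strand base ipd_s inserts`, 0-based forward
  coordinates, rows per read contiguous in synthesis order, floats at 6
  significant digits. `N` bases carry all-zero indicators and stay in the
  tracks to preserve positional alignment.
* Concatenation order is input file order, and trimming removes the tail;
  both choices are arbitrary but documented, which is what reproducibility
  needs.
* Pause-free-window flatness is judged by per-position two-sided Wilcoxon
  rank tests against the pooled out-of-pattern background with Holm
  correction across the window at family level 0.01: a window of ~128
  uncorrected tests would reject somewhere by construction.
* Problem sizes in the test suite (reference 1.2–2.5 kb, 30–500 reads,
  tracks up to $2^{16}$) are chosen so the full suite exercises every
  default — including the >1,000 nt read filter and scale-2048 ceiling —
  at desk scale; the track cap of $2^{23}$ is exercised through its
  trimming logic rather than by allocating 8M-position tracks.

## Known limitations

* Reads are taken as pre-aligned; alignment itself, and the sequencer's
  native container formats, are out of scope. Data arrive through the TSV
  interchange format only.
* With pause probability near 0.1, the 90% quantile of the pause-position
  IPD mixture sits at the lower edge of the pause component, so q90-based
  contrast between pause and background positions is conservative; the
  0.95 level, or the mean, separates more sharply when pauses are that
  rare.
* Correlations are reported without significance testing or multiple-
  testing control, matching the exploratory intent of the scale
  correlation display.
* The profiler pools (site, read) observations into one set of quantile
  bars; per-site heterogeneity is examined by profiling single-site subsets
  of the site table, and a read spanning two nearby sites contributes once
  per site.
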