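# pausewave

Multi-scale wavelet analysis of single-molecule polymerase kinetics.

Real-time single-molecule sequencers report an interpulse duration (IPD,
in seconds) for every incorporated base: the time the polymerase waited
between successive incorporation pulses. Long IPDs mean the polymerase
paused, and sequences able to adopt non-B-DNA conformations — G-quadruplexes
in G-rich tracts, Z-DNA in alternating purine–pyrimidine repeats, hairpins
in inverted repeats — are prime suspects for causing such pauses. `pausewave`
is for researchers who want to ask, from aligned per-read kinetics: *how
does polymerase speed relate to sequence composition at different length
scales, and does a particular sequence pattern slow the polymerase down?*

## The method

Both analyses rest on the orthonormal Haar wavelet transform. For a signal
*S* = {*s*₁, …, *s*_N} (N a power of two), the decimated transform applies
the low-pass filter *h* = (1/√2, 1/√2) and high-pass filter
*g* = (1/√2, −1/√2) recursively, producing smooth coefficients
*s*ₖ^(w) (scaled local sums) and detail coefficients *d*ₖ^(w) (scaled local
contrasts) at dyadic scales w = 2, 4, …, N; e.g.
*s*₁^(2) = (*s*₁ + *s*₂)/√2 and *d*₁^(2) = (*s*₁ − *s*₂)/√2. Orthonormality
means white noise has E(*d*) = 0 and E(*d*²) = 1 at *every* scale, so
variation can be compared across scales without the loss of power that
plain window-averaging causes.

**Scale correlation.** Reads longer than 1,000 nt are concatenated, trimmed
to a power of two, and converted into six aligned tracks: the IPD, the
insert-error count, and four 0/1 nucleotide indicator vectors (ACTG ↦
A = {1,0,0,0}, C = {0,1,0,0}, T = {0,0,1,0}, G = {0,0,0,1}). Each track is
Haar-decomposed once and every pair is correlated (Pearson) at every scale,
separately for smooth and detail coefficients, with the per-scale power
fraction Power_w = Σᵢ(*d*ᵢ^(w))² / Σ_wΣᵢ(*d*ᵢ^(w))² on the diagonal.

**Pause profiling.** A DNA pattern given as a regular expression (e.g. the
stable G-quadruplex pattern `(GGG(.){1,7}GGG(.){1,7}GGG(.){1,7}GGG)`) is
scanned on both strands of the reference. Around each site, reads
synthesizing that strand contribute their raw IPDs, plus 2-nt and 4-nt
causal wavelet smooths computed *within* each read — a trailing-window
variant of the non-decimated transform (obtained by reversing the read
before transforming) so that a pause is attributed to the base at which it
occurs and never to bases the polymerase has not yet reached. Per window
position the count, mean, 90% and 95% quantiles are reported.

A fully seeded simulator generates references and aligned reads with
log-normal baseline IPDs, base-identity-dependent mean shifts, rare
exponential pause events at chosen motif offsets, and Poisson insert
errors — so the whole pipeline is testable without any sequencer download.

## Worked example

```r
library(pausewave)

# a 1.5 kb reference carrying a (GGC)3GG repeat, and 500 reads in which
# 30% of polymerases pause (mean 4 s) at the repeat's first cytosine
cfg <- simulation_config(
  seed = 42, ref_length = 1500, n_reads = 500, read_length = c(1000, 1100),
  motifs = list(list(sequence = "GGCGGCGGCGG", position = 700)),
  pauses = list(list(offset = 2, p_pause = 0.3, tau = 4)))
ref <- simulate_reference(cfg)
sim <- simulate_reads(ref, cfg)

sites <- find_sites(ref, "GGCGGCGGCGG")
sites
#>             ref start end strand         seq
#> 1 synthetic_ref   700 711      + GGCGGCGGCGG

prof <- extract_profiles(sites[sites$strand == "+", ], sim$reads)
raw <- subset(prof, track == "raw")
raw[raw$position %in% 59:61, c("position", "count", "mean", "q90", "q95")]
#>    position count      mean       q90       q95
#> 60       59   256 0.2478721 0.4711431 0.6348761
#> 61       60   256 1.3672373 4.0800599 6.8203887
#> 62       61   256 0.2528445 0.5261942 0.7637556
```

The pattern starts at window position 58, so position 60 is its first
cytosine: the mean IPD jumps from ~0.25 s to ~1.4 s there, and the 90%/95%
quantiles show that 10% of reads waited longer than ~4.1 s — the classic
signature of a polymerase stalling at a structure-forming repeat, while the
neighbouring positions stay at background speed.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/pausewave.R simulate  --seed 42 --out sim \
    --motif GGCGGCGGCGG@700 --pause 2:0.3:4
Rscript inst/scripts/pausewave.R scan      --fasta sim/reference.fasta \
    --kinetics sim/kinetics.tsv --pattern "GGCGGCGGCGG" --out scan
Rscript inst/scripts/pausewave.R correlate --kinetics sim/kinetics.tsv --out corr
```

## Documentation

The methods vignette (`vignettes/pausewave-methods.Rmd`) describes the
transform conventions, the strand and coordinate model, the simulator's
assumptions and limits, and the numerical choices (quantile rule, boundary
policy, tie-breaks).
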