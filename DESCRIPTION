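Package: pausewave
Title: Multi-Scale Wavelet Analysis of Single-Molecule Polymerase Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relates real-time single-molecule polymerase kinetics (interpulse
    durations, IPD) to DNA sequence composition using a Haar wavelet
    multiresolution decomposition, and profiles polymerase pausing around
    regex-defined sequence patterns such as G-quadruplex and Z-DNA motifs.
    Provides a decimated Haar transform with per-scale power, a causal
    (trailing-window) non-decimated smooth for nucleotide-level attribution,
    scale-wise Pearson correlation of kinetic and nucleotide-composition
    tracks, pattern-site discovery on both strands of a reference, windowed
    mean/quantile pause profiles, and a seeded simulator of aligned kinetic
    reads with controllable pause events for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    data.table,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
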