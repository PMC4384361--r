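# Seeded generator of synthetic references and aligned kinetic reads.
#
# The generator emulates the statistical structure the analyses assume:
# a fast log-normal baseline IPD with small base-identity-dependent shifts,
# rare heavy-tailed (exponential) pause events at fixed offsets from motif
# occurrences on the synthesized strand, and sparse Poisson insert errors.
#
# RNG discipline: Mersenne-Twister, one stream per operation, seeded from
# the config (simulate_reference uses `seed`, simulate_reads uses
# `seed + 1`). Draw order in simulate_reads, per read in order: length,
# start, strand, the per-position baseline IPD vector, pause Bernoulli and
# exponential draws for each overlapped pause position in synthesis order,
# then the per-position insert counts. This makes every output byte
# reproducible from the seed.

#' Build a simulation configuration
#'
#' Defaults describe a whole-genome-amplified-like experiment at desk
#' scale: uniform base composition, a log-normal baseline IPD with median
#' 0.145-0.155 s depending on base identity (a deliberately small spread, so
#' composition explains only a little of the kinetic variation) and log-sd 1
#' (heavy right tail, IPDs over 1 s are rare), and sparse insert errors.
#'
#' @param seed Integer RNG seed.
#' @param ref_length Reference length in nucleotides.
#' @param base_probs Probabilities for A, C, G, T (must sum to 1).
#' @param motifs List of `list(sequence =, position =)` overwriting the
#'   random reference at the given 0-based positions.
#' @param n_reads Number of reads to simulate.
#' @param read_length Length-2 vector, uniform integer read length range.
#' @param mu_base Named log-means (seconds) of the baseline IPD per base
#'   identity (`A`, `C`, `G`, `T`; `N` falls back to their mean).
#' @param sigma Log-sd of the baseline IPD.
#' @param pauses List of `list(offset =, p_pause =, tau =)`: at synthesis
#'   offset `offset` (0-based) from the start of each motif occurrence on
#'   the synthesized strand, with probability `p_pause`, an
#'   `Exponential(mean = tau)` pause in seconds is added to the baseline.
#' @param insert_rate Poisson rate of inserted bases per position.
#' @param ref_name Reference record name.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              ref_length = 4000L,
                              base_probs = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25),
                              motifs = list(),
                              n_reads = 200L,
                              read_length = c(400L, 800L),
                              mu_base = log(c(A = 0.145, C = 0.155,
                                              G = 0.152, T = 0.148)),
                              sigma = 1,
                              pauses = list(),
                              insert_rate = 0.01,
                              ref_name = "synthetic_ref") {
  if (abs(sum(base_probs) - 1) > 1e-8 || any(base_probs < 0)) {
    stop("base_probs must be non-negative and sum to 1", call. = FALSE)
  }
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (insert_rate < 0) stop("insert_rate must be >= 0", call. = FALSE)
  for (p in pauses) {
    if (p$p_pause < 0 || p$p_pause > 1) {
      stop("p_pause must lie in [0, 1]", call. = FALSE)
    }
    if (p$tau <= 0) stop("tau must be > 0", call. = FALSE)
  }
  if (length(read_length) != 2L || read_length[1] > read_length[2]) {
    stop("read_length must be c(min, max) with min <= max", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), ref_length = as.integer(ref_length),
                 base_probs = base_probs, motifs = motifs,
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 mu_base = mu_base, sigma = sigma, pauses = pauses,
                 insert_rate = insert_rate, ref_name = ref_name),
            class = "simulation_config")
}

#' Simulate a reference sequence
#'
#' I.i.d. bases from `base_probs` with each configured motif overwritten at
#' its position. Deterministic given `config$seed`.
#'
#' @param config A `simulation_config`.
#' @return A `reference_seq`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  bases <- sample(c("A", "C", "G", "T"), config$ref_length, replace = TRUE,
                  prob = config$base_probs)
  for (m in config$motifs) {
    mseq <- strsplit(toupper(m$sequence), "")[[1]]
    if (m$position < 0 || m$position + length(mseq) > config$ref_length) {
      stop("motif '", m$sequence, "' at position ", m$position,
           " extends past the reference end", call. = FALSE)
    }
    bases[m$position + seq_along(mseq)] <- mseq
  }
  structure(list(name = config$ref_name,
                 sequence = paste(bases, collapse = "")),
            class = "reference_seq")
}

# Occurrences of each configured motif on both strands of the reference.
# Returns, per strand, the sorted synthesis-axis coordinates at which a
# pause may fire, with the motif and its forward-axis site start attached.
# A "+" occurrence at forward start s puts pause offset o at forward
# coordinate s + o; a motif occurring on the reverse strand (i.e. its
# reverse complement found on the forward sequence at [s, e)) puts offset o
# at forward coordinate e - 1 - o.
pause_positions <- function(reference, config) {
  out <- list(`+` = NULL, `-` = NULL)
  if (!length(config$pauses) || !length(config$motifs)) return(out)
  seqs <- unique(vapply(config$motifs, function(m) toupper(m$sequence),
                        character(1)))
  rows_f <- list(); rows_r <- list()
  for (mseq in seqs) {
    hits <- scan_pattern(reference$sequence, mseq, overlapping = FALSE)
    rc_hits <- scan_pattern(reference$sequence, revcomp(mseq),
                            overlapping = FALSE)
    for (p in config$pauses) {
      if (nrow(hits)) {
        rows_f[[length(rows_f) + 1L]] <- data.frame(
          motif = mseq, site_start = hits$start,
          offset = p$offset, fc = hits$start + p$offset,
          p_pause = p$p_pause, tau = p$tau, stringsAsFactors = FALSE)
      }
      if (nrow(rc_hits)) {
        rows_r[[length(rows_r) + 1L]] <- data.frame(
          motif = mseq, site_start = rc_hits$start,
          offset = p$offset, fc = rc_hits$end - 1L - p$offset,
          p_pause = p$p_pause, tau = p$tau, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows_f)) {
    df <- do.call(rbind, rows_f)
    out$`+` <- df[order(df$fc), , drop = FALSE]
  }
  if (length(rows_r)) {
    df <- do.call(rbind, rows_r)
    out$`-` <- df[order(df$fc), , drop = FALSE]
  }
  out
}

#' Simulate aligned kinetic reads with ground-truth pauses
#'
#' Read starts are uniform over the reference, lengths uniform over the
#' configured range, strands Bernoulli(0.5). Per position, IPD is
#' `LogNormal(mu_base[base], sigma)`; at each pause position of a motif
#' occurrence on the read's synthesis strand, an `Exponential(mean = tau)`
#' pause is added with probability `p_pause` (pauses are additive: structure
#' resolution time adds to normal incorporation time). Insert counts are
#' `Poisson(insert_rate)`. Deterministic given `config$seed` (stream seeded
#' with `seed + 1`; see the draw-order note in the source).
#'
#' @param reference A `reference_seq`, typically from [simulate_reference()].
#' @param config A `simulation_config`.
#' @return List with `reads` (list of `kinetic_read`) and `truth` (data
#'   frame `motif`, `site_start`, `offset`, `read_id`, `added_seconds`, one
#'   row per injected pause).
#' @export
simulate_reads <- function(reference, config) {
  stopifnot(inherits(config, "simulation_config"))
  n_ref <- nchar(reference$sequence)
  if (config$read_length[2] > n_ref) {
    stop("maximum read length (", config$read_length[2],
         ") exceeds the reference length (", n_ref, ")", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  ref_bases <- strsplit(reference$sequence, "")[[1]]
  mu <- config$mu_base
  mu_n <- mean(mu)
  pp <- pause_positions(reference, config)
  reads <- vector("list", config$n_reads)
  truth <- list()
  for (i in seq_len(config$n_reads)) {
    len <- config$read_length[1] +
      sample.int(config$read_length[2] - config$read_length[1] + 1L, 1L) - 1L
    start <- sample.int(n_ref - len + 1L, 1L) - 1L
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    fwd_slice <- ref_bases[start + seq_len(len)]
    bases <- if (strand == "+") fwd_slice else rev(unname(comp_bases(fwd_slice)))
    mub <- unname(mu[bases])
    mub[is.na(mub)] <- mu_n
    ipd <- stats::rlnorm(len, meanlog = mub, sdlog = config$sigma)
    rid <- sprintf("read_%05d", i)
    ptab <- pp[[strand]]
    if (!is.null(ptab)) {
      # synthesis position of forward coordinate fc within this read
      j <- if (strand == "+") ptab$fc - start + 1L else start + len - ptab$fc
      hit <- which(j >= 1L & j <= len)
      for (h in hit) {
        if (stats::runif(1) < ptab$p_pause[h]) {
          add <- stats::rexp(1, rate = 1 / ptab$tau[h])
          ipd[j[h]] <- ipd[j[h]] + add
          truth[[length(truth) + 1L]] <- data.frame(
            motif = ptab$motif[h], site_start = ptab$site_start[h],
            offset = ptab$offset[h], read_id = rid,
            added_seconds = add, stringsAsFactors = FALSE)
        }
      }
    }
    inserts <- stats::rpois(len, config$insert_rate)
    reads[[i]] <- kinetic_read(rid, reference$name, start, strand,
                               bases, ipd, inserts)
  }
  truth_df <- if (length(truth)) {
    do.call(rbind, truth)
  } else {
    data.frame(motif = character(0), site_start = integer(0),
               offset = integer(0), read_id = character(0),
               added_seconds = numeric(0), stringsAsFactors = FALSE)
  }
  list(reads = reads, truth = truth_df)
}

comp_bases <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}

#' Write a ground-truth pause table as TSV
#'
#' Columns `motif  site_start  offset  read_id  added_seconds` (seconds with
#' 6 significant digits).
#'
#' @param truth The `truth` data frame from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$added_seconds <- sprintf("%.6g", truth$added_seconds)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
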