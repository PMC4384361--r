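# Aligned per-read kinetics: interchange format, read containers, and the
# concatenated power-of-two tracks consumed by the correlation analysis.
#
# Coordinate conventions: 0-based half-open on the forward reference axis.
# Per-read arrays are always in synthesis order (5'->3' of the nascent
# strand); a reverse-strand read therefore stores the reverse complement of
# the forward reference slice, and its synthesis position j corresponds to
# forward coordinate reference_start + length - 1 - j.

KINETICS_COLUMNS <- c("read_id", "ref_name", "ref_pos", "strand", "base",
                      "ipd_s", "inserts")

#' Construct one aligned kinetic read
#'
#' @param read_id Read identifier.
#' @param reference_name Name of the reference the read aligns to.
#' @param reference_start 0-based start of the aligned window on the forward
#'   reference.
#' @param strand `"+"` (synthesis in increasing forward coordinates) or
#'   `"-"` (decreasing).
#' @param bases Base calls over `A,C,G,T,N` in synthesis order, as one
#'   string or a character vector.
#' @param ipd Interpulse durations in seconds, one per base; finite and
#'   non-negative.
#' @param inserts Number of inserted (unaligned) bases called immediately
#'   after each position; non-negative integers.
#' @return A `kinetic_read` object.
#' @export
kinetic_read <- function(read_id, reference_name, reference_start, strand,
                         bases, ipd, inserts) {
  if (length(bases) == 1L && nchar(bases[1]) > 1L) {
    bases <- strsplit(bases, "")[[1]]
  }
  bases <- toupper(as.character(bases))
  n <- length(bases)
  if (length(ipd) != n || length(inserts) != n) {
    stop("read '", read_id, "': bases, ipd and inserts lengths differ (",
         n, ", ", length(ipd), ", ", length(inserts), ")", call. = FALSE)
  }
  if (!all(bases %in% c("A", "C", "G", "T", "N"))) {
    stop("read '", read_id, "': bases must be over {A,C,G,T,N}",
         call. = FALSE)
  }
  if (!all(is.finite(ipd)) || any(ipd < 0)) {
    stop("read '", read_id, "': IPD values must be finite and >= 0",
         call. = FALSE)
  }
  if (any(inserts < 0) || any(inserts != round(inserts))) {
    stop("read '", read_id, "': insert counts must be non-negative integers",
         call. = FALSE)
  }
  if (!strand %in% c("+", "-")) {
    stop("read '", read_id, "': strand must be '+' or '-'", call. = FALSE)
  }
  structure(
    list(read_id = as.character(read_id),
         reference_name = as.character(reference_name),
         reference_start = as.integer(reference_start),
         strand = strand,
         bases = bases,
         ipd = as.double(ipd),
         inserts = as.integer(inserts)),
    class = "kinetic_read"
  )
}

#' @export
print.kinetic_read <- function(x, ...) {
  cat("kinetic_read ", x$read_id, ": ", length(x$bases), " nt on ",
      x$reference_name, ":", x$reference_start, " (", x$strand, ")\n",
      sep = "")
  invisible(x)
}

#' @export
length.kinetic_read <- function(x) length(x$bases)

#' Load a reference sequence from FASTA
#'
#' Returns the first record unless `name` selects a specific one; the
#' sequence is uppercased.
#'
#' @param path Path to a FASTA file.
#' @param name Optional record name (the word before the first whitespace in
#'   the header).
#' @return A list with `name` and `sequence` (class `reference_seq`).
#' @export
load_reference <- function(path, name = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("no FASTA records in ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  idx <- 1L
  if (!is.null(name)) {
    idx <- match(name, ids)
    if (is.na(idx)) {
      stop("record '", name, "' not found in ", path, call. = FALSE)
    }
  }
  structure(list(name = ids[idx],
                 sequence = toupper(as.character(seqs[[idx]]))),
            class = "reference_seq")
}

#' Write a reference sequence to FASTA
#'
#' @param ref A `reference_seq` (or any list with `name` and `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  dna <- Biostrings::DNAStringSet(ref$sequence)
  names(dna) <- ref$name
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read aligned kinetics from the tab-separated interchange format
#'
#' The format has a header line
#' `read_id  ref_name  ref_pos  strand  base  ipd_s  inserts` and one row
#' per synthesized position; rows of one read are contiguous and in
#' synthesis order. `ref_pos` is the 0-based forward-reference coordinate of
#' the position.
#'
#' @param path Path to the kinetics TSV.
#' @return List of `kinetic_read` objects in file order.
#' @export
load_kinetics <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  missing_cols <- setdiff(KINETICS_COLUMNS, names(dt))
  if (length(missing_cols)) {
    stop("kinetics file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("read_id", "ref_name", "strand", "base")) {
    dt[[col]] <- as.character(dt[[col]])
  }
  bad_ipd <- which(!is.finite(dt$ipd_s) | dt$ipd_s < 0)
  if (length(bad_ipd)) {
    stop("invalid IPD at data row ", bad_ipd[1], " of ", path,
         " (must be finite and >= 0)", call. = FALSE)
  }
  bad_strand <- which(!dt$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("unknown strand symbol '", dt$strand[bad_strand[1]],
         "' at data row ", bad_strand[1], " of ", path, call. = FALSE)
  }
  # contiguous runs of read_id, preserving file order
  grp <- rleid_vec(dt$read_id)
  rows <- split(seq_len(nrow(dt)), grp)
  lapply(rows, function(i) {
    sub <- dt[i, , drop = FALSE]
    start <- if (sub$strand[1] == "+") sub$ref_pos[1] else sub$ref_pos[nrow(sub)]
    kinetic_read(sub$read_id[1], sub$ref_name[1], start, sub$strand[1],
                 sub$base, sub$ipd_s, sub$inserts)
  })
}

rleid_vec <- function(x) {
  r <- rle(x)
  factor(rep(seq_along(r$lengths), r$lengths),
         levels = seq_along(r$lengths))
}

#' Write aligned kinetics to the tab-separated interchange format
#'
#' IPDs are written with 6 significant digits; the round trip
#' `load_kinetics(write_kinetics(reads, f))` is lossless at that precision.
#'
#' @param reads List of `kinetic_read` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinetics <- function(reads, path) {
  rows <- lapply(reads, function(r) {
    n <- length(r$bases)
    pos <- if (r$strand == "+") {
      r$reference_start + seq_len(n) - 1L
    } else {
      r$reference_start + n - seq_len(n)
    }
    data.frame(read_id = r$read_id, ref_name = r$reference_name,
               ref_pos = pos, strand = r$strand, base = r$bases,
               ipd_s = sprintf("%.6g", r$ipd), inserts = r$inserts,
               stringsAsFactors = FALSE)
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}

#' Keep reads longer than a length cutoff
#'
#' Strict inequality: with the default cutoff, a read of exactly 1000
#' positions is dropped. Input order is preserved.
#'
#' @param reads List of `kinetic_read` objects.
#' @param min_exclusive Length cutoff (default 1000).
#' @return Filtered list.
#' @export
filter_by_length <- function(reads, min_exclusive = 1000) {
  reads[vapply(reads, length, integer(1)) > min_exclusive]
}

#' Encode a base sequence as four nucleotide indicator tracks
#'
#' The sequence 5'-ACTG-3' becomes `A = (1,0,0,0)`, `C = (0,1,0,0)`,
#' `T = (0,0,1,0)`, `G = (0,0,0,1)`. An `N` scores 0 in all four tracks and
#' is retained (masking would desynchronize positions).
#'
#' @param bases Character vector of single bases, or one string.
#' @return List of numeric 0/1 vectors `A`, `C`, `G`, `T`.
#' @export
encode_indicators <- function(bases) {
  if (length(bases) == 1L && nchar(bases[1]) != 1L) {
    bases <- strsplit(bases, "")[[1]]
  }
  bases <- toupper(as.character(bases))
  if (length(bases) && !all(bases %in% c("A", "C", "G", "T", "N"))) {
    stop("bases must be over {A,C,G,T,N}", call. = FALSE)
  }
  lapply(stats::setNames(nm = c("A", "C", "G", "T")),
         function(b) as.numeric(bases == b))
}

largest_pow2_leq <- function(n) {
  if (n < 1) stop("need n >= 1", call. = FALSE)
  2^floor(log2(n) + 1e-12)
}

#' Concatenate reads into power-of-two analysis tracks
#'
#' Reads are concatenated in input order (synthesis order within each read)
#' and the resulting vectors are truncated from the end to the largest power
#' of two not exceeding `min(total length, max_length)`. Wavelet
#' coefficients that span the recorded read boundaries are deliberately not
#' masked downstream: boundary discontinuities are rare relative to track
#' length.
#'
#' @param reads List of `kinetic_read` objects (already length-filtered).
#' @param max_length Cap on the track length (default `2^23`).
#' @return A `concatenated_tracks` object: numeric vectors `ipd`, `inserts`,
#'   `A`, `C`, `G`, `T` of identical power-of-two length `L`, plus
#'   `read_boundaries` (0-based offsets where each retained read begins) and
#'   `read_ids`.
#' @export
concatenate_and_trim <- function(reads, max_length = 2^23) {
  if (length(reads) == 0L) {
    stop("no reads to concatenate", call. = FALSE)
  }
  lens <- vapply(reads, length, integer(1))
  total <- sum(lens)
  if (total < 2) {
    stop("total concatenated length (", total, ") is below 2", call. = FALSE)
  }
  L <- largest_pow2_leq(min(total, max_length))
  ipd <- unlist(lapply(reads, `[[`, "ipd"), use.names = FALSE)[seq_len(L)]
  ins <- unlist(lapply(reads, `[[`, "inserts"), use.names = FALSE)[seq_len(L)]
  bases <- unlist(lapply(reads, `[[`, "bases"), use.names = FALSE)[seq_len(L)]
  ind <- encode_indicators(bases)
  offsets <- cumsum(c(0L, lens))[seq_along(reads)]
  keep <- offsets < L
  structure(
    list(L = L,
         ipd = ipd, inserts = as.numeric(ins),
         A = ind$A, C = ind$C, G = ind$G, T = ind$T,
         read_boundaries = offsets[keep],
         read_ids = vapply(reads, `[[`, character(1), "read_id")[keep]),
    class = "concatenated_tracks"
  )
}

#' @export
print.concatenated_tracks <- function(x, ...) {
  cat("concatenated_tracks: L = ", x$L, " (2^", log2(x$L), "), ",
      length(x$read_boundaries), " reads\n", sep = "")
  invisible(x)
}
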