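# Regex pattern-site discovery on both strands and aggregation of raw and
# causally smoothed IPD into windowed mean/quantile pause profiles.
#
# Everything is computed on the "synthesis axis" of a site's strand: for a
# forward site, window position w corresponds to forward coordinate
# site_start - anchor + w; for a reverse site, to (end - 1 + anchor) - w.
# Reads contribute only on their own synthesis strand, so a pattern and its
# reverse complement never share (site, read) observations.

#' The canonical stable G-quadruplex pattern
#'
#' Four runs of three guanines separated by loops of 1-7 arbitrary bases:
#' `(GGG(.){1,7}GGG(.){1,7}GGG(.){1,7}GGG)`.
#'
#' @export
G_QUADRUPLEX_PATTERN <- "(GGG(.){1,7}GGG(.){1,7}GGG(.){1,7}GGG)"

#' Find regex pattern sites on a reference
#'
#' Scans the forward sequence and, when `both_strands`, independently the
#' reverse complement, using leftmost non-overlapping match semantics
#' (PCRE: grouping, alternation, bounded repetition `{m,n}` are all
#' available). Reverse-strand hits are reported in forward 0-based half-open
#' coordinates with strand `"-"`; a palindromic pattern therefore yields
#' paired sites on both strands at the same location.
#'
#' @param reference A `reference_seq` (see [load_reference()]).
#' @param pattern A regular expression over the DNA alphabet.
#' @param both_strands Also scan the reverse complement (default `TRUE`).
#' @param overlapping Report overlapping matches (each started at the next
#'   position after the previous match start) instead of the standard
#'   non-overlapping scan; useful for dense tandem repeats. Default `FALSE`.
#' @return Data frame of class `pattern_sites`: `ref`, `start`, `end`
#'   (0-based half-open, forward axis), `strand`, `seq` (the matched
#'   sequence, strand-appropriate: for `"-"` sites the reverse complement of
#'   the forward slice).
#' @export
find_sites <- function(reference, pattern, both_strands = TRUE,
                       overlapping = FALSE) {
  stopifnot(inherits(reference, "reference_seq"))
  tryCatch(suppressWarnings(regexpr(pattern, "", perl = TRUE)),
           error = function(e) {
             stop("invalid pattern: ", conditionMessage(e), call. = FALSE)
           })
  fwd <- reference$sequence
  n <- nchar(fwd)
  hits_f <- scan_pattern(fwd, pattern, overlapping)
  sites <- data.frame(ref = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
  if (nrow(hits_f)) {
    sites <- data.frame(ref = reference$name, start = hits_f$start,
                        end = hits_f$end, strand = "+", seq = hits_f$seq,
                        stringsAsFactors = FALSE)
  }
  if (both_strands) {
    rc <- revcomp(fwd)
    hits_r <- scan_pattern(rc, pattern, overlapping)
    if (nrow(hits_r)) {
      rev_sites <- data.frame(ref = reference$name,
                              start = n - hits_r$end,
                              end = n - hits_r$start,
                              strand = "-", seq = hits_r$seq,
                              stringsAsFactors = FALSE)
      sites <- rbind(sites, rev_sites)
    }
  }
  sites <- sites[order(sites$start, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("pattern_sites", "data.frame")
  sites
}

scan_pattern <- function(seq, pattern, overlapping) {
  starts <- integer(0); lens <- integer(0)
  if (!overlapping) {
    m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
    }
  } else {
    from <- 1L
    while (from <= nchar(seq)) {
      m <- regexpr(pattern, substr(seq, from, nchar(seq)), perl = TRUE)
      if (m == -1L) break
      starts <- c(starts, from + as.integer(m) - 1L)
      lens <- c(lens, attr(m, "match.length"))
      from <- from + as.integer(m)  # restart one past the match start
    }
  }
  if (length(starts) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  data.frame(start = starts - 1L, end = starts - 1L + lens,
             seq = substring(seq, starts, starts + lens - 1L),
             stringsAsFactors = FALSE)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Export pattern sites as BED
#'
#' Columns `ref  start  end  name  .  strand` (BED6 with a literal `.`
#' score).
#'
#' @param sites A `pattern_sites` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_sites_bed <- function(sites, path) {
  bed <- data.frame(ref = sites$ref, start = sites$start, end = sites$end,
                    name = if (nrow(sites)) {
                      sprintf("site_%d", seq_len(nrow(sites)))
                    } else character(0),
                    score = rep(".", nrow(sites)), strand = sites$strand,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Aggregate windowed IPD profiles around pattern sites
#'
#' For each site, every read that synthesizes the site's strand and overlaps
#' the window contributes its covered positions. Raw IPD is pooled directly;
#' the 2-nt and 4-nt smoothed tracks are computed within each read by
#' [causal_smooth()] (never across reads), so a position only carries a
#' smoothed value when the read provides the full trailing context. Per
#' window position and track the observation count, mean, and the requested
#' quantiles are returned. Quantiles use linear interpolation of order
#' statistics with rank `h = (n - 1) p + 1`.
#'
#' All sites must lie on one strand: a forward-pattern profile aggregates
#' forward-synthesis reads only, and the reverse-complement pattern is
#' profiled separately, preserving strand asymmetry of pausing.
#'
#' @param sites A `pattern_sites` data frame, single strand.
#' @param reads List of `kinetic_read` objects.
#' @param window Window length in nucleotides (default 128).
#' @param anchor Offset of the pattern start within the window; default
#'   `floor((window - max(pattern length)) / 2)` (pattern centered).
#' @param scales Causal smoothing widths (default `c(2, 4)`).
#' @param quantiles Quantile levels (default `c(0.90, 0.95)`).
#' @return An `aggregated_profile`: data frame `position` (0-based within
#'   the window), `track` (`"raw"`, `"smooth2"`, `"smooth4"`, ...), `count`,
#'   `mean`, and one `q<level>` column per quantile, plus attributes
#'   `window`, `anchor`, `strand`, `n_sites`, `contributions` (site/read
#'   pairs used). Zero contributing reads give a profile with all counts 0.
#' @export
extract_profiles <- function(sites, reads, window = 128, anchor = NULL,
                             scales = c(2, 4), quantiles = c(0.90, 0.95)) {
  if (nrow(sites)) {
    strand <- unique(sites$strand)
    if (length(strand) != 1L) {
      stop("sites must share one strand; profile each strand separately",
           call. = FALSE)
    }
  } else {
    strand <- NA_character_
  }
  if (any(diff(quantiles) <= 0) || any(quantiles <= 0 | quantiles >= 1)) {
    stop("quantile levels must be strictly increasing in (0, 1)",
         call. = FALSE)
  }
  pat_len <- if (nrow(sites)) max(sites$end - sites$start) else 0L
  if (window < pat_len) {
    stop("window (", window, ") is shorter than the longest pattern match (",
         pat_len, ")", call. = FALSE)
  }
  if (is.null(anchor)) anchor <- max(0L, floor((window - pat_len) / 2))

  tracks <- c("raw", paste0("smooth", scales))
  obs <- rep(list(rep(list(numeric(0)), window)), length(tracks))
  names(obs) <- tracks
  contrib <- list()

  for (s in seq_len(nrow(sites))) {
    site <- sites[s, ]
    for (r in reads) {
      if (r$strand != site$strand || r$reference_name != site$ref) next
      n <- length(r)
      # synthesis position j (1-based) of window position w (0-based):
      # forward: fc = start - anchor + w; j = fc - reference_start + 1
      # reverse: fc = (end - 1 + anchor) - w; j = reference_start + n - fc
      w_idx <- 0:(window - 1L)
      if (site$strand == "+") {
        j <- site$start - anchor + w_idx - r$reference_start + 1L
      } else {
        fc <- (site$end - 1L + anchor) - w_idx
        j <- r$reference_start + n - fc
      }
      cover <- j >= 1L & j <= n
      if (!any(cover)) next
      contrib[[length(contrib) + 1L]] <-
        data.frame(site = s, read_id = r$read_id, stringsAsFactors = FALSE)
      sm <- lapply(scales, function(w) {
        if (w <= n) causal_smooth(r$ipd, w) else rep(NA_real_, n)
      })
      for (wi in which(cover)) {
        wpos <- w_idx[wi] + 1L
        obs$raw[[wpos]] <- c(obs$raw[[wpos]], r$ipd[j[wi]])
        for (si in seq_along(scales)) {
          v <- sm[[si]][j[wi]]
          if (!is.na(v)) {
            tk <- tracks[si + 1L]
            obs[[tk]][[wpos]] <- c(obs[[tk]][[wpos]], v)
          }
        }
      }
    }
  }

  qcols <- paste0("q", sub("^0\\.", "", sprintf("%g", quantiles * 100)))
  rows <- lapply(tracks, function(tk) {
    per_pos <- obs[[tk]]
    df <- data.frame(position = 0:(window - 1L), track = tk,
                     count = vapply(per_pos, length, integer(1)),
                     mean = vapply(per_pos, function(v) {
                       if (length(v)) mean(v) else NA_real_
                     }, numeric(1)),
                     stringsAsFactors = FALSE)
    for (qi in seq_along(quantiles)) {
      df[[qcols[qi]]] <- vapply(per_pos, function(v) {
        if (length(v)) unname(stats::quantile(v, quantiles[qi], type = 7))
        else NA_real_
      }, numeric(1))
    }
    df
  })
  profile <- do.call(rbind, rows)
  rownames(profile) <- NULL
  structure(profile,
            class = c("aggregated_profile", "data.frame"),
            window = window, anchor = anchor, strand = strand,
            quantiles = quantiles, n_sites = nrow(sites),
            contributions = if (length(contrib)) {
              do.call(rbind, contrib)
            } else {
              data.frame(site = integer(0), read_id = character(0))
            })
}

#' Export / re-import an aggregated profile as TSV
#'
#' One row per (position, track) with count, mean and quantile columns.
#' Undefined statistics (count 0, or no smoothing context) are written as
#' empty fields. Positions whose count falls below `min_count` carry
#' `flagged = 1`.
#'
#' @param profile An `aggregated_profile`.
#' @param path Output path.
#' @param min_count Flag threshold (default 1).
#' @return `path` invisibly (`export_profile`); a plain data frame with the
#'   same columns (`read_profile_tsv`).
#' @export
export_profile <- function(profile, path, min_count = 1) {
  df <- as.data.frame(profile)
  df$flagged <- as.integer(df$count < min_count)
  num_cols <- setdiff(names(df), c("position", "track", "count", "flagged"))
  for (col in num_cols) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", sprintf("%.10g", df[[col]]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_profile
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "")
  num_cols <- setdiff(names(df), c("position", "track", "count", "flagged"))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Render a pause profile figure
#'
#' One panel per track (raw on top, then each smoothing width): the mean
#' IPD line with vertical quantile bars at each position — black for the
#' first quantile level (default 90%), grey for the second (95%). Format by
#' file extension (`.png` or `.pdf`).
#'
#' @param profile An `aggregated_profile`.
#' @param path Output figure path.
#' @return `path`, invisibly.
#' @export
render_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  tracks <- unique(df$track)
  qcols <- grep("^q", names(df), value = TRUE)
  open_device(path, width = 7, height = 2.5 * length(tracks))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(tracks), 1), mar = c(3, 4, 2, 1))
  for (tk in tracks) {
    sub <- df[df$track == tk, ]
    ylim <- range(0, unlist(sub[c("mean", qcols)]), na.rm = TRUE)
    if (!all(is.finite(ylim))) ylim <- c(0, 1)
    graphics::plot(sub$position, sub$mean, type = "n", ylim = ylim,
                   xlab = "window position (nt)", ylab = "IPD (s)",
                   main = tk)
    if (length(qcols) >= 2) {
      graphics::segments(sub$position, 0, sub$position, sub[[qcols[2]]],
                         col = "grey70")
    }
    if (length(qcols) >= 1) {
      graphics::segments(sub$position, 0, sub$position, sub[[qcols[1]]],
                         col = "black")
    }
    graphics::lines(sub$position, sub$mean, col = "red", lwd = 1.5)
  }
  invisible(path)
}
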