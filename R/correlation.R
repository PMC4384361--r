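# Scale-wise Pearson correlation of kinetic and nucleotide-composition
# tracks: every pair among {A, C, G, T, IPD, inserts} is correlated at every
# dyadic scale, separately for smooth and detail coefficients, with the
# per-scale power fraction of each track on the diagonal.

TRACK_LABELS <- c("A", "C", "G", "T", "IPD", "inserts")

#' Correlate wavelet coefficients across tracks and scales
#'
#' Each of the six tracks (four nucleotide indicators, IPD, inserts) is
#' Haar-decomposed once; for every unordered track pair and every scale up
#' to `max_scale`, Pearson's product-moment correlation is computed between
#' the smooth coefficient vectors and between the detail coefficient
#' vectors. A zero-variance coefficient vector makes the correlation
#' undefined; such entries are reported as `NA`, never coerced to 0. IPDs
#' enter in raw seconds by default; `log_ipd = TRUE` applies `log1p` first
#' (an extension, not the default analysis).
#'
#' @param tracks A `concatenated_tracks` object with power-of-two length
#'   `L >= 2 * max_scale`.
#' @param max_scale Coarsest scale (block width) to report; a power of two,
#'   also bounded by `L / 2`. Default 2048.
#' @param log_ipd Correlate `log1p(IPD)` instead of raw seconds.
#' @param mask_boundaries Drop coefficients whose block spans a read
#'   boundary before correlating (sensitivity analysis; default `FALSE`,
#'   i.e. the rare boundary discontinuities are kept).
#' @return A `scale_correlation_table`: list with `correlations` (data frame
#'   `track1`, `track2`, `scale`, `r_smooth`, `r_detail`) and `power` (data
#'   frame `track`, `scale`, `power`; fractions over the scales actually
#'   computed, so they sum to 1 per track).
#' @export
correlate_tracks <- function(tracks, max_scale = 2048, log_ipd = FALSE,
                             mask_boundaries = FALSE) {
  stopifnot(inherits(tracks, "concatenated_tracks"))
  if (!is_pow2(max_scale) || max_scale < 2) {
    stop("max_scale must be a power of two >= 2", call. = FALSE)
  }
  L <- tracks$L
  if (L < 2 * max_scale) {
    stop("track length (", L, ") must be at least 2 * max_scale (",
         2 * max_scale, ")", call. = FALSE)
  }
  ipd <- if (log_ipd) log1p(tracks$ipd) else tracks$ipd
  mat <- list(A = tracks$A, C = tracks$C, G = tracks$G, T = tracks$T,
              IPD = ipd, inserts = tracks$inserts)
  decs <- lapply(mat, haar_decompose)
  scales <- 2^seq_len(log2(max_scale))
  # coefficient k at scale w covers positions ((k-1)*w, k*w]; masked when a
  # read boundary falls strictly inside that block
  keep_at <- lapply(stats::setNames(nm = as.character(scales)), function(wc) {
    w <- as.numeric(wc)
    k <- seq_len(L / w)
    if (!mask_boundaries) return(k)
    inner <- tracks$read_boundaries[tracks$read_boundaries > 0]
    spans <- unique((floor(inner / w) + 1)[(inner %% w) != 0])
    setdiff(k, spans)
  })

  pairs <- expand.grid(i = seq_along(TRACK_LABELS),
                       j = seq_along(TRACK_LABELS))
  pairs <- pairs[pairs$i <= pairs$j, ]
  rows <- vector("list", nrow(pairs) * length(scales))
  k <- 0L
  for (p in seq_len(nrow(pairs))) {
    t1 <- TRACK_LABELS[pairs$i[p]]
    t2 <- TRACK_LABELS[pairs$j[p]]
    for (w in scales) {
      wc <- as.character(w)
      sel <- keep_at[[wc]]
      k <- k + 1L
      rows[[k]] <- data.frame(
        track1 = t1, track2 = t2, scale = w,
        r_smooth = if (t1 == t2) 1 else {
          safe_cor(decs[[t1]]$smooth[[wc]][sel], decs[[t2]]$smooth[[wc]][sel])
        },
        r_detail = if (t1 == t2) 1 else {
          safe_cor(decs[[t1]]$detail[[wc]][sel], decs[[t2]]$detail[[wc]][sel])
        },
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, rows)

  power <- do.call(rbind, lapply(TRACK_LABELS, function(t1) {
    energy <- vapply(decs[[t1]]$detail[as.character(scales)],
                     function(d) sum(d^2), numeric(1))
    total <- sum(energy)
    data.frame(track = t1, scale = scales,
               power = if (total > 0) energy / total else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(correlations) <- rownames(power) <- NULL
  structure(list(correlations = correlations, power = power,
                 max_scale = max_scale, L = L),
            class = "scale_correlation_table")
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' @export
print.scale_correlation_table <- function(x, ...) {
  cat("scale_correlation_table: ", length(unique(x$correlations$scale)),
      " scales (2..", x$max_scale, "), L = ", x$L, "\n", sep = "")
  invisible(x)
}

#' Export / re-import a scale correlation table as TSV
#'
#' One row per (pair, scale) with `r_smooth`, `r_detail`, and the power
#' fraction on self-pair rows (empty elsewhere). Undefined correlations are
#' written as empty fields.
#'
#' @param table A `scale_correlation_table`.
#' @param path Output path.
#' @return `path` invisibly (`export_table`); the re-built table
#'   (`read_table_tsv`).
#' @export
export_table <- function(table, path) {
  stopifnot(inherits(table, "scale_correlation_table"))
  df <- table$correlations
  pw <- table$power
  key <- paste(df$track1, df$scale)
  pkey <- paste(pw$track, pw$scale)
  df$power <- ifelse(df$track1 == df$track2,
                     pw$power[match(key, pkey)], NA_real_)
  out <- df
  for (col in c("r_smooth", "r_detail", "power")) {
    out[[col]] <- ifelse(is.na(df[[col]]), "",
                         sprintf("%.10g", df[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_table
#' @export
read_table_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "")
  for (col in c("r_smooth", "r_detail", "power")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  power <- df[df$track1 == df$track2, c("track1", "scale", "power")]
  names(power) <- c("track", "scale", "power")
  rownames(power) <- NULL
  correlations <- df[, c("track1", "track2", "scale", "r_smooth", "r_detail")]
  structure(list(correlations = correlations, power = power,
                 max_scale = max(df$scale), L = NA_integer_),
            class = "scale_correlation_table")
}

#' Render the correlation matrix figure
#'
#' One panel per scale is collapsed into a single matrix layout per the
#' conventional display: smooth-coefficient correlations in the upper
#' triangle, detail-coefficient correlations in the lower triangle, per
#' scale power fractions on the diagonal. Red marks positive correlations,
#' blue negative; intensity scales with `|r|`. The output format follows the
#' file extension (`.png` or `.pdf`).
#'
#' @param table A `scale_correlation_table`.
#' @param path Output figure path.
#' @param scales Scales to draw (default: all in the table).
#' @return `path`, invisibly.
#' @export
render_matrix <- function(table, path, scales = NULL) {
  stopifnot(inherits(table, "scale_correlation_table"))
  all_scales <- sort(unique(table$correlations$scale))
  if (is.null(scales)) scales <- all_scales
  open_device(path, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  nt <- length(TRACK_LABELS)
  ns <- length(scales)
  nc <- ceiling(sqrt(ns))
  nr <- ceiling(ns / nc)
  graphics::par(mfrow = c(nr, nc), mar = c(1.5, 1.5, 2, 0.5))
  for (w in scales) {
    sub <- table$correlations[table$correlations$scale == w, ]
    pw <- table$power[table$power$scale == w, ]
    m <- matrix(NA_real_, nt, nt, dimnames = list(TRACK_LABELS, TRACK_LABELS))
    for (r in seq_len(nrow(sub))) {
      i <- match(sub$track1[r], TRACK_LABELS)
      j <- match(sub$track2[r], TRACK_LABELS)
      if (i == j) {
        m[i, j] <- pw$power[match(sub$track1[r], pw$track)]
      } else {
        m[min(i, j), max(i, j)] <- sub$r_smooth[r]  # upper: smooth
        m[max(i, j), min(i, j)] <- sub$r_detail[r]  # lower: detail
      }
    }
    graphics::image(seq_len(nt), seq_len(nt), t(m[nt:1, ]),
                    col = grDevices::colorRampPalette(
                      c("blue", "white", "red"))(101),
                    zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                    main = paste0("scale ", w))
    graphics::axis(1, at = seq_len(nt), labels = TRACK_LABELS, tick = FALSE,
                   cex.axis = 0.7)
    graphics::axis(2, at = seq_len(nt), labels = rev(TRACK_LABELS),
                   tick = FALSE, las = 1, cex.axis = 0.7)
  }
  invisible(path)
}

open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height, units = "in",
                         res = 150),
    pdf = grDevices::pdf(path, width = width, height = height),
    stop("unsupported figure format '.", ext, "' (use .png or .pdf)",
         call. = FALSE)
  )
}
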