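# Haar multiresolution transform.
#
# Scales are labelled by block width in nucleotides (2, 4, ..., N), not by
# the dyadic level index: the detail vector at scale w has N/w coefficients,
# each a normalized contrast between the two halves of a w-wide block.

#' Haar low-pass / high-pass filter coefficients
#'
#' The orthonormal Haar pair: `h = (1, 1)/sqrt(2)` (low pass, local sums) and
#' `g = (1, -1)/sqrt(2)` (high pass, local differences). Both have unit L2
#' norm and are mutually orthogonal, which is what makes the decimated
#' transform energy-preserving.
#'
#' @return A list with numeric components `h` and `g`, each of length 2.
#' @export
#' @examples
#' f <- haar_filter()
#' sum(f$h^2)  # 1
#' sum(f$h * f$g)  # 0
haar_filter <- function() {
  list(h = c(1, 1) / sqrt(2), g = c(1, -1) / sqrt(2))
}

check_signal <- function(x, what = "x") {
  if (!is.numeric(x) || length(x) < 1L) {
    stop(what, " must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(as.double(x))
}

is_pow2 <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

#' Decimated Haar wavelet decomposition
#'
#' Recursively applies the Haar low-pass and high-pass filters, halving the
#' number of coefficients at each step. At scale `w` (block width in signal
#' positions), smooth coefficient `k` is `w^(-1/2)` times the sum of block
#' `k`, and detail coefficient `k` is `w^(-1/2)` times (first half sum minus
#' second half sum) of that block. The input length must be a power of two;
#' callers holding arbitrary-length tracks trim first (see
#' [concatenate_and_trim()]).
#'
#' @param x Numeric vector of finite values; `length(x)` must be a power of
#'   two and at least 2.
#' @return An object of class `haar_decomposition`: a list with `n` (input
#'   length), `scales` (block widths `2, 4, ..., n`), `smooth` and `detail`
#'   (lists of coefficient vectors named by scale, of length `n/scale`), and
#'   `final_smooth` (the single coarsest smooth coefficient,
#'   `sum(x)/sqrt(n)`).
#' @seealso [haar_reconstruct()], [power_by_scale()], [causal_smooth()]
#' @export
#' @examples
#' d <- haar_decompose(c(1, 3))
#' d$smooth[["2"]]  # 2 * sqrt(2)
#' d$detail[["2"]]  # -sqrt(2)
haar_decompose <- function(x) {
  x <- check_signal(x)
  n <- length(x)
  if (n < 2L || !is_pow2(n)) {
    stop("signal length must be a power of two >= 2, got ", n,
         " (trim the track first)", call. = FALSE)
  }
  flt <- haar_filter()
  scales <- 2^seq_len(log2(n))
  smooth <- detail <- vector("list", length(scales))
  names(smooth) <- names(detail) <- as.character(scales)
  s <- x
  for (j in seq_along(scales)) {
    odd <- s[seq(1L, length(s), by = 2L)]
    even <- s[seq(2L, length(s), by = 2L)]
    smooth[[j]] <- flt$h[1] * odd + flt$h[2] * even
    detail[[j]] <- flt$g[1] * odd + flt$g[2] * even
    s <- smooth[[j]]
  }
  structure(
    list(n = n, scales = scales, smooth = smooth, detail = detail,
         final_smooth = s),
    class = "haar_decomposition"
  )
}

#' @export
print.haar_decomposition <- function(x, ...) {
  cat("Haar decomposition of a length-", x$n, " signal\n", sep = "")
  cat("  scales (block width): ", paste(x$scales, collapse = ", "), "\n",
      sep = "")
  cat("  final smooth: ", format(x$final_smooth), "\n", sep = "")
  invisible(x)
}

check_decomposition <- function(dec) {
  if (!inherits(dec, "haar_decomposition")) {
    stop("expected a haar_decomposition object", call. = FALSE)
  }
  n <- dec$n
  for (j in seq_along(dec$scales)) {
    w <- dec$scales[j]
    if (length(dec$detail[[j]]) != n / w || length(dec$smooth[[j]]) != n / w) {
      stop("inconsistent coefficient counts at scale ", w, call. = FALSE)
    }
  }
  if (length(dec$final_smooth) != 1L) {
    stop("final smooth coefficient must be a single value", call. = FALSE)
  }
  invisible(dec)
}

#' Invert a decimated Haar decomposition
#'
#' Reconstructs the original signal from the detail coefficients and the
#' final smooth coefficient, undoing one filtering level at a time. Exact up
#' to floating-point rounding.
#'
#' @param dec A `haar_decomposition` from [haar_decompose()].
#' @return Numeric vector of length `dec$n`.
#' @export
haar_reconstruct <- function(dec) {
  check_decomposition(dec)
  flt <- haar_filter()
  s <- dec$final_smooth
  for (j in rev(seq_along(dec$scales))) {
    d <- dec$detail[[j]]
    out <- numeric(2L * length(s))
    out[seq(1L, length(out), by = 2L)] <- flt$h[1] * s + flt$g[1] * d
    out[seq(2L, length(out), by = 2L)] <- flt$h[2] * s + flt$g[2] * d
    s <- out
  }
  s
}

#' Per-scale power of the detail coefficients
#'
#' The power at scale `j` is the fraction of total detail energy carried by
#' that scale: `Power_j = sum_i d_i^(j)^2 / sum_j sum_i d_i^(j)^2`. Because
#' the Haar basis is orthonormal, these fractions describe how the signal's
#' variation distributes over scales; they sum to one.
#'
#' @param dec A `haar_decomposition`.
#' @return Named numeric vector of power fractions, one per scale.
#'   Errors if the total detail energy is zero (e.g. a constant signal),
#'   since power fractions are undefined there.
#' @export
#' @examples
#' p <- power_by_scale(haar_decompose(c(1, -1, 1, -1)))
#' p[["2"]]  # 1: all variation is at the 2-nucleotide scale
power_by_scale <- function(dec) {
  check_decomposition(dec)
  energy <- vapply(dec$detail, function(d) sum(d^2), numeric(1))
  total <- sum(energy)
  if (total <= 0) {
    stop("total detail energy is zero (constant signal); ",
         "power fractions are undefined", call. = FALSE)
  }
  energy / total
}

#' Causal non-decimated Haar smooth
#'
#' One smooth coefficient per signal position: position `i` carries
#' `scale^(-1/2)` times the sum of the trailing window
#' `x[i - scale + 1], ..., x[i]`. This is the non-decimated (stationary)
#' Haar smooth applied to the reversed signal, so each coefficient uses only
#' the position itself and its already-synthesized (upstream) context —
#' pauses are attributed to the nucleotide at which they occur, never to
#' bases the polymerase has not yet reached. The first `scale - 1` positions
#' have no full trailing window and are returned as `NA` rather than padded:
#' padding would fabricate kinetics across read starts.
#'
#' @param x Numeric vector of finite values.
#' @param scale Window width; a power of two not exceeding `length(x)`.
#' @return Numeric vector the same length as `x`, `NA` at positions
#'   `1:(scale-1)`.
#' @export
#' @examples
#' causal_smooth(c(1, 2, 3, 4), 2)  # NA, 3/sqrt(2), 5/sqrt(2), 7/sqrt(2)
causal_smooth <- function(x, scale) {
  x <- check_signal(x)
  if (length(scale) != 1L || !is_pow2(scale) || scale < 2) {
    stop("scale must be a single power of two >= 2", call. = FALSE)
  }
  n <- length(x)
  if (scale > n) {
    stop("scale (", scale, ") exceeds signal length (", n, ")",
         call. = FALSE)
  }
  cs <- cumsum(x)
  out <- rep(NA_real_, n)
  idx <- scale:n
  lead <- c(0, cs)[idx - scale + 1L]
  out[idx] <- (cs[idx] - lead) / sqrt(scale)
  out
}
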