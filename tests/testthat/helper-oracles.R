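# Independent brute-force oracles used across the suite. These recompute
# expected values directly from definitions (block sums, trailing sums,
# order statistics) and never call the transform code they check.

# Decimated Haar oracle: at scale w, block k covers x[(k-1)w + 1 .. kw];
# smooth = w^(-1/2) * block sum, detail = w^(-1/2) * (first half - second
# half of the block).
oracle_haar <- function(x, w) {
  n <- length(x)
  k <- n / w
  sm <- de <- numeric(k)
  for (i in seq_len(k)) {
    block <- x[((i - 1) * w + 1):(i * w)]
    sm[i] <- sum(block) / sqrt(w)
    de[i] <- (sum(block[1:(w / 2)]) - sum(block[(w / 2 + 1):w])) / sqrt(w)
  }
  list(smooth = sm, detail = de)
}

# Trailing-window oracle for the causal smooth.
oracle_causal <- function(x, w) {
  out <- rep(NA_real_, length(x))
  for (i in w:length(x)) {
    out[i] <- sum(x[(i - w + 1):i]) / sqrt(w)
  }
  out
}

# Quantile by linear interpolation of order statistics, rank h = (n-1)p + 1.
oracle_quantile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Reference sequence object without touching package I/O.
make_ref <- function(sequence, name = "ref") {
  structure(list(name = name, sequence = sequence), class = "reference_seq")
}

# A simple read over a reference slice with supplied IPDs.
make_read <- function(id, start, bases, ipd, strand = "+",
                      inserts = rep(0L, nchar(bases)), ref = "ref") {
  kinetic_read(id, ref, start, strand, bases, ipd, inserts)
}
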