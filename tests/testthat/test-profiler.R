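test_that("the G-quadruplex pattern matches the toy sequence at 2..17", {
  ref <- make_ref("AAGGGTGGGTGGGTGGGAA")
  sites <- find_sites(ref, G_QUADRUPLEX_PATTERN)
  fwd <- sites[sites$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$start, 2)
  expect_equal(fwd$end, 17)
  expect_equal(fwd$seq, "GGGTGGGTGGGTGGG")
})

test_that("palindromic patterns yield strand-paired sites; absent patterns none", {
  ref <- make_ref(paste0(strrep("A", 30), "CGCGCGCGCG", strrep("T", 30)))
  sites <- find_sites(ref, "CGCGCGCGCG")
  expect_equal(nrow(sites), 2)
  expect_setequal(sites$strand, c("+", "-"))
  expect_equal(unique(sites$start), 30)
  expect_equal(unique(sites$end), 40)

  expect_equal(nrow(find_sites(ref, "TTTAAATTTAAA")), 0)
  expect_error(find_sites(ref, "(GGG"), "invalid pattern")
})

test_that("reverse-strand hits come back in forward coordinates", {
  # GGCGGCGGCGG on the reverse strand = CCGCCGCCGCC on the forward sequence
  ref <- make_ref(paste0(strrep("T", 10), "CCGCCGCCGCC", strrep("T", 10)))
  sites <- find_sites(ref, "GGCGGCGGCGG")
  expect_equal(sites$strand, "-")
  expect_equal(sites$start, 10)
  expect_equal(sites$end, 21)
  expect_equal(sites$seq, "GGCGGCGGCGG")
})

test_that("overlapping scan reports dense tandem repeat matches", {
  ref <- make_ref("AACGCGCGCGAA")
  non <- find_sites(ref, "CGCG", both_strands = FALSE)
  ov <- find_sites(ref, "CGCG", both_strands = FALSE, overlapping = TRUE)
  expect_equal(nrow(non), 2)
  expect_gt(nrow(ov), nrow(non))
})

test_that("BED export has the six documented columns", {
  ref <- make_ref(paste0(strrep("A", 30), "CGCGCGCGCG", strrep("T", 30)))
  sites <- find_sites(ref, "CGCGCGCGCG")
  f <- withr::local_tempfile(fileext = ".bed")
  export_sites_bed(sites, f)
  got <- read.delim(f, header = FALSE)
  expect_equal(ncol(got), 6)
  expect_equal(got$V2, c(30, 30))
  expect_true(all(got$V5 == "."))
})

test_that("a constant-IPD read gives flat mean/quantiles with the smooth scaling", {
  ref_seq <- paste0(strrep("A", 20), "GGCGG", strrep("A", 20))
  sites <- find_sites(make_ref(ref_seq), "GGCGG", both_strands = FALSE)
  rd <- make_read("r1", 0, ref_seq, rep(0.2, nchar(ref_seq)))
  prof <- extract_profiles(sites, list(rd), window = 32)
  raw <- prof[prof$track == "raw" & prof$count > 0, ]
  expect_true(all(abs(raw$mean - 0.2) < 1e-12))
  expect_true(all(abs(raw$q90 - 0.2) < 1e-12))
  expect_true(all(abs(raw$q95 - 0.2) < 1e-12))
  s2 <- prof[prof$track == "smooth2" & prof$count > 0, ]
  expect_true(all(abs(s2$mean - 0.2 * sqrt(2)) < 1e-12))
  s4 <- prof[prof$track == "smooth4" & prof$count > 0, ]
  expect_true(all(abs(s4$mean - 0.2 * 2) < 1e-12))
})

test_that("profile quantiles follow the order-statistics interpolation rule", {
  ref_seq <- paste0(strrep("A", 5), "GGCGG", strrep("A", 5))
  sites <- find_sites(make_ref(ref_seq), "GGCGG", both_strands = FALSE)
  vals <- c(0.1 * (1:18), 4, 8)
  reads <- lapply(seq_along(vals), function(i) {
    make_read(sprintf("r%02d", i), 0, ref_seq, rep(vals[i], nchar(ref_seq)))
  })
  prof <- extract_profiles(sites, reads, window = 15, anchor = 5)
  raw <- prof[prof$track == "raw", ]
  at <- raw[raw$position == 7, ]  # fully covered position, n = 20
  expect_equal(at$count, 20)
  expect_equal(at$q90, oracle_quantile(vals, 0.90), tolerance = 1e-12)
  expect_equal(at$q95, oracle_quantile(vals, 0.95), tolerance = 1e-12)
  # frozen values from the order-statistics oracle:
  # h90 = 19*0.9+1 = 18.1 -> 1.8 + 0.1*(4 - 1.8) = 2.02
  # h95 = 19*0.95+1 = 19.05 -> 4 + 0.05*(8 - 4) = 4.2
  expect_equal(at$q90, 2.02, tolerance = 1e-12)
  expect_equal(at$q95, 4.2, tolerance = 1e-12)
  expect_true(all(raw$q95 >= raw$q90, na.rm = TRUE))
})

test_that("profiles error on short windows and stay empty without reads", {
  ref_seq <- paste0(strrep("A", 20), "GGCGGCGGCGG", strrep("A", 20))
  sites <- find_sites(make_ref(ref_seq), "GGCGGCGGCGG", both_strands = FALSE)
  expect_error(extract_profiles(sites, list(), window = 8), "shorter")
  prof <- extract_profiles(sites, list(), window = 16)
  expect_true(all(prof$count == 0))
  expect_true(all(is.na(prof$mean)))

  # mixed strands refuse to aggregate
  both <- find_sites(make_ref(paste0(strrep("A", 20), "CGCGCGCGCG",
                                     strrep("T", 20))), "CGCGCGCGCG")
  expect_error(extract_profiles(both, list(), window = 16), "one strand")
})

test_that("a pattern and its reverse complement share no (site, read) pairs", {
  cfg <- simulation_config(seed = 21, ref_length = 800, n_reads = 60,
                           read_length = c(150, 250),
                           motifs = list(list(sequence = "GGCGGCGGCGG",
                                              position = 400)))
  ref <- simulate_reference(cfg)
  sim <- simulate_reads(ref, cfg)
  fwd_sites <- find_sites(ref, "GGCGGCGGCGG")
  rev_sites <- find_sites(ref, "CCGCCGCCGCC")  # reverse complement pattern
  f <- extract_profiles(fwd_sites[fwd_sites$strand == "+", ], sim$reads,
                        window = 64)
  r <- extract_profiles(rev_sites[rev_sites$strand == "-", ], sim$reads,
                        window = 64)
  key <- function(p) {
    cb <- attr(p, "contributions")
    paste(cb$site, cb$read_id)
  }
  expect_gt(length(key(f)), 0)
  expect_length(intersect(key(f), key(r)), 0)
  fr <- attr(f, "contributions")$read_id
  rr <- attr(r, "contributions")$read_id
  strands <- vapply(sim$reads, `[[`, character(1), "strand")
  ids <- vapply(sim$reads, `[[`, character(1), "read_id")
  expect_true(all(strands[match(unique(fr), ids)] == "+"))
  if (length(rr)) expect_true(all(strands[match(unique(rr), ids)] == "-"))
})

test_that("quantile bars are monotone wherever counts are adequate", {
  cfg <- simulation_config(seed = 31, ref_length = 600, n_reads = 150,
                           read_length = c(200, 300),
                           motifs = list(list(sequence = "GGCGGCGGCGG",
                                              position = 300)),
                           pauses = list(list(offset = 2, p_pause = 0.3,
                                              tau = 4)))
  ref <- simulate_reference(cfg)
  sim <- simulate_reads(ref, cfg)
  sites <- find_sites(ref, "GGCGGCGGCGG")
  prof <- extract_profiles(sites[sites$strand == "+", ], sim$reads)
  raw <- prof[prof$track == "raw" & prof$count >= 20, ]
  expect_gt(nrow(raw), 0)
  expect_true(all(raw$q95 >= raw$q90))
  expect_true(all(raw$q90 >= 0))
})

test_that("profiles round-trip through TSV and flag low-count positions", {
  ref_seq <- paste0(strrep("A", 20), "GGCGG", strrep("A", 40))
  sites <- find_sites(make_ref(ref_seq), "GGCGG", both_strands = FALSE)
  rd <- make_read("r1", 10, substr(ref_seq, 11, 40), rlnorm(30, log(0.2), 1))
  prof <- extract_profiles(sites, list(rd), window = 48)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_profile(prof, f, min_count = 1)
  back <- read_profile_tsv(f)
  expect_equal(nrow(back), nrow(prof))
  expect_equal(back$mean, prof$mean, tolerance = 1e-9)
  expect_equal(back$q90, prof$q90, tolerance = 1e-9)
  expect_equal(back$flagged, as.integer(prof$count < 1))
  expect_true(any(back$flagged == 1))

  # empty profile exports header-only rows with zero counts
  empty <- extract_profiles(sites, list(), window = 48)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_profile(empty, f2)
  back2 <- read_profile_tsv(f2)
  expect_true(all(back2$count == 0))

  fig <- withr::local_tempfile(fileext = ".png")
  render_profile(prof, fig)
  expect_true(file.exists(fig) && file.size(fig) > 0)
})

test_that("forward and reverse profiles of a palindrome agree on symmetric data", {
  cfg <- simulation_config(seed = 55, ref_length = 900, n_reads = 400,
                           read_length = c(200, 300),
                           motifs = list(list(sequence = "CGCGCGCGCG",
                                              position = 450)))
  ref <- simulate_reference(cfg)
  sim <- simulate_reads(ref, cfg)
  sites <- find_sites(ref, "CGCGCGCGCG")
  f <- extract_profiles(sites[sites$strand == "+", ], sim$reads, window = 64)
  r <- extract_profiles(sites[sites$strand == "-", ], sim$reads, window = 64)
  fm <- f[f$track == "raw" & f$count >= 30, c("position", "mean")]
  rm_ <- r[r$track == "raw" & r$count >= 30, c("position", "mean")]
  common <- intersect(fm$position, rm_$position)
  expect_gt(length(common), 30)
  d <- fm$mean[match(common, fm$position)] - rm_$mean[match(common, rm_$position)]
  # Monte-Carlo agreement: same base composition and no pauses on either
  # strand, so mean differences are noise around zero
  expect_lt(mean(abs(d)), 0.15)
  expect_lt(abs(mean(d)), 0.05)
})
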