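# build an overlapping pair from an amplicon: r1 = first len1 bases,
# r2 = revcomp of the last len2 bases (sequencing orientation)
pair_from_amplicon <- function(amplicon, len1, len2, q1 = NULL, q2 = NULL) {
  n <- nchar(amplicon)
  if (is.null(q1)) q1 <- rep(40L, len1)
  if (is.null(q2)) q2 <- rep(40L, len2)
  list(r1 = read_record("p", substr(amplicon, 1, len1), q1),
       r2 = read_record("p", revcomp_oracle(substr(amplicon, n - len2 + 1, n)),
                        q2))
}

test_that("an exact overlap joins with max-quality reconciliation", {
  set.seed(31)
  amp <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  pr <- pair_from_amplicon(amp, 40, 40, q1 = sample(2:40, 40, replace = TRUE),
                           q2 = sample(2:40, 40, replace = TRUE))
  res <- join_pair(pr$r1, pr$r2, join_config(p_max_diff = 8))
  expect_identical(res$status, "joined")
  expect_identical(res$overlap_len, 20L)
  expect_identical(res$mismatches, 0L)
  expect_identical(res$merged$sequence, amp)
  ov_q1 <- pr$r1$qualities[21:40]
  ov_q2 <- rev(pr$r2$qualities)[1:20]
  expect_identical(res$merged$qualities[21:40], pmax(ov_q1, ov_q2))
})

test_that("mismatch percentage above the threshold rejects the pair", {
  set.seed(33)
  amp <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
  pr <- pair_from_amplicon(amp, 25, 25)          # true overlap 10
  s2 <- strsplit(pr$r2$sequence, "")[[1]]
  # corrupt 2 bases inside the overlap -> 20% of 10
  s2[24] <- setdiff(c("A", "C", "G", "T"), s2[24])[1]
  s2[20] <- setdiff(c("A", "C", "G", "T"), s2[20])[1]
  r2 <- read_record("p", paste(s2, collapse = ""), pr$r2$qualities)
  res <- join_pair(pr$r1, r2, join_config(p_max_diff = 8))
  expect_identical(res$status, "rejected")
  res2 <- join_pair(pr$r1, r2, join_config(p_max_diff = 25))
  expect_identical(res2$status, "joined")
})

test_that("a mismatch keeps the higher-quality base with the quality gap", {
  # 10-base amplicon, full 10-base overlap, one engineered mismatch
  amp <- "ACGTACGTAC"
  r1 <- read_record("m", amp, c(rep(35L, 4), 30L, rep(35L, 5)))
  r2seq <- strsplit(amp, "")[[1]]
  r2seq[5] <- "C"                                # r2 disagrees at position 5
  r2 <- read_record("m", revcomp_oracle(paste(r2seq, collapse = "")),
                    rep(20L, 10))
  res <- join_pair(r1, r2, join_config(p_max_diff = 15, min_overlap = 10))
  expect_identical(res$status, "joined")
  expect_identical(res$overlap_len, 10L)
  expect_identical(res$mismatches, 1L)
  expect_identical(substr(res$merged$sequence, 5, 5), "A")  # Q30 beats Q20
  expect_identical(res$merged$qualities[5], 10L)            # |30 - 20|
})

test_that("equal-quality mismatches take r1's base with quality zero", {
  amp <- "AACCGGTTAA"
  r1 <- read_record("t", amp, rep(30L, 10))
  r2seq <- strsplit(amp, "")[[1]]; r2seq[7] <- "A"
  r2 <- read_record("t", revcomp_oracle(paste(r2seq, collapse = "")),
                    rep(30L, 10))
  res <- join_pair(r1, r2, join_config(p_max_diff = 15, min_overlap = 10))
  expect_identical(substr(res$merged$sequence, 7, 7), "T")
  expect_identical(res$merged$qualities[7], 0L)
})

test_that("empty reads are rejected with a reason", {
  r <- random_read(20)
  res <- join_pair(structure("x", class = "empty_read"), r)
  expect_identical(res$status, "rejected")
  expect_identical(res$reason, "empty-read")
})

test_that("join_pair matches the exhaustive brute-force oracle", {
  set.seed(37)
  n_checked <- 0L
  for (i in 1:400) {
    r1 <- random_read(sample(8:40, 1), "a", qmin = 0L)
    r2 <- random_read(sample(8:40, 1), "a", qmin = 0L)
    p <- sample(c(0, 8, 20, 40, 80), 1)
    cfg <- join_config(p_max_diff = p, min_overlap = sample(1:6, 1))
    got <- join_pair(r1, r2, cfg)
    want <- join_oracle(r1, r2, p, cfg$min_overlap)
    expect_identical(got$status == "joined", want$joined)
    if (want$joined) {
      n_checked <- n_checked + 1L
      expect_identical(got$overlap_len, want$ov)
      expect_equal(got$mismatch_pct, want$pct)
      expect_identical(got$merged$sequence, want$seq)
      expect_identical(got$merged$qualities, want$qual)
    }
  }
  expect_gt(n_checked, 50L)  # the comparison exercises real joins
})

test_that("joining conserves pairs and error-free templates reconstruct", {
  amps <- make_tiny_amplicons(n = 8, seed = 41)
  cfg <- join_config(p_max_diff = 8)
  r1 <- lapply(amps, function(a) read_record(a$ref_id, a$r1_template,
                                             rep(40L, a$L)))
  r2 <- lapply(amps, function(a) read_record(a$ref_id, a$r2_template,
                                             rep(40L, a$L)))
  res <- join_pairs(r1, r2, cfg)
  expect_identical(res$n_joined + res$n_rejected, res$n_input)
  expect_identical(res$n_joined, length(amps))
  for (i in seq_along(amps)) {
    expect_identical(res$joined[[i]]$sequence, amps[[i]]$amplicon)
    expect_identical(res$overlap_len[i],
                     compute_overlap(310L, 310L, nchar(amps[[i]]$amplicon)))
  }
})

test_that("joined fraction is non-increasing as p_max_diff decreases", {
  set.seed(43)
  amps <- make_tiny_amplicons(n = 10, seed = 44)
  pool <- generate_quality_pool(50, 310, rng_seed = 6)
  cfg <- sim_config(n_samples = 1, min_refs = 8, max_refs = 10,
                    min_copies = 2, max_copies = 6, rng_seed = 9)
  set.seed(cfg$rng_seed)
  s <- simulate_sample(amps, pool, pool, cfg, "sC")
  fracs <- vapply(c(0, 4, 8, 16, 40), function(p) {
    join_pairs(s$r1, s$r2, join_config(p))$n_joined
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("mean-quality filtering uses the >= convention on the mean", {
  expect_true(mean_quality_filter(read_record("a", "ACG", rep(40L, 3)), 25))
  expect_false(mean_quality_filter(read_record("a", "ACG", rep(10L, 3)), 25))
  expect_true(mean_quality_filter(read_record("a", "AC", c(30L, 20L)), 25))
  expect_false(mean_quality_filter(structure("x", class = "empty_read"), 25))
})

test_that("good-read fraction is a guarded ratio", {
  expect_equal(good_read_fraction(100, 80), 0.8)
  expect_equal(good_read_fraction(57, 57), 1.0)
  expect_error(good_read_fraction(0, 0))
})
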