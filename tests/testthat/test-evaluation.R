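test_that("provenance composition counts reads per reference id", {
  reads <- list(read_record("s1.refA.1", "ACGT", rep(40L, 4)),
                read_record("s1.refA.2", "ACGT", rep(40L, 4)),
                read_record("s1.refB.1", "ACGT", rep(40L, 4)))
  comp <- build_composition(reads, "provenance")
  expect_identical(comp[["refA"]], 2L)
  expect_identical(comp[["refB"]], 1L)
  bad <- list(read_record("nodots", "ACGT", rep(40L, 4)))
  expect_error(build_composition(bad, "provenance"), "nodots")
})

test_that("exact-match composition assigns error-free joins only", {
  amps <- make_tiny_amplicons(n = 5, seed = 51)
  good <- read_record("x.y.1", amps[[2]]$amplicon,
                      rep(40L, nchar(amps[[2]]$amplicon)))
  seq2 <- amps[[3]]$amplicon
  substr(seq2, 10, 10) <- if (substr(seq2, 10, 10) == "A") "C" else "A"
  mutated <- read_record("x.z.1", seq2, rep(40L, nchar(seq2)))
  comp <- build_composition(list(good, mutated), "exact_match", refs = amps)
  expect_identical(comp[[amps[[2]]$ref_id]], 1L)
  expect_identical(attr(comp, "n_unassigned"), 1L)
})

test_that("fp/fn percentages follow their set-based definitions", {
  ff <- fp_fn_percent(c("a", "b", "c"), c("a", "b", "d"))
  expect_equal(as.numeric(ff), c(100 / 3, 100 / 3))
  expect_equal(as.numeric(fp_fn_percent(c("a", "b"), c("a", "b"))), c(0, 0))
  sup <- fp_fn_percent(c("a", "b", "c", "d"), c("a", "b"))
  expect_equal(sup[["fn_pct"]], 0)
  expect_gt(sup[["fp_pct"]], 0)
  expect_error(fp_fn_percent(c("a"), character(0)), "non-empty")
  # invariance under relabeling
  relab <- fp_fn_percent(c("x1", "x2", "x3"), c("x1", "x2", "x4"))
  expect_equal(as.numeric(relab), as.numeric(ff))
})

test_that("binary Jaccard matches the set formula", {
  tab <- composition_table(list(
    s1 = c(a = 5L, b = 1L),
    s2 = c(b = 2L, c = 9L),
    s3 = c(a = 1L, b = 1L)))
  d <- jaccard_matrix(tab, "binary")
  expect_equal(d["s1", "s2"], 2 / 3)   # share {b} of {a,b,c}
  expect_equal(d["s1", "s3"], 0)       # identical presence sets
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
  disjoint <- composition_table(list(u = c(a = 1L), v = c(b = 4L)))
  expect_equal(jaccard_matrix(disjoint, "binary")["u", "v"], 1)
})

test_that("abundance Jaccard equals 1 - sum(min)/sum(max)", {
  set.seed(53)
  tab <- matrix(rpois(5 * 8, 3), nrow = 5,
                dimnames = list(paste0("s", 1:5), paste0("r", 1:8)))
  tab[tab == 0] <- 1L    # avoid all-zero rows
  d <- jaccard_matrix(tab, "abundance")
  for (i in 1:4) for (j in (i + 1):5) {
    expected <- 1 - sum(pmin(tab[i, ], tab[j, ])) / sum(pmax(tab[i, ], tab[j, ]))
    expect_equal(d[i, j], expected)
    expect_equal(d[j, i], expected)
  }
})

test_that("jaccard matrices reject degenerate input", {
  tab <- composition_table(list(s1 = c(a = 1L), s2 = integer(0)))
  expect_error(jaccard_matrix(tab), "all-zero")
  expect_error(jaccard_matrix(composition_table(list(s1 = c(a = 1L)))))
})

test_that("random composition tables give bounded symmetric distances", {
  set.seed(59)
  for (i in 1:20) {
    tab <- matrix(rpois(6 * 10, 2), nrow = 6)
    tab[, 1] <- tab[, 1] + 1L  # guard against empty rows
    rownames(tab) <- paste0("s", 1:6); colnames(tab) <- paste0("r", 1:10)
    for (mode in c("binary", "abundance")) {
      d <- jaccard_matrix(tab, mode)
      expect_true(all(d >= 0 & d <= 1))
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
    }
  }
})

test_that("two-point PCoA splits a unit distance into +-0.5", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(pcoa_gold_distance(d, cbind("a", "b"))), 1)
  co <- pcoa_coordinates(d)
  expect_equal(unname(sort(abs(co[, 1]))), c(0.5, 0.5))
})

test_that("a sample at zero distance from its gold embeds at distance zero", {
  d <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0
  out <- pcoa_gold_distance(d, cbind("a", "b"))
  expect_equal(unname(out), 0, tolerance = 1e-10)
})

test_that("PCoA preserves Euclidean-embeddable distances", {
  set.seed(61)
  for (i in 1:10) {
    pts <- matrix(rnorm(6 * 3), 6, 3)
    rownames(pts) <- paste0("p", 1:6)
    D <- as.matrix(stats::dist(pts))
    co <- pcoa_coordinates(D)
    expect_equal(as.matrix(stats::dist(co)), D,
                 tolerance = 1e-8, ignore_attr = TRUE)
    # agrees with the direct eigendecomposition oracle on distances
    co2 <- pcoa_oracle(D)
    expect_equal(as.matrix(stats::dist(co2)), D,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("PCoA rejects non-symmetric input and unknown pair ids", {
  d <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(pcoa_gold_distance(d, cbind("a", "b")), "symmetric")
  ok <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(pcoa_gold_distance(ok, cbind("a", "z")), "z")
})
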