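# Brute-force oracles, kept independent of the package's implementation.

random_read <- function(len, id = "r", qmin = 2L, qmax = 40L) {
  read_record(id,
              paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = ""),
              sample(qmin:qmax, len, replace = TRUE))
}

revcomp_oracle <- function(s) {
  paste(rev(chartr("ACGT", "TGCA",
                   strsplit(s, "", fixed = TRUE)[[1L]])), collapse = "")
}

# enumerate every prefix, score it, tie toward the longest
mott_oracle <- function(quals, thr) {
  scores <- c(0, cumsum(quals - thr))  # scores[k + 1] = score of prefix length k
  best <- max(scores)
  max(which(scores == best)) - 1L
}

iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

find_primer_oracle <- function(seq, primer) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  p <- strsplit(primer, "", fixed = TRUE)[[1L]]
  if (length(p) > length(s)) return(NA_integer_)
  for (i in 0:(length(s) - length(p))) {
    ok <- TRUE
    for (j in seq_along(p)) {
      if (!s[i + j] %in% iupac_sets_oracle[[p[j]]]) { ok <- FALSE; break }
    }
    if (ok) return(i)
  }
  NA_integer_
}

# exhaustive overlap scan with full reconciliation, mirroring the stated
# merge semantics but written independently (vector arithmetic, no C++)
join_oracle <- function(r1, r2, p_max_diff, min_overlap) {
  s1 <- strsplit(r1$sequence, "", fixed = TRUE)[[1L]]
  s2rc <- strsplit(revcomp_oracle(r2$sequence), "", fixed = TRUE)[[1L]]
  q1 <- r1$qualities
  q2 <- rev(r2$qualities)
  L1 <- length(s1); L2 <- length(s2rc)
  best <- NULL
  for (ov in min_overlap:min(L1, L2)) {
    a <- s1[(L1 - ov + 1L):L1]
    b <- s2rc[1:ov]
    mm <- sum(a != b)
    pct <- 100 * mm / ov
    if (is.null(best) || pct < best$pct ||
        (pct == best$pct && ov > best$ov)) {
      best <- list(ov = ov, mm = mm, pct = pct)
    }
  }
  if (is.null(best) || best$pct > p_max_diff) {
    return(list(joined = FALSE, ov = if (is.null(best)) NA else best$ov,
                pct = if (is.null(best)) NA else best$pct))
  }
  ov <- best$ov
  head1 <- seq_len(L1 - ov)
  tail2 <- if (ov < L2) s2rc[(ov + 1L):L2] else character(0)
  tailq <- if (ov < L2) q2[(ov + 1L):L2] else integer(0)
  seq_out <- c(s1[head1], character(ov), tail2)
  qual_out <- c(q1[head1], integer(ov), tailq)
  for (j in seq_len(ov)) {
    i1 <- L1 - ov + j
    b1 <- s1[i1]; b2 <- s2rc[j]; a <- q1[i1]; b <- q2[j]
    if (b1 == b2) {
      seq_out[L1 - ov + j] <- b1; qual_out[L1 - ov + j] <- max(a, b)
    } else if (a >= b) {
      seq_out[L1 - ov + j] <- b1
      qual_out[L1 - ov + j] <- a - b
    } else {
      seq_out[L1 - ov + j] <- b2
      qual_out[L1 - ov + j] <- b - a
    }
  }
  list(joined = TRUE, ov = ov, mm = best$mm, pct = best$pct,
       seq = paste(seq_out, collapse = ""), qual = qual_out)
}

# classical PCoA by direct double-centering + eigendecomposition
pcoa_oracle <- function(D, tol = 1e-10) {
  D <- as.matrix(D)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- which(e$values > tol)
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  rownames(coords) <- rownames(D)
  coords
}

# small ready-made amplicon set for pipeline-level tests
make_tiny_amplicons <- function(n = 12, seed = 42) {
  refs <- generate_references(n, rng_seed = seed)
  extract_amplicons(refs)$amplicons
}
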