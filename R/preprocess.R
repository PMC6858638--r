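#' Trim leading primer bases from a read
#'
#' Removes the first `n` bases and their qualities: 17 for forward reads
#' and 21 for reverse reads with the default V3-V4 primer pair.
#'
#' @param read A [read_record()].
#' @param n Number of leading bases to remove.
#' @return The trimmed [read_record()]; if `n >= length`, an empty-read
#'   marker of class `empty_read` carrying the id.
#' @export
trim_primer <- function(read, n) {
  stopifnot(n >= 0)
  len <- nchar(read$sequence)
  if (n >= len) return(empty_read(read$id))
  if (n == 0L) return(read)
  new_read_record(read$id, substring(read$sequence, n + 1L),
                  read$qualities[(n + 1L):len])
}

empty_read <- function(id) structure(id, class = "empty_read")

#' Right-side quality trimming
#'
#' Trims the 3' (right) end of a read once quality drops below a phred
#' threshold. Two algorithms:
#' \describe{
#'   \item{`mott`}{Keep the prefix `[0, k)` maximizing
#'     `sum(Q[1:k] - q_thr)`, ties broken toward the longest prefix. This
#'     is the Mott running-sum rule used (right-side only) by common
#'     quality trimmers, and the package default.}
#'   \item{`first_below`}{Keep everything before the first position with
#'     `Q < q_thr` -- the literal "cut where quality first falls below the
#'     threshold" reading.}
#' }
#' Either may return an empty read (`k = 0`).
#'
#' @param read A [read_record()].
#' @param q_thr Phred threshold (>= 0).
#' @param algorithm `"mott"` or `"first_below"`.
#' @return The trimmed [read_record()], or an `empty_read` marker.
#' @examples
#' r <- read_record("r", "ACGTA", c(40L, 5L, 40L, 5L, 5L))
#' nchar(quality_trim_right(r, 10, "mott")$sequence)  # 3
#' @export
quality_trim_right <- function(read, q_thr, algorithm = c("mott", "first_below")) {
  algorithm <- match.arg(algorithm)
  stopifnot(q_thr >= 0)
  q <- read$qualities
  if (algorithm == "mott") {
    s <- cumsum(q - q_thr)
    best <- max(c(0, s))           # score of the empty prefix is 0
    cand <- which(s == best)
    k <- if (length(cand)) max(cand) else 0L
  } else {
    below <- which(q < q_thr)
    k <- if (length(below)) below[1L] - 1L else length(q)
  }
  if (k == 0L) return(empty_read(read$id))
  if (k == length(q)) return(read)
  new_read_record(read$id, substring(read$sequence, 1L, k), q[seq_len(k)])
}

#' Overlap length implied by read and amplicon lengths
#'
#' `len_r1 + len_r2 - amplicon_len`. Negative values are the calculated
#' gap between the two reads, in which case merging is impossible.
#'
#' @param len_r1,len_r2 Read lengths in bases.
#' @param amplicon_len Amplicon length in bases.
#' @return Signed overlap length (integer-valued).
#' @examples
#' compute_overlap(293, 289, 465)  # 117
#' compute_overlap(200, 200, 465)  # -65: a 65-base gap
#' @export
compute_overlap <- function(len_r1, len_r2, amplicon_len) {
  stopifnot(all(len_r1 >= 0), all(len_r2 >= 0), all(amplicon_len >= 0))
  len_r1 + len_r2 - amplicon_len
}

#' Trim a set of read pairs: primers, then right-side quality
#'
#' Applies [trim_primer()] (17/21 bases by default) followed by
#' [quality_trim_right()] to both mates, in that order. Pairs in which
#' either mate ends up shorter than `min_len` are discarded whole -- very
#' short or empty reads cannot take part in joining.
#'
#' @param r1,r2 Lists of [read_record()]s, pair-ordered.
#' @param q_thr Phred trimming threshold.
#' @param algorithm Trimming algorithm, see [quality_trim_right()].
#' @param fwd_primer_len,rev_primer_len Leading bases to remove (17/21).
#' @param min_len Minimum per-mate length to keep a pair (default 50).
#' @return List with `r1`, `r2` (surviving trimmed pairs, still ordered),
#'   `n_input`, `n_discarded`.
#' @export
trim_pairs <- function(r1, r2, q_thr, algorithm = c("mott", "first_below"),
                       fwd_primer_len = 17L, rev_primer_len = 21L,
                       min_len = 50L) {
  algorithm <- match.arg(algorithm)
  stopifnot(length(r1) == length(r2))
  t1 <- lapply(r1, function(r) {
    r <- trim_primer(r, fwd_primer_len)
    if (inherits(r, "empty_read")) r else quality_trim_right(r, q_thr, algorithm)
  })
  t2 <- lapply(r2, function(r) {
    r <- trim_primer(r, rev_primer_len)
    if (inherits(r, "empty_read")) r else quality_trim_right(r, q_thr, algorithm)
  })
  len1 <- vapply(t1, function(r) if (inherits(r, "empty_read")) 0L else nchar(r$sequence), integer(1))
  len2 <- vapply(t2, function(r) if (inherits(r, "empty_read")) 0L else nchar(r$sequence), integer(1))
  keep <- len1 >= min_len & len2 >= min_len
  list(r1 = t1[keep], r2 = t2[keep],
       n_input = length(r1), n_discarded = sum(!keep))
}
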