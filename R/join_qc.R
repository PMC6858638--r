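#' Pair-joining configuration
#'
#' @param p_max_diff Percent maximum difference: a candidate merge is
#'   rejected when the best overlap's mismatch percentage strictly exceeds
#'   this value. Default 8, the fastq-join default; the study design sweeps
#'   0--40 in steps of 4.
#' @param min_overlap Smallest overlap length considered (default 6).
#' @return A list of class `join_config`.
#' @export
join_config <- function(p_max_diff = 8, min_overlap = 6L) {
  stopifnot(p_max_diff >= 0, p_max_diff <= 100, min_overlap >= 1)
  structure(list(p_max_diff = p_max_diff, min_overlap = as.integer(min_overlap)),
            class = "join_config")
}

#' Merge one read pair by overlap
#'
#' R2 is reverse-complemented (qualities reversed) and slid along the end
#' of R1: every overlap length from `min_overlap` to `min(len1, len2)` is
#' scored by its mismatch percentage, and the overlap minimizing that
#' percentage is selected, ties broken toward the longer overlap. If the
#' best percentage strictly exceeds `p_max_diff` the pair is rejected.
#'
#' On a join the merged read is R1's non-overlap prefix, the reconciled
#' overlap, and the non-overlap suffix of reverse-complemented R2. Within
#' the overlap, agreeing bases keep the higher of the two qualities;
#' disagreeing positions take the base with the higher quality and a
#' quality equal to the absolute difference of the two (equal qualities:
#' R1's base, quality 0). Substitutions only; no gaps are modelled.
#'
#' @param r1,r2 [read_record()]s (R2 in sequencing orientation).
#' @param cfg A [join_config()].
#' @return A list of class `join_result`: `status` (`"joined"` /
#'   `"rejected"`), `merged` ([read_record()] or `NULL`), `overlap_len`,
#'   `mismatches`, `mismatch_pct`, and `reason` for rejections.
#' @export
join_pair <- function(r1, r2, cfg = join_config()) {
  if (inherits(r1, "empty_read") || inherits(r2, "empty_read") ||
      !nzchar(r1$sequence) || !nzchar(r2$sequence)) {
    return(structure(list(status = "rejected", merged = NULL,
                          overlap_len = NA_integer_,
                          mismatches = NA_integer_,
                          mismatch_pct = NA_real_, reason = "empty-read"),
                     class = "join_result"))
  }
  res <- cpp_join_pairs(r1$sequence, list(r1$qualities),
                        r2$sequence, list(r2$qualities),
                        cfg$p_max_diff, cfg$min_overlap)
  status <- if (res$joined[1L]) "joined" else "rejected"
  merged <- NULL
  if (res$joined[1L]) {
    merged <- read_record(r1$id, res$seq[1L], res$qual[[1L]])
  }
  structure(list(status = status, merged = merged,
                 overlap_len = res$overlap[1L],
                 mismatches = res$mismatches[1L],
                 mismatch_pct = res$pct[1L],
                 reason = if (res$joined[1L]) NA_character_ else "max-diff-exceeded"),
            class = "join_result")
}

#' Merge a set of read pairs
#'
#' Vectorized driver over [join_pair()] semantics (single C++ pass).
#'
#' @param r1,r2 Pair-ordered lists of [read_record()]s.
#' @param cfg A [join_config()].
#' @return List with `joined` (list of merged [read_record()]s),
#'   `overlap_len` / `mismatch_pct` (vectors over joined reads),
#'   `n_input`, `n_joined`, `n_rejected`.
#' @export
join_pairs <- function(r1, r2, cfg = join_config()) {
  stopifnot(length(r1) == length(r2))
  if (!length(r1)) {
    return(list(joined = list(), overlap_len = integer(0),
                mismatch_pct = numeric(0), n_input = 0L, n_joined = 0L,
                n_rejected = 0L))
  }
  res <- cpp_join_pairs(
    vapply(r1, `[[`, character(1), "sequence"),
    lapply(r1, `[[`, "qualities"),
    vapply(r2, `[[`, character(1), "sequence"),
    lapply(r2, `[[`, "qualities"),
    cfg$p_max_diff, cfg$min_overlap)
  ok <- res$joined
  ids <- vapply(r1, `[[`, character(1), "id")
  joined <- mapply(new_read_record, ids[ok], as.character(res$seq[ok]),
                   res$qual[ok], SIMPLIFY = FALSE, USE.NAMES = FALSE)
  list(joined = joined,
       overlap_len = res$overlap[ok],
       mismatch_pct = res$pct[ok],
       n_input = length(r1), n_joined = sum(ok), n_rejected = sum(!ok))
}

#' Mean-quality read filter
#'
#' Keeps a read iff the arithmetic mean of its phred scores is at least
#' `min_mean_q` -- the post-join quality-control rule that defines "good
#' reads" together with joining itself.
#'
#' @param read A [read_record()] (or `empty_read` marker, which is
#'   dropped).
#' @param min_mean_q Mean-quality threshold (default 25).
#' @return `TRUE` (keep) or `FALSE` (drop).
#' @export
mean_quality_filter <- function(read, min_mean_q = 25) {
  if (inherits(read, "empty_read") || !length(read$qualities)) return(FALSE)
  mean(read$qualities) >= min_mean_q
}

#' Fraction of good reads
#'
#' Number of reads surviving joining and quality control divided by the
#' original number of raw read pairs.
#'
#' @param raw_count Raw read-pair count (> 0).
#' @param good_count Good-read count (`0 <= good_count <= raw_count`).
#' @return `good_count / raw_count`.
#' @export
good_read_fraction <- function(raw_count, good_count) {
  stopifnot(raw_count > 0, good_count >= 0, good_count <= raw_count)
  good_count / raw_count
}
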