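IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Published V3-V4 primer pair
#'
#' Degenerate sequences of the bacterial 16S primers S-D-Bact-0341-b-S-17
#' (forward, 17 nt, "341F") and S-D-Bact-0785-a-A-21 (reverse, 21 nt,
#' "805R"), which delimit the ~460-470 nt V3-V4 amplicon.
#'
#' @return A named character vector with elements `fwd` and `rev`.
#' @export
default_primers <- function() {
  c(fwd = "CCTACGGGNGGCWGCAG", rev = "GACTACHVGGGTATCTAATCC")
}

#' IUPAC-aware base matching
#'
#' @param pattern_char Single IUPAC nucleotide code.
#' @param base Single concrete base in `{A,C,G,T}`.
#' @return `TRUE` iff `base` belongs to the degeneracy set of `pattern_char`.
#' @examples
#' iupac_match("W", "A")  # TRUE
#' iupac_match("W", "C")  # FALSE
#' @export
iupac_match <- function(pattern_char, base) {
  set <- IUPAC_SETS[[toupper(pattern_char)]]
  if (is.null(set)) {
    stop(sprintf("unknown IUPAC code '%s'", pattern_char), call. = FALSE)
  }
  if (!base %in% c("A", "C", "G", "T")) {
    stop(sprintf("subject base must be concrete, got '%s'", base),
         call. = FALSE)
  }
  base %in% set
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' @param x Nucleotide string (degenerate codes allowed).
#' @return The reverse complement, as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Locate the first occurrence of a degenerate primer
#'
#' Scans `seq` left to right for the first window at which every primer
#' position matches under IUPAC degeneracy ([iupac_match()]). Matching is
#' exact up to degeneracy: no mismatches or indels are tolerated.
#'
#' @param seq Concrete nucleotide string (subject).
#' @param primer Degenerate IUPAC primer string.
#' @param from 0-based position at which to start the search.
#' @return 0-based start index of the first match, or `NA_integer_` if the
#'   primer does not occur.
#' @examples
#' find_primer_site("TTACGTGG", "ACGT")  # 2
#' @export
find_primer_site <- function(seq, primer, from = 0L) {
  stopifnot(nzchar(primer))
  subj <- Biostrings::DNAString(seq)
  if (from > 0L) {
    if (from + nchar(primer) > nchar(seq)) return(NA_integer_)
    subj <- Biostrings::subseq(subj, start = from + 1L)
  }
  hits <- Biostrings::matchPattern(Biostrings::DNAString(primer), subj,
                                   fixed = FALSE)
  if (length(hits) == 0L) return(NA_integer_)
  as.integer(BiocGenerics::start(hits)[1L] - 1L + from)
}

#' Extract a primer-delimited amplicon and its paired read templates
#'
#' Locates the forward primer on the forward strand and the reverse primer
#' as the first occurrence of its reverse complement downstream of the
#' forward site (the proximal site, giving the shortest amplicon). The
#' amplicon spans from the start of the forward-primer site through the end
#' of the reverse-primer site inclusive, so both primer-binding regions are
#' part of the amplicon and of the simulated reads. The R1 template is the
#' first `L` bases of the amplicon; the R2 template is the reverse
#' complement of its last `L` bases. All coordinates are 0-based half-open.
#'
#' @param ref A [seq_record()] reference sequence.
#' @param fwd_primer,rev_primer Degenerate IUPAC primer strings (defaults:
#'   [default_primers()]).
#' @param L Template length in bases (default 310).
#' @return An object of class `amplicon_reference` with fields `ref_id`,
#'   `amplicon`, `r1_template`, `r2_template`, `L`; or `NULL` with attribute
#'   `skip_reason` unavailable -- skips are signalled by returning a
#'   character scalar of class `amplicon_skip` naming the reason
#'   (`"fwd-primer-not-found"`, `"rev-primer-not-found"`,
#'   `"amplicon-too-short"`).
#' @export
extract_amplicon <- function(ref, fwd_primer = default_primers()[["fwd"]],
                             rev_primer = default_primers()[["rev"]],
                             L = 310L) {
  fwd_at <- find_primer_site(ref$sequence, fwd_primer)
  if (is.na(fwd_at)) return(amplicon_skip(ref$id, "fwd-primer-not-found"))
  rev_site <- revcomp(rev_primer)
  rev_at <- find_primer_site(ref$sequence, rev_site,
                             from = fwd_at + nchar(fwd_primer))
  if (is.na(rev_at)) return(amplicon_skip(ref$id, "rev-primer-not-found"))
  amp_end <- rev_at + nchar(rev_site)       # half-open end
  amplicon <- substr(ref$sequence, fwd_at + 1L, amp_end)
  if (nchar(amplicon) < L) return(amplicon_skip(ref$id, "amplicon-too-short"))
  alen <- nchar(amplicon)
  structure(list(
    ref_id = ref$id,
    amplicon = amplicon,
    r1_template = substr(amplicon, 1L, L),
    r2_template = revcomp(substr(amplicon, alen - L + 1L, alen)),
    L = as.integer(L)
  ), class = "amplicon_reference")
}

amplicon_skip <- function(ref_id, reason) {
  structure(reason, ref_id = ref_id, class = "amplicon_skip")
}

#' Extract amplicons from a whole reference set
#'
#' Applies [extract_amplicon()] to every record, separating accepted
#' amplicons from skipped references.
#'
#' @param refs List of [seq_record()]s.
#' @inheritParams extract_amplicon
#' @return A list with `amplicons` (list of `amplicon_reference`) and
#'   `skipped` (data.frame with columns `ref_id`, `reason`).
#' @export
extract_amplicons <- function(refs, fwd_primer = default_primers()[["fwd"]],
                              rev_primer = default_primers()[["rev"]],
                              L = 310L) {
  res <- lapply(refs, extract_amplicon, fwd_primer = fwd_primer,
                rev_primer = rev_primer, L = L)
  is_skip <- vapply(res, inherits, logical(1), "amplicon_skip")
  skipped <- data.frame(
    ref_id = vapply(res[is_skip], attr, character(1), "ref_id"),
    reason = vapply(res[is_skip], unclass, character(1)),
    stringsAsFactors = FALSE
  )
  list(amplicons = res[!is_skip], skipped = skipped)
}

#' Write the amplicon set and paired templates as FASTA
#'
#' Emits `V3-V4.fasta` (full amplicons), `ref_R1.fasta` and `ref_R2.fasta`
#' (the L-base read templates) plus a tab-separated skip report.
#'
#' @param extraction Result of [extract_amplicons()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_amplicon_set <- function(extraction, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  amps <- extraction$amplicons
  write_fasta(lapply(amps, function(a) seq_record(a$ref_id, a$amplicon)),
              file.path(dir, "V3-V4.fasta"))
  write_fasta(lapply(amps, function(a) seq_record(a$ref_id, a$r1_template)),
              file.path(dir, "ref_R1.fasta"))
  write_fasta(lapply(amps, function(a) seq_record(a$ref_id, a$r2_template)),
              file.path(dir, "ref_R2.fasta"))
  utils::write.table(extraction$skipped, file.path(dir, "skipped.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
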