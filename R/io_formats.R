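#' Sequence and read containers
#'
#' `seq_record()` holds a named nucleotide sequence (a reference entry);
#' `read_record()` additionally carries one phred quality score per base,
#' as found in a FASTQ record.
#'
#' @param id Character scalar identifier.
#' @param sequence Uppercase nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param qualities Integer vector of per-base phred scores in `[0, 41]`,
#'   same length as `sequence`.
#' @return An object of class `seq_record` or `read_record` (a named list).
#' @examples
#' read_record("r1", "ACGT", c(40L, 40L, 38L, 2L))
#' @export
seq_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop("sequence must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence), class = "seq_record")
}

#' @rdname seq_record
#' @export
read_record <- function(id, sequence, qualities) {
  qualities <- as.integer(qualities)
  if (nchar(sequence) != length(qualities)) {
    stop(sprintf("read '%s': sequence length %d != quality length %d",
                 id, nchar(sequence), length(qualities)), call. = FALSE)
  }
  if (length(qualities) && (min(qualities) < 0L || max(qualities) > 41L)) {
    stop(sprintf("read '%s': phred scores must lie in [0, 41]", id),
         call. = FALSE)
  }
  rec <- seq_record(id, sequence)
  rec$qualities <- qualities
  class(rec) <- c("read_record", "seq_record")
  rec
}

# validation-free constructor for hot paths (simulation, trimming, joining);
# inputs there are produced by code that already guarantees the invariants
new_read_record <- function(id, sequence, qualities) {
  structure(list(id = id, sequence = sequence, qualities = qualities),
            class = c("read_record", "seq_record"))
}

#' @export
print.read_record <- function(x, ...) {
  cat(sprintf("<read_record> %s (%d bases)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' Phred+33 quality codec
#'
#' Converts between FASTQ quality strings and integer phred scores using the
#' phred+33 (Illumina 1.8+) offset. No encoding auto-detection is attempted.
#'
#' @param encoded ASCII quality string; all characters must have codepoints
#'   in `[33, 74]` (phred 0--41).
#' @param qualities Integer vector of phred scores in `[0, 41]`.
#' @return `decode_quality()`: an integer vector, one score per character.
#'   `encode_quality()`: a single ASCII string.
#' @examples
#' decode_quality("!I")        # 0 40
#' encode_quality(c(0L, 40L))  # "!I"
#' @export
decode_quality <- function(encoded) {
  stopifnot(is.character(encoded), length(encoded) == 1L)
  codes <- utf8ToInt(encoded)
  bad <- which(codes < 33L | codes > 74L)
  if (length(bad)) {
    stop(sprintf(
      "invalid phred+33 quality character '%s' at position %d",
      substr(encoded, bad[1L], bad[1L]), bad[1L]), call. = FALSE)
  }
  codes - 33L
}

#' @rdname decode_quality
#' @export
encode_quality <- function(qualities) {
  qualities <- as.integer(qualities)
  if (length(qualities) && (min(qualities) < 0L || max(qualities) > 41L)) {
    stop("phred scores must lie in [0, 41] for phred+33 encoding",
         call. = FALSE)
  }
  intToUtf8(qualities + 33L)
}

#' Read and write FASTQ files
#'
#' Strict 4-line-per-record FASTQ with phred+33 qualities. Reading is
#' transparent to gzip compression (via base R connections); writing is
#' always plain text.
#'
#' @param path File path; `.gz` inputs are decompressed on the fly.
#' @param records A list of [read_record()] objects.
#' @return `read_fastq()`: a list of [read_record()]s. `write_fastq()`:
#'   the path, invisibly.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ '%s': %d lines is not a multiple of 4",
                 path, length(lines)), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    j <- (i - 1L) * 4L
    hdr <- lines[j + 1L]
    if (!startsWith(hdr, "@")) {
      stop(sprintf("malformed FASTQ record %d in '%s': header '%s'",
                   i, path, hdr), call. = FALSE)
    }
    if (!startsWith(lines[j + 3L], "+")) {
      stop(sprintf("malformed FASTQ record %d in '%s': missing '+' line",
                   i, path), call. = FALSE)
    }
    id <- sub("\\s.*$", "", substring(hdr, 2L))
    out[[i]] <- read_record(id, lines[j + 2L], decode_quality(lines[j + 4L]))
  }
  out
}

#' @rdname read_fastq
#' @export
write_fastq <- function(records, path) {
  lines <- character(4L * length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    j <- (i - 1L) * 4L
    lines[j + 1L] <- paste0("@", r$id)
    lines[j + 2L] <- r$sequence
    lines[j + 3L] <- "+"
    lines[j + 4L] <- encode_quality(r$qualities)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings. Multi-line FASTA is accepted on read;
#' single-line records are written (greengenes style).
#'
#' @param path File path; gzip transparent on read.
#' @param records A list of [seq_record()] objects.
#' @return `read_fasta()`: a list of [seq_record()]s.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  mapply(seq_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  seqs <- vapply(records, `[[`, character(1), "sequence")
  names(seqs) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 20000L)
  invisible(path)
}
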