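#' Generate a synthetic 16S-like reference set with embedded primer sites
#'
#' Builds reference sequences that stand in for a 16S database: random
#' flanks surround an amplicon that begins with a concrete realization of
#' the degenerate forward primer and ends with a realization of the reverse
#' complement of the degenerate reverse primer. The primer-start to
#' primer-site-end span is drawn from Normal(`amplicon_len_mean`,
#' `amplicon_len_sd`), rounded and clipped to at least `min_amplicon_len`
#' so that read templates of the default length remain extractable.
#' Construction is rejection-checked so the forward primer and (downstream
#' of it) the reverse-primer site each occur exactly where intended.
#'
#' @param n Number of references.
#' @param amplicon_len_mean,amplicon_len_sd Amplicon length distribution in
#'   bases. The defaults, Normal(465, 10), reflect the V3-V4 span between
#'   the 341F/805R primer pair.
#' @param fwd_primer,rev_primer Degenerate IUPAC primers.
#' @param flank_len Random flank length on each side (bases).
#' @param min_amplicon_len Lower clip for the amplicon length (default 311).
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @return List of [seq_record()]s with ids `ref0001`, `ref0002`, ...
#' @export
generate_references <- function(n, amplicon_len_mean = 465,
                                amplicon_len_sd = 10,
                                fwd_primer = default_primers()[["fwd"]],
                                rev_primer = default_primers()[["rev"]],
                                flank_len = 50L,
                                min_amplicon_len = 311L,
                                rng_seed = 1L) {
  stopifnot(n >= 1)
  plen <- nchar(fwd_primer) + nchar(rev_primer)
  if (amplicon_len_mean < 2 * plen) {
    stop("amplicon_len_mean must be at least twice the combined primer length",
         call. = FALSE)
  }
  if (min_amplicon_len < plen + 1L) {
    stop("min_amplicon_len leaves no room between the primer sites",
         call. = FALSE)
  }
  set.seed(rng_seed)
  rev_site <- revcomp(rev_primer)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      alen <- max(round(stats::rnorm(1, amplicon_len_mean, amplicon_len_sd)),
                  min_amplicon_len)
      fwd_real <- realize_degenerate(fwd_primer)
      rev_real <- realize_degenerate(rev_site)
      mid <- random_bases(alen - plen)
      seqn <- paste0(random_bases(flank_len), fwd_real, mid, rev_real,
                     random_bases(flank_len))
      # reject the rare draw where a flank or the middle spawns a spurious site
      if (identical(find_primer_site(seqn, fwd_primer), as.integer(flank_len)) &&
          identical(find_primer_site(seqn, rev_site,
                                     from = flank_len + nchar(fwd_primer)),
                    as.integer(flank_len + alen - nchar(rev_site)))) {
        break
      }
    }
    out[[i]] <- seq_record(sprintf("ref%04d", i), seqn)
  }
  out
}

random_bases <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

realize_degenerate <- function(primer) {
  chars <- strsplit(primer, "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop(sprintf("unknown IUPAC code '%s'", ch), call. = FALSE)
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

#' Positional quality-decay parameters
#'
#' Describes the expected per-position phred profile of a 2x300-style
#' Illumina run: a high-quality plateau followed by a linear decline toward
#' a floor, with Gaussian position-wise noise. R2 profiles share the shape
#' but are uniformly worse by `r2_penalty`, as in real paired-end data.
#' The floor of 2 is the Illumina no-call score; the ceiling 40 matches the
#' gold-standard quality.
#'
#' @param plateau_q Expected quality before decay starts (default 38).
#' @param floor_q Lower bound of the expected quality (default 2).
#' @param decay_start 0-based position at which the decline begins.
#' @param decay_rate Expected phred units lost per base after `decay_start`.
#' @param noise_sd Standard deviation of the per-position Gaussian noise.
#' @param r2_penalty Phred units subtracted from the R2 expectation.
#' @return A list of class `decay_params`.
#' @export
decay_params <- function(plateau_q = 38L, floor_q = 2L, decay_start = 150L,
                         decay_rate = 0.18, noise_sd = 3, r2_penalty = 6L) {
  stopifnot(floor_q <= plateau_q, decay_start >= 0, decay_rate >= 0,
            noise_sd >= 0, r2_penalty >= 0)
  structure(list(plateau_q = plateau_q, floor_q = floor_q,
                 decay_start = decay_start, decay_rate = decay_rate,
                 noise_sd = noise_sd, r2_penalty = r2_penalty),
            class = "decay_params")
}

#' Generate a pool of per-read quality profiles
#'
#' Emulates the pools of quality-score vectors harvested from real V3-V4
#' FASTQ files: each profile is the expected decay curve of
#' [decay_params()] plus independent Gaussian noise, rounded and clipped to
#' `[2, 40]`. During simulation profiles are drawn from the pool with
#' replacement.
#'
#' @param n_profiles Number of profiles in the pool.
#' @param read_length Profile length in bases (default 310, matching the
#'   read templates).
#' @param params A [decay_params()] object.
#' @param mate `"R1"` or `"R2"`; R2 expectations are lowered by
#'   `params$r2_penalty`.
#' @param rng_seed Integer seed.
#' @return A list of integer vectors, each of length `read_length`.
#' @export
generate_quality_pool <- function(n_profiles, read_length = 310L,
                                  params = decay_params(),
                                  mate = c("R1", "R2"), rng_seed = 1L) {
  stopifnot(n_profiles >= 1, read_length >= 1)
  mate <- match.arg(mate)
  set.seed(rng_seed)
  pos <- seq_len(read_length) - 1L
  expected <- params$plateau_q -
    pmax(0, pos - params$decay_start) * params$decay_rate
  if (mate == "R2") expected <- expected - params$r2_penalty
  expected <- pmax(expected, params$floor_q)
  lapply(seq_len(n_profiles), function(i) {
    q <- round(expected + stats::rnorm(read_length, 0, params$noise_sd))
    as.integer(pmin(pmax(q, 2L), 40L))
  })
}

#' Write / read quality pools as plain text
#'
#' One profile per line, space-separated phred integers.
#'
#' @param pool List of integer vectors.
#' @param path File path.
#' @return `read_quality_pool()`: a list of integer vectors.
#' @export
write_quality_pool <- function(pool, path) {
  writeLines(vapply(pool, paste, character(1), collapse = " "), path)
  invisible(path)
}

#' @rdname write_quality_pool
#' @export
read_quality_pool <- function(path) {
  lapply(strsplit(readLines(path), " ", fixed = TRUE), as.integer)
}

#' Build a quality pool from existing FASTQ files
#'
#' Imports the quality vectors of user-supplied reads (e.g. real V3-V4
#' data) as a profile pool, discarding the sequences.
#'
#' @param paths FASTQ file paths.
#' @param read_length Keep only reads of exactly this length (`NULL` keeps
#'   all).
#' @return A list of integer quality vectors.
#' @export
quality_pool_from_fastq <- function(paths, read_length = NULL) {
  pool <- unlist(lapply(paths, function(p) {
    lapply(read_fastq(p), `[[`, "qualities")
  }), recursive = FALSE)
  if (!is.null(read_length)) {
    pool <- pool[lengths(pool) == read_length]
  }
  if (!length(pool)) stop("no usable quality profiles found", call. = FALSE)
  pool
}
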