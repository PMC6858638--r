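#' Map a phred score to base-call probabilities
#'
#' Two substitution error models are provided. `standard_phred` follows the
#' phred definition: the error probability is `10^(-Q/10)`, split evenly
#' over the three alternative bases. `as_printed` is the inverted mapping
#' in which `10^(-Q/10)` is the probability of the *called* base (so Q = 2
#' gives 0.63 for the called base and 0.123 for each alternative). Both are
#' kept because they imply very different error rates at high quality;
#' which to use is a [sim_config()] choice.
#'
#' @param Q Non-negative phred score (scalar or vector).
#' @param model `"standard_phred"` or `"as_printed"`.
#' @return A list with `p_called` and `p_each_alt`, each the same length as
#'   `Q`; always `p_called + 3 * p_each_alt == 1`.
#' @examples
#' phred_to_probs(2, "as_printed")      # p_called ~0.63
#' phred_to_probs(40, "standard_phred") # p_called 0.9999
#' @export
phred_to_probs <- function(Q, model = c("standard_phred", "as_printed")) {
  model <- match.arg(model)
  if (any(Q < 0)) stop("phred scores must be non-negative", call. = FALSE)
  p <- 10^(-Q / 10)
  p_called <- switch(model, as_printed = p, standard_phred = 1 - p)
  list(p_called = p_called, p_each_alt = (1 - p_called) / 3)
}

#' Inject phred-driven substitution errors into a template
#'
#' Each position is independently resampled: the template base is kept with
#' `p_called` for its quality score, otherwise one of the three alternative
#' bases is chosen uniformly. `N` bases in the template are first replaced
#' by a uniform random base. Uses the R RNG stream, so results are
#' reproducible under `set.seed()`.
#'
#' @param template Nucleotide string.
#' @param quals Integer phred vector, same length as `template`.
#' @param model Error model passed to [phred_to_probs()], or `"none"` to
#'   return the template unchanged (the gold-standard path).
#' @return The mutated nucleotide string.
#' @export
inject_errors <- function(template, quals,
                          model = c("standard_phred", "as_printed", "none")) {
  model <- match.arg(model)
  if (model == "none") return(template)
  if (nchar(template) != length(quals)) {
    stop("template and quality lengths differ", call. = FALSE)
  }
  cpp_inject_errors(template, as.integer(quals),
                    model == "as_printed")
}

#' Simulation configuration
#'
#' @param n_samples Number of samples (default 10).
#' @param min_refs,max_refs Range of distinct references per sample
#'   (uniform integer; defaults 20--60).
#' @param min_copies,max_copies Range of copies per chosen reference
#'   (uniform integer; defaults 1--100).
#' @param L Read/template length (default 310).
#' @param gold_quality Constant phred score of gold-standard reads
#'   (default 40).
#' @param error_model `"standard_phred"`, `"as_printed"` or `"none"`.
#' @param rng_seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 10L, min_refs = 20L, max_refs = 60L,
                       min_copies = 1L, max_copies = 100L, L = 310L,
                       gold_quality = 40L,
                       error_model = c("standard_phred", "as_printed", "none"),
                       rng_seed = 1L) {
  error_model <- match.arg(error_model)
  stopifnot(n_samples >= 1, min_refs >= 1, max_refs >= min_refs,
            min_copies >= 1, max_copies >= min_copies,
            gold_quality >= 2, gold_quality <= 41)
  structure(list(n_samples = n_samples, min_refs = min_refs,
                 max_refs = max_refs, min_copies = min_copies,
                 max_copies = max_copies, L = as.integer(L),
                 gold_quality = as.integer(gold_quality),
                 error_model = error_model, rng_seed = rng_seed),
            class = "sim_config")
}

#' Simulate one sample and its gold standard
#'
#' Draws a random subset of references and a random copy count per
#' reference; each copy receives R1/R2 quality profiles sampled (with
#' replacement) from the pools and substitution errors per the error model.
#' The gold standard contains the *same* reads -- same ids, same templates,
#' same multiset -- with unmutated sequences and constant quality
#' `gold_quality`. Read ids are `{sample}.{ref_id}.{copy}`, the provenance
#' channel used by the evaluation module.
#'
#' @param refs List of `amplicon_reference` objects ([extract_amplicons()]).
#' @param pool_r1,pool_r2 Quality profile pools ([generate_quality_pool()]);
#'   profile lengths must equal `cfg$L`.
#' @param cfg A [sim_config()].
#' @param sample_id Sample identifier (no dots).
#' @return A list with `r1`, `r2`, `gold_r1`, `gold_r2` (lists of
#'   [read_record()]s) and `truth` (data.frame `ref_id`, `count`).
#' @export
simulate_sample <- function(refs, pool_r1, pool_r2, cfg, sample_id) {
  if (!length(refs)) stop("empty reference set", call. = FALSE)
  if (!length(pool_r1) || !length(pool_r2)) {
    stop("empty quality pool", call. = FALSE)
  }
  if (any(lengths(pool_r1) != cfg$L) || any(lengths(pool_r2) != cfg$L)) {
    stop("quality profile length must equal the template length L",
         call. = FALSE)
  }
  if (grepl(".", sample_id, fixed = TRUE)) {
    stop("sample_id must not contain '.'", call. = FALSE)
  }
  n_refs <- sample(seq(min(cfg$min_refs, length(refs)),
                       min(cfg$max_refs, length(refs))), 1L)
  chosen <- sample(seq_along(refs), n_refs)
  counts <- sample(seq(cfg$min_copies, cfg$max_copies), n_refs,
                   replace = TRUE)
  total <- sum(counts)
  r1 <- vector("list", total); r2 <- vector("list", total)
  g1 <- vector("list", total); g2 <- vector("list", total)
  goldq <- rep.int(cfg$gold_quality, cfg$L)
  k <- 0L
  for (j in seq_len(n_refs)) {
    ref <- refs[[chosen[j]]]
    for (copy in seq_len(counts[j])) {
      k <- k + 1L
      id <- paste(sample_id, ref$ref_id, copy, sep = ".")
      q1 <- pool_r1[[sample.int(length(pool_r1), 1L)]]
      q2 <- pool_r2[[sample.int(length(pool_r2), 1L)]]
      r1[[k]] <- new_read_record(id, inject_errors(ref$r1_template, q1,
                                                   cfg$error_model), q1)
      r2[[k]] <- new_read_record(id, inject_errors(ref$r2_template, q2,
                                                   cfg$error_model), q2)
      g1[[k]] <- new_read_record(id, ref$r1_template, goldq)
      g2[[k]] <- new_read_record(id, ref$r2_template, goldq)
    }
  }
  truth <- data.frame(
    ref_id = vapply(refs[chosen], `[[`, character(1), "ref_id"),
    count = counts, stringsAsFactors = FALSE
  )
  list(r1 = r1, r2 = r2, gold_r1 = g1, gold_r2 = g2, truth = truth)
}

#' Simulate a whole study and optionally write it to disk
#'
#' Generates `cfg$n_samples` samples (ids `s1`, `s2`, ...) from one seeded
#' RNG stream. When `dir` is given, emits per sample
#' `{id}_R1.fastq`, `{id}_R2.fastq`, `{id}_gold_R1.fastq`,
#' `{id}_gold_R2.fastq` and `{id}_truth.tsv`.
#'
#' @inheritParams simulate_sample
#' @param dir Optional output directory.
#' @return Named list of [simulate_sample()] results, one per sample.
#' @export
simulate_study <- function(refs, pool_r1, pool_r2, cfg, dir = NULL) {
  set.seed(cfg$rng_seed)
  ids <- paste0("s", seq_len(cfg$n_samples))
  out <- lapply(ids, function(sid) {
    simulate_sample(refs, pool_r1, pool_r2, cfg, sid)
  })
  names(out) <- ids
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (sid in ids) {
      s <- out[[sid]]
      write_fastq(s$r1, file.path(dir, paste0(sid, "_R1.fastq")))
      write_fastq(s$r2, file.path(dir, paste0(sid, "_R2.fastq")))
      write_fastq(s$gold_r1, file.path(dir, paste0(sid, "_gold_R1.fastq")))
      write_fastq(s$gold_r2, file.path(dir, paste0(sid, "_gold_R2.fastq")))
      utils::write.table(s$truth, file.path(dir, paste0(sid, "_truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
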