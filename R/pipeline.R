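#' Sweep configuration
#'
#' Bundles every stage's parameters for the end-to-end experiment: a grid
#' of right-side quality-trimming thresholds crossed with
#' percent-maximum-difference values.
#'
#' @param q_thr_values Trimming thresholds (default the even values 0--20).
#' @param p_values Percent-maximum-difference values (default `c(4, 8, 12)`
#'   out of the full 0--40-step-4 sweep).
#' @param n_refs Number of synthetic references to generate.
#' @param sim A [sim_config()].
#' @param decay A [decay_params()] describing the quality pools.
#' @param n_profiles Profiles per quality pool.
#' @param trim_algorithm `"mott"` or `"first_below"`.
#' @param min_len Minimum per-mate length after trimming (default 50).
#' @param min_overlap Minimum join overlap (default 6).
#' @param min_mean_q Mean-quality threshold for good reads (default 25).
#' @param rng_seed Master seed; reference generation, pools and samples
#'   derive their streams from it.
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(q_thr_values = seq(0L, 20L, 2L),
                         p_values = c(4, 8, 12),
                         n_refs = 120L,
                         sim = sim_config(),
                         decay = decay_params(),
                         n_profiles = 500L,
                         trim_algorithm = c("mott", "first_below"),
                         min_len = 50L,
                         min_overlap = 6L,
                         min_mean_q = 25,
                         rng_seed = 1L) {
  trim_algorithm <- match.arg(trim_algorithm)
  stopifnot(all(q_thr_values >= 0), all(p_values >= 0), all(p_values <= 100))
  structure(list(q_thr_values = q_thr_values, p_values = p_values,
                 n_refs = n_refs, sim = sim, decay = decay,
                 n_profiles = n_profiles, trim_algorithm = trim_algorithm,
                 min_len = min_len, min_overlap = min_overlap,
                 min_mean_q = min_mean_q, rng_seed = rng_seed),
            class = "sweep_config")
}

#' Run the full trimming-by-merging sweep experiment
#'
#' Generates a synthetic reference set, quality pools and simulated samples
#' with gold standards, then for every (sample, q_thr, p) cell runs primer
#' trimming, right-side quality trimming, pair joining, mean-quality
#' filtering, composition recovery and gold-standard comparison. Samples
#' and their gold standards are processed identically and ordinated
#' together; failures in a cell (e.g. no surviving reads) yield `NA`
#' metrics rather than aborting the run.
#'
#' @param cfg A [sweep_config()].
#' @param verbose Print one progress line per grid cell.
#' @return A data.frame with one row per (sample, q_thr, p):
#'   `sample`, `q_thr`, `p_max_diff`, `n_raw`, `n_trim_discarded`,
#'   `n_joined`, `n_good`, `good_fraction`, `mean_overlap`
#'   (trimmed-length-implied overlap, negative = gap), `fp_pct`, `fn_pct`,
#'   `gold_distance`, `n_observed`.
#' @export
run_experiment <- function(cfg = sweep_config(), verbose = FALSE) {
  refs <- generate_references(cfg$n_refs, rng_seed = cfg$rng_seed)
  amps <- extract_amplicons(refs, L = cfg$sim$L)$amplicons
  pool_r1 <- generate_quality_pool(cfg$n_profiles, cfg$sim$L, cfg$decay,
                                   "R1", rng_seed = cfg$rng_seed + 1L)
  pool_r2 <- generate_quality_pool(cfg$n_profiles, cfg$sim$L, cfg$decay,
                                   "R2", rng_seed = cfg$rng_seed + 2L)
  sim <- cfg$sim
  sim$rng_seed <- cfg$rng_seed + 3L
  study <- simulate_study(amps, pool_r1, pool_r2, sim)
  amp_len <- vapply(amps, function(a) nchar(a$amplicon), integer(1))
  names(amp_len) <- vapply(amps, `[[`, character(1), "ref_id")

  rows <- list()
  for (q_thr in cfg$q_thr_values) {
    cells <- lapply(names(study), function(sid) {
      s <- study[[sid]]
      trimmed <- trim_pairs(s$r1, s$r2, q_thr, cfg$trim_algorithm,
                            min_len = cfg$min_len)
      gtrim <- trim_pairs(s$gold_r1, s$gold_r2, q_thr, cfg$trim_algorithm,
                          min_len = cfg$min_len)
      len1 <- vapply(trimmed$r1, function(r) nchar(r$sequence), integer(1))
      len2 <- vapply(trimmed$r2, function(r) nchar(r$sequence), integer(1))
      ref_of <- vapply(strsplit(vapply(trimmed$r1, `[[`, character(1), "id"),
                                ".", fixed = TRUE), `[`, character(1), 2L)
      mean_ov <- if (length(len1)) {
        mean(compute_overlap(len1, len2, amp_len[ref_of]))
      } else NA_real_
      list(sid = sid, trimmed = trimmed, gtrim = gtrim, mean_ov = mean_ov)
    })
    for (p in cfg$p_values) {
      comp_rows <- list()
      stats_rows <- list()
      jcfg <- join_config(p_max_diff = p, min_overlap = cfg$min_overlap)
      for (cell in cells) {
        sid <- cell$sid
        jr <- join_pairs(cell$trimmed$r1, cell$trimmed$r2, jcfg)
        good <- Filter(function(r) mean_quality_filter(r, cfg$min_mean_q),
                       jr$joined)
        gjr <- join_pairs(cell$gtrim$r1, cell$gtrim$r2, jcfg)
        ggood <- Filter(function(r) mean_quality_filter(r, cfg$min_mean_q),
                        gjr$joined)
        n_raw <- length(study[[sid]]$r1)
        comp_rows[[sid]] <- if (length(good)) {
          build_composition(good, "provenance")
        } else integer(0)
        comp_rows[[paste0(sid, "_gold")]] <- if (length(ggood)) {
          build_composition(ggood, "provenance")
        } else integer(0)
        stats_rows[[sid]] <- data.frame(
          sample = sid, q_thr = q_thr, p_max_diff = p,
          n_raw = n_raw, n_trim_discarded = cell$trimmed$n_discarded,
          n_joined = jr$n_joined, n_good = length(good),
          good_fraction = good_read_fraction(n_raw, length(good)),
          mean_overlap = cell$mean_ov,
          stringsAsFactors = FALSE
        )
        if (verbose) {
          message(sprintf("q=%d p=%g %s: raw=%d joined=%d good=%d",
                          q_thr, p, sid, n_raw, jr$n_joined, length(good)))
        }
      }
      tab <- composition_table(comp_rows)
      ids <- names(study)
      nonzero <- rowSums(tab) > 0
      gold_d <- stats::setNames(rep(NA_real_, length(ids)), ids)
      if (sum(nonzero) >= 2) {
        sub <- tab[nonzero, , drop = FALSE]
        sub <- sub[, colSums(sub) > 0, drop = FALSE]
        dmat <- jaccard_matrix(sub, "binary")
        ok_pairs <- ids[nonzero[ids] & nonzero[paste0(ids, "_gold")]]
        if (length(ok_pairs)) {
          gold_d[ok_pairs] <- pcoa_gold_distance(
            dmat, cbind(ok_pairs, paste0(ok_pairs, "_gold")))
        }
      }
      for (sid in ids) {
        obs <- names(comp_rows[[sid]])
        gold <- names(comp_rows[[paste0(sid, "_gold")]])
        if (length(gold)) {
          ff <- fp_fn_percent(obs, gold)
          fp <- ff[["fp_pct"]]; fn <- ff[["fn_pct"]]
        } else {
          fp <- NA_real_; fn <- NA_real_
        }
        stats_rows[[sid]]$fp_pct <- fp
        stats_rows[[sid]]$fn_pct <- fn
        stats_rows[[sid]]$gold_distance <- gold_d[[sid]]
        stats_rows[[sid]]$n_observed <- length(obs)
      }
      rows <- c(rows, stats_rows)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot good-read fraction against the trimming threshold
#'
#' Mean and standard error of the good-read fraction per (q_thr, p) cell.
#' Requires ggplot2.
#'
#' @param result Output of [run_experiment()].
#' @return A ggplot object.
#' @export
plot_good_fraction <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  agg <- stats::aggregate(good_fraction ~ q_thr + p_max_diff, result,
                          function(x) c(mean = mean(x),
                                        se = stats::sd(x) / sqrt(length(x))))
  agg <- cbind(agg[1:2], as.data.frame(agg$good_fraction))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$q_thr, y = .data$mean,
                                    colour = factor(.data$p_max_diff))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::labs(x = "quality trimming threshold",
                  y = "good reads / raw reads",
                  colour = "% max difference")
}
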