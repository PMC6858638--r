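#' Build a composition row from good reads
#'
#' Assigns each surviving read to a reference. `provenance` mode parses the
#' reference id out of simulator-formatted read ids
#' (`{sample}.{ref_id}.{copy}`) -- the stand-in for taxonomic assignment
#' that is exact by construction. `exact_match` assigns a read to the
#' unique reference whose amplicon equals its sequence exactly, counting
#' everything else as unassigned.
#'
#' @param good_reads List of [read_record()]s.
#' @param mode `"provenance"` or `"exact_match"`.
#' @param refs List of `amplicon_reference` objects (required for
#'   `exact_match`).
#' @return Named integer vector of counts per `ref_id`; `exact_match` mode
#'   additionally has an `n_unassigned` attribute.
#' @export
build_composition <- function(good_reads, mode = c("provenance", "exact_match"),
                              refs = NULL) {
  mode <- match.arg(mode)
  if (mode == "provenance") {
    ids <- vapply(good_reads, `[[`, character(1), "id")
    parts <- strsplit(ids, ".", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad)) {
      stop(sprintf("read id '%s' is not in {sample}.{ref_id}.{copy} form",
                   ids[bad[1L]]), call. = FALSE)
    }
    tab <- table(vapply(parts, `[`, character(1), 2L))
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    return(counts)
  }
  stopifnot(!is.null(refs))
  amp_by_seq <- vapply(refs, `[[`, character(1), "amplicon")
  names(amp_by_seq) <- vapply(refs, `[[`, character(1), "ref_id")
  lookup <- stats::setNames(names(amp_by_seq), amp_by_seq)
  hits <- lookup[vapply(good_reads, `[[`, character(1), "sequence")]
  n_unassigned <- sum(is.na(hits))
  tab <- table(hits[!is.na(hits)])
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  attr(counts, "n_unassigned") <- n_unassigned
  counts
}

#' Assemble a samples x references composition table
#'
#' @param rows Named list of composition vectors ([build_composition()]);
#'   names become row names.
#' @return Integer matrix, one row per sample, columns the union of
#'   observed `ref_id`s (all-zero columns cannot arise).
#' @export
composition_table <- function(rows) {
  cols <- sort(unique(unlist(lapply(rows, names))))
  mat <- matrix(0L, nrow = length(rows), ncol = length(cols),
                dimnames = list(names(rows), cols))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r)) mat[i, names(r)] <- as.integer(r)
  }
  mat
}

#' False positive / false negative percentages
#'
#' FP% is the percentage of observed units absent from the gold standard,
#' relative to the number of observed units; FN% is the percentage of
#' gold-standard units that went undetected, relative to the gold-standard
#' size.
#'
#' @param observed Character vector (or set) of observed reference ids.
#' @param gold Character vector of gold-standard reference ids (non-empty).
#' @return Named numeric vector `c(fp_pct, fn_pct)`, plus attributes
#'   `n_observed` and `n_gold` so alternative denominators can be
#'   recomputed.
#' @export
fp_fn_percent <- function(observed, gold) {
  observed <- unique(observed); gold <- unique(gold)
  if (!length(gold)) stop("gold-standard set must be non-empty", call. = FALSE)
  fp <- if (length(observed)) 100 * sum(!observed %in% gold) / length(observed) else 0
  fn <- 100 * sum(!gold %in% observed) / length(gold)
  structure(c(fp_pct = fp, fn_pct = fn),
            n_observed = length(observed), n_gold = length(gold))
}

#' Jaccard distance matrix
#'
#' Binary mode is the classic Jaccard distance `1 - |A n B| / |A u B|` on
#' presence/absence; abundance mode is the quantitative (Ruzicka) form
#' `1 - sum(min) / sum(max)` on counts. Both are computed with
#' `vegan::vegdist(method = "jaccard")`, which implements exactly these
#' formulas.
#'
#' @param table Composition matrix ([composition_table()]); >= 2 rows, no
#'   all-zero rows.
#' @param mode `"binary"` (default) or `"abundance"`.
#' @return Symmetric distance matrix with zero diagonal, values in [0, 1].
#' @export
jaccard_matrix <- function(table, mode = c("binary", "abundance")) {
  mode <- match.arg(mode)
  stopifnot(nrow(table) >= 2)
  if (any(rowSums(table) == 0)) {
    stop("composition table contains an all-zero row", call. = FALSE)
  }
  d <- vegan::vegdist(table, method = "jaccard", binary = mode == "binary")
  as.matrix(d)
}

#' Classical PCoA and sample-to-gold Euclidean distances
#'
#' Embeds all rows (samples and gold standards together) by principal
#' coordinates analysis -- eigendecomposition of the double-centred
#' squared-distance matrix, keeping axes with eigenvalue above `tol`
#' (negative eigenvalues, possible for non-Euclidean Jaccard matrices, are
#' dropped without correction) -- then measures the Euclidean distance
#' between each sample and its gold standard over all retained axes.
#'
#' @param dist Symmetric distance matrix with zero diagonal and row/column
#'   names.
#' @param pairs Two-column character matrix or data.frame: sample id, gold
#'   id; all ids must be rows of `dist`.
#' @param tol Eigenvalue tolerance (default 1e-10).
#' @return Numeric vector of per-pair distances, named by sample id.
#' @export
pcoa_gold_distance <- function(dist, pairs, tol = 1e-10) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  pairs <- as.matrix(pairs)
  missing_ids <- setdiff(c(pairs), rownames(dist))
  if (length(missing_ids)) {
    stop(sprintf("ids not in distance matrix: %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  coords <- pcoa_coordinates(dist, tol)
  d <- vapply(seq_len(nrow(pairs)), function(i) {
    sqrt(sum((coords[pairs[i, 1L], ] - coords[pairs[i, 2L], ])^2))
  }, numeric(1))
  names(d) <- pairs[, 1L]
  d
}

#' @rdname pcoa_gold_distance
#' @export
pcoa_coordinates <- function(dist, tol = 1e-10) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  mds <- suppressWarnings(stats::cmdscale(dist, k = n - 1L, eig = TRUE))
  eig <- mds$eig[seq_len(ncol(mds$points))]
  keep <- which(eig > tol)
  coords <- mds$points[, keep, drop = FALSE]
  rownames(coords) <- rownames(dist)
  coords
}
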