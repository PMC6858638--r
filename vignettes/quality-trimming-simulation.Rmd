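---
title: "Simulating the effect of quality trimming on paired-end amplicon analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the effect of quality trimming on paired-end amplicon analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtrimsim)
```

## The problem

Illumina paired-end 2x300 sequencing of the 16S rRNA V3--V4 region produces
read pairs whose 3' ends decay in quality, and whose overlap region -- the
only place where the two mates corroborate each other -- sits exactly in
that decayed tail. Right-side quality trimming removes unreliable tail
bases and therefore cleans the overlap, but it also *shortens* the reads:
trim too deep and the mates no longer overlap at all
(`len(R1) + len(R2) < amplicon length`), merging fails, and the sample's
reads are lost wholesale. `qtrimsim` simulates this trade-off end to end
against a per-sample error-free gold standard, so the effect of the
trimming threshold on community-composition recovery can be measured
without any confound from reference databases or denoising heuristics.

## The simulation model

**References.** `generate_references()` builds 16S-like sequences in which
one concrete realization of the degenerate forward primer
(S-D-Bact-0341-b-S-17, `CCTACGGGNGGCWGCAG`) and, downstream, of the
reverse complement of the reverse primer (S-D-Bact-0785-a-A-21,
`GACTACHVGGGTATCTAATCC`) bracket an amplicon whose length is drawn from
Normal(465, 10) -- the V3--V4 span between this primer pair -- clipped at
311 bases so that the read templates below remain extractable.
`extract_amplicon()` then plays the database-side step: locate the primers
(IUPAC-aware exact matching), cut the amplicon *including* both
primer-binding sites (the reads later have 17/21 leading primer bases
trimmed, so the primers must be present in the reads), and derive the
R1 template (first `L = 310` bases) and R2 template (reverse complement of
the last 310 bases). With a 465-base amplicon, untrimmed trimmed-primer
reads of 293 and 289 bases overlap by `293 + 289 - 465 = 117` bases.

**Quality profiles.** Real pipelines harvest per-read quality vectors from
public FASTQ files; `generate_quality_pool()` emulates such pools with a
plateau/decay model: expected quality `plateau_q = 38` up to position
`decay_start = 150`, then a linear decline of `decay_rate = 0.18` phred
units per base toward `floor_q = 2` (the Illumina no-call score), with
Gaussian position noise (`noise_sd = 3`) and R2 uniformly worse by
`r2_penalty = 6` -- the familiar picture of 2x300 runs where R2 tails are
markedly poorer. Values are rounded and clipped to `[2, 40]`. These
defaults were fixed from the overlap arithmetic: they put the raw overlap
region (the last ~117 bases of each mate) deep in the decayed tail, and
they move the trimmed-length crossover -- the threshold beyond which the
expected reads no longer span the amplicon -- into the upper half of the
0--30 threshold range, so both the benefit of moderate trimming and the
overlap collapse are expressible. A pool importer
(`quality_pool_from_fastq()`) accepts real data; fitting decay parameters
from data is deliberately out of scope.

**Reads and gold standards.** `simulate_sample()` picks 20--60 distinct
references per sample and 1--100 copies each (uniform; only "random" is
prescribed for these), assigns each copy quality vectors drawn from the
pools with replacement, and resamples every base from its quality score.
Two substitution models are available:

* `standard_phred`: the error probability is $10^{-Q/10}$, split evenly
  across the three alternative bases -- the phred definition, and the
  simulation default, since high-quality bases must be mostly correct for
  trimming to help at all;
* `as_printed`: the inverted mapping in which $10^{-Q/10}$ is the
  probability of the *called* base, so at $Q = 2$ the called base keeps
  probability $0.63$ and each alternative gets $(1 - 0.63)/3 = 0.123$.
  This reproduces a published worked example verbatim and is kept as an
  explicit mode; the two readings contradict each other and are not
  silently reconciled.

The gold standard of a sample contains the *same* reads -- same ids, same
multiset of templates -- with unmutated sequences and constant quality 40.
Read ids are `{sample}.{ref_id}.{copy}`, so truth is recoverable by
provenance at evaluation time.

## The measured pipeline

1. **Primer trim**: remove the first 17 (R1) / 21 (R2) bases.
2. **Right-side quality trim** at threshold `q_thr`. The default
   algorithm is the Mott running-sum rule (keep the prefix maximizing
   $\sum_i (Q_i - q_{thr})$, ties toward the longest prefix), which is
   what common right-side trimmers implement; `first_below` (cut at the
   first base under the threshold) is provided as the literal reading.
   Mott output length is not guaranteed monotone in the threshold, which
   is why the sweep records lengths rather than assuming monotonicity.
   Pairs in which either mate falls under `min_len = 50` bases are
   discarded whole (a package choice; some minimum is needed because
   near-empty reads cannot be merged).
3. **Merge** (`join_pairs()`): R2 is reverse-complemented, every overlap
   from `min_overlap = 6` to `min(len1, len2)` is scored by mismatch
   percentage, the minimum wins with ties to the longer overlap, and the
   pair is rejected if the best percentage strictly exceeds the percent
   maximum difference `p` (strict, so `p = 0` still accepts perfect
   overlaps). Agreeing overlap bases keep `max(q1, q2)`; disagreeing
   positions take the higher-quality base with quality `|q1 - q2|`.
   The scan rule and tie-break are package choices documented here; the
   merge-quality rules are the published ones.
4. **Quality control**: merged reads with mean quality below
   `min_mean_q = 25` are dropped. Reads surviving 3--4 are the
   *good reads*; the good-read fraction divides them by the raw pair
   count.
5. **Evaluation**: compositions are recovered by provenance (or by exact
   sequence match, as a stricter stand-in for closed-reference
   assignment), false-positive/false-negative percentages are computed
   with the observed set as FP denominator and the gold set as FN
   denominator (the FP denominator is the ambiguous one; both set sizes
   are attached so alternatives can be recomputed), and samples plus gold
   standards are ordinated together by classical PCoA on the binary
   Jaccard matrix. The per-sample Euclidean distance to its gold standard
   is taken over all retained axes (eigenvalues above `1e-10`; negative
   eigenvalues, possible because Jaccard matrices need not be Euclidean,
   are dropped without correction -- the simplest defensible rule).
   Binary Jaccard is the default because presence/absence is what the
   FP/FN definitions use; the quantitative (Ruzicka) variant is a mode.

`run_experiment()` crosses trimming thresholds (default even 0--20) with
`p` values (default 4, 8, 12 -- the merger's default and one value to
each side) over all samples and reports, per cell, stage counts, the
good-read fraction, the mean implied overlap
`len(R1) + len(R2) - amplicon` of the trimmed pairs (negative values are
gaps), FP/FN percentages, and the PCoA gold distance. Cells that lose all
reads report `NA` metrics and the run continues.

## What the defaults produce

With the default decay pools and `p = 8`, the good-read fraction is low
untrimmed (the 117-base raw overlap is error-rich, so most pairs exceed
8% mismatch), rises steeply to a maximum around thresholds 12--14, and
collapses once trimming pushes the implied overlap below `min_overlap`:
the mean overlap crosses zero near threshold 16--18, and by threshold 26
essentially no pair still joins. The decline is gradual around the
crossover because per-read Mott cut points vary with the noisy profiles;
"collapse" is therefore asserted deep in the gap regime rather than at
the first crossing. The gold distance follows the same U-shape: minimal
where the good fraction peaks.

```{r, eval = FALSE}
cfg <- sweep_config(q_thr_values = c(0, 10, 12, 14, 20, 26), p_values = 8,
                    rng_seed = 11)
res <- run_experiment(cfg)
aggregate(cbind(good_fraction, mean_overlap, gold_distance) ~ q_thr,
          res, mean, na.action = na.pass, na.rm = TRUE)
```

## Verification strategy and problem sizes

Every nontrivial kernel is checked against an independent brute-force
oracle under fixed seeds: Mott trimming against prefix enumeration and
the merger against an exhaustive overlap scan with full quality
reconciliation (1000+ random instances each); IUPAC primer search against
a position-by-position scan; PCoA against a direct double-centering
eigendecomposition and against metric preservation on Euclidean-embeddable
inputs; Jaccard against the set formulas. End-to-end, an error-free run
(`error_model = "none"`, `q_thr = 0`, `p = 8`) must return good-read
fraction 1.0, FP = FN = 0 and gold distance 0 for every sample -- full
parameter recovery. The stochastic trend check uses the default study
design (10 samples, 120 references) over five independent seeds with a
majority-vote criterion, at thresholds {0, 10, 12, 14, 26}; these sizes
keep a full replicate around a minute while leaving hundreds of reads per
sample.

## Limitations

* Errors are substitutions only -- no indels, so merging needs no gapped
  alignment, and no chimeras or PCR bias; length variation comes solely
  from trimming.
* The decay model is a smooth caricature of real quality profiles; real
  R2 tails show structured artifacts (intermittent Q2 stretches, cycle
  effects) that pools imported from FASTQ would capture but the generator
  does not. Passing trend tests show the trade-off logic, not calibration
  to any particular instrument run.
* Composition recovery by provenance is exact; real pipelines add
  reference-database and clustering error on top, so absolute FP/FN
  levels here are optimistic and only their response to trimming is
  meaningful.
* Whether quality pools should be 300 or 310 bases long is genuinely
  undetermined in the source protocol (reads are 300 nt, templates 310);
  the package defaults to 310 to match the templates, and `read_length`
  is a parameter.
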