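---
title: "Methods: sort-seq saturation-mutagenesis mapping with sortseqmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sort-seq saturation-mutagenesis mapping with sortseqmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortseqmap)
```

## The experiment this package analyzes

A short regulatory sequence (here, the 5'-UTR of a bacterial reporter
construct) is mutagenized close to saturation by error-prone PCR. The mutant
plasmid library is transformed into cells that either carry a repressing
small RNA (sRNA) or a control plasmid, cells are fractionated by FACS into
fluorescence gates (high, low, all), and the mutagenized amplicon is PCR
amplified from each sorted pool and paired-end sequenced. Mutations that
change expression or sRNA-mediated regulation change the composition of the
sorted pools, so comparing mutation counts between pools maps every position
of the sequence to a functional role in a single experiment.

`sortseqmap` implements the complete computational side of this design:

1. **design** — calculators for how many transformants cover the mutation
   space and how read length and phred score bound the fraction of
   error-free reads;
2. **sortseq_sim** — a full synthetic-data generator (library, phenotypes,
   gates, paired reads) with ground truth, so the pipeline is testable
   without external data;
3. **readproc** — quality trimming, paired-end merging, exact-length
   filtering;
4. **mutcall** — position-wise mutation calling and the 3L-row
   single-mutation count matrix;
5. **enrich** — negative-binomial exact tests for over-/under-represented
   mutations between conditions;
6. **clusterviz** — sample clustering of mutation patterns and replicate
   concordance.

## Coordinates and the mutation space

Internally all coordinates are 0-based with half-open intervals. Biological
labels are written in the RNA alphabet relative to the A of the start codon:
the A is +1, the base 5' of it is -1, and there is no position 0, so a label
reads like `U-75A` (reference U at -75 mutated to A). Sequences are stored
as DNA (the sequencer reads DNA); the RNA alphabet appears only in labels.

For an amplicon of length L there are exactly 3L possible single-nucleotide
substitutions; for the 158-nt analyzed amplicon that is 474. The enumeration
is ordered by position and then by alternative base (A < C < G < T, skipping
the reference base), and this row order is used by every count matrix and
output table, which makes results byte-comparable across runs.

## Experiment-design calculators

Assuming random mutagenesis, transformants are modeled as i.i.d. uniform
draws from the mutation space (3L single mutations, or 9·C(L,2) double
mutations at two distinct positions — a position holds one base, so two hits
at one position are excluded). The number of times a particular mutation is
drawn among n transformants is Binomial(n, 1/M), giving the closed-form
expected fraction covered at least k times,
`1 - pbinom(k - 1, n, 1/M)`, against which the Monte-Carlo simulator
(`simulate_coverage()`) is verified. For the 109-nt core, 3000 single-mutant
transformants cover about 95% of the 327 mutations at least five times.

Under this uniform model the probability of covering *every* mutation at
least once with 3000 transformants is about 0.967 (by inclusion-exclusion
and by simulation). A figure of 99.5% is sometimes quoted for this design
point; the uniform-draw model does not reproduce it, and we deliberately do
not adjust the model to match — the simulation model behind that figure is
not specified, and the uniform model is the assumption we state.

Read accuracy uses the phred relation: with per-base accuracy
`1 - 10^(-q/10)`, an L-base read is fully correct with probability
`(1 - 10^(-q/10))^L` — 99.9% per base at Q30, ~85% of 158-nt reads fully
correct, and ~39% of 500-nt reads incorrect, which is why amplicon length is
the binding constraint for this method, not transformant numbers.

## The synthetic-data generator

The simulator emulates the experiment end to end and is first-class, tested
code. Its defaults are the study conditions used throughout the test suite:

* **Library**: 10,000 clones; mutation-count distribution
  (0.45, 0.35, 0.13, 0.04, 0.03) over 0-4 mutations per clone (most reads
  wild type, ~35% of reads single-mutant); 90% of mutation mass in the
  109-nt mutagenized core vs 10% in the primer flanks, matching the ~90%
  regional specificity typical of amplicon-targeted mutagenesis.
* **Phenotype**: log10 fluorescence =
  `basal + sum(expression_shift) - repression * I(sRNA) * prod(1 - regulation_loss) + N(0, noise_sd)`,
  with basal 3.0, sRNA repression 1.0 (10-fold), noise SD 0.3 (a broad,
  approximately log-normal FACS spread). The two effect axes separate
  *intrinsic* expression changes (applied always) from *extrinsic* loss of
  sRNA regulation (visible only with the sRNA plasmid). The default effect
  table plants full regulation loss at positions -79..-61 (an sRNA binding
  site), +0.5 expression shifts at -24..-17 (destabilization of the
  stem-loop sequestering the ribosome-binding site) and -0.8 shifts in the
  Shine-Dalgarno motif (-12..-9) and start codon (+1..+3). All magnitudes
  are package choices — the assay gives no quantitative fluorescence model.
* **Gates**: percentile gates drawn on the wild-type construct in the same
  plasmid background (high = upper 5% tail, low = lower 5% tail, all =
  whole support), in closed form from the Gaussian noise model.
* **Sequencing**: 100-cycle paired reads (42-base overlap on the 158-nt
  amplicon), flat Q30 substitution errors, and a per-read probability
  (default 1%) of a single 1-bp indel. Indels are limited to one event per
  read so that every indel-bearing fragment has an incorrect length; a
  compensating insertion+deletion in one fragment would be invisible to any
  length filter, so allowing it would make the filter's removal guarantee
  untestable.
* **Scale**: 50,000 cells per culture and 50,000 read pairs per sample by
  default, with 4 conditions × 3 replicates (sRNA high/all, control
  high/low). The per-sample depth is a desk-scaled stand-in for the millions
  of reads a real run produces; it is chosen so that every mutation keeps
  double-digit counts even in sorted pools, which both lifts signal above
  the sequencing-error floor and keeps size-factor estimation stable (see
  below). The default sample plan uses four mutually *distinguishable*
  conditions: conditions whose expected mutation patterns are identical by
  construction (e.g. all-sorted pools from the two plasmid backgrounds)
  cannot be told apart by clustering, so including them would only test the
  tie-breaking of the dendrogram, not the method.

What the simulator does **not** model: PCR amplification bias and jackpots,
plasmid copy-number variation, fitness costs of high expression, adapter
read-through, or position-dependent quality decay (the quality profile is an
argument, so decay can be supplied). Passing tests on synthetic data
therefore show the pipeline's statistical machinery is correct under the
stated model, not that real libraries are free of these artifacts.

## Read processing

Trimming uses the standard 3'-end running-sum rule: remove the suffix
maximizing `sum(q_threshold - q_i)`, ties to the shortest removal, default
threshold Q30 on Sanger phred+33 qualities (we standardize on phred+33
throughout; offset-64 encodings are an artifact of an older era).

Merging re-specifies the ungapped-overlap approach of common read mergers:
every overlap length of at least 30 bases (the minimum for confident
merging) is scored by its mismatch fraction; the smallest fraction wins,
ties to the longer overlap; pairs are rejected with reason `no_overlap` or
`too_many_mismatches` (cap 2% by default, config-exposed). At overlap
mismatches the higher-quality base wins (tie: read 1) and the merged quality
is the maximum of the two. With a 2% cap and a 42-base overlap a single
overlap mismatch (2.4%) causes rejection — a conservative default that
discards ~8% of Q30 pairs rather than keep reads with conflicting
observations.

All merged reads whose length differs from the reference length are removed:
insertions, deletions and improper merges cannot be assigned to the 3L
substitution space. Reads containing N after merging are likewise dropped
(counted in QC). No alignment is performed anywhere: after exact-length
filtering reads are collinear with the reference by design.

Sequencing-error-induced false single mutations are *not* corrected; depth
is relied upon to lift true signal above this uniform floor, and the QC
report carries the expected error-free-read fraction so the floor is
visible.

## The enrichment model

For each mutation i and sample j the count `k_ij` is modeled as negative
binomial. Sample depths are normalized by median-of-ratios size factors
(`s_j = median_i k_ij / geomean_v(k_iv)` over rows positive in all
samples). Dispersion is estimated per mutation by method of moments on
normalized counts with the shot-noise term removed
(`alpha_raw = (v - qbar * zhat) / qbar^2`, `zhat = qbar * mean(1/s_j)`,
pooled within-condition variance), plus a smooth variance-mean trend fitted
by local regression on the log scale over all rows; the final dispersion is
the conservative `max(alpha_raw, trend, 1e-8)` — with three replicates a
per-row estimate alone is far too noisy, and the trend is fitted to the
variance (not to the positive raw dispersions only, whose selection would
bias it upward).

Testing conditions on the pooled count `k_S = k_A + k_B`: the two condition
sums get NB laws with means `q0 * sum(s_j)` and variances
`mu + alpha * q0^2 * sum(s_j^2)`, and the two-sided p-value is the
probability of all partitions of `k_S` no more likely than the observed one.
As dispersion vanishes with equal size factors this reduces exactly to the
two-sided exact binomial test, which the test suite verifies exhaustively.
P-values are Benjamini-Hochberg adjusted; mutations with adjusted p < 0.05
(config-exposed) are called over- or under-represented by the sign of the
normalized-mean difference.

**Normalization under sorting.** Global median-of-ratios assumes most rows
are null. A sorted pool violates this by design: in the repressed
high-fluorescence pool, regulation-loss mutations are enriched tens-fold
and make up a sizeable minority of rows, which drags the median and
produces a directional bias (silent mutations spuriously called
under-represented). The amplicon provides built-in control rows: mutations
in the primer flanks, whose counts derive from sequencing errors on
unmutated templates and from unenriched flank library members, and are
therefore neutral to the sorting condition. When the count matrix carries a
mutagenized-core annotation, `enrichment_table()` estimates size factors on
these flank rows only (the control-features variant of median-of-ratios),
falling back to all rows when fewer than 20 control rows are usable. The
choice is exposed via `normalization_rows`.

The baseline for a contrast is not hard-wired: sorted pools can be compared
against the all-sorted pool or against unsorted cells, and both are
exercised in the tests.

## Clustering and replicate concordance

Per-sample single-mutation fractions (each column divided by its
single-mutation read total) are row-standardized to zero mean and unit
population variance — the quantity a heatmap colors when comparing a cell
against its row — and samples are clustered by Euclidean distance with
complete linkage (both config-exposed; these are the defaults of the
heatmap stack commonly used for such figures). Whether to cluster counts,
fractions or standardized values is a genuine free choice; we standardize
fractions so that depth and per-mutation abundance differences do not
dominate the sample distances. The dendrogram exports to Newick with merge
heights as branch lengths, and replicate concordance is scored as the
fraction of (plasmid, gate) groups whose replicates form a connected
subtree.

## Numerical and degenerate-input choices

* All randomness flows through explicit seeds; seeded functions restore the
  caller's RNG state, and reruns of the pipeline are byte-identical
  (manifests carry no timestamps).
* Reads may trim to length zero (then rejected at merging as `no_overlap`);
  empty gate pools warn; zero-total samples are excluded from fraction
  tables with a warning; all-zero mutation rows are excluded from testing
  (`p = NA`, call `ns`); `k_S = 0` rows are skipped rather than assigned
  p = 1.
* Exact-test partition probabilities are compared with a `1 + 1e-7`
  relative guard so floating-point noise cannot flip a partition in or out
  of the tail sum.
* Mismatch-fraction ties between overlap candidates are resolved by exact
  integer cross-multiplication, not floating-point division.

## Problem sizes used by the test suite

Unit tests run on toy amplicons and small simulations; the end-to-end
recovery test uses the full default scenario (10,000 clones, 12 samples,
50,000 read pairs each) and completes in a few minutes; the statistical
calibration tests use 474-row, 3-vs-3 null and spiked matrices averaged over
four simulations. These sizes are the package's chosen desk-scale study
conditions and are stated here so results are interpretable, not tuned per
machine.

## Known limitations

* The exact-length filter discards any read with an indel, including reads
  whose indel is sequencing artifact rather than a true library indel; the
  method cannot score indel variants at all (by design).
* Positions whose mutations abolish PCR priming or systematically break
  merging would be invisible; the simulator does not model this.
* With very few usable flank control rows (short flanks or very shallow
  sorted pools), normalization falls back to the global median-of-ratios
  and inherits its composition bias; the QC and enrichment outputs do not
  currently flag how far the two normalizations diverge.
* The conditioned exact test treats the estimated dispersion as known;
  with three replicates this makes the test mildly liberal for rows whose
  dispersion is underestimated, which the conservative `max(raw, trend)`
  sharing counteracts but does not eliminate.
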