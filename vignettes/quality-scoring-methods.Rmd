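---
title: "Composition-based quality scoring of long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-based quality scoring of long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqfilter)
```

## The model

`sqfilter` treats read-quality estimation as self-supervised regression on
sequence composition. The premise is that long-read platforms make
systematic, composition-visible errors — in particular insertions and
deletions of the same continuous base inside homopolymer runs — so a read's
k-mer content drifts away from the genome's as its error rate rises. No
reference genome is consulted at scoring time.

Each read is mapped to 84 features: for k in {1, 2, 3}, the fraction of the
read's valid length-k windows equal to each k-mer over {A, C, G, T}. Labels
are obtained without annotation: raw sequencer reads form the low-quality
class (y = −1) and the output of an error-correction tool run on them forms
the high-quality class (y = +1). The score of a new read is the dot product
of its feature vector with the least-squares solution of Xw = Y — the
classical normal-equations predictor `X_new (XᵀX)⁻ XᵀY`.

Cross-scoring avoids scoring a read with a model that trained on it: raw
and corrected rows are each randomly halved, a model is fitted on each
half, and each half's raw reads are scored by the other half's model. The
two score lists are pooled without rescaling; a calibration warning is
emitted if the fold means differ by more than 0.5 pooled standard
deviations. Ranking the pooled scores and keeping the top P% (with
`round_half_up(N·P/100)` reads retained) completes the pipeline.

### Assumptions

* The corrected set is genuinely higher quality than the raw set, and
  the quality difference is expressed in 1–3-mer composition. Correctors
  that change composition for other reasons (aggressive trimming,
  chimera splitting) weaken the labels.
* Features are strand-specific: all 16 + 64 combinations are kept
  separate rather than collapsed into canonical classes, because
  basecaller error bias can be strand-asymmetric.
* A linear model suffices. The goal is a fast ranking signal, not a
  calibrated error-rate estimate; scores are only meaningful relative to
  other reads scored by the same model pair.

## Parameter choices that matter

* **Feature normalisation** (fixed design): a k-mer's content is its count
  divided by the number of *valid* windows of that order (length − k + 1
  for an N-free read). Per-window normalisation makes features independent
  of read length, which the linear model needs to compare reads spanning
  two orders of magnitude in length. Windows containing N are excluded
  from numerator and denominator alike, keeping the feature space at
  exactly 84 rather than promoting N to a fifth symbol.
* **`ridge`** (default 0): XᵀX is exactly singular — each feature order
  sums to one — so the default fit is the minimum-norm least-squares
  solution via the SVD, which coincides with the normal-equations formula
  whenever the inverse exists. A small ridge is available when near-
  dependencies beyond the structural ones make weights unstable; the
  ranking, not the weights, is the product, so the default favours
  faithfulness to the closed form.
* **No intercept**: the constant vector lies in the span of every
  sum-to-one feature block, so an intercept is representable implicitly,
  and a zero feature vector should score zero.
* **`seed`** (default 0): drives only the two-part split. Identical seeds
  give byte-identical score tables.
* **`read_error_rate`** (default 0.15): the alignment filter accepts hits
  with reference overlap > 2,000 bp and mismatch rate < 2 × this value.
  0.15 is the midpoint error of two-directional nanopore reads (80–88%
  accuracy). It is a single global knob; per-read error estimation is out
  of scope.
* **`top_percent`**: no default — the retention level is a pipeline
  decision. 80–95% are the conventional operating points.

## Numerical and edge-case decisions

* Rank decisions in the SVD use the tolerance `max(dim(X)) · max(d) · eps`.
  Effective rank and residual norm are reported in `glance()`.
* Retention counts round half *up*: at N = 28,429 and P = 95 this yields
  27,008 (27,007.55 rounds to 27,008), where truncation would differ by
  one read. Published per-dataset tables in this area are not always
  internally consistent on this point; half-up is adopted and documented.
* Ties in SQ score are broken by input order (stable sort), so output is
  deterministic without hidden secondary keys.
* Reads shorter than 3 bases cannot populate all three feature orders.
  They are excluded from the training matrix, and rather than being scored
  from a degenerate feature vector they receive a sentinel `NA` score that
  ranks below every scored read; every input read still appears exactly
  once in the score table. (An alternative would be to score them from
  their partial features; the sentinel was chosen so that selection never
  prefers an unassessable read to an assessed one.)
* The alignment filter uses strict inequalities at both boundaries
  (2,000 bp overlap; 2 × error-rate mismatch), and a read with several
  passing alignments counts once toward the aligned rate, evaluated at its
  best (most matched bases) hit — the aligned rate is a proportion of
  *reads*, not of hits.
* Raw and corrected reads are split into folds independently; no attempt
  is made to keep a corrected read in the same fold as the raw read it
  came from, since correctors rename and split reads. The residual
  leakage (a corrected read informing the model that scores its raw
  source) is a known, accepted approximation.
* Corrected reads are used only for training; only raw reads are scored
  and ranked.

## The simulator

`simulate_genome()` + `simulate_reads()` provide the ground truth that real
data cannot: per-read error counts and identity. The generator emulates:

* i.i.d. genomes at a target GC content;
* log-normal read lengths (σ = 0.6) clamped to a configurable range,
  approximating the long right tail of real length distributions;
* per-position edit scripts — deletion, substitution to a different base,
  or copy, with an insertion optionally following each surviving position;
* homopolymer indel bias: inside runs of length ≥ 3 the indel rates are
  multiplied by a configurable factor (default 3), and insertions
  duplicate the preceding base with probability 0.5;
* per-read error-scale jitter, drawn uniformly from a configurable range,
  so that true identity varies across reads the way it does across a real
  flowcell.

Ground-truth identity is defined exactly as the downstream alignment
metric: matched bases divided by consumed reference span, as a percent.
Under this definition insertions do not reduce identity (they consume no
reference), so the expected identity is `100 × (1 − sub − del)` at unit
jitter — the property the simulator tests freeze, verified independently by
re-aligning simulated reads to their source templates.

`make_benchmark()` fixes the study conditions used throughout the tests:
2,000 raw reads with sub/ins/del = 0.07/0.04/0.04 and jitter U(0.1, 2.6),
giving true identities spanning roughly 70–99% with mean ≈ 85% (the
two-directional nanopore regime), and 1,000 corrected-proxy reads at one
fifth of those error rates with a 2,000 bp minimum length, mirroring the
minimum length correctors emit. The genome is 100 kb — large enough that
reads sample diverse composition, small enough that the full pipeline runs
in tens of seconds on one core. Unit tests use a 300 + 150-read benchmark
on a 30 kb genome; the model-fit oracle tests use 50 random instances of up
to 40 × 84.

What the simulator does *not* emulate: basecaller-specific substitution
confusion matrices, quality-string realism, chimeric reads, coverage bias,
and real genome repeat structure. Passing the simulator benchmark therefore
shows that the pipeline recovers composition-encoded quality signal under
the stated error model; it does not guarantee the correlation magnitudes
seen on any particular real dataset, where reported score-identity
correlations are weaker than the simulator's (real error processes are
noisier and genomes are not i.i.d.).

## Limitations

* The score is relative and dataset-specific: SQ values from different
  runs, or different corrected sets, are not comparable.
* A corrected set is required; on datasets where correction fails badly,
  the labels — and hence the ranking — degrade.
* Composition features cannot see errors that preserve composition
  (e.g., balanced substitutions between complementary bases at equal
  rates), and k ≤ 3 bounds the detectable context length.
* The evaluation module parses alignments; it does not run an aligner,
  and assembly-level metrics (N50 and relatives) are out of scope.
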