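---
title: "Benchmarking virus mining with simulated mock communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking virus mining with simulated mock communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromock)
library(dplyr)
```

## Why simulate communities at all

Tools that mine dsDNA viruses from metagenomes — identification classifiers,
gene-sharing-network taxonomy, AMG annotators — are trained and tuned on
complete genomes, but the sequences they meet in practice are assembly
fragments embedded in mixtures dominated by non-viral "distractor" DNA.
Evaluating them therefore needs datasets where every sequence's origin is
known, the fragment length is controlled, and the virus-to-distractor ratio
is prescribed. `viromock` builds exactly these datasets and provides the
metric suites to score tool output against the embedded truth.

## The simulation model

**Fragmentation.** Each reference genome is cut from its 5′ end into
consecutive, non-overlapping fragments of exactly *L* base pairs
(`fragment_genome()`). The default ladder is 500 bp, 1, 3, 5, 10 and 20
kbp, spanning the contig sizes short-read virome assemblies typically
produce. The trailing remainder shorter than *L* is dropped by default so
every fragment in a length class has identical length; `keep_remainder`
retains it for users who want full genome coverage. Coordinates are 0-based
half-open everywhere, including the truth TSV (stated in its header
comment). Fragmentation is deterministic; the truth label of a fragment is
always its parent's label, by construction, so no leakage is possible.

**Mixing.** A community design is a ratio over (viral, prokaryote,
eukaryote, plasmid) anchored on an exact viral count: with base
*b* = `n_viral` / ratio₁, class *i* contributes round(*b*·ratioᵢ) fragments,
rounded half-up. Anchoring was chosen because published community totals
are generally not derivable from their ratios alone; fixing the viral count
makes the arithmetic exact and the totals reproducible (at ratio 1:10:1:1
and 1,695 viral anchors, the total is exactly 22,035). Draws are uniform
without replacement within each class pool; pools are kept in canonical
(parent, start) order so the same seed always yields the same roster
regardless of input file order. Two presets ship in two variants each
(`virome_1a`/`virome_1b`, `bulk_1a`/`bulk_1b`) because their eukaryote or
plasmid proportions are reported inconsistently in the designs'
descriptions; the package takes no side and neither variant is a silent
default.

**Seeding.** Every replicate's RNG seed is
`master_seed XOR hash31(design, L, replicate)`, with a platform-stable
31-bit polynomial string hash. One integer reproduces a whole study; any
single replicate can be regenerated in isolation; and distinct replicates
get (with overwhelming probability) distinct rosters.

## Identification metrics and the dual dialect

The metric suite works from per-stratum confusion matrices. Fragments with
no prediction record are counted as called non-viral, because
identification tools emit only their positives; a prediction for an id
that is not in the truth table is an error rather than a silently dropped
row, since it means the tool output and the manifest do not belong
together.

The suite is computed in two dialects. The `as_printed` dialect evaluates
recall as TP/(TP+FP) and false discovery as FP/(FP+TN) — formula variants
that circulate in the benchmarking literature, where the first equals
precision and the second the false-positive rate. The `standard` dialect
substitutes the textbook recall TP/(TP+FN) and FDR FP/(FP+TP). Which
variant underlies any given published figure is usually undecidable from
the text, so the package computes either on request and stamps every
report row with its dialect; `as_printed` is the default for reproduction
work and `standard` is recommended for new studies. MCC with a zero
denominator factor is reported as 0 with a degeneracy flag, a widespread
convention; the denominator switches to log-space evaluation when its
product would leave exact double range.

Fragment-length effects are tested with a paired two-sided Wilcoxon
signed-rank test of each length's per-replicate values against a reference
length (20 kbp by default, the longest rung of the ladder). With at most
12 pairs the p-value is computed by exhaustive sign-flip enumeration with
mid-ranks under ties — the normal approximation that standard
implementations fall back to under ties cannot reach the exact attainable
p-values at replicate-scale n (e.g. 0.125 at four constant differences).
Zero differences are dropped, as in the classic test. Raw p-values carry
the usual star legend; a Holm-adjusted column is emitted alongside because
the comparison sweeps several lengths at once.

## Taxonomy evaluation

Gene-sharing-network output reduces to an assignment table: each fragment
is clustered, outlier, overlapping or singleton. The clustering-wise
metrics (Sn, PPV, Acc = √(Sn·PPV), and the separation family) are computed
from the genus-by-cluster contingency table over clustered, genus-labeled,
non-reference fragments, with the weighted-maximum and product-sum
formulas given in `?clustering_metrics`. These definitions are fixed as
the package's normative contract; any divergence discovered against an
upstream implementation of the same scheme would be documented rather than
silently patched.

Genus assignment in cluster mode predicts the majority genus among a
cluster's reference members; ties abstain ("ambiguous") rather than guess,
and abstentions count as unassigned. The correctness percentage is
computed over assigned fragments, with the assignment rate reported
alongside so no information is lost relative to an all-fragments
denominator. Direct mode (for tools that emit genus calls with confidence
scores) gates on CS ≥ 0.2 and MR ≥ 0.2 by default, the regime reported to
give fully accurate assignments on complete genomes.

Similarity and distance matrices are compared pair-by-pair as percent
differences relative to the complete-genome value; pairs with a zero
complete-genome value are excluded and counted. Matrices are never
converted between similarity and distance, and cross-kind comparisons are
refused — the percent scales are not comparable across kinds or tools.

## AMG triage: making qualitative rules decidable

The curation workflow the triage implements is qualitative: inspect the
genomic context of each candidate AMG and down-rank candidates whose
context betrays a non-viral origin. To make that testable the package
fixes numeric defaults: a candidate is "at the edge" within 3 genes of a
contig end, its neighborhood is the ±5-gene window, and a window counts as
non-viral when fewer than half its genes are viral-compatible (hallmark,
viral-like, or unknown — unknown-dominated contigs are treated as possibly
viral, not as evidence against). These three numbers are declared package
defaults, user-overridable, not claims about any published workflow's
internal thresholds. Rule order is fixed and first-match-wins, so every
candidate gets exactly one verdict with a reason code; circular contigs
have no edge, so the prophage-boundary rule cannot fire on them.

The "dense short cellular genes" archetype is implemented only as the
zero-viral-genes test; gene density and mean gene length are emitted as
advisory columns without verdict effect, because no density cutoff is
stated anywhere in the source workflows. Class I/II AMG labels pass
through as optional input; deciding KEGG-pathway membership needs external
databases and is out of scope. pN and pS are consumed as given (they come
from micro-diversity tools operating on read alignments); the package only
forms the ratio and applies the 0.3 purifying-selection threshold, with
pS = 0 yielding an undefined call rather than an infinite ratio.

## What the synthetic fixtures do and do not emulate

`make_genomes()` draws uniform-random A/C/G/T sequences, with viral genera
built as ancestor copies mutated i.i.d. per site (default divergence 0.05,
emulating sets of closely related phage genomes that deep-sequenced
reference collections provide). This supports everything the package
computes — fragmentation arithmetic, composition ratios, seeded sampling,
metric recovery — because none of it reads sequence composition. It does
not emulate GC skew, repeats, codon structure, or real phylogenetic
divergence: passing tests therefore demonstrate the correctness of the
benchmarking machinery, not the field performance of any identification
tool on real genomes. Likewise `simulate_predictions()` draws independent
Bernoulli calls at configured sensitivity/FPR per length; it is a harness
for verifying that the scoring pipeline recovers known rates (within 3
binomial standard errors in the shipped tests), not a model of any
tool's error structure.

## Numerical and design choices

* Half-up rounding for ratio-to-count conversion (base `round()` is
  half-even, which would make counts parity-dependent).
* Community composition consumes its own RNG stream and restores the
  caller's, so library use never perturbs user code's randomness.
* Problem sizes in the tests are deliberately desk-scale: fixture genomes
  of 8–60 kbp, communities of 50–100 viral anchors, and one full
  ratio-fidelity check at 22,035 sequences; the exhaustive
  metric-equivalence check enumerates all confusion-matrix compositions of
  up to 12 fragments, which covers all label assignments up to the
  permutation invariance of the metrics.
* `quality_gate()` treats missing identification evidence as failure when
  evidence is required, and reports every violated gate, not just the
  first.
* Degenerate inputs error loudly (`"empty genome"`, `"pool exhausted"`,
  `"nothing to evaluate"`, kind mismatches) rather than returning empty
  results, except where the contract specifies a sentinel (undefined
  metrics carry a reason; sparse Wilcoxon strata yield NA rows).

## Known limitations

* No read-level simulation: fragments are exact genome substrings, so
  assembly error, chimerism and coverage effects are out of scope.
* The plasmid class inherits the field-wide problem that no phage-free
  plasmid reference exists; synthetic plasmids here are just labeled
  random sequence.
* Clustering simulation maps one genus to one cluster; it cannot emulate
  the overlapping/outlier statuses a real gene-sharing network produces
  (those enter only through real assignment tables).
* With exactly two genera, a fully erroneous simulated clustering is a
  pure relabeling and scores Sn = PPV = 1; degradation under full error is
  only observable from three genera up.
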