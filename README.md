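# viromock

Benchmarking dsDNA-virus mining from metagenomes requires datasets where the
truth is known. `viromock` builds those datasets and scores tools against
them. It simulates mock viromes and bulk metagenomes by cutting labeled
reference genomes into non-overlapping fragments and mixing them at
prescribed virus : prokaryote : eukaryote : plasmid ratios with full
ground-truth manifests; it scores virus-identification output with a
confusion-matrix metric suite; it evaluates virus-taxonomy output with
clustering-wise metrics, genus-assignment accuracy, and distance-matrix
degradation; and it triages candidate auxiliary metabolic genes (AMGs) with
genomic-context rules. A synthetic-fixture generator produces every input,
so complete studies run without downloading any reference database.

It is aimed at developers and evaluators of viral ecogenomics tools:
virus-identification classifiers, gene-sharing-network taxonomy, and AMG
annotation pipelines.

## The models and metrics

**Community simulation.** Each genome is cut 5′→3′ into non-overlapping
fragments of exact length *L* (defaults: 500 bp, 1, 3, 5, 10, 20 kbp),
tiling from offset 0; sub-*L* remainders are dropped by default. A community
design fixes a class ratio anchored on the viral count: with base
*b* = n_viral / ratio₁, each class contributes round(*b* · ratioᵢ)
fragments (half-up), drawn uniformly without replacement from its pool. Per
replicate seeds derive as `master_seed XOR hash(name, L, replicate)` so a
whole study reproduces from one integer. Ratio presets cover two virome and
two bulk designs (e.g. `bulk_2` = 1:10:1:1, which at 1,695 viral anchors
totals 22,035 sequences).

**Identification scoring.** From TP/FP/TN/FN per stratum (tool × cutoff ×
dataset × fragment length × replicate):

    MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))

plus recall, false discovery, accuracy = (TP+TN)/N, F1 = 2TP/(2TP+FP+FN),
PPV = TP/(TP+FP) and specificity = TN/(TN+FP). Two dialects are provided:
`as_printed` uses recall = TP/(TP+FP) and false_discovery = FP/(FP+TN)
(reproducing reports computed with those formulas), `standard` uses the
textbook recall = TP/(TP+FN) and FDR = FP/(FP+TP). Fragment lengths are
compared against a 20 kbp reference group with an exact paired Wilcoxon
signed-rank test.

**Taxonomy evaluation.** With T the genus-by-cluster contingency table,
clustering-wise sensitivity Sn = Σᵢ maxⱼ Tᵢⱼ / Σᵢ Nᵢ, PPV = Σⱼ maxᵢ Tᵢⱼ /
Σⱼ Mⱼ, Acc = √(Sn·PPV), and separation Sep = √(Sep_cl·Sep_co) with
Sep_co = (1/R)·Σᵢⱼ (Tᵢⱼ/Nᵢ)(Tᵢⱼ/Mⱼ) and Sep_cl the same sum over 1/C.
Genus assignment uses reference-majority voting per cluster (ties abstain)
or direct calls gated at confidence score ≥ 0.2 and membership ratio ≥ 0.2;
distance matrices from fragments are compared to complete-genome matrices
as per-pair percent differences.

**AMG triage.** Contigs pass a quality gate (≥ 10 kbp or circular, plus
high-confidence identification evidence), then each candidate AMG runs
through ordered context rules: AMG score > 3 → unlikely; edge position with
nearby integrase/tRNA → unlikely (miscalled prophage boundary); no
viral/viral-like genes on the contig → unlikely (cellular/MGE); < 50 %
viral-compatible genes in the ±5-gene window → unlikely; known-phage
similarity → likely; otherwise possible. pN/pS < 0.3 flags strong purifying
selection.

## Worked example

```r
library(viromock)
library(dplyr)

genomes <- make_genomes(fixture_spec(seed = 7))        # 12 viral (3 genera) + distractors
pools   <- build_fragment_pools(genomes, lengths = c(1000, 3000))
design  <- community_design("virome_demo", c(10, 1, 0.1, 0.01),
                            n_viral = 100, master_seed = 7)
manifest <- compose_community(pools, design, L = 3000, replicate_index = 1)
manifest
#> <community_manifest> virome_demo replicate 1 seed 1038708674
#>   members: 111 ( viral=100, prokaryote=10, eukaryote=1, plasmid=0 )
```

111 fragments: the 10:1:0.1:0.01 ratio anchored at 100 viral fragments
rounds to 100 + 10 + 1 + 0. Score a simulated identifier with 90 %
sensitivity and 5 % false-positive rate:

```r
truth <- manifest$members |>
  transmute(fragment_id, is_viral = class_label == "viral", length_class)
calls <- simulate_predictions(truth, c(`3000` = 0.9), c(`3000` = 0.05), seed = 7)
metric_suite(confusion_counts(truth, calls), dialect = "standard")
#> # A tibble: 1 × 13
#>      TP    FP    TN    FN   mcc recall false_discovery accuracy    f1   ppv
#>   <int> <int> <int> <int> <dbl>  <dbl>           <dbl>    <dbl> <dbl> <dbl>
#> 1    89    1    10    11 0.610   0.89          0.0111    0.892 0.937 0.989
```

The realized recall (0.89) recovers the configured sensitivity; the MCC of
0.61 reflects the class imbalance a virome-like mixture imposes. Triage the
five AMG genomic-context archetypes:

```r
arch <- make_amg_archetypes()
triage_report(arch$genes, arch$contigs)[, 1:4]
#> # A tibble: 5 × 4
#>   contig_id gene_index verdict        reasons
#>   <chr>          <int> <chr>          <chr>
#> 1 contig_1           6 likely_viral   "known_phage_hit"
#> 2 contig_2           6 possible_viral ""
#> 3 contig_3          75 unlikely_viral "cellular_or_MGE"
#> 4 contig_4          10 unlikely_viral "nonviral_neighborhood"
#> 5 contig_5           1 unlikely_viral "prophage_boundary"
```

A command-line wrapper over the same functions ships in
`inst/cli/viromock.R` (subcommands `fixtures`, `simulate`, `evaluate-id`,
`evaluate-tax`, `matrix-degradation`, `triage-amg`).

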