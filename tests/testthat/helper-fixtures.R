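# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no files are shipped.

# a small genome set with genus structure, cheap enough for every test file
small_genomes <- function(seed = 7L) {
  make_genomes(fixture_spec(
    n_per_class = c(prokaryote = 4, eukaryote = 1, plasmid = 1),
    genome_length_range = c(8000L, 15000L),
    n_genera = 3L, genomes_per_genus = 3L,
    within_genus_divergence = 0.05, seed = seed
  ))
}

# a truth table of n_viral + n_nonviral fragments at one length, built
# directly (no sequences needed for metric tests)
flat_truth <- function(n_viral, n_nonviral, length_class = 5000L,
                       dataset = "d", replicate = 1L) {
  tibble::tibble(
    fragment_id = c(sprintf("v%04d", seq_len(n_viral)),
                    sprintf("n%04d", seq_len(n_nonviral))),
    is_viral = rep(c(TRUE, FALSE), c(n_viral, n_nonviral)),
    length_class = length_class, dataset = dataset, replicate = replicate,
    genus = NA_character_
  )
}

# brute-force metric computation from per-fragment label lists; the
# independent oracle for the confusion-matrix path
brute_force_metrics <- function(truth_labels, called_labels, dialect) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth_labels)) {
    if (called_labels[i] && truth_labels[i]) tp <- tp + 1L
    else if (called_labels[i] && !truth_labels[i]) fp <- fp + 1L
    else if (!called_labels[i] && !truth_labels[i]) tn <- tn + 1L
    else fn <- fn + 1L
  }
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(
    TP = tp, FP = fp, TN = tn, FN = fn,
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den),
    recall = if (dialect == "as_printed") div(tp, tp + fp) else div(tp, tp + fn),
    false_discovery = if (dialect == "as_printed") div(fp, fp + tn) else div(fp, fp + tp),
    accuracy = div(tp + tn, tp + fp + tn + fn),
    f1 = div(2 * tp, 2 * tp + fp + fn),
    ppv = div(tp, tp + fp),
    specificity = div(tn, tn + fp)
  )
}
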