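#' Confusion counts for virus-identification calls
#'
#' Compares a set of "called viral" fragment ids against the truth table of a
#' simulated community. Fragments absent from the call set are counted as
#' called non-viral, matching how identification tools report only their
#' positive predictions. A call for an id that is not in the truth table is
#' an error: it indicates a manifest/tool-output mismatch, which must never
#' be silently absorbed into the counts.
#'
#' @param truth a data frame with columns `fragment_id` and `is_viral`
#'   (logical or 0/1)
#' @param called_viral character vector of fragment ids the tool called
#'   viral, or a data frame with a `fragment_id` column (rows = positives)
#' @return an object of class `"confusion"`: a one-row tibble with integer
#'   columns `TP`, `FP`, `TN`, `FN`
#' @examples
#' truth <- tibble::tibble(fragment_id = c("v1", "p1", "p2"),
#'                         is_viral = c(TRUE, FALSE, FALSE))
#' confusion_counts(truth, c("v1", "p1"))
#' @export
confusion_counts <- function(truth, called_viral) {
  if (is.data.frame(called_viral)) called_viral <- called_viral$fragment_id
  called_viral <- unique(as.character(called_viral))
  stopifnot(nrow(truth) > 0L)
  if (anyDuplicated(truth$fragment_id)) abort("duplicate fragment_id in truth")
  unknown <- setdiff(called_viral, truth$fragment_id)
  if (length(unknown)) {
    abort(paste0("unknown sequence id: ", paste(head(unknown, 5), collapse = ", ")))
  }
  is_viral <- as.logical(truth$is_viral)
  called <- truth$fragment_id %in% called_viral
  new_confusion(
    TP = sum(called & is_viral), FP = sum(called & !is_viral),
    TN = sum(!called & !is_viral), FN = sum(!called & is_viral)
  )
}

new_confusion <- function(TP, FP, TN, FN) {
  out <- tibble(TP = as.integer(TP), FP = as.integer(FP),
                TN = as.integer(TN), FN = as.integer(FN))
  class(out) <- c("confusion", class(out))
  out
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), a balanced
#' summary of a binary confusion matrix in \[-1, 1\]; 1 is a perfect
#' predictor, -1 a fully inverted one. When any denominator factor is zero
#' the coefficient is undefined; the widely used convention of returning 0 is
#' applied and flagged via the `"degenerate"` attribute. The denominator
#' switches to log-space evaluation when its product would exceed exact
#' double-precision range, so community-scale counts cannot overflow.
#'
#' @param cm a `"confusion"` object, or anything with named entries
#'   `TP`, `FP`, `TN`, `FN`
#' @return the coefficient (double), with attribute `degenerate = TRUE` when
#'   the zero-denominator convention fired
#' @examples
#' mcc(confusion_counts(
#'   tibble::tibble(fragment_id = c("a", "b"), is_viral = c(TRUE, FALSE)), "a"
#' ))
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm$TP); fp <- as.numeric(cm$FP)
  tn <- as.numeric(cm$TN); fn <- as.numeric(cm$FN)
  fac <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(fac == 0)) {
    return(structure(0, degenerate = TRUE))
  }
  num <- tp * tn - fp * fn
  if (num == 0) return(0)
  if (prod(fac) <= 2^53) {
    num / sqrt(prod(fac))
  } else {
    sign(num) * exp(log(abs(num)) - 0.5 * sum(log(fac)))
  }
}

#' The seven-metric identification suite
#'
#' Computes MCC, recall, false discovery, accuracy, F1, PPV and specificity
#' from one confusion matrix, in one of two dialects:
#'
#' * `"as_printed"` follows the benchmark's printed formulas verbatim:
#'   recall = TP/(TP+FP) (which algebraically equals precision) and
#'   false_discovery = FP/(FP+TN) (which equals the false-positive rate).
#'   Use this dialect to reproduce figures computed with those formulas.
#' * `"standard"` substitutes the textbook definitions,
#'   recall = TP/(TP+FN) and false_discovery = FP/(FP+TP), leaving the other
#'   five metrics unchanged. Recommended for new studies.
#'
#' A metric whose denominator is zero is reported as `NA` and the reason
#' recorded in the `undefined` column.
#'
#' @param cm a `"confusion"` object
#' @param dialect `"as_printed"` (default) or `"standard"`
#' @return a one-row tibble: TP/FP/TN/FN, the seven metrics, `dialect`, and
#'   `undefined` (comma-separated names of metrics with zero denominators)
#' @examples
#' cm <- confusion_counts(
#'   tibble::tibble(fragment_id = letters[1:4], is_viral = c(TRUE, TRUE, FALSE, FALSE)),
#'   c("a", "c"))
#' metric_suite(cm)
#' metric_suite(cm, dialect = "standard")
#' @export
metric_suite <- function(cm, dialect = c("as_printed", "standard")) {
  dialect <- match.arg(dialect)
  tp <- as.numeric(cm$TP); fp <- as.numeric(cm$FP)
  tn <- as.numeric(cm$TN); fn <- as.numeric(cm$FN)
  total <- tp + fp + tn + fn
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  recall <- if (dialect == "as_printed") frac(tp, tp + fp) else frac(tp, tp + fn)
  fdr <- if (dialect == "as_printed") frac(fp, fp + tn) else frac(fp, fp + tp)
  out <- tibble(
    TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN,
    mcc = as.numeric(mcc(cm)),
    recall = recall,
    false_discovery = fdr,
    accuracy = frac(tp + tn, total),
    f1 = frac(2 * tp, 2 * tp + fp + fn),
    ppv = frac(tp, tp + fp),
    specificity = frac(tn, tn + fp),
    dialect = dialect
  )
  und <- names(out)[vapply(out, function(v) is.numeric(v) && is.na(v), logical(1))]
  out$undefined <- if (length(und)) paste(und, collapse = ",") else NA_character_
  out
}

#' @exportS3Method generics::tidy
tidy.confusion <- function(x, dialect = c("as_printed", "standard"), ...) {
  metric_suite(x, dialect = match.arg(dialect)) |>
    select("mcc":"specificity") |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "metric", values_to = "value")
}

#' @exportS3Method generics::glance
glance.confusion <- function(x, ...) metric_suite(x)

#' Apply a tool's cutoff rule to raw prediction scores
#'
#' Turns a raw prediction table (id + score / p-value / category) into the
#' set of ids called viral under a threshold rule, the way benchmark studies
#' sweep tool cutoffs (e.g. score >= 0.9 with p <= 0.05, or an admitted
#' category set). Fragments whose score is missing under a score rule are
#' treated as non-viral calls and a warning notes how many.
#'
#' @param preds data frame with `fragment_id` and any of `score`, `pvalue`,
#'   `category`
#' @param score_min minimal score (inclusive), or `NULL` to skip
#' @param pvalue_max maximal p-value (inclusive), or `NULL` to skip
#' @param categories admitted category values, or `NULL` to skip
#' @return character vector of fragment ids called viral
#' @export
apply_cutoff <- function(preds, score_min = NULL, pvalue_max = NULL,
                         categories = NULL) {
  keep <- rep(TRUE, nrow(preds))
  if (!is.null(score_min)) {
    s <- preds$score
    n_missing <- sum(is.na(s))
    if (n_missing) warn(paste0(n_missing, " prediction(s) without a score treated as non-viral"))
    keep <- keep & !is.na(s) & s >= score_min
  }
  if (!is.null(pvalue_max)) keep <- keep & !is.na(preds$pvalue) & preds$pvalue <= pvalue_max
  if (!is.null(categories)) keep <- keep & !is.na(preds$category) & preds$category %in% categories
  unique(preds$fragment_id[keep])
}

#' Score a full benchmarking run
#'
#' Computes the metric suite for every stratum of a run — tool x cutoff x
#' dataset x fragment length x replicate — and appends aggregate rows with
#' the mean and standard deviation over replicates of each stratum.
#'
#' @param truths a data frame with columns `dataset`, `length_class`,
#'   `replicate`, `fragment_id`, `is_viral`: the concatenated truth tables
#' @param preds a data frame of positive calls with columns `tool`,
#'   `cutoff`, `dataset`, `length_class`, `replicate`, `fragment_id`; a
#'   stratum of a truth table with no matching prediction rows scores an
#'   empty call set
#' @param dialect passed to [metric_suite()]
#' @return a tibble with one row per stratum (`stat = "replicate"`) plus,
#'   per (tool, cutoff, dataset, length_class), one `stat = "mean"` and one
#'   `stat = "sd"` row over replicates
#' @export
evaluate_run <- function(truths, preds, dialect = c("as_printed", "standard")) {
  dialect <- match.arg(dialect)
  strata_keys <- c("dataset", "length_class", "replicate")
  need <- c(strata_keys, "fragment_id", "is_viral")
  if (!all(need %in% names(truths))) {
    abort(paste0("truths needs columns: ", paste(need, collapse = ", ")))
  }
  pred_strata <- distinct(preds, .data$tool, .data$cutoff,
                          .data$dataset, .data$length_class, .data$replicate)
  truth_strata <- distinct(truths[strata_keys])
  orphan <- dplyr::anti_join(pred_strata, truth_strata, by = strata_keys)
  if (nrow(orphan)) {
    abort(paste0("missing truth table for stratum: ",
                 paste(orphan$dataset[1], orphan$length_class[1],
                       orphan$replicate[1], sep = "/")))
  }
  # every tool x cutoff is evaluated on every truth stratum; absent
  # prediction rows mean the tool called nothing viral there
  grid <- tidyr::crossing(distinct(preds, .data$tool, .data$cutoff), truth_strata)
  rows <- purrr::pmap(grid, function(tool, cutoff, dataset, length_class, replicate) {
    tr <- truths[truths$dataset == dataset &
                   truths$length_class == length_class &
                   truths$replicate == replicate, ]
    pd <- preds[preds$tool == tool & preds$cutoff == cutoff &
                  preds$dataset == dataset &
                  preds$length_class == length_class &
                  preds$replicate == replicate, ]
    cm <- confusion_counts(tr, pd$fragment_id)
    dplyr::bind_cols(
      tibble(tool = tool, cutoff = cutoff, dataset = dataset,
             length_class = length_class, replicate = replicate),
      metric_suite(cm, dialect)
    )
  }) |> bind_rows()
  per_rep <- mutate(rows, stat = "replicate")

  metric_cols <- c("mcc", "recall", "false_discovery", "accuracy",
                   "f1", "ppv", "specificity")
  agg <- per_rep |>
    group_by(.data$tool, .data$cutoff, .data$dataset, .data$length_class) |>
    summarise(
      dplyr::across(all_of(metric_cols),
                    list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))),
      .groups = "drop"
    )
  means <- agg |>
    select("tool", "cutoff", "dataset", "length_class",
           dplyr::ends_with("_mean")) |>
    rename_with_suffix("_mean") |>
    mutate(stat = "mean", dialect = dialect)
  sds <- agg |>
    select("tool", "cutoff", "dataset", "length_class",
           dplyr::ends_with("_sd")) |>
    rename_with_suffix("_sd") |>
    mutate(stat = "sd", dialect = dialect)
  bind_rows(per_rep, means, sds) |>
    arrange(.data$tool, .data$cutoff, .data$dataset, .data$length_class)
}

rename_with_suffix <- function(x, suffix) {
  nm <- names(x)
  names(x) <- ifelse(endsWith(nm, suffix),
                     substr(nm, 1, nchar(nm) - nchar(suffix)), nm)
  x
}
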