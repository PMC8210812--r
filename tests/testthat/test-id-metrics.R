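test_that("confusion counts classify calls against truth", {
  truth <- tibble::tibble(fragment_id = c("v1", "p1", "p2"),
                          is_viral = c(TRUE, FALSE, FALSE))
  cm <- confusion_counts(truth, c("v1", "p1"))
  expect_equal(unlist(cm[, c("TP", "FP", "TN", "FN")]),
               c(TP = 1L, FP = 1L, TN = 1L, FN = 0L))
  perfect <- confusion_counts(truth, "v1")
  expect_equal(perfect$FP + perfect$FN, 0L)
  empty <- confusion_counts(truth, character())
  expect_equal(unlist(empty[, c("TP", "FP", "TN", "FN")]),
               c(TP = 0L, FP = 0L, TN = 2L, FN = 1L))
  expect_error(confusion_counts(truth, "ghost"), "unknown sequence id")
})

test_that("mcc matches the closed form and its conventions", {
  # frozen oracle: 7000 / sqrt(100*110*90*100) computed independently
  cm <- viromock:::new_confusion(TP = 90, FP = 10, TN = 80, FN = 20)
  expect_equal(mcc(cm), 7000 / sqrt(100 * 110 * 90 * 100), tolerance = 1e-12)
  expect_equal(round(mcc(cm), 4), 0.7035)
  # perfect and fully inverted predictors hit the interval endpoints exactly
  expect_identical(mcc(viromock:::new_confusion(5, 0, 7, 0)), 1)
  expect_identical(mcc(viromock:::new_confusion(0, 3, 0, 4)), -1)
  # zero-denominator convention: 0 with a degeneracy flag
  degen <- mcc(viromock:::new_confusion(0, 0, 5, 5))
  expect_equal(as.numeric(degen), 0)
  expect_true(attr(degen, "degenerate"))
})

test_that("mcc is symmetric under class swap and antisymmetric under inversion", {
  set.seed(42)
  for (i in 1:50) {
    v <- sample(0:30, 4, replace = TRUE)
    cm <- viromock:::new_confusion(v[1], v[2], v[3], v[4])
    swapped <- viromock:::new_confusion(v[3], v[4], v[1], v[2])   # TP<->TN, FP<->FN
    inverted <- viromock:::new_confusion(v[2], v[1], v[4], v[3])  # predictor negated
    expect_equal(as.numeric(mcc(cm)), as.numeric(mcc(swapped)), tolerance = 1e-12)
    expect_equal(as.numeric(mcc(cm)), -as.numeric(mcc(inverted)), tolerance = 1e-12)
  }
})

test_that("the metric suite implements both dialects", {
  cm <- viromock:::new_confusion(TP = 90, FP = 10, TN = 80, FN = 20)
  printed <- metric_suite(cm, "as_printed")
  expect_equal(printed$recall, 0.9)                 # TP/(TP+FP)
  expect_equal(printed$false_discovery, 10 / 90)    # FP/(FP+TN)
  expect_equal(printed$accuracy, 170 / 200)
  expect_equal(printed$f1, 180 / 210)
  expect_equal(printed$ppv, 0.9)
  expect_equal(printed$specificity, 80 / 90)

  std <- metric_suite(cm, "standard")
  expect_equal(std$recall, 90 / 110)                # TP/(TP+FN)
  expect_equal(std$false_discovery, 10 / 100)       # FP/(FP+TP)
  expect_equal(std$accuracy, printed$accuracy)      # shared metrics unchanged
  expect_equal(std$f1, printed$f1)

  expect_error(metric_suite(cm, "nonsense"))
})

test_that("zero denominators yield NA with a recorded reason", {
  cm <- viromock:::new_confusion(TP = 0, FP = 0, TN = 5, FN = 5)
  row <- metric_suite(cm, "as_printed")
  expect_true(is.na(row$ppv))
  expect_true(is.na(row$recall))   # as-printed recall shares the TP+FP denominator
  expect_match(row$undefined, "ppv")
})

test_that("f1 is the harmonic mean of precision and standard recall", {
  set.seed(99)
  for (i in 1:50) {
    v <- sample(1:40, 4, replace = TRUE)  # all positive: denominators nonzero
    cm <- viromock:::new_confusion(v[1], v[2], v[3], v[4])
    precision <- metric_suite(cm, "as_printed")$recall
    recall_std <- metric_suite(cm, "standard")$recall
    f1 <- metric_suite(cm, "as_printed")$f1
    expect_equal(f1, 2 * precision * recall_std / (precision + recall_std),
                 tolerance = 1e-12)
  }
})

test_that("confusion path equals brute-force counting for every small composition", {
  # exhaustive over all (TP, FP, TN, FN) compositions of n <= 12 fragments;
  # metrics are invariant to fragment order, so compositions cover all
  # label assignments
  for (n in 1:12) {
    comps <- expand.grid(tp = 0:n, fp = 0:n, tn = 0:n)
    comps <- comps[rowSums(comps) <= n, ]
    comps$fn <- n - rowSums(comps)
    for (j in seq_len(nrow(comps))) {
      k <- unlist(comps[j, ])
      truth_labels <- rep(c(TRUE, TRUE, FALSE, FALSE), k[c("tp", "fn", "fp", "tn")])
      called_labels <- rep(c(TRUE, FALSE, TRUE, FALSE), k[c("tp", "fn", "fp", "tn")])
      ids <- sprintf("f%02d", seq_len(n))
      truth <- tibble::tibble(fragment_id = ids, is_viral = truth_labels)
      cm <- confusion_counts(truth, ids[called_labels])
      for (dialect in c("as_printed", "standard")) {
        oracle <- brute_force_metrics(truth_labels, called_labels, dialect)
        got <- metric_suite(cm, dialect)
        expect_equal(got$TP, oracle$TP)
        expect_equal(got$FP, oracle$FP)
        expect_equal(got$TN, oracle$TN)
        expect_equal(got$FN, oracle$FN)
        for (m in c("mcc", "recall", "false_discovery", "accuracy",
                    "f1", "ppv", "specificity")) {
          expect_equal(got[[m]], oracle[[m]], tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("apply_cutoff implements score, p-value and category rules", {
  preds <- tibble::tibble(
    fragment_id = c("a", "b", "c", "d", "e"),
    score = c(0.95, 0.8, NA, 0.92, 0.3),
    pvalue = c(0.01, 0.2, 0.01, 0.04, 0.01),
    category = c("1", "3", "2", "4", "6")
  )
  expect_warning(
    called <- apply_cutoff(preds, score_min = 0.9, pvalue_max = 0.05),
    "without a score"
  )
  expect_setequal(called, c("a", "d"))
  expect_setequal(apply_cutoff(preds, categories = c("1", "2", "4", "5")),
                  c("a", "c", "d"))
})

test_that("evaluate_run stratifies, aggregates and guards missing truth", {
  truths <- dplyr::bind_rows(lapply(1:4, function(r) {
    flat_truth(10, 10, length_class = 500L, replicate = r)
  }))
  viral_ids <- dplyr::filter(truths, is_viral, replicate == 1)$fragment_id
  preds <- tidyr::crossing(tool = "toolA", cutoff = "c1",
                           dataset = "d", length_class = 500L,
                           replicate = 1:4, fragment_id = viral_ids)
  rep_rows <- dplyr::filter(
    evaluate_run(truths, preds), stat == "replicate")
  expect_equal(nrow(rep_rows), 4L)
  expect_true(all(rep_rows$mcc == 1))
  agg <- dplyr::filter(evaluate_run(truths, preds), stat == "sd")
  expect_equal(agg$mcc, 0)  # identical replicates: zero spread

  bad <- dplyr::mutate(preds, dataset = "other")
  expect_error(evaluate_run(truths, bad), "missing truth table")
})

test_that("row and aggregate counts scale with strata", {
  truths <- dplyr::bind_rows(lapply(c(500L, 1000L), function(L) {
    dplyr::bind_rows(lapply(1:2, function(r) {
      flat_truth(5, 5, length_class = L, replicate = r)
    }))
  }))
  preds <- truths |>
    dplyr::filter(is_viral) |>
    dplyr::mutate(tool = "t", cutoff = "c") |>
    dplyr::select(tool, cutoff, dataset, length_class, replicate, fragment_id)
  report <- evaluate_run(truths, preds)
  expect_equal(sum(report$stat == "replicate"), 4L)  # 2 lengths x 2 replicates
  expect_equal(sum(report$stat == "mean"), 2L)
  expect_equal(sum(report$stat == "sd"), 2L)
})
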