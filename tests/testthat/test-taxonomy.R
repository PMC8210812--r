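make_assignments <- function(statuses, genera = NULL, clusters = NULL,
                             is_reference = FALSE) {
  n <- length(statuses)
  tibble::tibble(
    item_id = sprintf("it%03d", seq_len(n)),
    cluster_id = if (is.null(clusters)) {
      ifelse(statuses == "clustered", "c1", NA)
    } else clusters,
    status = statuses,
    is_reference = rep_len(is_reference, n),
    genus = if (is.null(genera)) NA_character_ else genera
  )
}

test_that("status percentages are over non-reference items and sum to 100", {
  a <- make_assignments(c(rep("clustered", 8), "outlier", "singleton"))
  s <- clustering_status_summary(a)
  expect_equal(s$status$pct[s$status$status == "clustered"], 80)
  expect_equal(sum(s$status$pct), 100)

  even <- make_assignments(c("clustered", "outlier", "overlapping", "singleton"),
                           clusters = c("c1", NA, NA, NA))
  expect_equal(clustering_status_summary(even)$status$pct, rep(25, 4))
})

test_that("the cluster census separates reference-containing from new VCs", {
  a <- dplyr::bind_rows(
    make_assignments(rep("clustered", 4), clusters = c("c1", "c1", "c2", "c2")),
    tibble::tibble(item_id = "ref1", cluster_id = "c1", status = "clustered",
                   is_reference = TRUE, genus = "A")
  )
  census <- clustering_status_summary(a)$clusters
  expect_equal(census$n[census$cluster_type == "with_reference"], 1L)
  expect_equal(census$n[census$cluster_type == "new_vc"], 1L)
})

test_that("contingency counts only clustered, genus-labeled, non-reference items", {
  a <- dplyr::bind_rows(
    make_assignments(rep("clustered", 6), genera = "A",
                     clusters = rep("c1", 6)),
    make_assignments(rep("clustered", 4), genera = "B",
                     clusters = rep("c2", 4)) |>
      dplyr::mutate(item_id = paste0("b", item_id)),
    tibble::tibble(item_id = "u1", cluster_id = NA, status = "outlier",
                   is_reference = FALSE, genus = "A"),
    tibble::tibble(item_id = "ref", cluster_id = "c1", status = "clustered",
                   is_reference = TRUE, genus = "A")
  )
  T <- contingency(a)
  expect_equal(T, matrix(c(6L, 0L, 0L, 4L), 2,
                         dimnames = list(c("A", "B"), c("c1", "c2"))))
  none <- make_assignments(rep("outlier", 3), genera = "A")
  expect_error(contingency(none), "nothing to evaluate")
})

test_that("clustering metrics match hand-evaluated tables", {
  # perfect clustering: every metric is 1
  perfect <- matrix(c(6L, 0L, 0L, 4L), 2,
                    dimnames = list(c("A", "B"), c("c1", "c2")))
  m <- clustering_metrics(perfect)
  expect_equal(unlist(m[, c("Sn", "PPV", "Acc", "Sep_cl", "Sep_co", "Sep")]),
               c(Sn = 1, PPV = 1, Acc = 1, Sep_cl = 1, Sep_co = 1, Sep = 1))

  # one merged cluster: Sn = 1, PPV = max genus share, Acc their geometric mean
  merged <- matrix(c(6L, 4L), 2, 1, dimnames = list(c("A", "B"), "c1"))
  m2 <- clustering_metrics(merged)
  expect_equal(m2$Sn, 1)
  expect_equal(m2$PPV, 0.6)
  expect_equal(m2$Acc, sqrt(0.6))
  expect_equal(round(m2$Acc, 4), 0.7746)

  # one genus split evenly over two pure clusters
  split <- matrix(c(3L, 3L), 1, 2, dimnames = list("A", c("c1", "c2")))
  m3 <- clustering_metrics(split)
  expect_equal(m3$Sn, 0.5)
  expect_equal(m3$PPV, 1)
  expect_equal(m3$Acc, sqrt(0.5))

  expect_error(clustering_metrics(matrix(0L, 1, 1)), "degenerate")
})

test_that("separation matches direct evaluation of the product-sum formula", {
  T <- matrix(c(5L, 1L, 2L, 4L), 2, dimnames = list(c("A", "B"), c("c1", "c2")))
  N <- rowSums(T); M <- colSums(T)
  s <- 0
  for (i in 1:2) for (j in 1:2) s <- s + (T[i, j] / N[i]) * (T[i, j] / M[j])
  m <- clustering_metrics(T)
  expect_equal(m$Sep_co, unname(s) / 2)
  expect_equal(m$Sep_cl, unname(s) / 2)
  expect_equal(m$Sep, sqrt(m$Sep_co * m$Sep_cl))
})

test_that("all clustering metrics stay in [0, 1] on random tables", {
  set.seed(17)
  for (i in 1:100) {
    T <- matrix(rpois(12, 2), 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
    if (sum(T) == 0) next
    m <- clustering_metrics(T)
    vals <- unlist(m[, c("Sn", "PPV", "Acc", "Sep_cl", "Sep_co", "Sep")])
    expect_true(all(vals >= 0 & vals <= 1 | is.na(vals)))
    expect_equal(m$Acc, sqrt(m$Sn * m$PPV), tolerance = 1e-12)
    expect_equal(m$Sep, sqrt(m$Sep_cl * m$Sep_co), tolerance = 1e-12)
  }
})

test_that("merging pure clusters never raises PPV; splitting never raises Sn", {
  two_pure <- matrix(c(6L, 0L, 0L, 4L), 2,
                     dimnames = list(c("A", "B"), c("c1", "c2")))
  merged <- matrix(c(6L, 4L), 2, 1, dimnames = list(c("A", "B"), "m"))
  expect_lte(clustering_metrics(merged)$PPV, clustering_metrics(two_pure)$PPV)

  whole <- matrix(6L, 1, 1, dimnames = list("A", "c1"))
  halved <- matrix(c(3L, 3L), 1, 2, dimnames = list("A", c("c1", "c2")))
  expect_lte(clustering_metrics(halved)$Sn, clustering_metrics(whole)$Sn)
})

test_that("cluster-mode genus assignment uses reference majority with tie abstention", {
  a <- dplyr::bind_rows(
    tibble::tibble(item_id = c("f1", "f2", "f3"),
                   cluster_id = c("c1", "c1", "c2"),
                   status = "clustered", is_reference = FALSE,
                   genus = c("A", "B", "A")),
    tibble::tibble(item_id = c("r1", "r2", "r3", "r4"),
                   cluster_id = c("c1", "c1", "c2", "c2"),
                   status = "clustered", is_reference = TRUE,
                   genus = c("A", "A", "A", "B"))
  )
  out <- genus_assignment_accuracy(a, mode = "cluster")
  # c1 majority = A (f1 correct, f2 wrong); c2 tie A/B -> ambiguous, f3 unassigned
  expect_equal(out$n_assigned, 2L)
  expect_equal(out$n_correct, 1L)
  expect_equal(out$pct_correct_genus, 50)
  expect_equal(out$pct_assigned, 100 * 2 / 3)

  no_ref <- dplyr::filter(a, !is_reference)
  expect_error(genus_assignment_accuracy(no_ref, mode = "cluster"),
               "at least one clustered reference")
})

test_that("pure clusters with matching references give 100% correct genus", {
  frags <- tibble::tibble(
    fragment_id = sprintf("f%02d", 1:12),
    genus = rep(c("A", "B", "C"), each = 4)
  )
  a <- simulate_clustering(frags, error_rate = 0, seed = 3)
  out <- genus_assignment_accuracy(a, mode = "cluster")
  expect_equal(out$pct_correct_genus, 100)
  expect_equal(out$pct_assigned, 100)
})

test_that("direct-mode assignment applies CS/MR thresholds", {
  a <- tibble::tibble(
    item_id = c("f1", "f2", "f3"),
    cluster_id = NA_character_,
    status = "singleton", is_reference = FALSE,
    genus = c("A", "A", "B"),
    predicted_genus = c("A", "A", "A"),
    cs = c(0.5, 0.1, 0.4), mr = c(0.3, 0.9, 0.25)
  )
  out <- genus_assignment_accuracy(a, cs_min = 0.2, mr_min = 0.2, mode = "direct")
  # f2 fails CS >= 0.2 and is excluded from the correctness denominator
  expect_equal(out$n_assigned, 2L)
  expect_equal(out$pct_correct_genus, 50)  # f1 correct, f3 wrong
})

test_that("distance degradation matches hand arithmetic and excludes zero pairs", {
  labels <- c("a", "b", "c")
  complete <- matrix(0, 3, 3, dimnames = list(labels, labels))
  complete["a", "b"] <- complete["b", "a"] <- 0.5
  complete["a", "c"] <- complete["c", "a"] <- 0.2
  # b-c stays 0 -> excluded
  frag <- complete
  frag["a", "b"] <- frag["b", "a"] <- 0.6   # +20 %
  frag["a", "c"] <- frag["c", "a"] <- 0.1   # -50 %

  deg <- distance_degradation(frag, complete)
  expect_equal(sort(deg$pairs$delta_pct), c(-50, 20))
  expect_equal(deg$summary$n_excluded_zero, 1L)
  expect_equal(deg$summary$mean_abs_delta_pct, 35)
  expect_equal(deg$summary$median_abs_delta_pct, 35)

  ident <- distance_degradation(complete, complete)
  expect_true(all(ident$pairs$delta_pct == 0))
  expect_equal(ident$summary$mean_abs_delta_pct, 0)
})

test_that("degradation guards kind mismatch and disjoint label sets", {
  m <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  sim <- m; attr(sim, "kind") <- "similarity"
  expect_error(distance_degradation(sim, m, kind = "distance"), "kind mismatch")
  other <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_error(distance_degradation(m, other), "no shared pairs")
})

test_that("matrix TSV and assignment TSV round-trip", {
  m <- matrix(c(0, .3, .3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, p)
  back <- read_matrix_tsv(p, kind = "distance")
  expect_equal(unclass(back)[,], m[,])
  expect_equal(attr(back, "kind"), "distance")

  a <- make_assignments(c("clustered", "outlier"), genera = c("A", NA),
                        clusters = c("c1", NA))
  ap <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(a, ap)
  expect_equal(as.data.frame(read_assignments(ap)), as.data.frame(a))
})
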