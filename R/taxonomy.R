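#' Cluster assignment tables
#'
#' Taxonomy tools that build gene-sharing networks reduce to a per-item
#' assignment table: each fragment (or reference genome) either sits in
#' exactly one viral cluster (`status = "clustered"`) or fails to
#' (`"outlier"`, `"overlapping"`, `"singleton"`). Columns:
#' \describe{
#'   \item{item_id}{unique id}
#'   \item{cluster_id}{cluster label; `NA` iff status is not `"clustered"`}
#'   \item{status}{clustered / outlier / overlapping / singleton}
#'   \item{is_reference}{reference genome (known taxonomy) vs query fragment}
#'   \item{genus}{truth genus for fragments, known genus for references}
#'   \item{cs, mr}{optional confidence score and membership ratio in \[0,1\],
#'     for tools that assign taxa directly}
#' }
#' @param assignments a data frame with the columns above
#' @return the validated tibble, invisibly
#' @export
validate_assignments <- function(assignments) {
  assignments <- as_tibble(assignments)
  need <- c("item_id", "cluster_id", "status", "is_reference", "genus")
  if (!all(need %in% names(assignments))) {
    abort(paste0("assignment table needs columns: ", paste(need, collapse = ", ")))
  }
  ok_status <- c("clustered", "outlier", "overlapping", "singleton")
  bad <- setdiff(unique(assignments$status), ok_status)
  if (length(bad)) abort(paste0("unknown status: ", paste(bad, collapse = ", ")))
  mismatch <- xor(assignments$status == "clustered", !is.na(assignments$cluster_id))
  if (any(mismatch)) {
    abort("cluster_id must be set exactly for status == 'clustered'")
  }
  for (col in intersect(c("cs", "mr"), names(assignments))) {
    v <- assignments[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) abort(paste0(col, " must lie in [0, 1]"))
  }
  invisible(assignments)
}

#' Clustering-status summary and cluster census
#'
#' Summarises how the input fragments fared in a gene-sharing-network
#' classification: the percentage of (non-reference) items per status, and a
#' census splitting clusters into those containing at least one reference
#' genome versus fragment-only "new" viral clusters (new VCs).
#'
#' @param assignments see [validate_assignments()]
#' @return a list with tibbles `status` (status, n, pct over non-reference
#'   items) and `clusters` (cluster_type, n)
#' @examples
#' a <- tibble::tibble(
#'   item_id = c("f1", "f2", "f3", "ref1"),
#'   cluster_id = c("c1", "c1", NA, "c1"),
#'   status = c("clustered", "clustered", "singleton", "clustered"),
#'   is_reference = c(FALSE, FALSE, FALSE, TRUE),
#'   genus = c("A", "A", "B", "A"))
#' clustering_status_summary(a)
#' @export
clustering_status_summary <- function(assignments) {
  validate_assignments(assignments)
  stopifnot(nrow(assignments) > 0L)
  frags <- filter(assignments, !.data$is_reference)
  status_tbl <- frags |>
    count(status = factor(.data$status,
                          levels = c("clustered", "outlier", "overlapping", "singleton")),
          .drop = FALSE, name = "n") |>
    mutate(status = as.character(.data$status),
           pct = 100 * .data$n / sum(.data$n))
  census <- assignments |>
    filter(!is.na(.data$cluster_id)) |>
    group_by(.data$cluster_id) |>
    summarise(has_reference = any(.data$is_reference), .groups = "drop") |>
    count(cluster_type = ifelse(.data$has_reference, "with_reference", "new_vc"),
          name = "n")
  for (ct in c("with_reference", "new_vc")) {
    if (!ct %in% census$cluster_type) {
      census <- bind_rows(census, tibble(cluster_type = ct, n = 0L))
    }
  }
  list(status = status_tbl, clusters = arrange(census, dplyr::desc(.data$cluster_type)))
}

#' Genus-by-cluster contingency table
#'
#' Cross-tabulates truth genus against assigned cluster over the eligible
#' fragments: non-reference, clustered, and genus-labeled. Rows are genera,
#' columns clusters.
#'
#' @param assignments see [validate_assignments()]
#' @return an integer matrix with genus rownames and cluster colnames
#' @export
contingency <- function(assignments) {
  validate_assignments(assignments)
  elig <- filter(assignments, !.data$is_reference,
                 .data$status == "clustered", !is.na(.data$genus))
  if (!nrow(elig)) abort("nothing to evaluate: no clustered, genus-labeled fragments")
  tab <- table(genus = elig$genus, cluster = elig$cluster_id)
  matrix(as.integer(tab), nrow = nrow(tab),
         dimnames = list(rownames(tab), colnames(tab)))
}

#' Clustering-wise sensitivity, PPV, accuracy and separation
#'
#' The standard complex-vs-cluster evaluation scheme applied to genera
#' (complexes) against viral clusters. With `T[i, j]` the number of
#' fragments of genus i in cluster j, `N_i` row sums and `M_j` column sums:
#'
#' * Sn  = sum_i max_j T_ij / sum_i N_i  (weighted per-genus best recovery)
#' * PPV = sum_j max_i T_ij / sum_j M_j  (weighted per-cluster purity)
#' * Acc = sqrt(Sn * PPV) (geometric mean)
#' * Sep_co = (1/R) sum_ij (T_ij/N_i)(T_ij/M_j), R = number of genera
#' * Sep_cl = (1/C) sum_ij (T_ij/N_i)(T_ij/M_j), C = number of clusters
#' * Sep = sqrt(Sep_co * Sep_cl)
#'
#' All six lie in \[0, 1\]; a perfect one-genus-per-pure-cluster result
#' scores 1 everywhere.
#'
#' @param T a genus-by-cluster count matrix (from [contingency()]), or an
#'   assignment table which is tabulated first
#' @return a one-row tibble: Sn, PPV, Acc, Sep_cl, Sep_co, Sep, n_genera,
#'   n_clusters, n_fragments
#' @examples
#' clustering_metrics(matrix(c(6, 4), nrow = 2,
#'                    dimnames = list(c("A", "B"), "c1")))
#' @export
clustering_metrics <- function(T) {
  if (is.data.frame(T)) T <- contingency(T)
  stopifnot(is.matrix(T))
  if (sum(T) == 0) abort("degenerate contingency table: no positive entry")
  N <- rowSums(T)
  M <- colSums(T)
  keep_r <- N > 0
  keep_c <- M > 0
  T <- T[keep_r, keep_c, drop = FALSE]
  N <- N[keep_r]; M <- M[keep_c]
  sn <- sum(apply(T, 1, max)) / sum(N)
  ppv <- sum(apply(T, 2, max)) / sum(M)
  frac <- sweep(T, 1, N, "/") * sweep(T, 2, M, "/")
  sep_co <- sum(frac) / nrow(T)
  sep_cl <- sum(frac) / ncol(T)
  tibble(
    Sn = sn, PPV = ppv, Acc = sqrt(sn * ppv),
    Sep_cl = sep_cl, Sep_co = sep_co, Sep = sqrt(sep_cl * sep_co),
    n_genera = nrow(T), n_clusters = ncol(T), n_fragments = sum(T)
  )
}

#' Genus-assignment rate and correctness
#'
#' Evaluates how many fragments receive a genus call and how many of those
#' are correct, in either of two modes:
#'
#' * `mode = "cluster"`: a fragment is assigned when its cluster contains at
#'   least one reference genome; the predicted genus is the majority genus
#'   among the cluster's references, with ties abstaining ("ambiguous",
#'   unassigned — a genus is never guessed).
#' * `mode = "direct"`: for tools that emit a genus with a confidence score
#'   (CS) and membership ratio (MR); a fragment is assigned when
#'   CS >= `cs_min` and MR >= `mr_min` (thresholds 0.2/0.2 by default, the
#'   regime reported to give fully accurate assignments on complete
#'   genomes). Requires a `predicted_genus` column; a missing `cs` or `mr`
#'   column is treated as passing its threshold.
#'
#' `pct_correct_genus` is computed over assigned fragments only;
#' `pct_assigned` preserves the information an all-fragments denominator
#' would carry.
#'
#' @param assignments see [validate_assignments()]; `mode = "direct"` also
#'   needs `predicted_genus` (and optionally `cs`, `mr`)
#' @param cs_min,mr_min direct-mode thresholds in \[0, 1\]
#' @param mode `"cluster"` or `"direct"`
#' @return a one-row tibble: n_fragments, n_assigned, n_correct,
#'   pct_assigned, pct_correct_genus
#' @export
genus_assignment_accuracy <- function(assignments, cs_min = 0.2, mr_min = 0.2,
                                      mode = c("cluster", "direct")) {
  mode <- match.arg(mode)
  validate_assignments(assignments)
  stopifnot(cs_min >= 0, cs_min <= 1, mr_min >= 0, mr_min <= 1)
  frags <- filter(assignments, !.data$is_reference)
  if (mode == "cluster") {
    refs <- filter(assignments, .data$is_reference, !is.na(.data$cluster_id),
                   !is.na(.data$genus))
    if (!nrow(refs)) abort("cluster mode requires at least one clustered reference")
    ref_genus <- refs |>
      count(.data$cluster_id, .data$genus, name = "n") |>
      group_by(.data$cluster_id) |>
      summarise(
        predicted_genus = {
          top <- .data$genus[.data$n == max(.data$n)]
          if (length(top) == 1L) top else NA_character_  # tie -> ambiguous
        },
        .groups = "drop"
      )
    frags <- left_join(frags, ref_genus, by = "cluster_id")
    assigned <- !is.na(frags$cluster_id) & !is.na(frags$predicted_genus)
  } else {
    if (!"predicted_genus" %in% names(frags)) {
      abort("direct mode requires a predicted_genus column")
    }
    cs <- if ("cs" %in% names(frags)) frags$cs else rep(1, nrow(frags))
    mr <- if ("mr" %in% names(frags)) frags$mr else rep(1, nrow(frags))
    assigned <- !is.na(frags$predicted_genus) &
      !is.na(cs) & cs >= cs_min & !is.na(mr) & mr >= mr_min
  }
  correct <- assigned & !is.na(frags$genus) &
    frags$predicted_genus == frags$genus
  n <- nrow(frags)
  tibble(
    n_fragments = n,
    n_assigned = sum(assigned),
    n_correct = sum(correct, na.rm = TRUE),
    pct_assigned = 100 * sum(assigned) / n,
    pct_correct_genus = if (sum(assigned) == 0) NA_real_ else
      100 * sum(correct, na.rm = TRUE) / sum(assigned)
  )
}

#' Pairwise distance degradation relative to complete genomes
#'
#' Compares the pairwise similarity/distance matrix a tool produced on
#' genome fragments against the matrix it produced on the corresponding
#' complete genomes. For every unordered shared pair (a, b) with a non-zero
#' complete-genome value, the relative difference is
#' `100 * (D_frag - D_complete) / D_complete` (percent). Pairs whose
#' complete-genome value is zero are excluded and counted. Matrices of
#' different kinds (similarity vs distance) are refused: their percent
#' scales are not comparable.
#'
#' @param d_frag,d_complete square numeric matrices with matching dimnames
#'   (at least partially overlapping label sets)
#' @param kind `"distance"` or `"similarity"`; both matrices must share it
#' @return a list: `pairs` (tibble a, b, complete, frag, delta_pct) and
#'   `summary` (one-row tibble: n_pairs, n_excluded_zero, mean_abs_delta_pct,
#'   median_abs_delta_pct)
#' @examples
#' m <- matrix(c(0, .5, .5, 0), 2, dimnames = list(c("a","b"), c("a","b")))
#' m2 <- m; m2["a","b"] <- m2["b","a"] <- .6
#' distance_degradation(m2, m)
#' @export
distance_degradation <- function(d_frag, d_complete,
                                 kind = c("distance", "similarity")) {
  kind <- match.arg(kind)
  k1 <- attr(d_frag, "kind"); k2 <- attr(d_complete, "kind")
  for (k in c(k1, k2)) {
    if (!is.null(k) && k != kind) abort("matrix kind mismatch")
  }
  shared <- intersect(rownames(d_frag), rownames(d_complete))
  if (length(shared) < 2L) abort("no shared pairs between the two matrices")
  pairs <- utils::combn(shared, 2)
  a <- pairs[1, ]; b <- pairs[2, ]
  complete <- d_complete[cbind(a, b)]
  frag <- d_frag[cbind(a, b)]
  zero <- complete == 0
  res <- tibble(a = a[!zero], b = b[!zero],
                complete = complete[!zero], frag = frag[!zero]) |>
    mutate(delta_pct = 100 * (.data$frag - .data$complete) / .data$complete)
  if (!nrow(res)) abort("no shared pairs with non-zero complete-genome value")
  list(
    pairs = res,
    summary = tibble(
      n_pairs = nrow(res),
      n_excluded_zero = sum(zero),
      mean_abs_delta_pct = mean(abs(res$delta_pct)),
      median_abs_delta_pct = median(abs(res$delta_pct))
    )
  )
}

#' Read/write square labeled matrices as TSV
#'
#' The matrix file format is a square TSV with a leading label column and a
#' header row of the same labels, as exported by genome-similarity tools.
#'
#' @param path file path
#' @param kind stored on the matrix as the `"kind"` attribute
#' @return `read_matrix_tsv()`: a numeric matrix with dimnames and a
#'   `"kind"` attribute
#' @export
read_matrix_tsv <- function(path, kind = c("distance", "similarity")) {
  kind <- match.arg(kind)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  if (!identical(colnames(m), labels)) abort("matrix row/column labels differ")
  if (max(abs(m - t(m))) > 1e-8) abort("matrix is not symmetric")
  attr(m, "kind") <- kind
  m
}

#' @rdname read_matrix_tsv
#' @param m a labeled square matrix
#' @export
write_matrix_tsv <- function(m, path) {
  df <- as_tibble(m)
  df <- dplyr::bind_cols(tibble(label = rownames(m)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a cluster-assignment TSV
#'
#' Columns: item_id, cluster_id, status, is_reference, genus, and optionally
#' cs, mr, predicted_genus. Empty strings and `"NA"` are missing.
#'
#' @param path file path
#' @return a validated assignment tibble
#' @export
read_assignments <- function(path) {
  a <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       na = c("", "NA"))
  a$is_reference <- as.logical(a$is_reference)
  validate_assignments(a)
  as_tibble(a)
}
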