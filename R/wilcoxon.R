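# Exact two-sided Wilcoxon signed-rank p-value by enumerating all 2^n sign
# assignments of the non-zero paired differences. Zero differences are
# dropped first (classic Wilcoxon); tied |d| get mid-ranks, and the
# enumeration handles the resulting lattice exactly, which the usual
# normal-approximation fallback cannot. Used for n <= max_exact pairs.
signed_rank_exact_p <- function(d, max_exact = 12L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  if (n > max_exact) {
    return(suppressWarnings(
      stats::wilcox.test(d, mu = 0, exact = FALSE)$p.value
    ))
  }
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  eps <- 1e-9
  mean(abs(v_all - mu) >= abs(v_obs - mu) - eps)
}

#' Compare per-replicate metric values against a reference fragment length
#'
#' For one metric of an [evaluate_run()] report, runs a paired two-sided
#' Wilcoxon signed-rank test of each fragment length's per-replicate values
#' against the values at a reference length (20 kbp by default, the longest
#' standard fragment size). Pairing is by (tool, cutoff, dataset, replicate).
#' For 12 or fewer pairs the p-value is exact (full sign-flip enumeration,
#' mid-ranks under ties, zero differences dropped); beyond that a normal
#' approximation is used. Significance stars follow the usual legend:
#' `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001, `****` p <= 0.0001.
#' Raw p-values are reported alongside a Holm-adjusted column.
#'
#' Strata with fewer than two pairs yield `NA` with a reason rather than an
#' error, so sparse runs still produce a complete table.
#'
#' @param report tibble from [evaluate_run()]
#' @param metric name of the metric column to compare (e.g. `"mcc"`)
#' @param reference_length the reference fragment length (default 20000)
#' @return a tibble: `length_class`, `n_pairs`, `p_value`, `p_holm`,
#'   `stars`, `reason`
#' @export
compare_to_reference <- function(report, metric = "mcc",
                                 reference_length = 20000L) {
  stopifnot(metric %in% names(report))
  reps <- filter(report, .data$stat == "replicate")
  if (!reference_length %in% reps$length_class) {
    abort(paste0("reference length ", reference_length, " not present in report"))
  }
  keys <- c("tool", "cutoff", "dataset", "replicate")
  ref <- reps |>
    filter(.data$length_class == reference_length) |>
    select(all_of(keys), ref_value = all_of(metric))
  lengths <- sort(setdiff(unique(reps$length_class), reference_length))
  out <- purrr::map(lengths, function(L) {
    cur <- reps |>
      filter(.data$length_class == L) |>
      select(all_of(keys), value = all_of(metric)) |>
      dplyr::inner_join(ref, by = keys) |>
      filter(!is.na(.data$value), !is.na(.data$ref_value))
    n_pairs <- nrow(cur)
    if (n_pairs < 2L) {
      return(tibble(length_class = L, n_pairs = n_pairs,
                    p_value = NA_real_, reason = "fewer than 2 pairs"))
    }
    p <- signed_rank_exact_p(cur$value - cur$ref_value)
    tibble(length_class = L, n_pairs = n_pairs, p_value = p,
           reason = NA_character_)
  }) |> bind_rows()
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out$stars <- significance_stars(out$p_value)
  select(out, "length_class", "n_pairs", "p_value", "p_holm", "stars", "reason")
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 5e-2 ~ "*",
    TRUE ~ ""
  )
}
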