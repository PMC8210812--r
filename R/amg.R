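#' Gene categories on an annotated viral contig
#'
#' @return character vector of admissible gene `category` values
#' @export
gene_categories <- function() {
  c("viral_hallmark", "viral_like", "cellular", "unknown", "integrase", "tRNA")
}

# columns required in the two AMG-triage input tables
.gene_cols <- c("contig_id", "gene_index", "start", "end", "strand",
                "category", "is_amg")
.contig_cols <- c("contig_id", "length_bp", "circular", "known_phage_similarity")

validate_annotations <- function(genes, contigs) {
  genes <- as_tibble(genes); contigs <- as_tibble(contigs)
  if (!all(.gene_cols %in% names(genes))) {
    abort(paste0("gene table needs columns: ", paste(.gene_cols, collapse = ", ")))
  }
  if (!all(.contig_cols %in% names(contigs))) {
    abort(paste0("contig table needs columns: ", paste(.contig_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(genes$category), gene_categories())
  if (length(bad)) abort(paste0("unknown gene category: ", paste(bad, collapse = ", ")))
  if (!"amg_score" %in% names(genes)) genes$amg_score <- NA_integer_
  if (!"amg_flags" %in% names(genes)) genes$amg_flags <- NA_character_
  if (any(!is.na(genes$amg_score) & !genes$is_amg)) {
    abort("amg_score may be set only on candidate AMGs")
  }
  for (col in c("virsorter_category", "dvf_score", "dvf_pvalue")) {
    if (!col %in% names(contigs)) contigs[[col]] <- NA_real_
  }
  list(genes = genes, contigs = contigs)
}

#' Quality-gate candidate viral contigs for AMG work
#'
#' A contig passes the gate when it is long enough to give a candidate AMG
#' genomic context — at least `min_len` bp (10 kbp default) or circular
#' (interpreted as a complete genome) — and, when identification evidence is
#' required, when it was called viral with high confidence: a conservative
#' gene-content category (1 or 2) or a k-mer score >= 0.9 with p < 0.05.
#' Every violated gate is reported as a reason code.
#'
#' @param contigs contig-level table: `contig_id`, `length_bp`, `circular`,
#'   `known_phage_similarity`, and optionally `virsorter_category`,
#'   `dvf_score`, `dvf_pvalue`
#' @param min_len minimum contig length in bp (default 10000)
#' @param require_id_evidence require high-confidence identification
#'   evidence? (default `TRUE`)
#' @return a tibble: `contig_id`, `pass`, `reasons` (comma-separated codes
#'   among `short_contig`, `weak_id_evidence`; empty string when passing)
#' @examples
#' ctg <- tibble::tibble(contig_id = "c1", length_bp = 8000, circular = FALSE,
#'   known_phage_similarity = FALSE, virsorter_category = 1,
#'   dvf_score = NA, dvf_pvalue = NA)
#' quality_gate(ctg)
#' @export
quality_gate <- function(contigs, min_len = 10000L, require_id_evidence = TRUE) {
  v <- validate_annotations(
    tibble(contig_id = character(), gene_index = integer(), start = integer(),
           end = integer(), strand = character(), category = character(),
           is_amg = logical()),
    contigs
  )
  contigs <- v$contigs
  long_enough <- contigs$length_bp >= min_len | contigs$circular
  vs_ok <- !is.na(contigs$virsorter_category) & contigs$virsorter_category %in% c(1, 2)
  dvf_ok <- !is.na(contigs$dvf_score) & !is.na(contigs$dvf_pvalue) &
    contigs$dvf_score >= 0.9 & contigs$dvf_pvalue < 0.05
  id_ok <- if (require_id_evidence) (vs_ok | dvf_ok) else TRUE
  reasons <- purrr::map2_chr(long_enough, id_ok, function(len, id) {
    paste(c(if (!len) "short_contig", if (!id) "weak_id_evidence"),
          collapse = ",")
  })
  tibble(contig_id = contigs$contig_id,
         pass = long_enough & id_ok, reasons = reasons)
}

#' Default genomic-context triage parameters
#'
#' @param edge_genes how close (in genes) to a contig end counts as "at the
#'   edge" for the prophage-boundary rule
#' @param window neighborhood half-width in genes around the candidate AMG
#' @param min_viral_fraction minimal fraction of viral-compatible
#'   (hallmark / viral-like / unknown) genes in the window
#' @param max_amg_score highest acceptable AMG score (two-component scoring
#'   convention: scores 1-3 are candidate-grade)
#' @param min_len,require_id_evidence passed to [quality_gate()]
#' @return a named list of parameters
#' @export
triage_params <- function(edge_genes = 3L, window = 5L,
                          min_viral_fraction = 0.5, max_amg_score = 3L,
                          min_len = 10000L, require_id_evidence = TRUE) {
  list(edge_genes = as.integer(edge_genes), window = as.integer(window),
       min_viral_fraction = min_viral_fraction,
       max_amg_score = as.integer(max_amg_score),
       min_len = as.integer(min_len),
       require_id_evidence = isTRUE(require_id_evidence))
}

#' Triage one candidate AMG by genomic context
#'
#' Applies the ordered context rules to a single candidate AMG on one
#' contig; the first matching rule wins:
#'
#' 0. AMG score above `max_amg_score` — `unlikely_viral` (`low_amg_score`).
#' 1. AMG within `edge_genes` of a contig end with an integrase or tRNA
#'    within `window` genes — `unlikely_viral` (`prophage_boundary`): the
#'    classic signature of a miscalled prophage boundary dragging host
#'    genes onto a "viral" contig. Circular contigs have no edge, so this
#'    rule never fires on them.
#' 2. Contig has no viral hallmark and no viral-like gene at all —
#'    `unlikely_viral` (`cellular_or_MGE`): likely a cellular region or
#'    mobile genetic element.
#' 3. Fewer than `min_viral_fraction` of the `window` genes on either side
#'    of the AMG (excluding it) are viral-compatible (hallmark, viral-like
#'    or unknown) — `unlikely_viral` (`nonviral_neighborhood`).
#' 4. Contig closely related to a known phage — `likely_viral`
#'    (`known_phage_hit`).
#' 5. Otherwise — `possible_viral`.
#'
#' If the contig fails [quality_gate()], the verdict is `rejected_contig`
#' with the gate's reason codes.
#'
#' @param genes gene table for (at least) this contig; see
#'   [validate_annotations] columns in [triage_report()]
#' @param contig one-row contig-level table
#' @param gene_index index of the candidate AMG gene
#' @param params a [triage_params()] list
#' @return a one-row tibble: `contig_id`, `gene_index`, `verdict`, `reasons`
#' @export
triage_amg <- function(genes, contig, gene_index, params = triage_params()) {
  if (is.data.frame(contig)) {
    stopifnot(nrow(contig) == 1L)
  }
  v <- validate_annotations(genes, contig)
  genes <- v$genes; contig <- v$contigs
  g <- filter(genes, .data$contig_id == contig$contig_id) |>
    arrange(.data$gene_index)
  pos <- which(g$gene_index == gene_index)
  if (!length(pos)) abort(paste0("gene_index ", gene_index, " not on contig"))
  if (!g$is_amg[pos]) abort(paste0("gene ", gene_index, " is not a candidate AMG"))

  verdict_row <- function(verdict, reasons) {
    tibble(contig_id = contig$contig_id, gene_index = as.integer(gene_index),
           verdict = verdict, reasons = paste(reasons, collapse = ","))
  }
  gate <- quality_gate(contig, min_len = params$min_len,
                       require_id_evidence = params$require_id_evidence)
  if (!gate$pass) return(verdict_row("rejected_contig", gate$reasons))

  n <- nrow(g)
  score <- g$amg_score[pos]
  if (!is.na(score) && score > params$max_amg_score) {
    return(verdict_row("unlikely_viral", "low_amg_score"))
  }
  near_edge <- !contig$circular &&
    (pos <= params$edge_genes || pos > n - params$edge_genes)
  neighbors <- abs(seq_len(n) - pos) <= params$window & seq_len(n) != pos
  mobile_near <- any(g$category[neighbors] %in% c("integrase", "tRNA"))
  if (near_edge && mobile_near) {
    return(verdict_row("unlikely_viral", "prophage_boundary"))
  }
  if (!any(g$category %in% c("viral_hallmark", "viral_like"))) {
    return(verdict_row("unlikely_viral", "cellular_or_MGE"))
  }
  win_cat <- g$category[neighbors]
  viral_frac <- mean(win_cat %in% c("viral_hallmark", "viral_like", "unknown"))
  if (length(win_cat) && viral_frac < params$min_viral_fraction) {
    return(verdict_row("unlikely_viral", "nonviral_neighborhood"))
  }
  if (isTRUE(contig$known_phage_similarity)) {
    return(verdict_row("likely_viral", "known_phage_hit"))
  }
  verdict_row("possible_viral", "")
}

#' Purifying-selection call from polymorphism counts
#'
#' The ratio of non-synonymous (pN) to synonymous (pS) polymorphisms of a
#' gene; values below the threshold (0.3 by default) indicate strong
#' purifying selection, as expected for a functional, virus-encoded gene.
#' The counts themselves come from a micro-diversity tool; this function
#' only forms and classifies the ratio. With `pS = 0` the ratio and the
#' call are undefined (`NA`), never infinite.
#'
#' @param pn,ps non-negative polymorphism counts (vectorised)
#' @param threshold purifying-selection cutoff on pN/pS (default 0.3)
#' @return a tibble: `pn`, `ps`, `ratio`, `purifying`
#' @examples
#' selection_classification(2, 10)   # ratio 0.2 -> purifying
#' @export
selection_classification <- function(pn, ps, threshold = 0.3) {
  if (any(pn < 0) || any(ps < 0)) abort("pN and pS must be non-negative")
  ratio <- ifelse(ps > 0, pn / ps, NA_real_)
  tibble(pn = pn, ps = ps, ratio = ratio,
         purifying = ifelse(is.na(ratio), NA, ratio < threshold))
}

#' Triage every candidate AMG across a set of contigs
#'
#' Runs [triage_amg()] on every candidate AMG gene, in deterministic
#' (contig_id, gene_index) order, and attaches per-contig advisory
#' annotations (viral gene count, mean gene length, coding density) that
#' inform manual review without affecting any verdict. When `path` is
#' given, the table is written as TSV with the parameter snapshot embedded
#' as header comments for provenance.
#'
#' @param genes gene table: `contig_id`, `gene_index`, `start`, `end`,
#'   `strand`, `category`, `is_amg`, optionally `amg_score`, `amg_flags`
#' @param contigs contig-level table (see [quality_gate()])
#' @param params a [triage_params()] list
#' @param path optional output TSV path
#' @return a tibble of verdicts with advisory columns `n_viral_genes`,
#'   `mean_gene_len`, `coding_density`; the per-verdict count summary is
#'   attached as attribute `"summary"`
#' @export
triage_report <- function(genes, contigs, params = triage_params(), path = NULL) {
  v <- validate_annotations(genes, contigs)
  genes <- v$genes; contigs <- v$contigs
  cand <- genes |>
    filter(.data$is_amg) |>
    arrange(.data$contig_id, .data$gene_index)
  advisory <- genes |>
    group_by(.data$contig_id) |>
    summarise(
      n_viral_genes = sum(.data$category %in% c("viral_hallmark", "viral_like")),
      mean_gene_len = mean(.data$end - .data$start),
      .groups = "drop"
    ) |>
    left_join(select(contigs, "contig_id", "length_bp"), by = "contig_id") |>
    mutate(coding_density = NA_real_)
  # coding density = fraction of contig covered by genes (overlap-unaware
  # sum is fine for advisory purposes)
  cov <- genes |>
    group_by(.data$contig_id) |>
    summarise(covered = sum(.data$end - .data$start), .groups = "drop")
  advisory <- advisory |>
    left_join(cov, by = "contig_id") |>
    mutate(coding_density = pmin(1, .data$covered / .data$length_bp)) |>
    select("contig_id", "n_viral_genes", "mean_gene_len", "coding_density")

  rows <- purrr::map2(cand$contig_id, cand$gene_index, function(cid, gi) {
    triage_amg(genes, contigs[contigs$contig_id == cid, ], gi, params)
  }) |> bind_rows()
  if (!nrow(rows)) {
    rows <- tibble(contig_id = character(), gene_index = integer(),
                   verdict = character(), reasons = character())
  }
  out <- left_join(rows, advisory, by = "contig_id")
  summary_tbl <- count(out, .data$verdict, .data$reasons, name = "n")
  attr(out, "summary") <- summary_tbl
  if (!is.null(path)) {
    hdr <- c(
      "# viromock AMG triage report",
      paste0("# params: ",
             paste(names(params), unlist(params), sep = "=", collapse = " "))
    )
    writeLines(hdr, path)
    readr::write_tsv(out, path, append = TRUE, col_names = TRUE, na = "NA")
  }
  out
}

#' Read AMG annotation tables
#'
#' `read_gene_annotations()` reads the per-gene TSV (columns of
#' [triage_report()]'s `genes` argument); `read_contig_annotations()` the
#' contig-level TSV.
#'
#' @param path file path
#' @return a tibble
#' @export
read_gene_annotations <- function(path) {
  g <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       na = c("", "NA"))
  g$is_amg <- as.logical(g$is_amg)
  g
}

#' @rdname read_gene_annotations
#' @export
read_contig_annotations <- function(path) {
  ctg <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         na = c("", "NA"))
  for (col in c("circular", "known_phage_similarity")) {
    if (col %in% names(ctg)) ctg[[col]] <- as.logical(ctg[[col]])
  }
  ctg
}
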