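#' Fragment a genome into non-overlapping pieces
#'
#' Cuts one genome, 5' to 3', into consecutive non-overlapping fragments of
#' exactly `L` bp, tiling from offset 0. The trailing remainder shorter than
#' `L` is dropped unless `keep_remainder = TRUE`, in which case one extra
#' fragment of length `len %% L` is emitted. Coordinates are 0-based
#' half-open. The operation is fully deterministic.
#'
#' A genome shorter than `L` yields zero fragments (an empty tibble).
#'
#' @param record one genome: either a one-row genome tibble (see
#'   [validate_genomes()]) or a list with fields `id`, `sequence`,
#'   `class_label`, and optionally `genus`
#' @param L fragment length in bp (positive integer)
#' @param keep_remainder keep the trailing sub-`L` fragment? (default `FALSE`)
#' @return a tibble of fragments with columns `fragment_id`, `parent_id`,
#'   `start`, `end`, `class_label`, `genus`, `length_class`
#' @examples
#' g <- tibble::tibble(id = "g1", sequence = strrep("ACGT", 2500),
#'                     class_label = "viral", genus = NA, circular = FALSE)
#' fragment_genome(g, L = 3000)   # 3 fragments, remainder dropped
#' @export
fragment_genome <- function(record, L, keep_remainder = FALSE) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  L <- as.integer(L)
  stopifnot(L >= 1L)
  len <- nchar(record$sequence)
  if (is.na(len) || len == 0L) abort("empty genome")
  n_full <- len %/% L
  starts <- seq_len(n_full) * L - L
  ends <- starts + L
  if (isTRUE(keep_remainder) && len %% L > 0L) {
    starts <- c(starts, n_full * L)
    ends <- c(ends, len)
  }
  if (!length(starts)) {
    return(tibble(
      fragment_id = character(), parent_id = character(),
      start = integer(), end = integer(), class_label = character(),
      genus = character(), length_class = integer()
    ))
  }
  tibble(
    fragment_id = paste0(record$id, "|L=", L, "|i=", seq_along(starts) - 1L),
    parent_id = record$id,
    start = as.integer(starts),
    end = as.integer(ends),
    class_label = record$class_label,
    genus = as.character(record$genus %||% NA_character_),
    length_class = L
  )
}

#' Build per-class fragment pools at each fragment length
#'
#' Fragments every genome at every length in `lengths` and collects the
#' results into pools keyed by (class, length). Pools are kept in canonical
#' order (parent id, then start) so that downstream seeded sampling is
#' reproducible regardless of input order. Empty pools (a class with no
#' genomes long enough) are permitted.
#'
#' @param genomes a genome tibble (see [validate_genomes()])
#' @param lengths strictly increasing positive fragment lengths in bp;
#'   defaults to the six standard sizes 500 bp to 20 kbp
#' @param keep_remainder passed to [fragment_genome()]
#' @return a tibble of all fragments (columns as [fragment_genome()]);
#'   filter on `class_label` and `length_class` to obtain a single pool
#' @export
build_fragment_pools <- function(genomes,
                                 lengths = c(500L, 1000L, 3000L, 5000L, 10000L, 20000L),
                                 keep_remainder = FALSE) {
  validate_genomes(genomes)
  genomes <- as_tibble(genomes)
  if (!"genus" %in% names(genomes)) genomes$genus <- NA_character_
  stopifnot(nrow(genomes) > 0L, length(lengths) > 0L)
  lengths <- as.integer(lengths)
  if (any(diff(lengths) <= 0L) || any(lengths < 1L)) {
    abort("lengths must be strictly increasing positive integers")
  }
  rows <- split(genomes, seq_len(nrow(genomes)))
  purrr::map(lengths, function(L) {
    purrr::map(rows, fragment_genome, L = L, keep_remainder = keep_remainder) |>
      bind_rows()
  }) |>
    bind_rows() |>
    arrange(.data$length_class, .data$class_label, .data$parent_id, .data$start)
}
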