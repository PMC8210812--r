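#' Labeled reference genomes
#'
#' A genome table is the package's source material: one row per reference
#' sequence, carrying the nucleotide sequence itself plus the truth class used
#' for benchmarking. `genome_classes()` lists the admissible class labels.
#' `validate_genomes()` checks the invariants every downstream operation
#' relies on and returns the table (invisibly coerced to a tibble) so it can
#' be used inside a pipe.
#'
#' Columns of a genome table:
#' \describe{
#'   \item{id}{unique, non-empty sequence identifier}
#'   \item{sequence}{nucleotide string over A/C/G/T/N}
#'   \item{class_label}{one of `genome_classes()`: viral, prokaryote,
#'     eukaryote, plasmid, archaea}
#'   \item{genus}{optional genus (viral records only); `NA` otherwise}
#'   \item{circular}{logical; circular genomes are treated as complete}
#' }
#'
#' @param genomes a data frame with the columns above (`genus` and
#'   `circular` may be omitted and default to `NA` / `FALSE`)
#' @return `validate_genomes()`: the validated genome tibble, invisibly.
#' @examples
#' g <- tibble::tibble(
#'   id = "phage1", sequence = "ACGTACGTAC",
#'   class_label = "viral", genus = "T4likevirus", circular = FALSE
#' )
#' validate_genomes(g)
#' @export
validate_genomes <- function(genomes) {
  genomes <- as_tibble(genomes)
  if (!all(c("id", "sequence", "class_label") %in% names(genomes))) {
    abort("genome table needs columns: id, sequence, class_label")
  }
  if (!"genus" %in% names(genomes)) genomes$genus <- NA_character_
  if (!"circular" %in% names(genomes)) genomes$circular <- FALSE
  if (anyDuplicated(genomes$id)) abort("genome ids must be unique")
  if (any(!nzchar(genomes$id)) || anyNA(genomes$id)) abort("genome ids must be non-empty")
  bad <- setdiff(unique(genomes$class_label), genome_classes())
  if (length(bad)) {
    abort(paste0("unknown class_label: ", paste(bad, collapse = ", ")))
  }
  if (any(!is.na(genomes$genus) & genomes$class_label != "viral")) {
    abort("genus may be set only for viral records")
  }
  if (any(grepl("[^ACGTN]", genomes$sequence))) {
    abort("sequences must be over the alphabet {A,C,G,T,N}")
  }
  invisible(genomes)
}

#' @rdname validate_genomes
#' @export
genome_classes <- function() {
  c("viral", "prokaryote", "eukaryote", "plasmid", "archaea")
}

#' Read labeled genomes from FASTA plus a label table
#'
#' Reads reference sequences from a FASTA file (single-line or wrapped) and
#' joins the per-sequence truth labels from a tab-separated table with columns
#' `id`, `class_label` and optionally `genus`, `circular`.
#'
#' @param fasta_path path to a FASTA file of reference sequences
#' @param labels_path path to a TSV with columns `id`, `class_label`,
#'   optionally `genus` and `circular`
#' @return a validated genome tibble (see [validate_genomes()])
#' @export
read_genomes <- function(fasta_path, labels_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  labels <- readr::read_tsv(labels_path, comment = "#", show_col_types = FALSE)
  if (!all(c("id", "class_label") %in% names(labels))) {
    abort("label table needs columns: id, class_label")
  }
  missing <- setdiff(ids, labels$id)
  if (length(missing)) {
    abort(paste0("no label for sequence(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  g <- tibble(id = ids, sequence = as.character(seqs)) |>
    left_join(labels, by = "id")
  if ("circular" %in% names(g)) g$circular <- as.logical(g$circular)
  validate_genomes(g)
  as_tibble(g)
}

#' Write genomes (or any id/sequence table) to FASTA
#'
#' @param x a data frame with `id` and `sequence` columns
#' @param path output FASTA path; sequences are wrapped at 80 columns
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}
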