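#' Mock community designs
#'
#' A community design names a target mixture of sequence classes. The ratio
#' is ordered (viral, prokaryote, eukaryote, plasmid) and is anchored on the
#' viral count: `compose_community()` draws exactly `n_viral` viral fragments
#' and `round(n_viral / ratio[1] * ratio[i])` (half-up) fragments of every
#' other class.
#'
#' `community_designs()` returns the named presets for the four standard
#' virome / bulk-metagenome mixtures. Two of them exist in two variants
#' (`_a` / `_b`) because their eukaryote or plasmid proportion is reported
#' inconsistently across descriptions of the designs; neither variant is
#' preferred.
#'
#' @param name design name; `ratio` four non-negative numbers in class order
#'   (viral, prokaryote, eukaryote, plasmid) with `ratio[1] > 0`;
#'   `n_viral` the viral anchor count; `n_replicates` replicates to draw;
#'   `master_seed` single integer from which all per-replicate seeds derive
#' @return `community_design()`: a list of class `"community_design"`.
#'   `community_designs()`: a tibble of the presets with a `ratio` list-column.
#' @examples
#' community_designs()
#' community_design("bulk_2", c(1, 10, 1, 1), n_viral = 1695)
#' @export
community_design <- function(name, ratio, n_viral,
                             n_replicates = 4L, master_seed = 1L) {
  ratio <- as.numeric(ratio)
  stopifnot(length(ratio) == 4L, all(ratio >= 0), n_viral >= 1, n_replicates >= 1)
  if (ratio[1] <= 0) abort("viral ratio (first entry) must be positive")
  structure(
    list(
      name = as.character(name), ratio = ratio,
      n_viral = as.integer(n_viral),
      n_replicates = as.integer(n_replicates),
      master_seed = as.integer(master_seed)
    ),
    class = "community_design"
  )
}

#' @rdname community_design
#' @export
community_designs <- function() {
  tibble(
    name = c("virome_1a", "virome_1b", "virome_2", "bulk_1a", "bulk_1b", "bulk_2"),
    ratio = list(
      c(10, 1, 0.1, 0.001),
      c(10, 1, 0.1, 0.01),
      c(10, 1, 0.01, 1),
      c(1, 10, 0.01, 10),
      c(1, 10, 0.1, 10),
      c(1, 10, 1, 1)
    ),
    kind = c("virome", "virome", "virome", "bulk", "bulk", "bulk")
  )
}

#' @export
print.community_design <- function(x, ...) {
  cat("<community_design>", x$name, "\n")
  cat("  ratio (viral:prok:euk:plasmid):", paste(x$ratio, collapse = ":"), "\n")
  cat("  n_viral:", x$n_viral, " replicates:", x$n_replicates,
      " master_seed:", x$master_seed, "\n")
  invisible(x)
}

# per-class target counts for one design, anchored so viral is exact
design_target_counts <- function(design) {
  base <- design$n_viral / design$ratio[1]
  counts <- as.integer(round_half_up(base * design$ratio))
  counts[1] <- design$n_viral
  setNames(counts, c("viral", "prokaryote", "eukaryote", "plasmid"))
}

#' Compose one replicate of a mock community
#'
#' Draws fragments uniformly without replacement from each class pool at one
#' fragment length, at the class counts implied by the design ratio (see
#' [community_design()]). The RNG seed is derived deterministically as
#' `master_seed XOR hash(name, L, replicate_index)`, so a whole study is
#' reproducible from a single integer and every replicate gets an
#' independent, recorded seed.
#'
#' @param pools fragment table from [build_fragment_pools()]
#' @param design a [community_design()]
#' @param L fragment length to compose at (must be present in `pools`)
#' @param replicate_index which replicate to draw (1-based)
#' @param allow_exhaust if `TRUE`, a class pool smaller than its target is
#'   used in full and the shortfall recorded instead of erroring
#' @return a list of class `"community_manifest"` with fields `design`,
#'   `replicate_index`, `seed`, `members` (tibble: fragment_id, class_label,
#'   genus, length_class), `class_counts`, `shortfall`
#' @examples
#' g <- make_genomes(fixture_spec(n_per_class = c(viral = 4, prokaryote = 4,
#'   eukaryote = 1, plasmid = 1), seed = 1))
#' pools <- build_fragment_pools(g, lengths = 500)
#' compose_community(pools, community_design("demo", c(10, 1, 0.1, 0.01), 20), 500, 1)
#' @export
compose_community <- function(pools, design, L, replicate_index,
                              allow_exhaust = FALSE) {
  stopifnot(inherits(design, "community_design"))
  L <- as.integer(L)
  targets <- design_target_counts(design)
  seed <- replicate_seed(design$master_seed, design$name, L, replicate_index)
  at_L <- filter(pools, .data$length_class == L)
  if (!nrow(at_L)) abort(paste0("no fragments at length ", L, " in pools"))

  shortfall <- integer(0)
  members <- vector("list", length(targets))
  # draw classes in fixed order so one RNG stream yields reproducible rosters
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (k in seq_along(targets)) {
    cls <- names(targets)[k]
    want <- targets[[k]]
    if (want == 0L) next
    pool <- filter(at_L, .data$class_label == cls)
    if (nrow(pool) < want) {
      if (!allow_exhaust) abort(paste0("pool exhausted: ", cls))
      shortfall[cls] <- want - nrow(pool)
      want <- nrow(pool)
    }
    idx <- sample.int(nrow(pool), want)
    members[[k]] <- pool[sort(idx), c("fragment_id", "class_label", "genus", "length_class")]
  }
  members <- bind_rows(members)
  counts <- table(factor(members$class_label, levels = names(targets)))
  structure(
    list(
      design = design, replicate_index = as.integer(replicate_index),
      seed = seed, members = members,
      class_counts = setNames(as.integer(counts), names(targets)),
      shortfall = shortfall
    ),
    class = "community_manifest"
  )
}

#' @export
print.community_manifest <- function(x, ...) {
  cat("<community_manifest>", x$design$name,
      "replicate", x$replicate_index, "seed", x$seed, "\n")
  cat("  members:", nrow(x$members), "(",
      paste(names(x$class_counts), x$class_counts, sep = "=", collapse = ", "), ")\n")
  if (length(x$shortfall)) {
    cat("  shortfall:", paste(names(x$shortfall), x$shortfall, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.community_manifest <- function(x, ...) x$members

# save/restore the global RNG state so composing a community does not
# perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a composed community to FASTA plus a truth table
#'
#' Extracts each member fragment's subsequence from its parent genome and
#' writes (i) a FASTA whose headers are the fragment ids and (ii) a
#' tab-separated truth table. Coordinates in the truth table are 0-based
#' half-open (documented in its header comment). Reading the truth table
#' back with [read_truth()] reproduces the manifest roster exactly, in order.
#'
#' @param manifest a `community_manifest` from [compose_community()]
#' @param genomes the genome tibble the pools were built from
#' @param pools the fragment table from [build_fragment_pools()] (supplies
#'   fragment coordinates)
#' @param fasta_path,truth_path output paths
#' @return `truth_path`, invisibly
#' @export
write_community <- function(manifest, genomes, pools, fasta_path, truth_path) {
  stopifnot(inherits(manifest, "community_manifest"))
  frags <- manifest$members |>
    left_join(
      select(pools, "fragment_id", "parent_id", "start", "end"),
      by = "fragment_id"
    )
  if (anyNA(frags$parent_id)) abort("manifest member not resolvable in pools")
  frags <- left_join(frags, select(genomes, "id", "sequence"),
                     by = c(parent_id = "id"))
  frags$sequence <- substr(frags$sequence, frags$start + 1L, frags$end)
  write_fasta(rename(frags, id = "fragment_id"), fasta_path)

  header <- c(
    "# viromock truth table; coordinates are 0-based, half-open [start, end)",
    paste0("# design=", manifest$design$name,
           " replicate=", manifest$replicate_index,
           " seed=", manifest$seed)
  )
  truth <- frags |>
    mutate(is_viral = as.integer(.data$class_label == "viral")) |>
    select("fragment_id", "parent_id", "class_label", "is_viral",
           "genus", "length_class", "start", "end")
  writeLines(header, truth_path)
  readr::write_tsv(truth, truth_path, append = TRUE, col_names = TRUE, na = "NA")
  invisible(truth_path)
}

#' Read a truth table written by [write_community()]
#'
#' @param path path to the truth TSV
#' @return a tibble with the truth columns; `is_viral` is logical
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(genus = readr::col_character())) |>
    mutate(is_viral = as.logical(.data$is_viral))
}
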